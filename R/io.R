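#' @importFrom data.table fread fwrite setDF
NULL

# orientation + validation shared by readWeights() and the simulator.
# Rows with OR < 1 are flipped (alleles swapped, OR inverted) so that the
# stored odds ratio always refers to the risk allele and weight >= 0.
makeWeightTable <- function(df, quiet = FALSE) {
    need <- c("variant_id", "risk_allele", "odds_ratio")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("weight table is missing columns: ", paste(miss, collapse = ", "))
    if (any(!is.finite(df$odds_ratio)) || any(df$odds_ratio <= 0))
        stop("odds ratios must be positive and finite")
    for (col in c("chrom", "pos", "other_allele", "locus_label", "categories")) {
        if (!col %in% colnames(df))
            df[[col]] <- if (col == "pos") NA_integer_ else NA_character_
    }
    flip <- df$odds_ratio < 1
    if (any(flip)) {
        if (!quiet)
            message("re-oriented ", sum(flip), " variant(s) with OR < 1 to the risk allele: ",
                    paste(df$variant_id[flip], collapse = ", "))
        tmp <- df$risk_allele[flip]
        df$risk_allele[flip] <- df$other_allele[flip]
        df$other_allele[flip] <- tmp
        df$odds_ratio[flip] <- 1 / df$odds_ratio[flip]
    }
    if (any(df$odds_ratio == 1))
        warning("variant(s) with OR = 1 carry zero GRS weight: ",
                paste(df$variant_id[df$odds_ratio == 1], collapse = ", "))
    df$weight <- log(df$odds_ratio)
    df$categories[is.na(df$categories)] <- ""
    df$locus_label[is.na(df$locus_label)] <- ""
    df <- df[, c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
                 "odds_ratio", "weight", "locus_label", "categories")]
    rownames(df) <- NULL
    new("VariantWeightTable", table = df)
}

#' Read a variant weight table
#'
#' Expects a TSV with at least \code{variant_id}, \code{risk_allele} and
#' \code{odds_ratio} columns (optionally \code{chrom}, \code{pos},
#' \code{other_allele}, \code{locus_label}, \code{categories}). The GRS
#' weight is the natural log of the odds ratio; rows with OR < 1 are
#' re-oriented (alleles swapped, OR inverted) so every stored weight is
#' non-negative, and the re-orientation is reported.
#'
#' @param path TSV file path.
#' @return a \linkS4class{VariantWeightTable}.
#' @export
readWeights <- function(path) {
    df <- setDF(fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = "variant_id")))
    makeWeightTable(df)
}

#' Write a variant weight table
#'
#' @param weights a \linkS4class{VariantWeightTable}.
#' @param path output TSV path.
#' @export
writeWeights <- function(weights, path) {
    fwrite(weightTable(weights), path, sep = "\t", quote = FALSE)
    invisible(path)
}

# ---- genotype readers -------------------------------------------------------

# apply the variant exclusion rules to a raw dosage matrix; `missing` and
# `multiallelic` counts may be precomputed by the VCF parser
.filterGenotypes <- function(dosage, meta, mafFloor, report) {
    isMissing <- apply(dosage, 2L, anyNA)
    report$missing <- report$missing + sum(isMissing)
    dosage <- dosage[, !isMissing, drop = FALSE]
    meta <- meta[!isMissing, , drop = FALSE]
    maf <- dosageMAF(dosage)
    lowMaf <- maf < mafFloor
    report$low_maf <- sum(lowMaf)
    dosage <- dosage[, !lowMaf, drop = FALSE]
    meta <- meta[!lowMaf, , drop = FALSE]
    meta$maf <- as.numeric(maf[!lowMaf])
    if (ncol(dosage) == 0)
        stop("no variants survive the exclusion filters (multiallelic: ",
             report$multiallelic, ", missing: ", report$missing,
             ", low MAF: ", report$low_maf, ")")
    report$retained <- ncol(dosage)
    newGenotypeMatrix(dosage, meta, report)
}

.readGenotypesVCF <- function(path, mafFloor, weights) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    report <- list(multiallelic = 0L, missing = 0L, low_maf = 0L, retained = 0L)

    multi <- grepl(",", fix$ALT, fixed = TRUE)
    report$multiallelic <- sum(multi)
    if (all(multi)) stop("no biallelic variants in ", path)
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]

    gt <- vcfR::extract.gt(vcf, element = "GT")
    # allele counts of ALT, NA for missing calls
    alt <- apply(gt, c(1, 2), function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
    })
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    rownames(alt) <- ids

    # dosage of the risk allele: ALT by default, flipped/oriented by the
    # weight table when one is supplied
    dosage <- t(alt)
    risk <- fix$ALT
    other <- fix$REF
    if (!is.null(weights)) {
        wt <- weightTable(weights)
        keep <- rep(TRUE, ncol(dosage))
        for (j in seq_len(ncol(dosage))) {
            i <- match(colnames(dosage)[j], wt$variant_id)
            if (is.na(i)) next
            if (identical(wt$risk_allele[i], fix$REF[j])) {
                dosage[, j] <- 2L - dosage[, j]
                risk[j] <- fix$REF[j]
                other[j] <- fix$ALT[j]
            } else if (!identical(wt$risk_allele[i], fix$ALT[j])) {
                warning("risk allele of ", colnames(dosage)[j],
                        " matches neither REF nor ALT; variant dropped")
                keep[j] <- FALSE
            }
        }
        dosage <- dosage[, keep, drop = FALSE]
        risk <- risk[keep]; other <- other[keep]
        fix <- fix[keep, , drop = FALSE]
    }
    meta <- data.frame(
        chrom = fix$CHROM, pos = as.integer(fix$POS),
        risk_allele = risk, other_allele = other,
        maf = NA_real_, row.names = colnames(dosage), stringsAsFactors = FALSE
    )
    .filterGenotypes(dosage, meta, mafFloor, report)
}

.readGenotypesTSV <- function(path, mafFloor) {
    df <- setDF(fread(path, sep = "\t", header = TRUE))
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (length(m) && !all(is.na(m) | m %in% c(0, 1, 2)))
        stop("malformed dosage TSV ", path, ": entries must be 0/1/2 or missing")
    dosage <- t(m)
    colnames(dosage) <- ids
    rownames(dosage) <- colnames(df)[-1]
    meta <- data.frame(
        chrom = rep(NA_character_, length(ids)), pos = rep(NA_integer_, length(ids)),
        risk_allele = rep(NA_character_, length(ids)),
        other_allele = rep(NA_character_, length(ids)),
        maf = rep(NA_real_, length(ids)), row.names = ids, stringsAsFactors = FALSE
    )
    report <- list(multiallelic = 0L, missing = 0L, low_maf = 0L, retained = 0L)
    .filterGenotypes(dosage, meta, mafFloor, report)
}

#' Read genotype dosages with variant exclusion filters
#'
#' Loads hard-called genotypes from VCF v4.2 (GT field) or a dosage TSV
#' (rows = variants, first column the variant identifier, remaining columns
#' samples) and applies the exclusion rules used to assemble the analysis
#' panel: multi-allelic records are dropped, variants with any missing call
#' are dropped (no imputation), and variants whose sample minor allele
#' frequency falls below \code{mafFloor} are dropped. The per-rule counts
#' are recorded in the returned object's load report.
#'
#' For VCF input the dosage counts ALT alleles unless a weight table is
#' supplied, in which case each variant is oriented to its risk allele.
#' TSV input is assumed to already hold risk-allele dosages.
#'
#' @param path input file.
#' @param format \code{"vcf"} or \code{"tsv"} (default: guessed from the
#'   file extension).
#' @param mafFloor minor allele frequency floor in [0, 0.5); the reference
#'   analysis used 0.05.
#' @param weights optional \linkS4class{VariantWeightTable} used to orient
#'   dosages to the risk allele.
#' @return a \linkS4class{GenotypeMatrix}; see [loadReport()] for the
#'   exclusion accounting.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          mafFloor = 0.05, weights = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (mafFloor < 0 || mafFloor >= 0.5)
        stop("mafFloor must be in [0, 0.5)")
    if (!file.exists(path)) stop("genotype file not found: ", path)
    if (format == "vcf") .readGenotypesVCF(path, mafFloor, weights)
    else .readGenotypesTSV(path, mafFloor)
}

#' Read a gene expression matrix
#'
#' TSV with rows = genes (first column the gene identifier) and columns =
#' samples; values are normalized continuous expression levels.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
    df <- setDF(fread(path, sep = "\t", header = TRUE))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
    m
}

#' Write a gene expression matrix
#' @param expression genes x samples matrix.
#' @param path output TSV path.
#' @export
writeExpression <- function(expression, path) {
    fwrite(data.table::data.table(gene_id = rownames(expression), expression),
           path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a covariate table
#'
#' TSV with first column \code{sample_id}; character columns are treated as
#' categorical and converted to factors.
#'
#' @param path TSV file path.
#' @return data.frame with sample rownames.
#' @export
readCovariates <- function(path) {
    df <- setDF(fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = 1)))
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
    for (col in colnames(df))
        if (is.character(df[[col]])) df[[col]] <- factor(df[[col]])
    df
}

#' Write a covariate table
#' @param covariates data.frame with sample rownames.
#' @param path output TSV path.
#' @export
writeCovariates <- function(covariates, path) {
    fwrite(data.table::data.table(sample_id = rownames(covariates), covariates),
           path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Read a variant category annotation
#'
#' TSV with columns \code{category} and \code{variant_id}; categories are
#' consumed as a prebuilt annotation (how variants were assigned to
#' biological pathways is upstream of this package).
#'
#' @param path TSV file path.
#' @param weights optional \linkS4class{VariantWeightTable}; when given,
#'   every annotated variant must exist in it.
#' @return named list mapping category -> character vector of variant ids.
#' @export
readCategories <- function(path, weights = NULL) {
    df <- setDF(fread(path, sep = "\t", header = TRUE, colClasses = "character"))
    if (!all(c("category", "variant_id") %in% colnames(df)))
        stop("category annotation needs columns: category, variant_id")
    if (!is.null(weights)) {
        unknown <- setdiff(df$variant_id, variantIDs(weights))
        if (length(unknown))
            stop("annotated variants absent from the weight table: ",
                 paste(unknown, collapse = ", "))
    }
    split(df$variant_id, df$category)
}

#' Join genotypes, expression and covariates on the common sample set
#'
#' Restricts all three inputs to the intersection of their sample
#' identifiers and reorders them identically (sorted by sample ID), the
#' deterministic analysis order used by every downstream stage.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param expression genes x samples matrix.
#' @param covariates data.frame with sample rownames, or \code{NULL} for a
#'   covariate-free analysis.
#' @return a \linkS4class{GrsCohort}.
#' @export
alignCohort <- function(genotypes, expression, covariates = NULL) {
    gIds <- sampleIDs(genotypes)
    eIds <- colnames(expression)
    cIds <- if (is.null(covariates)) gIds else rownames(covariates)
    common <- sort(Reduce(intersect, list(gIds, eIds, cIds)))
    if (!length(common))
        stop("no samples shared across inputs (genotypes: ", length(gIds),
             ", expression: ", length(eIds), ", covariates: ", length(cIds), ")")
    geno <- newGenotypeMatrix(genotypes@dosage[common, , drop = FALSE],
                              genotypes@variantMeta, genotypes@loadReport)
    cov <- if (is.null(covariates))
        data.frame(row.names = common)
    else droplevels(covariates[common, , drop = FALSE])
    new("GrsCohort",
        genotypes = geno,
        expression = expression[, common, drop = FALSE],
        covariates = cov)
}

#' Write / read association records
#'
#' Association records are exchanged as TSV with columns
#' \code{combination} (canonical \code{"+"}-joined key), \code{gene_id},
#' \code{n_low}, \code{n_high}, \code{es}, \code{se}, \code{p}, \code{q};
#' numeric values round-trip to full double precision.
#'
#' @param records data.frame of association records.
#' @param path TSV file path.
#' @return \code{readAssociations} returns the records data.frame.
#' @export
writeAssociations <- function(records, path) {
    cols <- c("combination", "gene_id", "n_low", "n_high", "es", "se", "p", "q")
    miss <- setdiff(cols, colnames(records))
    if (length(miss))
        stop("association records are missing columns: ", paste(miss, collapse = ", "))
    fwrite(records[, cols, drop = FALSE], path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname writeAssociations
#' @export
readAssociations <- function(path) {
    df <- setDF(fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = c("combination", "gene_id"))))
    need <- c("combination", "gene_id", "n_low", "n_high", "es", "se", "p", "q")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("association file is missing columns: ", paste(miss, collapse = ", "))
    df
}
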