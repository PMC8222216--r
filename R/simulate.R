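#' Construct a planted regulatory effect
#'
#' @param geneId target gene.
#' @param variantSet variants carrying the effect.
#' @param perVariantBeta expression change per risk allele (same slope, same
#'   sign, for every variant in the set).
#' @param mode \code{"single_cis"} (one variant) or \code{"joint_additive"}
#'   (the summation-of-small-unidirectional-effects model of epistasis).
#' @return a \linkS4class{PlantedEffect}.
#' @export
plantedEffect <- function(geneId, variantSet, perVariantBeta,
                          mode = c("joint_additive", "single_cis")) {
    new("PlantedEffect", geneId = as.character(geneId),
        variantSet = as.character(variantSet),
        perVariantBeta = as.numeric(perVariantBeta),
        mode = match.arg(mode))
}

#' Covariate structure of the reference cohort
#'
#' Age, sex, source study (4 levels, mirroring a cohort assembled from four
#' studies) and five genotype principal components, with modest expression
#' effects so that covariate adjustment is actually exercised.
#'
#' @param effects named numeric vector of effect scales (expression units)
#'   overriding the defaults.
#' @return data.frame with columns \code{name}, \code{kind}, \code{effect},
#'   \code{levels}.
#' @export
defaultCovariateSpec <- function(effects = c()) {
    spec <- data.frame(
        name = c("age", "sex", "study", paste0("pc", 1:5)),
        kind = c("continuous", "categorical", "categorical", rep("pc", 5)),
        effect = c(0.3, 0.2, 0.3, rep(0.1, 5)),
        levels = c(NA, 2L, 4L, rep(NA, 5)),
        stringsAsFactors = FALSE
    )
    if (length(effects)) {
        i <- match(names(effects), spec$name)
        spec$effect[i[!is.na(i)]] <- effects[!is.na(i)]
    }
    spec
}

#' Assemble a synthetic cohort configuration
#'
#' Defaults describe the demonstration-scale study conditions: 600
#' individuals, a 7-variant weighted panel with MAF drawn uniformly in
#' [0.05, 0.5] (matching the 5\% MAF floor of the reference panel), 500
#' genes with unit Gaussian noise, odds ratios log-uniform in [1.05, 2.0],
#' and the default covariate structure.
#'
#' @param nIndividuals,nVariants,nGenes cohort dimensions.
#' @param mafRange length-2 MAF sampling interval within (0, 0.5].
#' @param noiseSd expression noise standard deviation.
#' @param covariateSpec see [defaultCovariateSpec()].
#' @param plantedEffects list of \linkS4class{PlantedEffect}.
#' @param orRange odds-ratio sampling interval (log-uniform).
#' @param seed master seed; all generator randomness derives from it.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nIndividuals = 600, nVariants = 7,
                             mafRange = c(0.05, 0.5), nGenes = 500,
                             noiseSd = 1,
                             covariateSpec = defaultCovariateSpec(),
                             plantedEffects = list(),
                             orRange = c(1.05, 2.0), seed = 1) {
    new("SimulationConfig",
        nIndividuals = as.integer(nIndividuals),
        nVariants = as.integer(nVariants),
        mafRange = as.numeric(mafRange),
        nGenes = as.integer(nGenes),
        noiseSd = as.numeric(noiseSd),
        covariateSpec = covariateSpec,
        plantedEffects = plantedEffects,
        orRange = as.numeric(orRange),
        seed = as.integer(seed))
}

.sampleIdsFor <- function(n) sprintf("ind%04d", seq_len(n))
.variantIdsFor <- function(m) sprintf("snp%03d", seq_len(m))
.geneIdsFor <- function(g) sprintf("gene%05d", seq_len(g))

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws one minor allele frequency per variant uniformly from
#' \code{mafRange} and samples risk-allele dosages as Binomial(2, MAF),
#' i.e. independent variants in Hardy-Weinberg equilibrium with genotype
#' frequencies \eqn{(1-p)^2, 2p(1-p), p^2}. The risk allele is the minor
#' allele; variant metadata records the true sampled MAF.
#'
#' @param nIndividuals cohort size.
#' @param nVariants panel size.
#' @param mafRange length-2 interval within (0, 0.5].
#' @param seed RNG seed; a fixed seed gives bit-identical matrices.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(nIndividuals, nVariants, mafRange = c(0.05, 0.5),
                              seed = 1) {
    if (length(mafRange) != 2 || any(mafRange <= 0) || any(mafRange > 0.5) ||
        mafRange[1] > mafRange[2])
        stop("mafRange must lie within (0, 0.5] with min <= max")
    withSeed(seed, {
        maf <- stats::runif(nVariants, mafRange[1], mafRange[2])
        d <- matrix(stats::rbinom(nIndividuals * nVariants, 2L,
                                  rep(maf, each = nIndividuals)),
                    nrow = nIndividuals, ncol = nVariants,
                    dimnames = list(.sampleIdsFor(nIndividuals),
                                    .variantIdsFor(nVariants)))
        alleles <- t(vapply(seq_len(nVariants),
                            function(i) sample(c("A", "C", "G", "T"), 2L),
                            character(2)))
        meta <- data.frame(
            chrom = as.character(sample(1:22, nVariants, replace = TRUE)),
            pos = sort(sample.int(1e8, nVariants)),
            risk_allele = alleles[, 1], other_allele = alleles[, 2],
            maf = maf, row.names = colnames(d), stringsAsFactors = FALSE
        )
        newGenotypeMatrix(d, meta)
    })
}

#' Simulate a GWAS-style variant weight table
#'
#' Odds ratios are drawn log-uniformly from \code{orRange}; weights are
#' their natural logs (all non-negative, so no orientation is needed).
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} supplying variant ids,
#'   alleles and positions.
#' @param orRange odds-ratio interval.
#' @param seed RNG seed.
#' @return a \linkS4class{VariantWeightTable}.
#' @export
simulateWeights <- function(genotypes, orRange = c(1.05, 2.0), seed = 1) {
    meta <- variantMeta(genotypes)
    withSeed(seed, {
        or <- exp(stats::runif(nrow(meta), log(orRange[1]), log(orRange[2])))
        makeWeightTable(data.frame(
            variant_id = rownames(meta),
            chrom = meta$chrom, pos = meta$pos,
            risk_allele = meta$risk_allele, other_allele = meta$other_allele,
            odds_ratio = or,
            locus_label = paste0("locus_", seq_len(nrow(meta))),
            categories = "",
            stringsAsFactors = FALSE
        ), quiet = TRUE)
    })
}

#' Simulate per-sample covariates
#'
#' Continuous covariates and principal components are standard normal;
#' categorical covariates get balanced, randomly permuted labels.
#'
#' @param nIndividuals cohort size.
#' @param covariateSpec data.frame as in [defaultCovariateSpec()]; zero rows
#'   give a covariate-free table.
#' @param seed RNG seed.
#' @return data.frame with sample rownames.
#' @export
simulateCovariates <- function(nIndividuals, covariateSpec = defaultCovariateSpec(),
                               seed = 1) {
    ids <- .sampleIdsFor(nIndividuals)
    out <- data.frame(row.names = ids)
    if (is.null(covariateSpec) || nrow(covariateSpec) == 0) return(out)
    withSeed(seed, {
        for (i in seq_len(nrow(covariateSpec))) {
            kind <- covariateSpec$kind[i]
            nm <- covariateSpec$name[i]
            if (kind %in% c("continuous", "pc")) {
                out[[nm]] <- stats::rnorm(nIndividuals)
            } else {
                k <- covariateSpec$levels[i]
                if (is.na(k) || k < 2) stop("categorical covariate ", nm,
                                            " needs >= 2 levels")
                out[[nm]] <- factor(sample(rep_len(paste0(nm, seq_len(k)),
                                                   nIndividuals)))
            }
        }
        out
    })
}

#' Per-sample covariate contribution to expression
#'
#' The generative model adds the same covariate term to every gene:
#' continuous covariates contribute \code{effect * x}; each level of a
#' categorical covariate contributes a fixed, seed-derived N(0, effect)
#' offset. Exposed so the analytic variance of a simulated gene
#' (covariate variance + noise variance) can be computed exactly.
#'
#' @param covariates data.frame from [simulateCovariates()].
#' @param covariateSpec matching spec with effect sizes.
#' @param seed seed for the categorical level offsets.
#' @return numeric vector, one value per sample.
#' @export
covariateContribution <- function(covariates, covariateSpec, seed = 1) {
    contrib <- numeric(nrow(covariates))
    if (is.null(covariateSpec) || nrow(covariateSpec) == 0) return(contrib)
    withSeed(seed, {
        for (i in seq_len(nrow(covariateSpec))) {
            nm <- covariateSpec$name[i]
            eff <- covariateSpec$effect[i]
            x <- covariates[[nm]]
            if (is.null(x)) stop("covariate ", nm, " missing from table")
            if (is.numeric(x)) {
                contrib <- contrib + eff * x
            } else {
                lev <- levels(x)
                levEff <- stats::rnorm(length(lev), 0, eff)
                contrib <- contrib + levEff[as.integer(x)]
            }
        }
        contrib
    })
}

#' Simulate gene expression with planted regulatory structure
#'
#' Generates \deqn{y_{gj} = \sum_{\mathrm{planted}(g)} \beta \sum_{v \in S}
#' d_{jv} + c_j + \varepsilon_{gj}} where \eqn{c_j} is the shared covariate
#' contribution and \eqn{\varepsilon \sim N(0, \sigma^2)} with
#' \eqn{\sigma = } \code{noiseSd}. Genes without a planted effect are pure
#' nulls (covariates + noise only). The returned truth table records every
#' planted effect; it is the ground truth against which recovery and false
#' discovery are measured.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param covariates data.frame from [simulateCovariates()].
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{expression} (genes x samples matrix) and
#'   \code{truth} (data.frame gene_id, variant_set, per_variant_beta, mode).
#' @export
simulateExpression <- function(genotypes, covariates, config) {
    d <- dosages(genotypes)
    n <- nrow(d)
    g <- config@nGenes
    genes <- .geneIdsFor(g)
    for (pe in config@plantedEffects) {
        if (!pe@geneId %in% genes)
            stop("planted effect references unknown gene: ", pe@geneId)
        unknown <- setdiff(pe@variantSet, colnames(d))
        if (length(unknown))
            stop("planted effect references unknown variant(s): ",
                 paste(unknown, collapse = ", "))
    }
    contrib <- covariateContribution(covariates, config@covariateSpec,
                                     seed = config@seed + 1L)
    expr <- withSeed(config@seed + 2L, {
        matrix(stats::rnorm(g * n, 0, config@noiseSd), nrow = g, ncol = n,
               dimnames = list(genes, rownames(d)))
    })
    expr <- sweep(expr, 2L, contrib, "+")
    for (pe in config@plantedEffects) {
        load <- pe@perVariantBeta *
            rowSums(d[, pe@variantSet, drop = FALSE])
        expr[pe@geneId, ] <- expr[pe@geneId, ] + load
    }
    truth <- if (length(config@plantedEffects)) {
        data.frame(
            gene_id = vapply(config@plantedEffects, slot, character(1), "geneId"),
            variant_set = vapply(config@plantedEffects,
                                 function(pe) canonicalCombination(pe@variantSet),
                                 character(1)),
            per_variant_beta = vapply(config@plantedEffects, slot, numeric(1),
                                      "perVariantBeta"),
            mode = vapply(config@plantedEffects, slot, character(1), "mode"),
            stringsAsFactors = FALSE
        )
    } else {
        data.frame(gene_id = character(), variant_set = character(),
                   per_variant_beta = numeric(), mode = character(),
                   stringsAsFactors = FALSE)
    }
    list(expression = expr, truth = truth)
}

#' Simulate a complete aligned cohort
#'
#' Runs the generator end to end: genotypes, weight table, covariates and
#' expression, aligned into a \linkS4class{GrsCohort}. All randomness
#' derives from \code{config@seed} (sub-stages use fixed offsets of it), so
#' a fixed configuration reproduces bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{cohort} (\linkS4class{GrsCohort}),
#'   \code{weights} (\linkS4class{VariantWeightTable}) and \code{truth}.
#' @export
simulateCohort <- function(config) {
    geno <- simulateGenotypes(config@nIndividuals, config@nVariants,
                              config@mafRange, seed = config@seed)
    weights <- simulateWeights(geno, config@orRange, seed = config@seed + 3L)
    cov <- simulateCovariates(config@nIndividuals, config@covariateSpec,
                              seed = config@seed + 4L)
    sim <- simulateExpression(geno, cov, config)
    cohort <- alignCohort(geno, sim$expression, cov)
    list(cohort = cohort, weights = weights, truth = sim$truth)
}

# minimal VCF v4.2 writer (GT-only FORMAT); plain text so fixtures stay
# diffable, reread with vcfR
.writeVCF <- function(genotypes, path, extraMultiallelic = FALSE) {
    d <- dosages(genotypes)
    meta <- variantMeta(genotypes)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
    gtCodes <- c("0/0", "0/1", "1/1")
    chrom <- meta$chrom
    chrom[is.na(chrom)] <- "1"
    pos <- meta$pos
    pos[is.na(pos)] <- seq_len(nrow(meta))[is.na(pos)] * 1000L
    refA <- meta$other_allele; refA[is.na(refA)] <- "A"
    altA <- meta$risk_allele; altA[is.na(altA)] <- "C"
    for (j in seq_len(ncol(d))) {
        writeLines(paste(c(chrom[j], pos[j], colnames(d)[j], refA[j], altA[j],
                           ".", "PASS", ".", "GT", gtCodes[d[, j] + 1L]),
                         collapse = "\t"), con)
    }
    if (extraMultiallelic) {
        n <- nrow(d)
        gts <- rep(c("0/1", "1/2", "0/0", "2/2"), length.out = n)
        writeLines(paste(c("1", "999999999", "snpMULTI", "A", "C,G", ".",
                           "PASS", ".", "GT", gts), collapse = "\t"), con)
    }
    invisible(path)
}

#' Write a simulated cohort as a plain-text fixture set
#'
#' Emits the cohort in the exchange formats read by the package's loaders:
#' genotypes as both VCF v4.2 and dosage TSV, expression TSV, covariate
#' TSV, weight TSV and the planted-effect truth TSV. The set round-trips
#' losslessly through [readGenotypes()], [readExpression()],
#' [readCovariates()] and [readWeights()], and is byte-identical across
#' runs under a fixed seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outputDir writable directory (created if needed).
#' @param multiallelic if TRUE the VCF additionally carries one
#'   multi-allelic record, which the reader must drop.
#' @return named character vector of the six file paths, invisibly.
#' @export
writeFixture <- function(config, outputDir, multiallelic = FALSE) {
    if (!dir.exists(outputDir) &&
        !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create fixture directory: ", outputDir)
    sim <- simulateCohort(config)
    geno <- genotypes(sim$cohort)
    paths <- c(
        vcf = file.path(outputDir, "genotypes.vcf"),
        genotypes = file.path(outputDir, "genotypes.tsv"),
        expression = file.path(outputDir, "expression.tsv"),
        covariates = file.path(outputDir, "covariates.tsv"),
        weights = file.path(outputDir, "weights.tsv"),
        truth = file.path(outputDir, "truth.tsv")
    )
    .writeVCF(geno, paths["vcf"], extraMultiallelic = multiallelic)
    fwrite(data.table::data.table(variant_id = variantIDs(geno),
                                  t(dosages(geno))),
           paths["genotypes"], sep = "\t", quote = FALSE)
    writeExpression(exprMatrix(sim$cohort), paths["expression"])
    writeCovariates(covariates(sim$cohort), paths["covariates"])
    writeWeights(sim$weights, paths["weights"])
    fwrite(sim$truth, paths["truth"], sep = "\t", quote = FALSE)
    invisible(paths)
}
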