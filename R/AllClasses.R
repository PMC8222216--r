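#' @import methods
NULL

#' GenotypeMatrix: risk-allele dosages with per-variant metadata
#'
#' Container for hard-called biallelic genotypes coded as risk-allele dosages
#' (0, 1 or 2 copies), one row per individual and one column per variant,
#' together with per-variant metadata (chromosome, position, risk and other
#' allele, minor allele frequency computed on the loaded sample set) and the
#' load report produced by the exclusion filters applied at read time.
#'
#' @slot dosage integer-valued matrix, individuals x variants, entries in
#'   \{0, 1, 2\}; rownames are sample identifiers, colnames variant identifiers.
#' @slot variantMeta data.frame keyed by variant identifier with columns
#'   \code{chrom}, \code{pos}, \code{risk_allele}, \code{other_allele},
#'   \code{maf}.
#' @slot loadReport list of per-rule exclusion counts
#'   (\code{multiallelic}, \code{missing}, \code{low_maf}) recorded when the
#'   object was built by a reader; empty for simulated data.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
    representation(
        dosage = "matrix",
        variantMeta = "data.frame",
        loadReport = "list"
    )
)

setValidity("GenotypeMatrix", function(object) {
    d <- object@dosage
    msg <- character()
    if (is.null(rownames(d)) || is.null(colnames(d)))
        msg <- c(msg, "dosage matrix must have sample rownames and variant colnames")
    if (anyNA(d))
        msg <- c(msg, "dosage matrix contains missing values")
    else if (length(d) && !all(d %in% c(0, 1, 2)))
        msg <- c(msg, "dosages must be 0, 1 or 2")
    if (anyDuplicated(rownames(d)))
        msg <- c(msg, "sample identifiers must be unique")
    if (anyDuplicated(colnames(d)))
        msg <- c(msg, "variant identifiers must be unique")
    if (!identical(rownames(object@variantMeta), colnames(d)))
        msg <- c(msg, "variantMeta rows must match dosage columns")
    need <- c("chrom", "pos", "risk_allele", "other_allele", "maf")
    if (!all(need %in% colnames(object@variantMeta)))
        msg <- c(msg, paste("variantMeta must have columns:",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' VariantWeightTable: GWAS-derived per-variant GRS weights
#'
#' One row per variant: the risk allele, the GWAS odds ratio and its natural
#' logarithm (the GRS weight), a free-text locus label, and optional category
#' tags. Rows are oriented at construction so that the odds ratio refers to
#' the risk allele and the weight is non-negative.
#'
#' @slot table data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{risk_allele}, \code{other_allele}, \code{odds_ratio},
#'   \code{weight}, \code{locus_label}, \code{categories} (comma-separated
#'   tags, possibly empty).
#'
#' @aliases VariantWeightTable-class
#' @exportClass VariantWeightTable
setClass("VariantWeightTable", representation(table = "data.frame"))

setValidity("VariantWeightTable", function(object) {
    tb <- object@table
    msg <- character()
    need <- c("variant_id", "risk_allele", "other_allele", "odds_ratio",
              "weight", "locus_label", "categories")
    if (!all(need %in% colnames(tb)))
        return(paste("weight table must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tb$variant_id))
        msg <- c(msg, "variant identifiers must be unique")
    if (any(!is.finite(tb$odds_ratio)) || any(tb$odds_ratio <= 0))
        msg <- c(msg, "odds ratios must be positive and finite")
    if (nrow(tb) && !isTRUE(all.equal(tb$weight, log(tb$odds_ratio), tolerance = 1e-12)))
        msg <- c(msg, "weight must equal ln(odds_ratio)")
    if (any(tb$weight < 0))
        msg <- c(msg, "weights must be >= 0 after risk-allele orientation")
    if (length(msg)) msg else TRUE
})

#' GrsCohort: an aligned genotype / expression / covariate cohort
#'
#' The joined analysis view: a \linkS4class{GenotypeMatrix}, a gene x sample
#' expression matrix and a per-sample covariate table, all restricted to the
#' same samples in the same (sorted) order.
#'
#' @slot genotypes \linkS4class{GenotypeMatrix}.
#' @slot expression numeric matrix, genes x individuals, with gene rownames
#'   and sample colnames.
#' @slot covariates data.frame of per-sample covariates (possibly zero
#'   columns), rownames are sample identifiers.
#'
#' @aliases GrsCohort-class
#' @exportClass GrsCohort
setClass("GrsCohort",
    representation(
        genotypes = "GenotypeMatrix",
        expression = "matrix",
        covariates = "data.frame"
    )
)

setValidity("GrsCohort", function(object) {
    ids <- rownames(object@genotypes@dosage)
    msg <- character()
    if (!identical(colnames(object@expression), ids))
        msg <- c(msg, "expression columns must match genotype samples (same order)")
    if (!identical(rownames(object@covariates), ids))
        msg <- c(msg, "covariate rows must match genotype samples (same order)")
    if (length(object@expression) && any(!is.finite(object@expression)))
        msg <- c(msg, "expression values must be finite")
    if (is.null(rownames(object@expression)))
        msg <- c(msg, "expression matrix must have gene rownames")
    if (length(msg)) msg else TRUE
})

#' RiskAssignment: quantile risk-group labels for one combination
#'
#' Per-individual low / high / excluded labels obtained by ranking the
#' normalized GRS of one variant combination and taking the bottom and top
#' q-quantile groups of equal size \code{floor(q * n)}.
#'
#' @slot combination character vector of variant identifiers (canonical
#'   sorted order).
#' @slot q quantile fraction in (0, 0.5].
#' @slot labels factor with levels \code{low}, \code{excluded}, \code{high},
#'   named by sample identifier.
#' @slot nLow,nHigh group sizes (equal by construction).
#'
#' @aliases RiskAssignment-class
#' @exportClass RiskAssignment
setClass("RiskAssignment",
    representation(
        combination = "character",
        q = "numeric",
        labels = "factor",
        nLow = "integer",
        nHigh = "integer"
    )
)

setValidity("RiskAssignment", function(object) {
    msg <- character()
    if (!identical(levels(object@labels), c("low", "excluded", "high")))
        msg <- c(msg, "labels must have levels low, excluded, high")
    if (sum(object@labels == "low") != object@nLow ||
        sum(object@labels == "high") != object@nHigh)
        msg <- c(msg, "label counts disagree with nLow/nHigh")
    if (object@nLow != object@nHigh)
        msg <- c(msg, "low and high groups must have equal size")
    if (length(msg)) msg else TRUE
})

#' PlantedEffect: one regulatory effect wired into a simulated cohort
#'
#' Describes either a single-variant cis effect (\code{mode = "single_cis"})
#' or a joint additive effect spread over several variants
#' (\code{mode = "joint_additive"}), in which case the same per-variant
#' slope (shared sign) applies to every member of the variant set.
#'
#' @slot geneId target gene identifier.
#' @slot variantSet variant identifiers carrying the effect.
#' @slot perVariantBeta expression change per risk allele, identical for all
#'   members of the set.
#' @slot mode \code{"single_cis"} or \code{"joint_additive"}.
#'
#' @aliases PlantedEffect-class
#' @exportClass PlantedEffect
setClass("PlantedEffect",
    representation(
        geneId = "character",
        variantSet = "character",
        perVariantBeta = "numeric",
        mode = "character"
    )
)

setValidity("PlantedEffect", function(object) {
    msg <- character()
    if (length(object@variantSet) < 1)
        msg <- c(msg, "variantSet must be non-empty")
    if (!object@mode %in% c("single_cis", "joint_additive"))
        msg <- c(msg, "mode must be single_cis or joint_additive")
    if (object@mode == "single_cis" && length(object@variantSet) != 1)
        msg <- c(msg, "single_cis effects must have exactly one variant")
    if (length(object@perVariantBeta) != 1 || !is.finite(object@perVariantBeta))
        msg <- c(msg, "perVariantBeta must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: full description of a synthetic cohort
#'
#' All knobs of the generator: cohort and panel sizes, the minor allele
#' frequency range used for Hardy-Weinberg genotype sampling, the expression
#' noise level, covariate structure, odds-ratio range for the simulated
#' weight table, the planted regulatory effects and the master seed.
#'
#' @slot nIndividuals number of individuals (>= 4).
#' @slot nVariants number of variants in the weighted panel.
#' @slot mafRange length-2 numeric in (0, 0.5]; per-variant MAF is drawn
#'   uniformly from this interval.
#' @slot nGenes number of genes in the expression matrix.
#' @slot noiseSd standard deviation of Gaussian expression noise (> 0).
#' @slot covariateSpec data.frame with columns \code{name},
#'   \code{kind} (\code{continuous}, \code{categorical} or \code{pc}),
#'   \code{effect} (expression-unit effect scale) and \code{levels}
#'   (number of levels; used for categorical only).
#' @slot plantedEffects list of \linkS4class{PlantedEffect}.
#' @slot orRange length-2 numeric; simulated GWAS odds ratios are drawn
#'   log-uniformly from this interval.
#' @slot seed integer master seed; a fixed seed makes every output
#'   reproducible bit-for-bit.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nIndividuals = "integer",
        nVariants = "integer",
        mafRange = "numeric",
        nGenes = "integer",
        noiseSd = "numeric",
        covariateSpec = "data.frame",
        plantedEffects = "list",
        orRange = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nIndividuals < 4)
        msg <- c(msg, "nIndividuals must be >= 4")
    mr <- object@mafRange
    if (length(mr) != 2 || any(mr <= 0) || any(mr > 0.5) || mr[1] > mr[2])
        msg <- c(msg, "mafRange must lie within (0, 0.5] with min <= max")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (length(object@orRange) != 2 || any(object@orRange <= 0))
        msg <- c(msg, "orRange must be two positive numbers")
    if (!all(vapply(object@plantedEffects, is, logical(1), "PlantedEffect")))
        msg <- c(msg, "plantedEffects must be PlantedEffect objects")
    if (nrow(object@covariateSpec) &&
        !all(object@covariateSpec$kind %in% c("continuous", "categorical", "pc")))
        msg <- c(msg, "covariate kind must be continuous, categorical or pc")
    if (length(msg)) msg else TRUE
})
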