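#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIDs", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantIDs", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantMeta", "GenotypeMatrix", function(x) x@variantMeta)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) {
    stats::setNames(x@variantMeta$maf, rownames(x@variantMeta))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("loadReport", "GenotypeMatrix", function(x) x@loadReport)

setMethod("show", "GenotypeMatrix", function(object) {
    cat(sprintf("GenotypeMatrix: %d individuals x %d variants\n",
                nrow(object@dosage), ncol(object@dosage)))
    if (ncol(object@dosage)) {
        m <- object@variantMeta$maf
        cat(sprintf("  MAF range: %.3f - %.3f\n", min(m), max(m)))
    }
    if (length(object@loadReport))
        cat("  load report:",
            paste(names(object@loadReport), unlist(object@loadReport),
                  sep = "=", collapse = ", "), "\n")
    invisible(NULL)
})

#' @rdname VariantWeightTable-class
#' @export
setMethod("weightTable", "VariantWeightTable", function(x) x@table)

#' @rdname VariantWeightTable-class
#' @export
setMethod("grsWeights", "VariantWeightTable", function(x) {
    stats::setNames(x@table$weight, x@table$variant_id)
})

#' @rdname VariantWeightTable-class
#' @export
setMethod("variantIDs", "VariantWeightTable", function(x) x@table$variant_id)

setMethod("show", "VariantWeightTable", function(object) {
    cat(sprintf("VariantWeightTable: %d variants, OR %.3g - %.3g\n",
                nrow(object@table),
                if (nrow(object@table)) min(object@table$odds_ratio) else NA,
                if (nrow(object@table)) max(object@table$odds_ratio) else NA))
    invisible(NULL)
})

#' @rdname GrsCohort-class
#' @export
setMethod("genotypes", "GrsCohort", function(x) x@genotypes)

#' @rdname GrsCohort-class
#' @export
setMethod("exprMatrix", "GrsCohort", function(x) x@expression)

#' @rdname GrsCohort-class
#' @export
setMethod("geneIDs", "GrsCohort", function(x) rownames(x@expression))

#' @rdname GrsCohort-class
#' @export
setMethod("covariates", "GrsCohort", function(x) x@covariates)

#' @rdname GrsCohort-class
#' @export
setMethod("sampleIDs", "GrsCohort", function(x) rownames(x@genotypes@dosage))

#' @rdname GrsCohort-class
#' @export
setMethod("variantIDs", "GrsCohort", function(x) colnames(x@genotypes@dosage))

setMethod("show", "GrsCohort", function(object) {
    cat(sprintf("GrsCohort: %d individuals, %d variants, %d genes, %d covariate column(s)\n",
                nrow(object@genotypes@dosage), ncol(object@genotypes@dosage),
                nrow(object@expression), ncol(object@covariates)))
    invisible(NULL)
})

#' @rdname RiskAssignment-class
#' @export
setMethod("riskLabels", "RiskAssignment", function(x) x@labels)

#' @rdname RiskAssignment-class
#' @export
setMethod("combinationKey", "RiskAssignment", function(x) {
    canonicalCombination(x@combination)
})

setMethod("show", "RiskAssignment", function(object) {
    cat(sprintf("RiskAssignment: %s @ q=%.2f  (low %d / high %d / excluded %d)\n",
                canonicalCombination(object@combination), object@q,
                object@nLow, object@nHigh,
                sum(object@labels == "excluded")))
    invisible(NULL)
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d individuals, %d variants ",
                       "(MAF %.2f-%.2f), %d genes, noise sd %.2f, %d planted ",
                       "effect(s), seed %d\n"),
                object@nIndividuals, object@nVariants, object@mafRange[1],
                object@mafRange[2], object@nGenes, object@noiseSd,
                length(object@plantedEffects), object@seed))
    invisible(NULL)
})

setMethod("show", "PlantedEffect", function(object) {
    cat(sprintf("PlantedEffect: %s <- {%s} beta=%.3g (%s)\n", object@geneId,
                paste(object@variantSet, collapse = ", "),
                object@perVariantBeta, object@mode))
    invisible(NULL)
})
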