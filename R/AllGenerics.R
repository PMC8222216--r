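#' @rdname GenotypeMatrix-class
#' @param x,object a grsQTL object
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantIDs", function(x) standardGeneric("variantIDs"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantMeta", function(x) standardGeneric("variantMeta"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

#' @rdname VariantWeightTable-class
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))

#' @rdname VariantWeightTable-class
#' @export
setGeneric("grsWeights", function(x) standardGeneric("grsWeights"))

#' @rdname GrsCohort-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GrsCohort-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname GrsCohort-class
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' @rdname GrsCohort-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname RiskAssignment-class
#' @export
setGeneric("riskLabels", function(x) standardGeneric("riskLabels"))

#' @rdname RiskAssignment-class
#' @export
setGeneric("combinationKey", function(x) standardGeneric("combinationKey"))
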