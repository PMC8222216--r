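# internal helpers shared across modules

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Canonical key for a variant combination
#'
#' Combinations are identified by their member set only; the canonical key is
#' the lexicographically sorted member list joined with \code{"+"}, used for
#' deduplication and joins throughout.
#'
#' @param members character vector of variant identifiers.
#' @return single character key.
#' @examples
#' canonicalCombination(c("rs2", "rs1"))  # "rs1+rs2"
#' @export
canonicalCombination <- function(members) {
    if (!length(members)) stop("a combination must contain at least one variant")
    if (anyDuplicated(members)) stop("duplicate variants in combination")
    paste(sort(as.character(members)), collapse = "+")
}

#' Split a canonical combination key back into members
#'
#' @param key combination key as produced by [canonicalCombination()].
#' @return character vector of variant identifiers.
#' @export
splitCombination <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

# round-half-up at `digits` decimals (printed-percentage convention;
# base round() would round half to even)
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

# sample allele frequency of the counted allele -> minor allele frequency
dosageMAF <- function(dosage) {
    p <- colMeans(dosage) / 2
    pmin(p, 1 - p)
}

# shared constructor used by readers and the simulator
newGenotypeMatrix <- function(dosage, variantMeta = NULL, loadReport = list()) {
    storage.mode(dosage) <- "integer"
    if (is.null(variantMeta)) {
        variantMeta <- data.frame(
            chrom = rep(NA_character_, ncol(dosage)),
            pos = rep(NA_integer_, ncol(dosage)),
            risk_allele = rep(NA_character_, ncol(dosage)),
            other_allele = rep(NA_character_, ncol(dosage)),
            maf = as.numeric(dosageMAF(dosage)),
            row.names = colnames(dosage),
            stringsAsFactors = FALSE
        )
    }
    new("GenotypeMatrix", dosage = dosage, variantMeta = variantMeta,
        loadReport = loadReport)
}
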