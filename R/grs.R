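#' Normalized genetic risk score for one variant combination
#'
#' The GRS of individual \eqn{j} for a variant set \eqn{S} is the sum of the
#' individual's risk-allele dosages weighted by each variant's log odds
#' ratio, normalized by the mean weight of the included variants:
#' \deqn{GRS_j = \frac{\sum_{i \in S} d_{ji} w_i}{\frac{1}{|S|}\sum_{i \in S} w_i},
#'   \quad w_i = \ln(OR_i).}
#' The normalization makes scores comparable across combinations of
#' different sizes and cancels any common scaling of the weights; for a
#' single variant the score equals the risk-allele dosage exactly.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix} (or bare dosage matrix
#'   with sample rownames and variant colnames).
#' @param weights a \linkS4class{VariantWeightTable} (or named numeric
#'   vector of log-OR weights).
#' @param combination character vector of variant identifiers, or a
#'   canonical \code{"+"}-joined key.
#' @return numeric vector of scores named by sample identifier, with the
#'   canonical combination key in attribute \code{"combination"}.
#' @examples
#' d <- matrix(c(1L, 1L), 1, 2, dimnames = list("s1", c("rs1", "rs2")))
#' computeGRS(d, c(rs1 = 0.2, rs2 = 0.6), c("rs1", "rs2"))  # 2.0
#' @export
computeGRS <- function(genotypes, weights, combination) {
    d <- if (is(genotypes, "GenotypeMatrix")) genotypes@dosage else genotypes
    w <- if (is(weights, "VariantWeightTable")) grsWeights(weights) else weights
    members <- if (length(combination) == 1L && grepl("+", combination, fixed = TRUE))
        splitCombination(combination) else as.character(combination)
    if (!length(members)) stop("a combination must contain at least one variant")
    missG <- setdiff(members, colnames(d))
    if (length(missG))
        stop("variants absent from genotypes: ", paste(missG, collapse = ", "))
    missW <- setdiff(members, names(w))
    if (length(missW))
        stop("variants absent from weight table: ", paste(missW, collapse = ", "))
    wS <- w[members]
    mw <- mean(wS)
    if (mw == 0)
        stop("mean weight of the combination is zero (all odds ratios 1); ",
             "GRS normalization is undefined")
    scores <- as.vector(d[, members, drop = FALSE] %*% wS) / mw
    names(scores) <- rownames(d)
    attr(scores, "combination") <- canonicalCombination(members)
    scores
}

#' Risk-group size for a quantile fraction
#'
#' Each of the low- and high-risk groups holds \code{floor(q * n)}
#' individuals; flooring is the rounding consistent with a 30\% group of 176
#' from a cohort of 588.
#'
#' @param nIndividuals cohort size.
#' @param q quantile fraction in (0, 0.5]; larger values would make the
#'   groups overlap.
#' @return integer group size.
#' @examples
#' groupSize(588, 0.30)  # 176
#' @export
groupSize <- function(nIndividuals, q) {
    if (q <= 0 || q > 0.5)
        stop("q must be in (0, 0.5]; groups would overlap for q > 0.5")
    as.integer(floor(q * nIndividuals))
}

#' Stratify individuals into low/high GRS risk groups
#'
#' Ranks the scores and labels the \code{floor(q n)} lowest-scoring
#' individuals \code{low}, the same number of highest-scoring individuals
#' \code{high}, and everyone in between \code{excluded}. Ties at a group
#' boundary are broken deterministically by sample identifier (stable sort
#' on (score, sample ID)), so repeated runs and permuted inputs give
#' identical group membership.
#'
#' @param grs numeric score vector named by sample identifier, as returned
#'   by [computeGRS()].
#' @param q quantile fraction in (0, 0.5].
#' @return a \linkS4class{RiskAssignment}.
#' @examples
#' g <- stats::setNames(c(3, 1, 2, 5, 4, 6), paste0("s", 1:6))
#' riskLabels(stratify(g, 1/3))
#' @export
stratify <- function(grs, q) {
    n <- length(grs)
    if (is.null(names(grs))) stop("scores must be named by sample identifier")
    gs <- groupSize(n, q)
    if (gs < 1) stop("cohort too small: group size is zero at q = ", q)
    if (n < 2 * gs) stop("cohort too small for two disjoint groups at q = ", q)
    ord <- order(grs, names(grs), method = "radix")
    lab <- rep("excluded", n)
    lab[ord[seq_len(gs)]] <- "low"
    lab[ord[seq.int(n - gs + 1L, n)]] <- "high"
    combo <- attr(grs, "combination")
    if (is.null(combo)) combo <- "GRS"
    new("RiskAssignment",
        combination = splitCombination(combo),
        q = q,
        labels = factor(stats::setNames(lab, names(grs)),
                        levels = c("low", "excluded", "high")),
        nLow = gs, nHigh = gs)
}
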