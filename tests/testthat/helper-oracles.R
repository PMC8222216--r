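# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (loops, normal equations, definitions) so
# they stay independent of the package's vectorized implementations.

# brute-force OLS via normal equations: returns es/se/p for column 2 of X
oracleOLS <- function(y, X) {
    XtXi <- solve(t(X) %*% X)
    beta <- XtXi %*% t(X) %*% y
    res <- y - X %*% beta
    df <- nrow(X) - ncol(X)
    sigma2 <- sum(res^2) / df
    se <- sqrt(sigma2 * XtXi[2, 2])
    tt <- beta[2] / se
    list(es = as.numeric(beta[2]), se = as.numeric(se),
         p = 2 * pt(-abs(tt), df))
}

# definition-based BH, O(m^2): q_i = min(1, min over { p_j >= p_i } of
# m p_j / rank_j) with rank_j = #{ p <= p_j }
oracleBH <- function(p) {
    m <- length(p)
    vapply(p, function(pi) {
        cands <- vapply(p[p >= pi],
                        function(pj) m * pj / sum(p <= pj), numeric(1))
        min(1, cands)
    }, numeric(1))
}

# loop-based GRS oracle, straight from the definition
oracleGRS <- function(dosage, w, members) {
    scores <- numeric(nrow(dosage))
    for (j in seq_len(nrow(dosage))) {
        s <- 0
        for (v in members) s <- s + dosage[j, v] * w[v]
        scores[j] <- s / (sum(w[members]) / length(members))
    }
    scores
}

# full powerset of ids (list of sorted character vectors), brute force
oraclePowerset <- function(ids, maxSize = length(ids)) {
    out <- list()
    for (mask in seq_len(2^length(ids) - 1)) {
        members <- ids[bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0]
        if (length(members) <= maxSize)
            out[[length(out) + 1]] <- sort(members)
    }
    # enumeration order: size then lexicographic on the joined key
    keys <- vapply(out, paste, character(1), collapse = "+")
    out[order(lengths(out), keys)]
}

# a tiny deterministic cohort with hand-set dosages for IO/GRS tests
tinyCohort <- function(nGenes = 5, seed = 11) {
    geno <- simulateGenotypes(40, 3, c(0.2, 0.4), seed = seed)
    weights <- simulateWeights(geno, seed = seed + 1)
    cov <- simulateCovariates(40, defaultCovariateSpec(), seed = seed + 2)
    cfg <- simulationConfig(nIndividuals = 40, nVariants = 3, nGenes = nGenes,
                            seed = seed)
    sim <- simulateExpression(geno, cov, cfg)
    list(cohort = alignCohort(geno, sim$expression, cov), weights = weights)
}

# association records built directly from a description table; used by the
# reporting tests (combination, gene_id, es, p[, q])
makeRecords <- function(combination, gene_id, es, p, q = NA_real_) {
    data.frame(combination = combination, gene_id = gene_id,
               n_low = 10L, n_high = 10L, es = es, se = abs(es) / 2,
               p = p, q = q, flag = "", stringsAsFactors = FALSE)
}
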