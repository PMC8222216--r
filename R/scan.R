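# Expand a covariate data.frame to numeric columns (categoricals ->
# treatment-coded indicators), without the intercept.
.covariateDesign <- function(covariates) {
    if (is.null(covariates) || ncol(covariates) == 0)
        return(matrix(0, nrow = if (is.null(covariates)) 0 else nrow(covariates),
                      ncol = 0))
    mm <- stats::model.matrix(~ ., data = droplevels(covariates))
    mm[, -1, drop = FALSE]
}

# Core OLS kernel shared by all association fits: regress every column of Y
# on X = [intercept, high-indicator, covariates]; report the high-indicator
# coefficient (es), its standard error, and the two-sided t-test p with
# residual df. Genes with zero variance among the used samples are flagged
# "degenerate" (es = 0, p = 1); p-values below 1e-300 are floored and
# flagged "underflow".
.fitMany <- function(Y, X) {
    n <- nrow(X)
    p <- ncol(X)
    qrX <- qr(X)
    if (qrX$rank < p) {
        bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
        stop("design matrix is rank deficient; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    df <- n - p
    if (df < 1) stop("not enough samples for the design (", n, " rows, ",
                     p, " parameters)")
    coefs <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    rss <- colSums(res^2)
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qrX))
    # column order after pivoting
    unpivot <- order(qrX$pivot)
    v2 <- XtXinv[unpivot[2L], unpivot[2L]]
    es <- coefs[2L, ]
    se <- sqrt(sigma2 * v2)
    tt <- es / se
    pval <- 2 * stats::pt(-abs(tt), df)
    flag <- rep("", ncol(Y))
    degen <- matrixStats_colVars(Y) == 0
    if (any(degen)) {
        es[degen] <- 0; se[degen] <- 0; pval[degen] <- 1
        flag[degen] <- "degenerate"
    }
    # an exactly-fitting model leaves only rounding error in the residuals;
    # report the underflow floor rather than a noise-driven p
    tss <- matrixStats_colVars(Y) * (n - 1)
    exact <- !degen & rss <= 1e-24 * pmax(tss, .Machine$double.xmin)
    under <- !degen & (exact | !is.finite(pval) | pval < 1e-300)
    if (any(under)) {
        pval[under] <- 1e-300
        flag[under] <- "underflow"
    }
    data.frame(gene_id = colnames(Y), es = unname(es), se = unname(se),
               p = unname(pval), flag = flag, stringsAsFactors = FALSE,
               row.names = NULL)
}

# colVars without an extra dependency
matrixStats_colVars <- function(Y) {
    n <- nrow(Y)
    if (n < 2) return(rep(0, ncol(Y)))
    mu <- colMeans(Y)
    (colSums(Y^2) - n * mu^2) / (n - 1)
}

#' Covariate-adjusted association between risk group and expression
#'
#' Ordinary least squares of expression on
#' \code{[intercept, high-indicator, covariates]} over the low- and
#' high-group individuals (excluded middle-quantile individuals are dropped
#' from the fit). The effect size (ES) is the high-vs-low coefficient in
#' expression units, with its standard error and the two-sided t-test
#' p-value at residual degrees of freedom. Without covariates this is
#' exactly the classical pooled-variance two-sample t-test with
#' ES = difference of group means.
#'
#' @param y numeric expression vector (one gene), aligned with
#'   \code{labels}.
#' @param labels a \linkS4class{RiskAssignment}, or a factor/character
#'   vector with values \code{low} / \code{high} / \code{excluded}.
#' @param covariates optional data.frame aligned with \code{y}; categorical
#'   columns are expanded to indicators.
#' @return list with \code{es}, \code{se}, \code{p}, \code{df} and
#'   \code{flag} (\code{""}, \code{"degenerate"} or \code{"underflow"}).
#' @export
fitGroupAssociation <- function(y, labels, covariates = NULL) {
    lab <- if (is(labels, "RiskAssignment")) as.character(riskLabels(labels))
           else as.character(labels)
    if (length(lab) != length(y)) stop("labels and y lengths differ")
    used <- lab %in% c("low", "high")
    if (!any(lab == "low") || !any(lab == "high"))
        stop("both risk groups must be non-empty")
    hi <- as.numeric(lab[used] == "high")
    C <- if (is.null(covariates)) NULL
         else .covariateDesign(covariates[used, , drop = FALSE])
    X <- cbind(`(Intercept)` = 1, high = hi, C)
    Y <- matrix(y[used], ncol = 1, dimnames = list(NULL, "y"))
    fit <- .fitMany(Y, X)
    list(es = fit$es, se = fit$se, p = fit$p, df = sum(used) - ncol(X),
         flag = fit$flag)
}

#' Scan all variant combinations against all genes
#'
#' The central operation: for every combination of the variant panel
#' (streamed in enumeration order: increasing size, then lexicographic) the
#' normalized GRS is computed, individuals are stratified into low/high
#' q-quantile groups, and every gene is tested for a covariate-adjusted
#' expression difference between the groups. Gene fits for one combination
#' share a single QR decomposition, so the scan is vectorized over genes;
#' memory stays bounded by the combination chunk.
#'
#' Raw p-values are returned; apply [adjustFdr()] once across the whole
#' series (one call per category run) to obtain Q-values.
#'
#' @param cohort a \linkS4class{GrsCohort}.
#' @param weights a \linkS4class{VariantWeightTable}.
#' @param variantSubset variants to scan (default: all genotyped variants
#'   present in the weight table).
#' @param q risk-group quantile fraction (reference analysis: 0.30).
#' @param maxSize optional maximum combination size.
#' @param covariateCols covariate columns to adjust for (default: all).
#' @param genes optional subset of gene identifiers to test.
#' @param chunkSize combinations per streamed chunk.
#' @return data.frame of association records with columns
#'   \code{combination}, \code{gene_id}, \code{n_low}, \code{n_high},
#'   \code{es}, \code{se}, \code{p}, \code{q} (NA until adjustment) and
#'   \code{flag}; the run log (test counts, configuration echo) is attached
#'   as attribute \code{"runLog"}.
#' @export
runScan <- function(cohort, weights, variantSubset = NULL, q = 0.3,
                    maxSize = NULL, covariateCols = NULL, genes = NULL,
                    chunkSize = 4096L) {
    panel <- if (is.null(variantSubset))
        intersect(variantIDs(cohort), variantIDs(weights))
    else as.character(variantSubset)
    if (!length(panel)) stop("no variants to scan")
    missing <- setdiff(panel, variantIDs(cohort))
    if (length(missing))
        stop("variant(s) not genotyped: ", paste(missing, collapse = ", "))
    cov <- covariates(cohort)
    if (!is.null(covariateCols)) {
        miss <- setdiff(covariateCols, colnames(cov))
        if (length(miss)) stop("unknown covariate column(s): ",
                               paste(miss, collapse = ", "))
        cov <- cov[, covariateCols, drop = FALSE]
    }
    covDesign <- .covariateDesign(cov)
    tExpr <- t(exprMatrix(cohort))
    if (!is.null(genes)) {
        miss <- setdiff(genes, colnames(tExpr))
        if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
        tExpr <- tExpr[, genes, drop = FALSE]
    }
    w <- grsWeights(weights)
    d <- dosages(genotypes(cohort))
    gs <- groupSize(nrow(d), q)

    it <- combinationIterator(panel, maxSize, chunkSize)
    out <- list()
    nCombos <- 0
    failures <- list()
    repeat {
        chunk <- it$nextChunk()
        if (is.null(chunk)) break
        for (members in chunk) {
            key <- paste(members, collapse = "+")   # already canonical order
            rec <- tryCatch({
                scores <- as.vector(d[, members, drop = FALSE] %*% w[members]) /
                    mean(w[members])
                ord <- order(scores, rownames(d), method = "radix")
                lowIdx <- ord[seq_len(gs)]
                highIdx <- ord[seq.int(length(scores) - gs + 1L, length(scores))]
                used <- c(lowIdx, highIdx)
                X <- cbind(`(Intercept)` = 1,
                           high = rep(c(0, 1), each = gs),
                           covDesign[used, , drop = FALSE])
                fit <- .fitMany(tExpr[used, , drop = FALSE], X)
                fit$combination <- key
                fit$n_low <- gs
                fit$n_high <- gs
                fit
            }, error = function(e) {
                failures[[length(failures) + 1L]] <<-
                    list(combination = key, message = conditionMessage(e))
                NULL
            })
            if (!is.null(rec)) out[[length(out) + 1L]] <- rec
            nCombos <- nCombos + 1
        }
    }
    records <- data.table::setDF(data.table::rbindlist(out))
    if (nrow(records)) {
        records$q <- NA_real_
        records <- records[, c("combination", "gene_id", "n_low", "n_high",
                               "es", "se", "p", "q", "flag")]
    }
    attr(records, "runLog") <- list(
        n_variants = length(panel),
        n_combinations = nCombos,
        n_genes = ncol(tExpr),
        n_tests = nCombos * as.double(ncol(tExpr)),
        q_fraction = q,
        max_size = if (is.null(maxSize)) length(panel) else maxSize,
        group_size = gs,
        covariate_columns = colnames(cov),
        failed_combinations = failures
    )
    records
}

#' Benjamini-Hochberg adjustment of one test series
#'
#' Step-up FDR adjustment with monotonicity enforcement, applied once
#' across an entire test series (all combinations x all genes of one
#' category run), exactly as \code{stats::p.adjust(method = "BH")}
#' computes it.
#'
#' @param p numeric p-values in (0, 1].
#' @return Q-values in the same order.
#' @examples
#' adjustFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustFdr <- function(p) {
    if (!length(p)) return(numeric())
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Attach series-level Q-values to scan records
#'
#' @param records association records from [runScan()].
#' @return records with the \code{q} column filled by [adjustFdr()] across
#'   all rows (one FDR scope per series).
#' @export
adjustSeries <- function(records) {
    records$q <- adjustFdr(records$p)
    records
}

#' Quantile-quantile data for a p-value series
#'
#' Pairs sorted observed p-values with Uniform(0,1) order-statistic
#' expectations \eqn{i/(m+1)} on the \eqn{-\log_{10}} scale, the diagnostic
#' used to judge whether a test series deviates from chance and to justify
#' fixed p-value thresholds for very large series.
#'
#' @param p numeric p-values.
#' @return data.frame with columns \code{expected} and \code{observed}
#'   (both \eqn{-\log_{10}}), ordered from least to most significant.
#' @export
qqData <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    m <- length(p)
    df <- data.frame(expected = -log10(seq.int(m, 1L) / (m + 1)),
                     observed = -log10(sort(p, decreasing = TRUE)))
    rownames(df) <- NULL
    df
}

#' Calibrate the risk-group quantile against known eGenes
#'
#' Re-runs the replication analysis used to fix the group size: the GRS of
#' the full variant panel stratifies the cohort at each grid fraction; only
#' the known eGenes are tested; BH adjustment is applied within each
#' per-fraction batch; a fraction replicates when every known eGene reaches
#' Q-value < \code{alpha}. The selected fraction is the smallest grid value
#' that replicates all known eGenes.
#'
#' @param cohort a \linkS4class{GrsCohort}.
#' @param weights a \linkS4class{VariantWeightTable}.
#' @param variantSet panel used for the calibration GRS (default: all).
#' @param knownEgenes gene identifiers expected to replicate.
#' @param qGrid candidate quantile fractions.
#' @param alpha FDR level (default 0.05).
#' @return list with \code{table} (per-fraction replication results) and
#'   \code{selected} (chosen fraction, or NA with a warning when no grid
#'   value replicates all genes).
#' @export
calibrateGroupSize <- function(cohort, weights, variantSet = NULL, knownEgenes,
                               qGrid = seq(0.05, 0.35, by = 0.05),
                               alpha = 0.05) {
    if (!length(knownEgenes)) stop("knownEgenes must be non-empty")
    if (any(qGrid <= 0 | qGrid > 0.5)) stop("qGrid must lie in (0, 0.5]")
    panel <- if (is.null(variantSet)) variantIDs(cohort) else variantSet
    miss <- setdiff(knownEgenes, geneIDs(cohort))
    if (length(miss)) stop("unknown eGene(s): ", paste(miss, collapse = ", "))
    scores <- computeGRS(genotypes(cohort), weights, panel)
    cov <- covariates(cohort)
    rows <- lapply(sort(qGrid), function(qf) {
        ra <- stratify(scores, qf)
        fits <- vapply(knownEgenes, function(g) {
            fitGroupAssociation(exprMatrix(cohort)[g, ], ra, cov)$p
        }, numeric(1))
        qv <- adjustFdr(fits)
        rep_genes <- knownEgenes[qv < alpha]
        data.frame(q = qf, n_replicated = length(rep_genes),
                   replicated = paste(rep_genes, collapse = ","),
                   all_replicated = length(rep_genes) == length(knownEgenes),
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    sel <- tab$q[tab$all_replicated]
    selected <- if (length(sel)) min(sel) else NA_real_
    if (is.na(selected))
        warning("no grid fraction replicates all known eGenes at FDR < ", alpha)
    list(table = tab, selected = selected)
}
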