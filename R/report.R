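.combSize <- function(keys) {
    lengths(regmatches(keys, gregexpr("+", keys, fixed = TRUE))) + 1L
}

.sigRecords <- function(records, threshold, statistic = c("p", "q")) {
    statistic <- match.arg(statistic)
    if (!statistic %in% colnames(records))
        stop("records carry no '", statistic, "' column")
    v <- records[[statistic]]
    if (statistic == "q" && all(is.na(v)))
        stop("q column is unset; run adjustSeries() first")
    records[!is.na(v) & v < threshold, , drop = FALSE]
}

#' Summarize eGenes from a scanned test series
#'
#' A gene is an eGene when at least \code{minCombinations} distinct
#' combinations pass the significance threshold for it. For each eGene the
#' summary reports the number of significant eCombinations, the range of
#' combination sizes involved, the strongest record (maximum absolute ES,
#' ties broken by smaller p then canonical combination order), and whether
#' a single variant is already sufficient (some size-1 combination is
#' significant). The reference analysis of the largest series used
#' \code{threshold = 1e-7} on p with \code{minCombinations = 3}.
#'
#' @param records association records (see [runScan()]).
#' @param threshold significance cutoff, applied as strictly-less-than.
#' @param statistic \code{"p"} (raw) or \code{"q"} (BH-adjusted).
#' @param minCombinations minimum number of significant combinations.
#' @return data.frame with one row per eGene: \code{gene_id},
#'   \code{n_significant}, \code{min_size}, \code{max_size},
#'   \code{strongest_combination}, \code{strongest_es}, \code{strongest_se},
#'   \code{strongest_p}, \code{single_variant_sufficient}.
#' @export
summarizeEgenes <- function(records, threshold, statistic = c("p", "q"),
                            minCombinations = 1L) {
    statistic <- match.arg(statistic)
    empty <- data.frame(gene_id = character(), n_significant = integer(),
                        min_size = integer(), max_size = integer(),
                        strongest_combination = character(),
                        strongest_es = numeric(), strongest_se = numeric(),
                        strongest_p = numeric(),
                        single_variant_sufficient = logical(),
                        stringsAsFactors = FALSE)
    if (!nrow(records)) return(empty)
    sig <- .sigRecords(records, threshold, statistic)
    if (!nrow(sig)) return(empty)
    sig$size <- .combSize(sig$combination)
    out <- lapply(split(sig, sig$gene_id), function(gr) {
        if (nrow(gr) < minCombinations) return(NULL)
        o <- order(-abs(gr$es), gr$p, gr$combination)
        top <- gr[o[1L], ]
        data.frame(gene_id = top$gene_id,
                   n_significant = nrow(gr),
                   min_size = min(gr$size), max_size = max(gr$size),
                   strongest_combination = top$combination,
                   strongest_es = top$es, strongest_se = top$se,
                   strongest_p = top$p,
                   single_variant_sufficient = any(gr$size == 1L),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
    out[order(out$gene_id), , drop = FALSE]
}

#' Variant contribution profile for one eGene
#'
#' For the significant eCombinations of one gene, counts how often each
#' variant appears and reports the fraction of eCombinations containing it
#' (the effect-driver diagnostic: a variant present in every significant
#' combination has fraction 1). Percentages are rounded half-up to one
#' decimal, the presentation resolution used for printed contribution
#' figures.
#'
#' @param records association records for the gene's test series.
#' @param geneId the gene to profile.
#' @inheritParams summarizeEgenes
#' @return data.frame with \code{variant_id}, \code{n_combinations},
#'   \code{fraction} and \code{percent}, sorted by descending contribution;
#'   attribute \code{"n_total"} holds the number of significant
#'   eCombinations.
#' @export
contributionProfile <- function(records, geneId, threshold,
                                statistic = c("p", "q")) {
    statistic <- match.arg(statistic)
    sig <- .sigRecords(records[records$gene_id == geneId, , drop = FALSE],
                       threshold, statistic)
    if (!nrow(sig))
        stop("gene ", geneId, " has no significant record at ", statistic,
             " < ", threshold)
    members <- strsplit(sig$combination, "+", fixed = TRUE)
    counts <- table(unlist(members))
    total <- nrow(sig)
    out <- data.frame(variant_id = names(counts),
                      n_combinations = as.integer(counts),
                      fraction = as.numeric(counts) / total,
                      stringsAsFactors = FALSE)
    out$percent <- roundHalfUp(100 * out$fraction, 1)
    out <- out[order(-out$n_combinations, out$variant_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_total") <- total
    out
}

#' Combination tree (subset lattice) rooted at one combination
#'
#' Starting from a root combination, expands breadth-first through tested
#' combinations that add exactly one variant per step, mirroring tree
#' charts that trace how an effect changes as variants join the risk model.
#' Nodes carry the ES, p-value and a significance flag; edges are exactly
#' the covering relations (parent plus one variant) among the included
#' nodes, so a node can have several parents.
#'
#' @param records association records of one gene's test series (filter to
#'   one gene before calling if the series covers several).
#' @param geneId gene whose records form the tree payload.
#' @param rootCombination root members (character vector or "+" key).
#' @inheritParams summarizeEgenes
#' @return list with \code{nodes} (data.frame: combination, size, es, p,
#'   significant) and \code{edges} (data.frame: parent, child).
#' @export
buildCombinationTree <- function(records, geneId, rootCombination,
                                 threshold = 0.05, statistic = c("p", "q")) {
    statistic <- match.arg(statistic)
    rootKey <- canonicalCombination(
        if (length(rootCombination) == 1L && grepl("+", rootCombination, fixed = TRUE))
            splitCombination(rootCombination) else rootCombination)
    gr <- records[records$gene_id == geneId, , drop = FALSE]
    if (!rootKey %in% gr$combination)
        stop("root combination ", rootKey, " was not tested for gene ", geneId)
    keyMembers <- strsplit(gr$combination, "+", fixed = TRUE)
    names(keyMembers) <- gr$combination
    sizes <- lengths(keyMembers)

    include <- rootKey
    frontier <- rootKey
    edges <- list()
    while (length(frontier)) {
        nxt <- character()
        for (par in frontier) {
            pm <- keyMembers[[par]]
            childIdx <- which(sizes == length(pm) + 1L)
            for (i in childIdx) {
                if (all(pm %in% keyMembers[[i]])) {
                    child <- gr$combination[i]
                    edges[[length(edges) + 1L]] <- c(parent = par, child = child)
                    if (!child %in% include) {
                        include <- c(include, child)
                        nxt <- c(nxt, child)
                    }
                }
            }
        }
        frontier <- unique(nxt)
    }
    idx <- match(include, gr$combination)
    stat <- gr[[statistic]][idx]
    nodes <- data.frame(combination = include,
                        size = sizes[idx],
                        es = gr$es[idx], p = gr$p[idx],
                        significant = !is.na(stat) & stat < threshold,
                        stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    edges <- if (length(edges))
        data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    else data.frame(parent = character(), child = character(),
                    stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    list(nodes = nodes, edges = edges)
}

#' Export a combination tree as nested JSON
#'
#' Serializes the lattice as a nested structure (each node with its payload
#' and children), suitable for downstream plotting tools.
#'
#' @param tree result of [buildCombinationTree()].
#' @param path output JSON path.
#' @export
writeCombinationTree <- function(tree, path) {
    build <- function(key) {
        i <- match(key, tree$nodes$combination)
        kids <- tree$edges$child[tree$edges$parent == key]
        list(combination = key,
             size = tree$nodes$size[i],
             es = tree$nodes$es[i],
             p = tree$nodes$p[i],
             significant = tree$nodes$significant[i],
             children = lapply(kids, build))
    }
    roots <- setdiff(tree$nodes$combination, tree$edges$child)
    jsonlite::write_json(lapply(roots, build), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' Overlap of eGene sets from two datasets
#'
#' @param egenesA,egenesB eGene summaries (data.frames from
#'   [summarizeEgenes()]) or character vectors of gene ids, produced under
#'   the same thresholding mode.
#' @return list with \code{shared} (sorted gene ids), \code{n_a},
#'   \code{n_b}, \code{n_shared}.
#' @export
crossDatasetOverlap <- function(egenesA, egenesB) {
    a <- unique(if (is.data.frame(egenesA)) egenesA$gene_id else as.character(egenesA))
    b <- unique(if (is.data.frame(egenesB)) egenesB$gene_id else as.character(egenesB))
    shared <- sort(intersect(a, b))
    list(shared = shared, n_a = length(a), n_b = length(b),
         n_shared = length(shared))
}

#' Re-test the strongest eCombinations in a second cohort
#'
#' Cross-dataset replication: for each eGene of the discovery series, the
#' \code{topK} significant combinations with the largest absolute ES are
#' re-tested in an independent cohort. Combinations whose variants are not
#' genotyped in the replication cohort are flagged untestable rather than
#' dropped.
#'
#' @param recordsA discovery association records.
#' @param cohortB replication \linkS4class{GrsCohort}.
#' @param weights \linkS4class{VariantWeightTable} (shared GWAS weights).
#' @param topK combinations per gene to carry over.
#' @param threshold,statistic discovery significance rule.
#' @param q risk-group fraction used for the replication fits.
#' @param alphaB nominal p threshold declaring replication significant.
#' @return data.frame with one row per (gene, combination):
#'   \code{gene_id}, \code{combination}, \code{es_a}, \code{es_b},
#'   \code{p_b}, \code{same_sign}, \code{significant_b}, \code{testable}.
#' @export
replicateTopCombinations <- function(recordsA, cohortB, weights, topK = 5L,
                                     threshold = 0.05,
                                     statistic = c("p", "q"), q = 0.3,
                                     alphaB = 0.05) {
    statistic <- match.arg(statistic)
    if (topK < 1) stop("topK must be >= 1")
    sig <- .sigRecords(recordsA, threshold, statistic)
    if (!nrow(sig)) stop("no significant discovery records")
    cov <- covariates(cohortB)
    rows <- lapply(split(sig, sig$gene_id), function(gr) {
        o <- order(-abs(gr$es), gr$p, gr$combination)
        gr <- gr[o[seq_len(min(topK, nrow(gr)))], , drop = FALSE]
        do.call(rbind, lapply(seq_len(nrow(gr)), function(i) {
            key <- gr$combination[i]
            members <- splitCombination(key)
            testable <- all(members %in% variantIDs(cohortB)) &&
                gr$gene_id[i] %in% geneIDs(cohortB)
            esB <- pB <- NA_real_
            if (testable) {
                scores <- computeGRS(genotypes(cohortB), weights, members)
                ra <- stratify(scores, q)
                fit <- fitGroupAssociation(
                    exprMatrix(cohortB)[gr$gene_id[i], ], ra, cov)
                esB <- fit$es; pB <- fit$p
            }
            data.frame(gene_id = gr$gene_id[i], combination = key,
                       es_a = gr$es[i], es_b = esB, p_b = pB,
                       same_sign = if (testable) sign(esB) == sign(gr$es[i]) else NA,
                       significant_b = if (testable) pB < alphaB else NA,
                       testable = testable, stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
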