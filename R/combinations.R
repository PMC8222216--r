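#' Exact count of variant combinations
#'
#' Number of non-empty subsets of \code{n} variants with at most
#' \code{maxSize} members, computed from exact binomial coefficients. With
#' no size cap this is \eqn{2^n - 1}: 127 subsets for 7 variants, 32,767 for
#' 15 and 524,287 for 19.
#'
#' @param n number of variants in the panel.
#' @param maxSize optional maximum combination size (default: no cap).
#' @return combination count as a double (counts exceed integer range for
#'   large panels).
#' @examples
#' countCombinations(7)            # 127
#' countCombinations(31, maxSize = 9)
#' @export
countCombinations <- function(n, maxSize = NULL) {
    n <- as.integer(n)
    if (n < 1) stop("need at least one variant")
    k <- if (is.null(maxSize)) n else min(as.integer(maxSize), n)
    if (k < 1) stop("maxSize must be >= 1")
    sum(choose(n, seq_len(k)))
}

#' Planned test count for a scan series
#'
#' Bookkeeping used by the run manifest: every combination is tested against
#' every gene, so the planned number of association tests is
#' \code{countCombinations(nVariants, maxSize) * nGenes}. No tests are
#' executed. For the reference cohort's 24,123 genes this reproduces the
#' scale of full scans: a 15-variant panel plans 790,418,541 tests and a
#' 19-variant panel about 12.6 billion.
#'
#' @inheritParams countCombinations
#' @param nGenes number of genes in the expression matrix.
#' @return planned test count (double).
#' @export
plannedTests <- function(n, nGenes, maxSize = NULL) {
    countCombinations(n, maxSize) * as.double(nGenes)
}

# lexicographic successor of an index k-combination of 1..n (NULL when done)
.combSuccessor <- function(comb, n) {
    k <- length(comb)
    i <- k
    while (i >= 1 && comb[i] == n - k + i) i <- i - 1L
    if (i < 1) return(NULL)
    comb[i] <- comb[i] + 1L
    if (i < k) comb[(i + 1L):k] <- comb[i] + seq_len(k - i)
    comb
}

#' Streaming enumeration of variant combinations
#'
#' Enumerates every non-empty subset of the variant panel exactly once, in
#' deterministic order: increasing size, then lexicographic within a size
#' (variant identifiers are sorted first, so emitted members are already in
#' canonical order). The iterator yields chunks so that full-scale panels
#' (billions of subsets) never need to be materialized; memory use is
#' bounded by \code{chunkSize}. Size classes small enough to fit in one
#' chunk are generated with \code{utils::combn}; larger classes advance a
#' lexicographic successor cursor, so a truncated run is a well-defined
#' prefix that can be resumed from the reported cursor.
#'
#' @param variantIds character vector of variant identifiers.
#' @param maxSize optional maximum combination size.
#' @param chunkSize maximum number of combinations returned per call.
#' @return an object of class \code{CombinationIterator} with elements
#'   \describe{
#'     \item{nextChunk()}{returns a list of character vectors (each one
#'       combination in canonical member order), or \code{NULL} when
#'       exhausted.}
#'     \item{nextKeys()}{as \code{nextChunk()} but canonical
#'       \code{"+"}-joined keys.}
#'     \item{cursor()}{list \code{(size, index)} of the next combination to
#'       be emitted, for checkpointing.}
#'     \item{total}{exact total count.}
#'   }
#' @seealso [enumerateCombinations()] for small panels.
#' @examples
#' it <- combinationIterator(c("rs1", "rs2", "rs3"))
#' it$nextKeys()
#' @export
combinationIterator <- function(variantIds, maxSize = NULL, chunkSize = 131072L) {
    ids <- sort(unique(as.character(variantIds)))
    if (length(ids) != length(variantIds)) stop("variant identifiers must be unique")
    n <- length(ids)
    if (n < 1) stop("need at least one variant")
    kmax <- if (is.null(maxSize)) n else min(as.integer(maxSize), n)
    if (kmax < 1) stop("maxSize must be >= 1")
    chunkSize <- as.integer(chunkSize)

    size <- 1L         # current size class
    comb <- 1L         # next index combination within class (integer vector)
    classIdx <- 1L     # 1-based lexicographic index of `comb` within class
    done <- FALSE

    advanceClass <- function() {
        if (size < kmax) {
            size <<- size + 1L
            comb <<- seq_len(size)
            classIdx <<- 1L
        } else done <<- TRUE
    }

    nextIndexChunk <- function() {
        if (done) return(NULL)
        classTotal <- choose(n, size)
        remaining <- classTotal - classIdx + 1
        if (classIdx == 1L && remaining <= chunkSize) {
            out <- utils::combn(n, size)
            advanceClass()
            return(out)
        }
        m <- as.integer(min(remaining, chunkSize))
        out <- matrix(0L, nrow = size, ncol = m)
        cur <- comb
        for (j in seq_len(m)) {
            out[, j] <- cur
            cur <- .combSuccessor(cur, n)
        }
        classIdx <<- classIdx + m
        if (is.null(cur)) advanceClass() else comb <<- cur
        out
    }

    structure(list(
        nextChunk = function() {
            idx <- nextIndexChunk()
            if (is.null(idx)) return(NULL)
            lapply(seq_len(ncol(idx)), function(j) ids[idx[, j]])
        },
        nextKeys = function() {
            idx <- nextIndexChunk()
            if (is.null(idx)) return(NULL)
            if (nrow(idx) == 1L) ids[idx[1L, ]]
            else apply(idx, 2L, function(i) paste(ids[i], collapse = "+"))
        },
        nextN = function() {
            idx <- nextIndexChunk()
            if (is.null(idx)) NULL else ncol(idx)
        },
        cursor = function() if (done) NULL else list(size = size, index = classIdx),
        total = countCombinations(n, kmax),
        n = n,
        maxSize = kmax
    ), class = "CombinationIterator")
}

#' Materialize all combinations of a small panel
#'
#' Convenience wrapper around [combinationIterator()] that collects every
#' combination into a list; refuses panels whose subset count exceeds
#' \code{limit} (use the iterator for those).
#'
#' @inheritParams combinationIterator
#' @param limit guard on the materialized count.
#' @return list of character vectors in enumeration order.
#' @examples
#' length(enumerateCombinations(paste0("rs", 1:7)))  # 127
#' @export
enumerateCombinations <- function(variantIds, maxSize = NULL, limit = 2^20) {
    total <- countCombinations(length(variantIds), maxSize)
    if (total > limit)
        stop("panel enumerates ", total,
             " combinations; use combinationIterator() for streaming")
    it <- combinationIterator(variantIds, maxSize)
    out <- vector("list", total)
    i <- 0L
    repeat {
        ch <- it$nextChunk()
        if (is.null(ch)) break
        out[i + seq_along(ch)] <- ch
        i <- i + length(ch)
    }
    out
}

#' Count combinations by walking the streaming iterator
#'
#' @param iterator a \code{CombinationIterator}.
#' @return observed number of combinations yielded.
#' @export
streamCount <- function(iterator) {
    count <- 0
    repeat {
        m <- iterator$nextN()
        if (is.null(m)) break
        count <- count + m
    }
    count
}
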