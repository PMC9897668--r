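## Internal helpers shared across modules.

#' Nearest-rank percentile
#'
#' Lower nearest-rank percentile: the smallest element x[k] of the sorted
#' sample with k = ceiling(p/100 * n).  Used for the empirical FDR
#' thresholds and all gamma percentile rules, so every threshold is an
#' observed value.
#'
#' @param x numeric vector (NAs dropped).
#' @param p percentile in (0, 100].
#' @return the nearest-rank percentile value.
#' @export
nearestRankPercentile <- function(x, p) {
    x <- sort(x[!is.na(x)])
    n <- length(x)
    if (n == 0L) stop("no finite values")
    if (p <= 0 || p > 100) stop("p must be in (0, 100]")
    x[ceiling(p / 100 * n)]
}

## midpoints of axis elements (numeric, 1-based genome coords)
.midpoints <- function(gr) {
    (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2
}

## chromosome (character) per axis element
.chromOf <- function(gr) as.character(GenomicRanges::seqnames(gr))

## log-spaced bin edges
.logBinEdges <- function(d_min, d_max, n_bins) {
    exp(seq(log(d_min), log(d_max), length.out = n_bins + 1L))
}

## build a symmetric sparse matrix from canonical triplets (diagonal kept)
.sparseSym <- function(cm) {
    tr <- cm@triplets
    n <- length(cm@anchors)
    if (!nrow(tr))
        return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                    dims = c(n, n), symmetric = TRUE))
    Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$value, dims = c(n, n),
                         symmetric = TRUE)
}

## canonicalize triplets: i <= j, duplicates summed, zero rows dropped
.canonicalTriplets <- function(i, j, value) {
    swap <- i > j
    if (any(swap)) {
        tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
    }
    dt <- data.table::data.table(i = as.integer(i), j = as.integer(j),
                                 value = as.numeric(value))
    dt <- dt[, list(value = sum(value)), by = c("i", "j")]
    data.table::setorderv(dt, c("i", "j"))
    as.data.frame(dt)
}

## fast keyed lookup table for contact values; returns function(i, j) -> value
.contactLookup <- function(cm) {
    tr <- cm@triplets
    n <- length(cm@anchors)
    key <- (tr$i - 1) * n + tr$j
    val <- tr$value
    ord <- order(key)
    key <- key[ord]; val <- val[ord]
    function(qi, qj) {
        lo <- pmin(qi, qj); hi <- pmax(qi, qj)
        q <- (lo - 1) * n + hi
        pos <- findInterval(q, key)
        out <- numeric(length(q))
        hit <- pos > 0L
        hit[hit] <- key[pos[hit]] == q[hit]
        out[hit] <- val[pos[hit]]
        out
    }
}

## Mann-Whitney AUROC of scores for positives vs negatives
.auroc <- function(pos, neg) {
    r <- rank(c(pos, neg))
    n1 <- length(pos); n2 <- length(neg)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

## new ContactMatrix with shared boilerplate
.newContactMatrix <- function(anchors, triplets, state = "raw",
                              binsize = NA_real_, mask = integer(),
                              biases = numeric(), diagnostics = list()) {
    new("ContactMatrix", anchors = anchors, triplets = triplets,
        state = state, binsize = binsize, mask = mask, biases = biases,
        diagnostics = diagnostics)
}
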