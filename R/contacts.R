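## Contact-matrix operations: binning, iterative-correction balancing,
## global decay fitting, distance-stratified joint normalization and
## sample-correlation clustering.

#' Build a uniform bin axis
#'
#' @param x a [FragmentMap] (bins cover its chromosomes) or a named numeric
#'   vector of chromosome lengths.
#' @param binsize bin size in bp.
#' @return GRanges of bins with an `index` column and a `binsize` attribute.
#' @export
binAxis <- function(x, binsize) {
    if (binsize <= 0) stop("binsize must be positive")
    sl <- if (is(x, "FragmentMap")) {
        gr <- fragments(x)
        vapply(split(end(gr), .chromOf(gr)), max, numeric(1))
    } else x
    sl <- sl[order(names(sl))]
    pieces <- lapply(names(sl), function(chr) {
        n <- ceiling(sl[[chr]] / binsize)
        st <- (seq_len(n) - 1) * binsize + 1
        data.frame(chrom = chr, start = st,
                   end = pmin(st + binsize - 1, sl[[chr]]))
    })
    df <- do.call(rbind, pieces)
    bins <- GRanges(df$chrom, IRanges(df$start, df$end))
    bins$index <- seq_along(bins)
    GenomeInfoDb::seqlengths(bins) <- sl[GenomeInfoDb::seqlevels(bins)]
    attr(bins, "binsize") <- binsize
    bins
}

#' Bin a fragment-level contact matrix
#'
#' Each fragment-pair count is added to the bin pair containing the two
#' fragment midpoints.  Total counts are conserved exactly.
#'
#' @param cm raw fragment-level [ContactMatrix].
#' @param binsize bin size in bp.
#' @return A raw [ContactMatrix] on a uniform bin axis.
#' @export
binContacts <- function(cm, binsize) {
    if (binsize <= 0) stop("binsize must be positive")
    if (!is.na(binSize(cm))) stop("matrix is already binned")
    frags <- anchors(cm)
    sl <- vapply(split(end(frags), .chromOf(frags)), max, numeric(1))
    bins <- binAxis(sl, binsize)
    ## map every fragment to the bin holding its midpoint
    bchr <- .chromOf(bins)
    offsets <- vapply(unique(bchr), function(chr) min(bins$index[bchr == chr]) - 1L,
                      numeric(1))
    mid <- .midpoints(frags)
    fbin <- offsets[.chromOf(frags)] + floor((mid - 1) / binsize) + 1L
    tr <- triplets(cm)
    out <- .canonicalTriplets(fbin[tr$i], fbin[tr$j], tr$value)
    .newContactMatrix(bins, out, binsize = binsize)
}

#' Iterative-correction (IC) balancing
#'
#' Imakaev-style matrix balancing: factors the observed counts o_ij into
#' b_ij = o_ij / (v_i v_j) with a multiplicative bias v per axis element,
#' such that the row sums of the balanced matrix are equal.  The diagonal
#' is excluded from balancing; rows with fewer than `min_row_sum` raw
#' off-diagonal counts are masked and removed from the output.
#'
#' @param cm raw [ContactMatrix].
#' @param max_iter maximum number of iterations (default 200).
#' @param tol convergence tolerance on the relative spread of unmasked row
#'   sums (default 1e-5).
#' @param min_row_sum minimum raw off-diagonal row sum (default 10).
#' @return A balanced [ContactMatrix]; the bias vector is available via
#'   [biases()] (NA at masked elements) and convergence information in the
#'   `diagnostics` slot.  Non-convergence raises a warning and flags the
#'   partial result.
#' @export
icNormalize <- function(cm, max_iter = 200L, tol = 1e-5, min_row_sum = 10) {
    if (contactState(cm) != "raw") stop("icNormalize expects a raw matrix")
    n <- length(anchors(cm))
    tr <- triplets(cm)
    off <- tr[tr$i != tr$j, , drop = FALSE]
    W <- Matrix::sparseMatrix(i = off$i, j = off$j, x = off$value,
                              dims = c(n, n), symmetric = TRUE)
    raw_rs <- Matrix::rowSums(W)
    mask <- which(raw_rs < min_row_sum)
    keep <- setdiff(seq_len(n), mask)
    if (!length(keep)) stop("all rows masked; nothing to balance")
    W <- W[keep, keep, drop = FALSE]
    v <- rep(1, length(keep))
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(max_iter)) {
        iters <- it
        s <- as.vector(W %*% (1 / v)) / v
        m <- mean(s)
        if (max(abs(s / m - 1)) < tol) { converged <- TRUE; break }
        d <- sqrt(s / m)
        d[s == 0] <- 1
        v <- v * d
    }
    if (!converged)
        warning("iterative correction did not converge after ", max_iter,
                " iterations; result flagged")
    ## scale so balanced row sums are ~1
    s <- as.vector(W %*% (1 / v)) / v
    v <- v * sqrt(mean(s))
    vfull <- rep(NA_real_, n)
    vfull[keep] <- v
    ok <- !(tr$i %in% mask) & !(tr$j %in% mask)
    out <- tr[ok, , drop = FALSE]
    out$value <- out$value / (vfull[out$i] * vfull[out$j])
    rownames(out) <- NULL
    .newContactMatrix(anchors(cm), out, state = "balanced",
                      binsize = binSize(cm), mask = as.integer(mask),
                      biases = vfull,
                      diagnostics = list(converged = converged,
                                         iterations = iters, tol = tol))
}

## per-axis-element counts of possible intra-chromosomal partners per
## distance bin (one-sided, j > i), plus one-sided observed aggregation
## helpers; edges are log-bin boundaries in bp.
.possiblePairsPerBin <- function(anchors, keep, edges) {
    chr <- .chromOf(anchors)
    nb <- length(edges) - 1L
    counts <- matrix(0, nrow = length(anchors), ncol = nb)
    for (c0 in unique(chr)) {
        sel <- which(chr == c0 & seq_along(anchors) %in% keep)
        if (!length(sel)) next
        mids <- .midpoints(anchors)[sel]
        for (b in seq_len(nb)) {
            lo <- findInterval(mids + edges[b], mids)       # d >  edges[b]
            hi <- findInterval(mids + edges[b + 1], mids)   # d <= edges[b+1]
            counts[sel, b] <- counts[sel, b] + (hi - lo)
        }
    }
    counts
}

#' Fit the global power-law contact decay
#'
#' Mean balanced contact per possible intra-chromosomal pair is computed in
#' log-spaced distance bins; a least-squares line on (log d, log mean)
#' yields the scaling exponent alpha (slope = -alpha).  The representative
#' distance of a bin is the mean log distance of its observed pairs, which
#' makes the estimator exact on noiseless power-law input.
#'
#' @param cm balanced [ContactMatrix].
#' @param d_min,d_max fitted distance range in bp (default 10 kb - 1 Mb).
#' @param n_logbins number of log-spaced distance bins (default 20).
#' @return A [DecayModel].
#' @export
fitDecay <- function(cm, d_min = 1e4, d_max = 1e6, n_logbins = 20L) {
    if (contactState(cm) == "raw")
        stop("fitDecay expects a balanced matrix")
    if (d_min >= d_max) stop("d_min must be < d_max")
    a <- anchors(cm)
    keep <- setdiff(seq_along(a), maskedAnchors(cm))
    edges <- .logBinEdges(d_min, d_max, n_logbins)
    tr <- triplets(cm)
    chr <- .chromOf(a); mid <- .midpoints(a)
    intra <- chr[tr$i] == chr[tr$j] & tr$i != tr$j
    d <- abs(mid[tr$j] - mid[tr$i])
    sel <- intra & d > edges[1] & d <= edges[length(edges)]
    d <- d[sel]; val <- tr$value[sel]
    bin <- findInterval(d, edges, left.open = TRUE)
    sumv <- tapply(val, factor(bin, levels = seq_len(n_logbins)), sum)
    sumv[is.na(sumv)] <- 0
    obs <- val > 0
    xlog <- tapply(log(d[obs]), factor(bin[obs], levels = seq_len(n_logbins)),
                   mean)
    poss <- colSums(.possiblePairsPerBin(a, keep, edges))
    ok <- poss > 0 & sumv > 0 & !is.na(xlog)
    if (sum(ok) < 3L) stop("fewer than 3 non-empty distance bins")
    y <- log(as.numeric(sumv[ok]) / poss[ok])
    x <- as.numeric(xlog[ok])
    fit <- stats::lm.fit(cbind(1, x), y)
    new("DecayModel", exponent = -fit$coefficients[[2]],
        intercept = fit$coefficients[[1]], dRange = c(d_min, d_max),
        binTable = data.frame(bin = which(ok), log_d = x, log_mean = y,
                              n_possible = poss[ok]))
}

## stratum id per triplet row: intra-chromosomal bin offset (binned axes)
## or log-distance bin (fragment axes); diagonal and inter-chromosomal
## pairs get their own strata.
.strataIds <- function(cm) {
    a <- anchors(cm)
    tr <- triplets(cm)
    chr <- .chromOf(a)
    intra <- chr[tr$i] == chr[tr$j]
    id <- rep("inter", nrow(tr))
    if (!is.na(binSize(cm))) {
        id[intra] <- sprintf("d%d", tr$j[intra] - tr$i[intra])
    } else {
        mid <- .midpoints(a)
        d <- abs(mid[tr$j] - mid[tr$i])
        edges <- .logBinEdges(max(1, min(d[intra & d > 0])),
                              max(d[intra]) + 1, 20L)
        b <- findInterval(d, edges, rightmost.closed = TRUE)
        id[intra] <- sprintf("d%d", b[intra])
        id[intra & d == 0] <- "diag"
    }
    id
}

#' Distance-stratified joint normalization
#'
#' Rescales a set of samples so that, within every distance stratum, each
#' sample's stratum total equals the geometric mean of the stratum totals
#' across samples.  For binned axes a stratum is one bin offset; diagonal
#' and inter-chromosomal entries form their own strata.  This removes
#' between-sample sampling-depth and decay-shape differences before
#' contact-crossing and looping comparisons.
#'
#' @param samples list of [ContactMatrix] objects on identical axes.
#' @return list of jointly-normalized [ContactMatrix] objects.
#' @export
jointNormalize <- function(samples) {
    if (length(samples) < 2L) stop("need at least two samples")
    ref <- anchors(samples[[1]])
    for (s in samples[-1]) {
        a <- anchors(s)
        if (length(a) != length(ref) ||
            !all(start(a) == start(ref)) ||
            !all(.chromOf(a) == .chromOf(ref)))
            stop("samples must share an identical axis")
    }
    ids <- lapply(samples, .strataIds)
    totals <- lapply(seq_along(samples), function(k)
        tapply(triplets(samples[[k]])$value, ids[[k]], sum))
    strata <- unique(unlist(lapply(totals, names)))
    tmat <- vapply(totals, function(t) {
        out <- rep(0, length(strata)); names(out) <- strata
        out[names(t)] <- t
        out
    }, numeric(length(strata)))
    pos <- tmat > 0
    gm <- exp(rowSums(log(pmax(tmat, 1e-300)) * pos) / pmax(rowSums(pos), 1))
    gm[rowSums(pos) == 0] <- 0
    lapply(seq_along(samples), function(k) {
        cm <- samples[[k]]
        tr <- triplets(cm)
        tot <- tmat[ids[[k]], k]
        f <- ifelse(tot > 0, gm[ids[[k]]] / tot, 1)
        tr$value <- tr$value * f
        .newContactMatrix(anchors(cm), tr, state = "joint",
                          binsize = binSize(cm), mask = maskedAnchors(cm),
                          biases = biases(cm), diagnostics = cm@diagnostics)
    })
}

#' Correlation-based clustering of Hi-C samples
#'
#' For every pair of samples, bin pairs passing all filters in both samples
#' (value >= `min_count`, separation <= `max_sep`, off-diagonal when
#' `drop_diagonal`) are correlated; the between-sample distance is
#' 1 - |correlation| and samples are clustered hierarchically.
#'
#' @param samples named list of >= 2 [ContactMatrix] objects on a common
#'   axis.
#' @param min_count minimum contact count required in both samples
#'   (default 2).
#' @param max_sep maximum bin-pair separation in bp (default 1.6 Mb).
#' @param drop_diagonal drop within-bin (diagonal) contacts (default TRUE).
#' @param corr `"spearman"` or `"pearson"`.
#' @param linkage hclust agglomeration: `"average"` or `"complete"`.
#' @return list with `distance` (a dist), `correlation` (matrix) and
#'   `tree` (hclust dendrogram).
#' @export
correlationCluster <- function(samples, min_count = 2, max_sep = 1.6e6,
                               drop_diagonal = TRUE,
                               corr = c("spearman", "pearson"),
                               linkage = c("average", "complete")) {
    corr <- match.arg(corr)
    linkage <- match.arg(linkage)
    if (length(samples) < 2L) stop("need at least two samples")
    if (is.null(names(samples)))
        names(samples) <- paste0("sample", seq_along(samples))
    a <- anchors(samples[[1]])
    chr <- .chromOf(a); mid <- .midpoints(a)
    filt <- lapply(samples, function(cm) {
        tr <- data.table::as.data.table(triplets(cm))
        tr <- tr[tr$value >= min_count &
                 chr[tr$i] == chr[tr$j] &
                 abs(mid[tr$j] - mid[tr$i]) <= max_sep, ]
        if (drop_diagonal) tr <- tr[tr$i != tr$j, ]
        data.table::setkeyv(tr, c("i", "j"))
        tr
    })
    ns <- length(samples)
    cmat <- diag(1, ns)
    rownames(cmat) <- colnames(cmat) <- names(samples)
    for (p in seq_len(ns - 1)) for (q in seq(p + 1, ns)) {
        m <- merge(filt[[p]], filt[[q]], by = c("i", "j"))
        if (!nrow(m)) stop("no surviving bin pairs for ",
                           names(samples)[p], " vs ", names(samples)[q])
        cmat[p, q] <- cmat[q, p] <-
            stats::cor(m$value.x, m$value.y, method = corr)
    }
    dmat <- stats::as.dist(1 - abs(cmat))
    list(distance = dmat, correlation = cmat,
         tree = stats::hclust(dmat, method = linkage))
}
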