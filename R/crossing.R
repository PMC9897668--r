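## Contact-crossing difference curves: symmetric bin-pair contacts at
## increasing offsets around candidate insulators, mutant minus control,
## averaged over regions.

## bin index containing each region midpoint
.centerBins <- function(cm, regs) {
    a <- anchors(cm)
    .resolveAxis(a, .chromOf(regs), floor(.midpoints(regs)))
}

#' Symmetric crossing contacts around a center bin
#'
#' Returns the contact values between bin pairs `(center - k, center + k)`
#' for k = 1..`max_offset`.  Offsets for which either bin falls outside
#' the center's chromosome are NA (unavailable); entries absent from the
#' sparse matrix read as 0.
#'
#' @param cm a binned (ideally jointly-normalized) [ContactMatrix].
#' @param center_bin axis index of the center bin.
#' @param max_offset largest offset in bins (default 60).
#' @return numeric vector of length `max_offset`.
#' @export
crossingContacts <- function(cm, center_bin, max_offset = 60L) {
    a <- anchors(cm)
    chr <- .chromOf(a)
    c0 <- chr[center_bin]
    lo <- min(which(chr == c0)); hi <- max(which(chr == c0))
    k <- seq_len(max_offset)
    left <- center_bin - k; right <- center_bin + k
    out <- rep(NA_real_, max_offset)
    ok <- left >= lo & right <= hi
    if (any(ok)) {
        lookup <- .contactLookup(cm)
        out[ok] <- lookup(left[ok], right[ok])
    }
    out
}

#' Contact-crossing difference curve
#'
#' For every center, the symmetric crossing contacts of the mutant and
#' control matrices are subtracted (mutant minus control, so loss of
#' insulation in the mutant yields a positive curve) and averaged over
#' centers per offset, ignoring offsets unavailable for a region.
#' Offsets 1-2 are flagged low-confidence (close-range Hi-C estimates are
#' less reliable) but kept.
#'
#' @param cm_mut,cm_con jointly-normalized binned [ContactMatrix] objects
#'   on a common axis.
#' @param centers GRanges of candidate regions (midpoints define center
#'   bins) or an integer vector of bin indices.
#' @param max_offset largest offset in bins (default 60).
#' @return A [CrossingCurve].
#' @export
crossingDifferenceCurve <- function(cm_mut, cm_con, centers,
                                    max_offset = 60L) {
    a <- anchors(cm_mut)
    b <- anchors(cm_con)
    if (length(a) != length(b) || !all(start(a) == start(b)) ||
        !all(.chromOf(a) == .chromOf(b)))
        stop("matrices must share an identical axis")
    if (contactState(cm_mut) == "raw" || contactState(cm_con) == "raw")
        warning("crossing curves expect normalized matrices")
    bins <- if (is(centers, "GRanges")) .centerBins(cm_mut, centers)
            else as.integer(centers)
    chr <- .chromOf(a)
    lookup_m <- .contactLookup(cm_mut)
    lookup_c <- .contactLookup(cm_con)
    k <- seq_len(max_offset)
    per <- matrix(NA_real_, nrow = length(bins), ncol = max_offset)
    for (r in seq_along(bins)) {
        cb <- bins[r]
        c0 <- chr[cb]
        lo <- min(which(chr == c0)); hi <- max(which(chr == c0))
        ok <- (cb - k) >= lo & (cb + k) <= hi
        if (any(ok))
            per[r, ok] <- lookup_m(cb - k[ok], cb + k[ok]) -
                          lookup_c(cb - k[ok], cb + k[ok])
    }
    n <- colSums(!is.na(per))
    mu <- colMeans(per, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    se <- apply(per, 2, function(x) {
        x <- x[!is.na(x)]
        if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    })
    new("CrossingCurve", offsets = as.integer(k), mean = mu, se = se,
        n = as.integer(n), perRegion = per,
        binsize = binSize(cm_mut),
        lowConfidence = k <= 2L)
}

#' Combine crossing curves from replicate experiments
#'
#' Replicate curves can be combined after region-averaging (`"after"`,
#' the default: the mean of the replicate mean curves) or before
#' (`"before"`: per-region differences of all replicates pooled, then
#' averaged).
#'
#' @param curves list of [CrossingCurve] objects on the same offsets.
#' @param order `"after"` or `"before"`.
#' @return A combined [CrossingCurve].
#' @export
combineCrossingCurves <- function(curves, order = c("after", "before")) {
    order <- match.arg(order)
    if (length(curves) < 2L) stop("need at least two curves")
    K <- length(curves[[1]]@offsets)
    for (cv in curves[-1])
        if (length(cv@offsets) != K) stop("offset grids differ")
    per <- do.call(rbind, lapply(curves, slot, "perRegion"))
    if (order == "after") {
        mus <- vapply(curves, slot, numeric(K), "mean")
        mu <- rowMeans(mus)
        ses <- vapply(curves, slot, numeric(K), "se")
        se <- sqrt(rowSums(ses^2)) / length(curves)
    } else {
        mu <- colMeans(per, na.rm = TRUE)
        se <- apply(per, 2, function(x) {
            x <- x[!is.na(x)]
            if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
        })
    }
    new("CrossingCurve", offsets = curves[[1]]@offsets, mean = mu, se = se,
        n = as.integer(colSums(!is.na(per))), perRegion = per,
        binsize = curves[[1]]@binsize,
        lowConfidence = curves[[1]]@lowConfidence)
}

#' Tabulate a crossing curve
#'
#' @param curve a [CrossingCurve].
#' @return data.frame with offset_bins, offset_kb, mean_diff, se, n,
#'   low_confidence.
#' @export
crossingCurveTable <- function(curve) {
    data.frame(offset_bins = curve@offsets,
               offset_kb = curve@offsets * curve@binsize / 1000,
               mean_diff = curve@mean, se = curve@se, n = curve@n,
               low_confidence = curve@lowConfidence)
}
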