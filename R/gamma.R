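## The distance-scaling factor gamma: per-fragment fits, region assignment
## via weighted 200-bp sliding windows, delta-gamma, and TAD border
## calling/reconciliation.

## two-sided possible-partner counts per fragment per distance bin,
## restricted to partners in `keep`
.possiblePartnersPerBin <- function(anchors, keep, edges) {
    chr <- .chromOf(anchors)
    nb <- length(edges) - 1L
    counts <- matrix(0L, nrow = length(anchors), ncol = nb)
    keepmask <- logical(length(anchors))
    keepmask[keep] <- TRUE
    allmid <- .midpoints(anchors)
    eps <- 1e-6
    for (c0 in unique(chr)) {
        sel <- which(chr == c0 & keepmask)
        if (length(sel) < 2L) next
        mids <- allmid[sel]
        for (b in seq_len(nb)) {
            lo <- edges[b]; hi <- edges[b + 1]
            right <- findInterval(mids + hi, mids) -
                     findInterval(mids + lo, mids)
            left <- findInterval(mids - lo - eps, mids) -
                    findInterval(mids - hi - eps, mids)
            counts[sel, b] <- right + left
        }
    }
    counts
}

## High-pass filter for an IC bias vector: technical per-fragment biases
## are fragment-autonomous (high-frequency along the genome), whereas
## contact-limiting topology depresses IC biases smoothly over tens of
## kb.  Dividing by a running median keeps the former and discards the
## latter, so bias correction does not erase the very deficits gamma
## must detect.
.highPassBiases <- function(b, chrom, window = 51L) {
    out <- rep(NA_real_, length(b))
    for (c0 in unique(chrom)) {
        sel <- which(chrom == c0)
        x <- b[sel]
        ok <- !is.na(x)
        if (!any(ok)) next
        k <- min(window, sum(ok))
        if (k %% 2L == 0L) k <- k - 1L
        smooth <- if (k < 3L) rep(stats::median(x[ok]), sum(ok))
                  else stats::runmed(x[ok], k, endrule = "median")
        v <- rep(NA_real_, length(x))
        v[ok] <- x[ok] / smooth
        out[sel] <- v
    }
    out
}

#' Fit the per-fragment distance-scaling factor gamma
#'
#' For each fragment, its bias-corrected contacts `o_ij / (v_i v_j)` with
#' partners at distances within `[d_min, d_max]` are aggregated into
#' log-spaced distance bins (sum divided by the number of possible
#' partners per bin, so unobserved pairs count as zeros); gamma is the
#' negative least-squares slope through the fragment's (log d, log mean)
#' profile, weighted by per-bin contact totals and anchored on the
#' intercept of the global decay fit pooled over all fragments.  The
#' anchoring means a fragment whose contacts sit uniformly below the
#' global expectation — the signature of a contact-limiting element —
#' receives a correspondingly higher scaling factor, while on
#' homogeneous power-law input gamma equals the generating exponent
#' everywhere.  Technical biases are taken as the high-frequency
#' component of the IC bias vector (see Details).  Fragments with fewer
#' than `min_bins` non-empty bins are undefined: masked, never
#' zero-filled.
#'
#' @details Raw balancing biases are unsuitable for per-pair correction
#'   here for two reasons: raw row sums depend on the local restriction-
#'   fragment geometry (how close the nearest midpoints sit), and they
#'   absorb the smooth topological depletion around contact-limiting
#'   elements — the very signal gamma must detect.  `fitGamma` therefore
#'   re-estimates fragment-autonomous biases internally: each fragment's
#'   contacts in the fit band are compared to the distance-matched global
#'   expectation (removing the geometry artifact), and the resulting
#'   level is divided by a `bias_window`-fragment running median per
#'   chromosome (removing smooth topology while keeping the
#'   fragment-autonomous technical bias).  The supplied IC vector defines
#'   which fragments are masked.
#'
#' @param cm raw fragment-level [ContactMatrix].
#' @param biases per-fragment bias vector from [icNormalize()] (NA at
#'   masked fragments).
#' @param d_min,d_max distance range in bp (defaults 10 kb and 500 kb).
#' @param n_logbins number of log-spaced distance bins (default 12).
#' @param min_bins minimum non-empty bins for a defined gamma (default 5).
#' @param bias_window running-median window (fragments) of the bias
#'   high-pass (default 51).
#' @return A [GammaTrack].
#' @export
fitGamma <- function(cm, biases, d_min = 1e4, d_max = 5e5,
                     n_logbins = 12L, min_bins = 5L, bias_window = 51L) {
    if (missing(biases) || is.null(biases))
        stop("fitGamma needs the bias vector from icNormalize")
    frags <- anchors(cm)
    n <- length(frags)
    if (length(biases) != n) stop("bias vector length != number of fragments")
    chr <- .chromOf(frags)
    mid <- .midpoints(frags)
    edges <- .logBinEdges(d_min, d_max, n_logbins)
    tr <- triplets(cm)
    ok <- chr[tr$i] == chr[tr$j] & tr$i != tr$j &
        !is.na(biases[tr$i]) & !is.na(biases[tr$j])
    tr <- tr[ok, , drop = FALSE]
    d <- abs(mid[tr$j] - mid[tr$i])
    inrange <- d > edges[1] & d <= edges[length(edges)]
    tr <- tr[inrange, , drop = FALSE]
    d <- d[inrange]
    bin <- findInterval(d, edges, left.open = TRUE)
    logd <- log(d)
    keep <- which(!is.na(biases))
    poss <- .possiblePartnersPerBin(frags, keep, edges)
    ## weighted pooled decay fit on (x, y) bin aggregates
    pooledFit <- function(agg) {
        glob <- agg[, list(sumval = sum(sumval), possible = sum(possible),
                           x = sum(sumlogd) / sum(nobs)), by = "bin"]
        gx <- glob$x; gy <- log(glob$sumval / glob$possible)
        gw <- glob$sumval
        sw <- sum(gw); mx <- sum(gw * gx) / sw; my <- sum(gw * gy) / sw
        slope <- sum(gw * (gx - mx) * (gy - my)) / sum(gw * (gx - mx)^2)
        c(intercept = my - slope * mx, slope = slope)
    }
    aggregate <- function(val) {
        ## each pair informs both endpoints
        dt <- data.table::data.table(
            frag = c(tr$i, tr$j), bin = c(bin, bin),
            val = c(val, val), logd = c(logd, logd))
        agg <- dt[, list(sumval = sum(val), nobs = .N,
                         sumlogd = sum(logd)), by = c("frag", "bin")]
        agg$possible <- poss[cbind(agg$frag, agg$bin)]
        agg[agg$sumval > 0 & agg$possible > 0, ]
    }
    ## pass 1: raw levels against the distance-matched global expectation
    agg <- aggregate(tr$value)
    gf <- pooledFit(agg)
    agg$x <- agg$sumlogd / agg$nobs
    lev <- agg[, list(level = sum(sumval) /
                          sum(possible * exp(gf[["intercept"]] +
                                             gf[["slope"]] * x))),
               by = "frag"]
    level <- rep(NA_real_, n)
    level[lev$frag] <- lev$level
    vhat <- .highPassBiases(level, chr, bias_window)
    vhat[is.na(vhat)] <- 1
    ## pass 2: bias-corrected profiles, anchored on the global intercept
    agg <- aggregate(tr$value / (vhat[tr$i] * vhat[tr$j]))
    gf <- pooledFit(agg)
    c0 <- gf[["intercept"]]
    agg$x <- agg$sumlogd / agg$nobs
    agg$y <- log(agg$sumval / agg$possible)
    agg$w <- agg$sumval
    fit <- agg[, {
        if (.N >= min_bins) {
            list(gamma = sum(w * x * (c0 - y)) / sum(w * x^2),
                 n_bins = .N, contacts = sum(sumval))
        } else list(gamma = NA_real_, n_bins = .N, contacts = sum(sumval))
    }, by = "frag"]
    gamma <- rep(NA_real_, n)
    nb <- integer(n)
    contacts <- numeric(n)
    gamma[fit$frag] <- fit$gamma
    nb[fit$frag] <- fit$n_bins
    contacts[fit$frag] <- fit$contacts
    gamma[is.na(biases)] <- NA_real_
    out <- frags
    out$gamma <- gamma
    out$n_bins <- nb
    out$contacts <- contacts
    out$defined <- !is.na(gamma)
    new("GammaTrack", fragments = out,
        params = list(d_min = d_min, d_max = d_max, n_logbins = n_logbins,
                      min_bins = min_bins))
}

#' Assign gamma values to regions via sliding windows
#'
#' Each region is segmented into `window`-bp sliding windows (step
#' `step`); a window's gamma is the overlap-weighted mean of the gamma of
#' the fragments it covers (weights renormalized over defined fragments),
#' and the region's gamma is the highest window value.  Regions shorter
#' than the window use one truncated window spanning the region.
#'
#' @param track a [GammaTrack].
#' @param regs GRanges of regions (same genome as the track).
#' @param window window width in bp (default 200).
#' @param step window step in bp (default 100).
#' @return the input GRanges with `gamma` and `n_windows` columns
#'   (`gamma` NA where all windows are undefined).
#' @export
assignRegionGamma <- function(track, regs, window = 200L, step = 100L) {
    frags <- fragments(track)
    fchr <- unique(.chromOf(frags))
    chrlen <- vapply(fchr, function(c0) max(end(frags)[.chromOf(frags) == c0]),
                     numeric(1))
    rchr <- .chromOf(regs)
    if (any(!rchr %in% fchr) ||
        any(end(regs) > chrlen[rchr]) || any(start(regs) < 1))
        stop("region outside the fragment map")
    if (!length(regs)) {
        regs$gamma <- numeric(0); regs$n_windows <- integer(0)
        return(regs)
    }
    ## enumerate windows per region
    wstarts <- lapply(seq_along(regs), function(r) {
        s <- start(regs)[r]; e <- end(regs)[r]
        if (e - s + 1 < window) return(s)  # single truncated window
        seq(s, e - window + 1, by = step)
    })
    nwin <- lengths(wstarts)
    ws <- unlist(wstarts)
    rid <- rep(seq_along(regs), nwin)
    we <- pmin(ws + window - 1L, end(regs)[rid])
    wins <- GRanges(rchr[rid], IRanges(ws, we))
    ov <- GenomicRanges::findOverlaps(wins, frags)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    wbp <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(wins)[qh], IRanges::ranges(frags)[sh]))
    g <- frags$gamma[sh]
    dt <- data.table::data.table(win = qh, w = wbp, g = g)[!is.na(g)]
    wg <- dt[, list(gamma = sum(w * g) / sum(w)), by = "win"]
    wingamma <- rep(NA_real_, length(wins))
    wingamma[wg$win] <- wg$gamma
    rg <- tapply(wingamma, rid, function(x)
        if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    regs$gamma <- as.numeric(rg[as.character(seq_along(regs))])
    regs$n_windows <- as.integer(nwin)
    regs
}

#' Region-level delta-gamma between knockout and control
#'
#' delta-gamma = gamma_KO - gamma_control per region; strongly negative
#' values mean the region lost its contact-limiting activity in the
#' knockout.  Undefined whenever either side is undefined (never imputed).
#'
#' @param track_ko,track_control [GammaTrack]s on identical fragment maps.
#' @param regs GRanges of regions.
#' @param window,step sliding-window parameters (see
#'   [assignRegionGamma()]).
#' @return the input GRanges with `gamma_control`, `gamma_ko` and
#'   `dgamma` columns.
#' @export
deltaGamma <- function(track_ko, track_control, regs,
                       window = 200L, step = 100L) {
    fk <- fragments(track_ko); fc <- fragments(track_control)
    if (length(fk) != length(fc) || !all(start(fk) == start(fc)) ||
        !all(.chromOf(fk) == .chromOf(fc)))
        stop("gamma tracks are on different fragment maps")
    ko <- assignRegionGamma(track_ko, regs, window, step)
    con <- assignRegionGamma(track_control, regs, window, step)
    regs$gamma_control <- con$gamma
    regs$gamma_ko <- ko$gamma
    regs$dgamma <- ko$gamma - con$gamma
    regs
}

#' Call TAD borders from a gamma track
#'
#' Fragments with gamma strictly above the genome-wide nearest-rank
#' percentile qualify; adjacent qualifiers (gap of at most one fragment)
#' are merged into border intervals scored by their peak gamma.
#'
#' @param track a [GammaTrack] with at least 100 defined fragments.
#' @param percentile gamma percentile threshold (default 95).
#' @param replicate replicate identifier stored in the result.
#' @return A [BorderSet].
#' @export
callTadBorders <- function(track, percentile = 95, replicate = "rep1") {
    frags <- fragments(track)
    g <- frags$gamma
    def <- which(frags$defined)
    if (length(def) < 100L)
        stop("need at least 100 defined fragments to call borders")
    thr <- nearestRankPercentile(g[def], percentile)
    qual <- def[g[def] > thr]
    if (!length(qual)) {
        return(new("BorderSet", borders = GRanges(), replicate = replicate))
    }
    chr <- .chromOf(frags)
    grp <- cumsum(c(1L, (diff(qual) > 2L) | (chr[qual[-1]] != chr[qual[-length(qual)]])))
    pieces <- lapply(split(qual, grp), function(ix) {
        data.frame(chrom = chr[ix[1]], start = start(frags)[ix[1]],
                   end = end(frags)[ix[length(ix)]],
                   score = max(g[ix]))
    })
    df <- do.call(rbind, pieces)
    bs <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
    new("BorderSet", borders = GenomicRanges::sort(bs),
        replicate = replicate)
}

#' Write a gamma track as TSV
#'
#' Columns: chrom, start (0-based), end, gamma, n_bins, defined.
#'
#' @param track a [GammaTrack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGammaTrack <- function(track, path) {
    fr <- fragments(track)
    utils::write.table(
        data.frame(chrom = .chromOf(fr), start = start(fr) - 1L,
                   end = end(fr), gamma = fr$gamma, n_bins = fr$n_bins,
                   defined = fr$defined),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gamma track written by [writeGammaTrack()]
#'
#' @param path TSV path.
#' @return A [GammaTrack].
#' @export
readGammaTrack <- function(path) {
    df <- as.data.frame(data.table::fread(path))
    fm <- fragmentMap(df[, c("chrom", "start", "end")])
    fr <- fragments(fm)
    fr$gamma <- df$gamma
    fr$n_bins <- as.integer(df$n_bins)
    fr$contacts <- if (is.null(df$contacts)) rep(NA_real_, nrow(df))
                   else df$contacts
    fr$defined <- df$defined
    new("GammaTrack", fragments = fr, params = list())
}

#' Reconcile TAD borders between replicates
#'
#' Greedy nearest-first matching of border midpoints within each
#' chromosome: the closest pair is merged first (ties broken by leftmost),
#' each border is matched at most once, and only pairs within `tol` bp
#' survive.  The consensus border is centered on the mean midpoint.
#'
#' @param set1,set2 [BorderSet]s from replicate experiments.
#' @param tol maximum midpoint distance in bp (default 2000).
#' @return A consensus [BorderSet].
#' @export
reconcileBorders <- function(set1, set2, tol = 2000) {
    b1 <- borders(set1); b2 <- borders(set2)
    out <- list()
    for (c0 in intersect(unique(.chromOf(b1)), unique(.chromOf(b2)))) {
        i1 <- which(.chromOf(b1) == c0); i2 <- which(.chromOf(b2) == c0)
        m1 <- .midpoints(b1)[i1]; m2 <- .midpoints(b2)[i2]
        cand <- expand.grid(a = seq_along(i1), b = seq_along(i2))
        cand$d <- abs(m1[cand$a] - m2[cand$b])
        cand <- cand[cand$d <= tol, , drop = FALSE]
        cand <- cand[order(cand$d, pmin(m1[cand$a], m2[cand$b])), ,
                     drop = FALSE]
        useda <- logical(length(i1)); usedb <- logical(length(i2))
        for (r in seq_len(nrow(cand))) {
            a <- cand$a[r]; b <- cand$b[r]
            if (useda[a] || usedb[b]) next
            useda[a] <- TRUE; usedb[b] <- TRUE
            mid <- (m1[a] + m2[b]) / 2
            out[[length(out) + 1L]] <- data.frame(
                chrom = c0, start = floor(mid), end = floor(mid) + 1,
                score = mean(c(b1$score[i1[a]], b2$score[i2[b]])))
        }
    }
    if (!length(out))
        return(new("BorderSet", borders = GRanges(), replicate = "consensus"))
    df <- do.call(rbind, out)
    bs <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
    new("BorderSet", borders = GenomicRanges::sort(bs),
        replicate = "consensus")
}

#' Overlap statistics between TAD borders and bound regions
#'
#' @param bset a [BorderSet] or GRanges of borders.
#' @param bound GRanges of insulator-protein bound regions.
#' @param slack bp added to each border before testing overlap (default 0).
#' @return list with `n_borders`, `n_overlapping_bound`, `pct_borders_bound`
#'   (rounded to one decimal), and the inverse `n_bound`,
#'   `n_bound_at_borders`, `pct_bound_at_borders`.
#' @examples
#' ## borders at TAD boundaries vs protein-bound regions
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 900), width = 50))
#' p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, 130))
#' borderOverlapStats(b, p)$pct_borders_bound  # 50
#' @export
borderOverlapStats <- function(bset, bound, slack = 0) {
    b <- if (is(bset, "BorderSet")) borders(bset) else bset
    if (!length(b)) stop("no borders")
    bx <- if (slack > 0) GenomicRanges::resize(b, width(b) + 2 * slack,
                                               fix = "center") else b
    hit <- IRanges::overlapsAny(bx, bound)
    inv <- IRanges::overlapsAny(bound, bx)
    list(n_borders = length(b),
         n_overlapping_bound = sum(hit),
         pct_borders_bound = round(100 * sum(hit) / length(b), 1),
         n_bound = length(bound),
         n_bound_at_borders = sum(inv),
         pct_bound_at_borders = round(100 * sum(inv) / length(bound), 1))
}
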