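## The insulator screen: random unbound control regions, empirical FDR
## thresholds on delta-gamma, class-level one-sided Fisher enrichment
## (both the gamma "limiting" test and the delta-gamma test), and the
## final insulator catalog with dependence labels.

#' Sample random unbound control regions
#'
#' Draws `n` regions with lengths resampled from the bound-region length
#' distribution, placed uniformly over chromosomes, rejecting candidates
#' that overlap any pooled peak (padded by `exclusion_pad`) or touch a
#' fragment without a defined gamma.  Seeded and deterministic.
#'
#' @param track a [GammaTrack] (defines chromosomes and defined-gamma
#'   territory).
#' @param all_peaks GRanges, pooled peaks of all profiled proteins.
#' @param n number of regions (default 344).
#' @param lengths numeric vector to resample region lengths from
#'   (typically `width()` of the bound regions).
#' @param exclusion_pad bp added around peaks (default 1000).
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget (default `1000 * n`).
#' @return GRanges of `n` control regions.
#' @export
sampleRandomUnbound <- function(track, all_peaks, n = 344L, lengths,
                                exclusion_pad = 1000, seed = 1L,
                                max_attempts = 1000L * n) {
    set.seed(seed)
    frags <- fragments(track)
    chr <- .chromOf(frags)
    chroms <- unique(chr)
    chrlen <- vapply(chroms, function(c0) max(end(frags)[chr == c0]),
                     numeric(1))
    excl <- if (length(all_peaks))
        GenomicRanges::reduce(GenomicRanges::resize(
            all_peaks, width(all_peaks) + 2 * exclusion_pad, fix = "center"))
    else GRanges()
    ## undefined-gamma fragments are exclusion zones too
    undef <- GenomicRanges::reduce(frags[!frags$defined])
    got <- list()
    n_got <- 0L
    attempts <- 0L
    while (n_got < n) {
        batch <- min(4L * (n - n_got), max_attempts - attempts)
        if (batch <= 0L)
            stop("could not place ", n, " unbound regions after ",
                 max_attempts, " attempts")
        attempts <- attempts + batch
        len <- sample(lengths, batch, replace = TRUE)
        c0 <- sample(chroms, batch, replace = TRUE, prob = chrlen)
        s <- floor(stats::runif(batch, 1, pmax(chrlen[c0] - len, 2)))
        cand <- GRanges(c0, IRanges(s, s + len - 1))
        bad <- s + len - 1 > chrlen[c0]
        if (length(excl)) bad <- bad | IRanges::overlapsAny(cand, excl)
        if (length(undef)) bad <- bad | IRanges::overlapsAny(cand, undef)
        keep <- which(!bad)
        if (length(keep)) {
            keep <- keep[seq_len(min(length(keep), n - n_got))]
            got[[length(got) + 1L]] <- cand[keep]
            n_got <- n_got + length(keep)
        }
    }
    picked <- suppressWarnings(do.call(c, got))
    picked$name <- sprintf("random%03d", seq_len(n))
    picked
}

#' Empirical FDR thresholds from a null delta-gamma distribution
#'
#' Nearest-rank lower percentiles of the delta-gamma values at random
#' unbound regions; regions at least as negative as a threshold are
#' callable at that FDR level.
#'
#' @param null_dgamma delta-gamma values at the random control regions
#'   (NAs dropped).
#' @param percentiles FDR levels in percent (default 5, 10, 15).
#' @return named numeric vector of thresholds (monotone non-decreasing).
#' @export
empiricalFdrThresholds <- function(null_dgamma, percentiles = c(5, 10, 15)) {
    x <- null_dgamma[!is.na(null_dgamma)]
    if (!length(x)) stop("no finite null values")
    if (any(!is.finite(x))) stop("null values must be finite")
    out <- vapply(percentiles, function(p) nearestRankPercentile(x, p),
                  numeric(1))
    names(out) <- paste0("fdr", percentiles)
    out
}

#' Class-level delta-gamma enrichment (one-sided Fisher test)
#'
#' Compares the proportion of class regions at or below the bottom-`q`
#' null threshold to that proportion among the null regions, one-sided
#' (alternative: the class proportion is greater).  Ties at the threshold
#' count as below.
#'
#' @param class_dgamma delta-gamma values of one cobinding class (NAs
#'   dropped).
#' @param null_dgamma delta-gamma values of the random control regions.
#' @param q bottom quantile defining the threshold (default 0.10).
#' @return list with `p.value`, `threshold`, `table` (2x2), `n_class`,
#'   `n_below`.
#' @export
classDgammaEnrichment <- function(class_dgamma, null_dgamma, q = 0.10) {
    cls <- class_dgamma[!is.na(class_dgamma)]
    nul <- null_dgamma[!is.na(null_dgamma)]
    if (!length(cls)) stop("class has no defined delta-gamma values")
    thr <- nearestRankPercentile(nul, 100 * q)
    tab <- matrix(c(sum(cls <= thr), sum(cls > thr),
                    sum(nul <= thr), sum(nul > thr)), nrow = 2,
                  dimnames = list(c("below", "above"), c("class", "null")))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    list(p.value = p, threshold = thr, table = tab,
         n_class = length(cls), n_below = tab[1, 1])
}

#' Class-level "limiting" test on control-condition gamma
#'
#' Tests whether a class has more regions with gamma above the top
#' quartile of the random-region gamma distribution than the 25% baseline
#' (one-tailed Fisher's exact test).
#'
#' @param class_gamma gamma values of one class (control condition).
#' @param null_gamma gamma values of the random control regions.
#' @return list with `fraction_above`, `p.value`, `threshold`, `table`.
#' @export
classLimitingTest <- function(class_gamma, null_gamma) {
    cls <- class_gamma[!is.na(class_gamma)]
    nul <- null_gamma[!is.na(null_gamma)]
    if (!length(cls)) stop("empty class")
    thr <- nearestRankPercentile(nul, 75)
    tab <- matrix(c(sum(cls > thr), sum(cls <= thr),
                    sum(nul > thr), sum(nul <= thr)), nrow = 2,
                  dimnames = list(c("above", "below"), c("class", "null")))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    list(fraction_above = tab[1, 1] / length(cls), p.value = p,
         threshold = thr, table = tab)
}

#' Call putative insulator elements
#'
#' Two-step rule per knockout: (1) classes whose fraction of regions in
#' the bottom-`q` delta-gamma tail significantly exceeds the random-region
#' fraction (one-sided Fisher, `p < alpha`) are significant; (2) a region
#' is called at FDR level f iff its class is significant for that
#' knockout and its delta-gamma is at or below the level-f threshold.
#' Calls are nested (a 5% call is also a 10% and 15% call); the reported
#' level is the strictest one.  Dependence is Cp190 / CTCF / both by
#' which knockout(s) call the region at the loosest level.
#'
#' @param regs GRanges with metadata columns `class`, `dgamma_cp190`,
#'   `dgamma_ctcf` (see [deltaGamma()]); an optional logical `excluded`
#'   column removes flagged classes from testing.
#' @param null_cp190,null_ctcf delta-gamma values of the random control
#'   regions under each knockout.
#' @param alpha class-significance cutoff (default 1e-4).
#' @param q bottom quantile for the class test (default 0.10).
#' @param fdr_levels FDR levels in percent (default 5, 10, 15).
#' @return A [ScreenResult].
#' @export
callInsulators <- function(regs, null_cp190, null_ctcf, alpha = 1e-4,
                           q = 0.10, fdr_levels = c(5, 10, 15)) {
    mc <- mcols(regs)
    need <- c("class", "dgamma_cp190", "dgamma_ctcf")
    if (!all(need %in% names(mc)))
        stop("regions need class, dgamma_cp190 and dgamma_ctcf columns")
    excluded <- if ("excluded" %in% names(mc)) mc$excluded else
        logical(length(regs))
    kos <- c(Cp190KO = "dgamma_cp190", CTCFKO = "dgamma_ctcf")
    nulls <- list(Cp190KO = null_cp190[!is.na(null_cp190)],
                  CTCFKO = null_ctcf[!is.na(null_ctcf)])
    thresholds <- lapply(nulls, empiricalFdrThresholds,
                         percentiles = fdr_levels)
    classes <- sort(unique(mc$class))
    stats_list <- list()
    signif <- list(Cp190KO = character(), CTCFKO = character())
    for (ko in names(kos)) {
        dg <- mc[[kos[[ko]]]]
        for (cl in classes) {
            sel <- mc$class == cl & !is.na(dg)
            if (!sum(sel) || any(excluded[mc$class == cl])) {
                stats_list[[length(stats_list) + 1L]] <- data.frame(
                    class = cl, ko = ko, n = sum(sel), n_below = NA_integer_,
                    p.value = NA_real_, significant = FALSE)
                next
            }
            res <- classDgammaEnrichment(dg[sel], nulls[[ko]], q = q)
            sig <- res$p.value < alpha
            if (sig) signif[[ko]] <- c(signif[[ko]], cl)
            stats_list[[length(stats_list) + 1L]] <- data.frame(
                class = cl, ko = ko, n = res$n_class, n_below = res$n_below,
                p.value = res$p.value, significant = sig)
        }
    }
    classStats <- do.call(rbind, stats_list)
    ## per-region calls, nested across levels
    lev <- sort(fdr_levels)
    callLevel <- function(dg, cl, ko) {
        out <- rep("none", length(dg))
        ok <- !is.na(dg) & cl %in% signif[[ko]]
        for (f in rev(lev)) {  # loosest first, strictest wins
            thr <- thresholds[[ko]][[paste0("fdr", f)]]
            out[ok & dg <= thr] <- as.character(f)
        }
        out
    }
    called_cp <- callLevel(mc$dgamma_cp190, mc$class, "Cp190KO")
    called_cf <- callLevel(mc$dgamma_ctcf, mc$class, "CTCFKO")
    loosest <- as.character(max(lev))
    atloosest_cp <- called_cp != "none"
    atloosest_cf <- called_cf != "none"
    dependence <- rep(NA_character_, length(regs))
    dependence[atloosest_cp & !atloosest_cf] <- "Cp190"
    dependence[!atloosest_cp & atloosest_cf] <- "CTCF"
    dependence[atloosest_cp & atloosest_cf] <- "both"
    num <- function(x) suppressWarnings(as.numeric(x))
    called_at <- pmin(num(called_cp), num(called_cf), na.rm = TRUE)
    called_at <- ifelse(is.finite(called_at), as.character(called_at), "none")
    called_at[is.na(called_at)] <- "none"
    regions_df <- data.frame(
        chrom = .chromOf(regs), start = start(regs) - 1L, end = end(regs),
        class = mc$class,
        dgamma_cp190 = mc$dgamma_cp190, dgamma_ctcf = mc$dgamma_ctcf,
        called_cp190 = called_cp, called_ctcf = called_cf,
        called_at = called_at, dependence = dependence)
    new("ScreenResult", classStats = classStats, thresholds = thresholds,
        regions = regions_df,
        params = list(alpha = alpha, q = q, fdr_levels = lev,
                      loosest = loosest))
}
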