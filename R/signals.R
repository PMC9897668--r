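## ChIP-signal scores over regions, knockout/control log-ratios, TSS
## activity classes, nearest-TSS assignment and the delta-gamma versus
## expression-change correlation.

#' Average per-bp signal over regions
#'
#' Mean read count per base pair over each region, scaled to reads per
#' million: `mean_coverage * 1e6 / library_size`.  Bases not covered by
#' the track count as zero.
#'
#' @param coverage GRanges with a `score` column (e.g. from
#'   [readBedGraph()]).
#' @param regs GRanges of regions.
#' @param library_size library size used for per-million normalization
#'   (default 1e6, i.e. no scaling).
#' @return numeric scores, one per region.
#' @export
regionSignal <- function(coverage, regs, library_size = 1e6) {
    if (length(coverage) && any(coverage$score < 0))
        stop("coverage must be non-negative")
    ov <- GenomicRanges::findOverlaps(regs, coverage)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
        IRanges::ranges(regs)[qh], IRanges::ranges(coverage)[sh]))
    tot <- rep(0, length(regs))
    contrib <- w * coverage$score[sh]
    agg <- tapply(contrib, qh, sum)
    tot[as.integer(names(agg))] <- agg
    tot / width(regs) * 1e6 / library_size
}

#' Log2 knockout/control signal change
#'
#' `log2((score_ko + pc) / (score_con + pc))` with a pseudocount to keep
#' ratios defined at zero signal.
#'
#' @param score_ko,score_con signal scores.
#' @param pseudocount added to both scores (default 0.1 mean-per-bp
#'   units).
#' @return numeric log2 ratios.
#' @export
log2Change <- function(score_ko, score_con, pseudocount = 0.1) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    log2((score_ko + pseudocount) / (score_con + pseudocount))
}

#' Classify genes by transcriptional activity
#'
#' Genes with counts strictly above the nearest-rank 75th percentile are
#' TSS-high (transcriptionally active); genes at or below the 25th
#' percentile are TSS-low; the rest are middle.
#'
#' @param counts data.frame with `gene` and `count` columns.
#' @param count_col column holding the counts (default `"count"`).
#' @return the data.frame with an `activity` factor column
#'   (high/middle/low).
#' @export
tssActivityClasses <- function(counts, count_col = "count") {
    x <- counts[[count_col]]
    if (is.null(x)) stop("no column ", count_col)
    thr_hi <- nearestRankPercentile(x, 75)
    thr_lo <- nearestRankPercentile(x, 25)
    act <- rep("middle", length(x))
    act[x > thr_hi] <- "high"
    act[x <= thr_lo] <- "low"
    counts$activity <- factor(act, levels = c("high", "middle", "low"))
    counts
}

#' TSS regions from a gene table
#'
#' @param genes data.frame with `chrom` and `tss` columns.
#' @param pad extension in bp on both sides (default 1000).
#' @return GRanges of `TSS +/- pad` regions carrying the gene metadata.
#' @export
tssRegions <- function(genes, pad = 1000) {
    gr <- GRanges(genes$chrom,
                  IRanges(pmax(genes$tss - pad, 1), genes$tss + pad))
    mcols(gr) <- genes
    gr
}

#' Nearest TSS per region
#'
#' Midpoint-to-TSS distances; ties are broken toward the lower
#' coordinate.  Regions on chromosomes without any TSS get NA.
#'
#' @param regs GRanges of regions.
#' @param tss GRanges of TSS positions (midpoints used) — must be
#'   non-empty.
#' @return data.frame with `tss_index` (into `tss`) and `distance` (bp).
#' @export
nearestTss <- function(regs, tss) {
    if (!length(tss)) stop("empty TSS set")
    rmid <- .midpoints(regs); rchr <- .chromOf(regs)
    tmid <- .midpoints(tss); tchr <- .chromOf(tss)
    idx <- rep(NA_integer_, length(regs))
    dist <- rep(NA_real_, length(regs))
    for (c0 in unique(rchr)) {
        tsel <- which(tchr == c0)
        if (!length(tsel)) next
        o <- tsel[order(tmid[tsel])]
        tm <- tmid[o]
        rsel <- which(rchr == c0)
        pos <- findInterval(rmid[rsel], tm)
        left <- pmax(pos, 1L)
        right <- pmin(pos + 1L, length(tm))
        dl <- abs(rmid[rsel] - tm[left])
        dr <- abs(rmid[rsel] - tm[right])
        pickleft <- dl <= dr  # tie -> lower coordinate
        pick <- ifelse(pickleft, left, right)
        idx[rsel] <- o[pick]
        dist[rsel] <- pmin(dl, dr)
    }
    data.frame(tss_index = idx, distance = dist)
}

#' Correlation between delta-gamma and expression change
#'
#' Rank correlation between region delta-gamma and the log-fold
#' expression change of the nearest gene; a flat scatter argues that
#' contact-crossing changes are not transcription-driven.
#'
#' @param region_dgamma delta-gamma per region.
#' @param expr_change log-fold expression change of the nearest gene.
#' @return list with `rho`, `p.value`, `n`.
#' @export
dgammaExpressionCorrelation <- function(region_dgamma, expr_change) {
    ok <- !is.na(region_dgamma) & !is.na(expr_change)
    if (sum(ok) < 3L) stop("need at least 3 complete pairs")
    ct <- suppressWarnings(stats::cor.test(region_dgamma[ok],
                                           expr_change[ok],
                                           method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}

#' Compare delta-gamma between TSS groups
#'
#' Two-sided Wilcoxon rank-sum test between delta-gamma of TSSs with
#' higher transcription in the mutant versus higher in the control.
#'
#' @param dgamma_up delta-gamma at TSSs more transcribed in the mutant.
#' @param dgamma_down delta-gamma at TSSs more transcribed in the
#'   control.
#' @return list with `p.value`, medians and group sizes.
#' @export
tssCrossingComparison <- function(dgamma_up, dgamma_down) {
    up <- dgamma_up[!is.na(dgamma_up)]
    dn <- dgamma_down[!is.na(dgamma_down)]
    if (!length(up) || !length(dn)) stop("empty group")
    wt <- stats::wilcox.test(up, dn, alternative = "two.sided",
                             exact = FALSE, correct = FALSE)
    list(p.value = wt$p.value, median_up = stats::median(up),
         median_down = stats::median(dn), n_up = length(up),
         n_down = length(dn))
}
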