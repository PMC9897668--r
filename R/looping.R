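## The insulator looping test: closest insulator pairs versus three
## distance-matched control pairs; contact counts, distance-grouped
## summaries with notched medians, and rank-sum comparisons.

#' Closest insulator pairs
#'
#' Insulators are sorted by start position within each chromosome;
#' consecutive (adjacent) elements form pairs, so an element can appear
#' in two pairs.  L is the distance between pair midpoints.
#'
#' @param insulators GRanges of insulator elements.
#' @return data.frame(chrom, pos1, pos2, L) with pos = midpoints.
#' @export
closestPairs <- function(insulators) {
    chr <- .chromOf(insulators)
    out <- list()
    for (c0 in unique(chr)) {
        sel <- which(chr == c0)
        sel <- sel[order(start(insulators)[sel])]
        if (length(sel) < 2L) next
        m <- .midpoints(insulators)[sel]
        out[[c0]] <- data.frame(chrom = c0, pos1 = m[-length(m)],
                                pos2 = m[-1], L = diff(m))
    }
    if (!length(out))
        return(data.frame(chrom = character(), pos1 = numeric(),
                          pos2 = numeric(), L = numeric()))
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
}

#' Build distance-matched control pairs for the looping test
#'
#' For a pair (i1, i2) at separation L: c1 = i1 + L/2 (toward i2, rounded
#' down to bin resolution when `binsize` is given), c2 = i1 - L and
#' c3 = i1 - 2L.  A quartet is skipped (with reason) when any control
#' falls outside chromosome bounds, inside another insulator (same bin
#' when `binsize` is given), or inside an avoided region.
#'
#' @param pairs data.frame from [closestPairs()].
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param insulators optional GRanges; controls may not land in them.
#' @param avoid optional GRanges of regions controls must not touch.
#' @param binsize optional bin size in bp for rounding and same-bin
#'   rejection.
#' @return list with `quartets` (kept: chrom, i1, i2, L, c1, c2, c3) and
#'   `skipped` (with a `reason` column).
#' @export
buildControlPairs <- function(pairs, chrom_lengths, insulators = NULL,
                              avoid = NULL, binsize = NULL) {
    halfL <- if (is.null(binsize)) floor(pairs$L / 2)
             else floor(pairs$L / 2 / binsize) * binsize
    q <- data.frame(chrom = pairs$chrom, i1 = pairs$pos1, i2 = pairs$pos2,
                    L = pairs$L, c1 = pairs$pos1 + halfL,
                    c2 = pairs$pos1 - pairs$L,
                    c3 = pairs$pos1 - 2 * pairs$L)
    reason <- rep(NA_character_, nrow(q))
    lim <- chrom_lengths[q$chrom]
    oob <- q$c3 < 1 | q$c2 < 1 | q$c1 > lim
    reason[oob] <- "control outside chromosome"
    inIns <- function(pos) {
        if (is.null(insulators)) return(rep(FALSE, nrow(q)))
        if (!is.null(binsize)) {
            ibins <- unique(paste(.chromOf(insulators),
                                  floor((.midpoints(insulators) - 1) / binsize)))
            paste(q$chrom, floor((pos - 1) / binsize)) %in% ibins
        } else {
            pts <- GRanges(q$chrom, IRanges(pmax(pos, 1), pmax(pos, 1)))
            IRanges::overlapsAny(pts, insulators)
        }
    }
    hit <- inIns(q$c1) | inIns(q$c2) | inIns(q$c3)
    reason[is.na(reason) & hit] <- "control inside an insulator"
    if (!is.null(avoid)) {
        pts <- function(pos) GRanges(q$chrom,
                                     IRanges(pmax(pos, 1), pmax(pos, 1)))
        av <- IRanges::overlapsAny(pts(q$c1), avoid) |
              IRanges::overlapsAny(pts(q$c2), avoid) |
              IRanges::overlapsAny(pts(q$c3), avoid)
        reason[is.na(reason) & av] <- "control inside an avoided region"
    }
    keep <- is.na(reason)
    skipped <- q[!keep, , drop = FALSE]
    skipped$reason <- reason[!keep]
    list(quartets = q[keep, , drop = FALSE], skipped = skipped)
}

#' Contact counts for looping-test quartets
#'
#' Looks up the (jointly-normalized, binned) contact value between the
#' bins containing the two positions of every pair: n1 = (i1, i2),
#' n2 = (i1, c1), n3 = (i1, c2), n4 = (c2, c3).  Absent entries read
#' as 0.
#'
#' @param cm binned [ContactMatrix].
#' @param quartets data.frame from [buildControlPairs()].
#' @return the quartets with columns n1..n4 added.
#' @export
pairContacts <- function(cm, quartets) {
    a <- anchors(cm)
    lookup <- .contactLookup(cm)
    bin <- function(pos) .resolveAxis(a, quartets$chrom, pos)
    b_i1 <- bin(quartets$i1); b_i2 <- bin(quartets$i2)
    b_c1 <- bin(quartets$c1); b_c2 <- bin(quartets$c2)
    b_c3 <- bin(quartets$c3)
    quartets$n1 <- lookup(b_i1, b_i2)
    quartets$n2 <- lookup(b_i1, b_c1)
    quartets$n3 <- lookup(b_i1, b_c2)
    quartets$n4 <- lookup(b_c2, b_c3)
    quartets
}

#' Summarize the looping test
#'
#' Quartets are split into `n_groups` equal-size groups by separation L;
#' per group and pair kind the median and its approximate 95% notch
#' (median +/- 1.57 IQR / sqrt(n)) are reported, together with one-sided
#' Wilcoxon rank-sum tests of n1 against each control.  Looping is
#' supported only if, in every group, the insulator pairs (n1) exceed all
#' three controls (greater median and rank-sum p < 0.05).
#'
#' @param quartets data.frame with n1..n4 (see [pairContacts()]).
#' @param n_groups number of separation groups (default 4).
#' @return list with `groups` (per group x kind: median, notch bounds, n),
#'   `tests` (per group: Wilcoxon p for n1 vs n2/n3/n4),
#'   `looping_supported` (logical) and `group_breaks`.
#' @export
loopingSummary <- function(quartets, n_groups = 4L) {
    if (nrow(quartets) < 8L) stop("need at least 8 quartets")
    n <- nrow(quartets)
    grp <- ceiling(rank(quartets$L, ties.method = "first") * n_groups / n)
    kinds <- c("n1", "n2", "n3", "n4")
    groups <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
        sel <- grp == g
        do.call(rbind, lapply(kinds, function(k) {
            x <- quartets[[k]][sel]
            med <- stats::median(x)
            notch <- 1.57 * stats::IQR(x) / sqrt(length(x))
            data.frame(group = g, kind = k, n = length(x), median = med,
                       notch_lo = med - notch, notch_hi = med + notch,
                       L_min = min(quartets$L[sel]),
                       L_max = max(quartets$L[sel]))
        }))
    }))
    tests <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
        sel <- grp == g
        ps <- vapply(c("n2", "n3", "n4"), function(k) {
            p <- suppressWarnings(
                stats::wilcox.test(quartets$n1[sel], quartets[[k]][sel],
                                   alternative = "greater",
                                   exact = FALSE)$p.value)
            if (is.na(p)) 1 else p   # fully tied groups carry no evidence
        }, numeric(1))
        data.frame(group = g, p_n1_vs_n2 = ps[["n2"]],
                   p_n1_vs_n3 = ps[["n3"]], p_n1_vs_n4 = ps[["n4"]])
    }))
    med <- function(g, k) groups$median[groups$group == g & groups$kind == k]
    supported <- all(vapply(seq_len(n_groups), function(g) {
        all(med(g, "n1") > c(med(g, "n2"), med(g, "n3"), med(g, "n4"))) &&
            all(tests[tests$group == g, -1] < 0.05)
    }, logical(1)))
    list(groups = groups, tests = tests, looping_supported = supported,
         group_assignment = grp)
}
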