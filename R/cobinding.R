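## Insulator-protein cobinding classes: replicate-consistent peaks, summit
## extension, and the ordered pairwise-overlap classification that labels
## every bound region with the letters of the proteins present
## (alphabet M = Mod(mdg4), C = Cp190, I = Ibf1, F = CTCF, S = Su(Hw)).

#' Keep peaks consistent between replicates
#'
#' Retains the replicate-1 peaks that overlap (>= 1 bp) a replicate-2
#' peak.
#'
#' @param rep1,rep2 GRanges of peaks for one antibody.
#' @return GRanges subset of `rep1`.
#' @export
replicateConsistentPeaks <- function(rep1, rep2) {
    rep1[IRanges::overlapsAny(rep1, rep2)]
}

#' Extend peak summits
#'
#' Point summits are extended to `[summit - pad, summit + pad)` (clamped
#' at chromosome bounds when sequence lengths are known); interval inputs
#' use their midpoint as the summit.
#'
#' @param summits GRanges of summits (points or intervals).
#' @param pad half-width in bp (default 300).
#' @return GRanges of extended regions.
#' @export
extendSummits <- function(summits, pad = 300) {
    mid <- floor(.midpoints(summits))
    s <- pmax(mid - pad + 1, 1)
    e <- mid + pad
    sl <- GenomeInfoDb::seqlengths(summits)
    chr <- .chromOf(summits)
    if (!all(is.na(sl))) {
        lim <- sl[chr]
        e <- ifelse(is.na(lim), e, pmin(e, lim))
    }
    out <- GRanges(chr, IRanges(s, e), seqinfo = GenomeInfoDb::seqinfo(summits))
    mcols(out) <- mcols(summits)
    out
}

#' Classify insulator-protein cobinding
#'
#' Iterative ordered splitting: starting from the first protein's peaks,
#' each current group is split at every step into regions that do or do
#' not overlap the next protein's peaks, and next-protein peaks that
#' overlap nothing seen so far seed a new group.  The final label
#' concatenates the letters of all proteins present (always in alphabet
#' order) and a region's footprint is the union of its member intervals.
#' When one peak bridges two previously separate regions they are merged
#' into one (flagged in the `merged` column).
#'
#' @param peaksets named list of five GRanges in the order M, C, I, F, S
#'   (replicate-consistent, summit-extended peaks per protein).
#' @param proteins the ordered class alphabet (default M, C, I, F, S).
#' @return A [CobindingCatalog].
#' @export
classifyCobinding <- function(peaksets,
                              proteins = c("M", "C", "I", "F", "S")) {
    if (anyDuplicated(proteins)) stop("duplicate protein letter")
    if (length(peaksets) != length(proteins))
        stop("need one peak set per protein")
    names(peaksets) <- proteins
    ## current regions: GRanges with label + merged flag
    cur <- GRanges()
    for (pr in proteins) {
        pk <- peaksets[[pr]]
        if (!length(cur)) {
            if (length(pk)) {
                cur <- pk
                mcols(cur) <- NULL
                cur$label <- pr
                cur$merged <- FALSE
            }
            next
        }
        if (!length(pk)) next
        ov <- GenomicRanges::findOverlaps(cur, pk)
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        hitreg <- unique(qh)
        ## peaks bridging >1 region force a merge of those regions
        newregs <- cur
        if (length(hitreg)) {
            ## union-find over regions connected through shared peaks
            parent <- seq_along(cur)
            findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
            for (p in unique(sh)) {
                rs <- qh[sh == p]
                if (length(rs) > 1L) {
                    roots <- vapply(rs, findp, integer(1))
                    parent[roots[-1]] <- roots[1]
                }
            }
            root <- vapply(seq_along(cur), findp, integer(1))
            keep <- !logical(length(cur))
            for (g in unique(root[hitreg])) {
                members <- which(root == g)
                lead <- members[1]
                peaks_here <- sh[qh %in% members]
                newstart <- min(start(cur)[members], min(start(pk)[peaks_here]))
                newend <- max(end(cur)[members], max(end(pk)[peaks_here]))
                letters_here <- unique(unlist(strsplit(cur$label[members], "")))
                GenomicRanges::start(newregs)[lead] <- newstart
                GenomicRanges::end(newregs)[lead] <- newend
                newregs$label[lead] <- paste(c(letters_here, pr), collapse = "")
                newregs$merged[lead] <- newregs$merged[lead] ||
                    length(members) > 1L
                if (length(members) > 1L) keep[members[-1]] <- FALSE
            }
            newregs <- newregs[keep]
        }
        ## unmatched peaks seed new regions
        orphan <- setdiff(seq_along(pk), unique(sh))
        if (length(orphan)) {
            np <- pk[orphan]
            mcols(np) <- NULL
            np$label <- pr
            np$merged <- FALSE
            newregs <- c(newregs, np)
        }
        cur <- newregs
    }
    if (!length(cur)) {
        cur <- GRanges()
        cur$label <- character()
        cur$merged <- logical()
    }
    ## order letters by the alphabet
    lab <- vapply(strsplit(cur$label, ""), function(x)
        paste(proteins[sort(match(x, proteins))], collapse = ""), "")
    out <- cur
    mcols(out) <- NULL
    out$class <- lab
    out$merged <- cur$merged
    out$excluded <- FALSE
    o <- order(.chromOf(out), start(out))
    new("CobindingCatalog", regions = out[o], proteins = proteins)
}

#' Flag small cobinding classes as excluded
#'
#' Classes with fewer than `min_size` regions are flagged `excluded`
#' (counts are conserved; nothing is dropped).
#'
#' @param catalog a [CobindingCatalog].
#' @param min_size minimum class size.
#' @return the catalog with updated `excluded` flags.
#' @export
classFilter <- function(catalog, min_size) {
    regs <- regions(catalog)
    sizes <- table(regs$class)
    regs$excluded <- as.integer(sizes[regs$class]) < min_size
    new("CobindingCatalog", regions = regs, proteins = catalog@proteins)
}
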