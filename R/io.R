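## Readers, writers and constructors for the on-disk formats: BED regions,
## restriction-fragment maps, sparse triplet contact text (including
## "ginteraction"-style cooler dumps), bedGraph coverage and count TSVs.
## Coordinates on disk are 0-based half-open (BED dialect); in memory
## everything is a 1-based closed GRanges.

#' Read genomic regions from a BED file
#'
#' Parses BED3+ lines into a sorted GRanges.  Malformed lines (non-integer
#' coordinates, start >= end, missing fields) raise an error naming the
#' offending line number.
#'
#' @param path path to a BED file (plain text, tab- or space-separated).
#' @return A [GenomicRanges::GRanges] sorted by (chrom, start), with `name`
#'   and `score` metadata columns when present in the file.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2L\t100\t400\tpeak1", bed)
#' readRegions(bed)
#' @export
readRegions <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    if (!length(lines)) return(GRanges())
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 3L)
    if (length(bad))
        stop(sprintf("line %d: fewer than 3 BED fields", bad[1]))
    chrom <- vapply(fields, `[`, "", 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
    if (length(bad))
        stop(sprintf("line %d: non-integer coordinates", bad[1]))
    bad <- which(s < 0 | s >= e)
    if (length(bad))
        stop(sprintf("line %d: invalid interval (start >= end or start < 0)",
                     bad[1]))
    gr <- GRanges(chrom, IRanges(s + 1, e))
    if (any(nf >= 4L))
        gr$name <- vapply(fields, function(f)
            if (length(f) >= 4L) f[4L] else NA_character_, "")
    if (any(nf >= 5L))
        gr$score <- suppressWarnings(as.numeric(vapply(fields, function(f)
            if (length(f) >= 5L) f[5L] else NA_character_, "")))
    GenomicRanges::sort(gr)
}

#' Write genomic regions to a BED file
#'
#' @param gr a GRanges; `name`/`score` metadata columns are written when
#'   present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    if (!is.null(gr$name)) {
        df$name <- gr$name
        if (!is.null(gr$score)) df$score <- gr$score
    } else if (!is.null(gr$score)) {
        df$name <- "."
        df$score <- gr$score
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Build a FragmentMap from 0-based fragment coordinates
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), fragments tiling each chromosome gaplessly.
#' @return A [FragmentMap].
#' @export
fragmentMap <- function(df) {
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
    gr$index <- seq_along(gr)
    sl <- tapply(end(gr), as.character(seqnames(gr)), max)
    GenomeInfoDb::seqlengths(gr) <- as.numeric(sl[GenomeInfoDb::seqlevels(gr)])
    new("FragmentMap", fragments = gr)
}

#' Read a restriction-fragment map from BED
#'
#' @param path BED file of fragments tiling each chromosome.
#' @return A [FragmentMap].
#' @export
readFragmentMap <- function(path) {
    gr <- readRegions(path)
    fragmentMap(data.frame(chrom = as.character(seqnames(gr)),
                           start = start(gr) - 1L, end = end(gr)))
}

#' @rdname readFragmentMap
#' @param fm a FragmentMap.
#' @export
writeFragmentMap <- function(fm, path) {
    gr <- fragments(fm)
    gr$name <- paste0("frag", gr$index)
    writeRegions(gr, path)
}

## resolve genomic positions (1-based) to axis indices
.resolveAxis <- function(anchors, chrom, pos) {
    idx <- rep(NA_integer_, length(pos))
    achr <- .chromOf(anchors)
    for (chr in unique(chrom)) {
        sel <- chrom == chr
        ax <- which(achr == chr)
        if (!length(ax))
            stop("chromosome not on axis: ", chr)
        st <- GenomicRanges::start(anchors)[ax]
        en <- GenomicRanges::end(anchors)[ax]
        k <- findInterval(pos[sel], st)
        if (any(k == 0L) || any(pos[sel] > en[pmax(k, 1L)]))
            stop("position not resolvable to an axis element on ", chr)
        idx[sel] <- ax[k]
    }
    idx
}

#' Read sparse Hi-C contacts
#'
#' Accepts three plain-text layouts: `i j value` (1-based axis indices),
#' `chrom1 pos1 chrom2 pos2 value` (0-based positions resolved to the axis
#' element containing them), and 7-column "ginteraction"-style dumps
#' (`chrom1 start1 end1 chrom2 start2 end2 value`, interval midpoints
#' resolved to axis elements).  Pairs are canonicalized to i <= j and
#' duplicate pairs summed; the result is a raw-state [ContactMatrix].
#'
#' @param path triplet text file.
#' @param axis a [FragmentMap] or a bin-axis GRanges (as produced by
#'   [binAxis()]), defining the matrix axis.
#' @return A raw [ContactMatrix].
#' @export
readContacts <- function(path, axis) {
    anchors <- if (is(axis, "FragmentMap")) fragments(axis) else axis
    binsize <- if (is(axis, "FragmentMap")) NA_real_
               else attr(axis, "binsize") %||% NA_real_
    dt <- data.table::fread(path, header = FALSE)
    if (!nrow(dt)) {
        return(.newContactMatrix(anchors,
            data.frame(i = integer(), j = integer(), value = numeric()),
            binsize = binsize))
    }
    nc <- ncol(dt)
    if (nc == 3L) {
        i <- dt[[1]]; j <- dt[[2]]; v <- dt[[3]]
        if (any(i < 1L | i > length(anchors) | j < 1L | j > length(anchors)))
            stop("axis index out of range")
    } else if (nc == 5L) {
        i <- .resolveAxis(anchors, as.character(dt[[1]]), dt[[2]] + 1)
        j <- .resolveAxis(anchors, as.character(dt[[3]]), dt[[4]] + 1)
        v <- dt[[5]]
    } else if (nc == 7L) {
        i <- .resolveAxis(anchors, as.character(dt[[1]]),
                          floor((dt[[2]] + dt[[3]]) / 2) + 1)
        j <- .resolveAxis(anchors, as.character(dt[[4]]),
                          floor((dt[[5]] + dt[[6]]) / 2) + 1)
        v <- dt[[7]]
    } else stop("unrecognized contact layout (expect 3, 5 or 7 columns)")
    if (any(v < 0)) stop("negative contact value")
    .newContactMatrix(anchors, .canonicalTriplets(i, j, v), binsize = binsize)
}

#' Write sparse Hi-C contacts as triplet text
#'
#' @param cm a [ContactMatrix].
#' @param path output path.
#' @param format `"index"` writes `i j value`; `"position"` writes
#'   `chrom1 pos1 chrom2 pos2 value` with 0-based axis-midpoint positions.
#' @return `path`, invisibly.
#' @export
writeContacts <- function(cm, path, format = c("index", "position")) {
    format <- match.arg(format)
    tr <- triplets(cm)
    if (format == "index") {
        utils::write.table(tr, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    } else {
        a <- anchors(cm)
        mid <- floor(.midpoints(a)) - 1L
        chr <- .chromOf(a)
        utils::write.table(
            data.frame(chr[tr$i], mid[tr$i], chr[tr$j], mid[tr$j], tr$value),
            path, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
    }
    invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file.
#' @return GRanges with a `score` column.
#' @export
readBedGraph <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    GenomicRanges::sort(gr)
}

#' Write a bedGraph coverage track
#'
#' @param gr GRanges with a `score` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(gr, path) {
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a per-gene count table
#'
#' @param path TSV with at least columns `gene` and `count` (extra columns
#'   such as `chrom`/`tss` are preserved).
#' @return data.frame.
#' @export
readCounts <- function(path) {
    df <- as.data.frame(data.table::fread(path))
    if (!all(c("gene", "count") %in% names(df)))
        stop("count table needs 'gene' and 'count' columns")
    df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
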