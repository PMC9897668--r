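## Synthetic Hi-C experiments with known ground truth: genomes of
## geometric restriction fragments, power-law contact decay with
## per-fragment multiplicative biases and Poisson counts, implanted
## boundaries whose attenuation is knockout-dependent, optional loop
## pairs, cobinding peak sets over five insulator proteins, coverage
## tracks and expression count tables.

#' Construct a synthetic-experiment specification
#'
#' @param n_chrom number of chromosomes (default 1).
#' @param chrom_length chromosome length in bp (default 1e6).
#' @param mean_fragment mean restriction-fragment length in bp
#'   (default 256, DpnII-like).
#' @param alpha power-law decay exponent (default 0.85).
#' @param bias_sd log-sd of the lognormal per-fragment biases
#'   (default 0.3).
#' @param depth expected total contacts per chromosome (default 2e6).
#' @param d0 reference distance of the decay law in bp (default 10 kb).
#' @param max_dist maximal simulated pair distance in bp (default 1 Mb);
#'   beyond it expected contacts are negligible and pairs are not drawn.
#' @param boundaries data.frame(chrom, pos, beta, label) with beta in
#'   (0, 1] (per-crossing attenuation; smaller = stronger boundary) and
#'   label in `Cp190`/`CTCF`/`both`/`none` naming the knockout(s) that
#'   inactivate the boundary.
#' @param loops data.frame(chrom, pos1, pos2, lambda >= 1).
#' @return A [SyntheticSpec].
#' @export
syntheticSpec <- function(n_chrom = 1L, chrom_length = 1e6,
                          mean_fragment = 256, alpha = 0.85, bias_sd = 0.3,
                          depth = 2e6, d0 = 1e4, max_dist = 1e6,
                          boundaries = NULL, loops = NULL) {
    if (is.null(boundaries))
        boundaries <- data.frame(chrom = character(), pos = numeric(),
                                 beta = numeric(), label = character())
    if (is.null(loops))
        loops <- data.frame(chrom = character(), pos1 = numeric(),
                            pos2 = numeric(), lambda = numeric())
    boundaries <- boundaries[order(boundaries$chrom, boundaries$pos), ,
                             drop = FALSE]
    rownames(boundaries) <- NULL
    new("SyntheticSpec", nChrom = as.integer(n_chrom),
        chromLength = chrom_length, meanFragment = mean_fragment,
        alpha = alpha, biasSd = bias_sd, depth = depth, d0 = d0,
        maxDist = max_dist, boundaries = boundaries, loops = loops)
}

.chromNames <- function(spec) sprintf("chr%d", seq_len(spec@nChrom))

#' Place non-overlapping synthetic sites on a genome
#'
#' Spreads `sum(counts)` sites across all chromosomes with at least
#' `min_gap` bp between sites and `margin` bp clear of chromosome ends,
#' then shuffles kind labels over positions.  Convenience for building
#' boundary/decoy layouts.
#'
#' @param spec a [SyntheticSpec] (for chromosome count and length).
#' @param counts named integer vector: number of sites per kind.
#' @param min_gap minimum distance between adjacent sites (bp).
#' @param margin distance kept free at both chromosome ends (bp).
#' @param seed RNG seed.
#' @return data.frame(chrom, pos, kind) sorted by (chrom, pos).
#' @export
placeSites <- function(spec, counts, min_gap = 20000, margin = 50000,
                       seed = 1L) {
    set.seed(seed)
    total <- sum(counts)
    per <- rep(floor(total / spec@nChrom), spec@nChrom)
    extra <- total - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    usable <- spec@chromLength - 2 * margin
    out <- list()
    for (k in seq_len(spec@nChrom)) {
        n <- per[k]
        if (n == 0L) next
        if (usable < (n - 1) * min_gap)
            stop("chromosome too short to place ", n, " sites ", min_gap,
                 " bp apart")
        ## jittered regular grid keeps the min-gap guarantee
        slot_w <- usable / n
        jit <- stats::runif(n, 0.1, 0.9)
        pos <- round(margin + (seq_len(n) - 1 + jit) * slot_w)
        out[[k]] <- data.frame(chrom = .chromNames(spec)[k], pos = pos)
    }
    df <- do.call(rbind, out)
    df$kind <- sample(rep(names(counts), counts))
    df[order(df$chrom, df$pos), ]
}

#' Simulate a restriction-fragment map
#'
#' Fragment lengths are geometric with the specified mean and tile each
#' chromosome gaplessly; the last fragment is truncated at the chromosome
#' end.  Deterministic under `seed`.
#'
#' @param spec a [SyntheticSpec].
#' @param seed RNG seed.
#' @return A [FragmentMap].
#' @export
simulateGenome <- function(spec, seed = 1L) {
    validObject(spec)
    set.seed(seed)
    pieces <- lapply(.chromNames(spec), function(chr) {
        len <- spec@chromLength
        n_guess <- ceiling(len / spec@meanFragment * 1.5) + 10L
        w <- stats::rgeom(n_guess, 1 / spec@meanFragment) + 1
        while (sum(w) < len)
            w <- c(w, stats::rgeom(n_guess, 1 / spec@meanFragment) + 1)
        ends <- cumsum(w)
        k <- which(ends >= len)[1]
        ends <- ends[seq_len(k)]
        ends[k] <- len
        data.frame(chrom = chr, start = c(0, ends[-k]), end = ends)
    })
    fragmentMap(do.call(rbind, pieces))
}

## boundary attenuation per condition: inactivated boundaries get beta = 1
.activeBeta <- function(boundaries, condition) {
    beta <- boundaries$beta
    inactive <- switch(condition,
        control = rep(FALSE, nrow(boundaries)),
        Cp190KO = boundaries$label %in% c("Cp190", "both"),
        CTCFKO  = boundaries$label %in% c("CTCF", "both"),
        stop("condition must be control/Cp190KO/CTCFKO"))
    beta[inactive] <- 1
    beta
}

#' Simulate condition-specific Hi-C contacts
#'
#' Expected counts follow
#' `E[o_ij] = A v_i v_j (d_ij/d0)^-alpha  prod_k beta_k  lambda`,
#' where the product runs over boundaries strictly between the fragment
#' midpoints that are active in `condition`, lambda applies to loop
#' anchor-anchor pairs, and A is calibrated per chromosome so the total
#' expectation equals the sequencing depth.  Observed counts are Poisson.
#'
#' @param fragmap a [FragmentMap] (from [simulateGenome()]).
#' @param spec a [SyntheticSpec].
#' @param condition `"control"`, `"Cp190KO"` or `"CTCFKO"`.
#' @param seed RNG seed.
#' @param biases optional per-fragment bias vector; drawn lognormal(0,
#'   bias_sd) when NULL.
#' @param loop_bin width of the loop-anchor window in bp (default 5000).
#' @return list with `contacts` (raw [ContactMatrix]) and `truth`
#'   (a [TruthSet] carrying boundaries with their condition-active
#'   attenuation, loops and the bias vector).
#' @export
simulateContacts <- function(fragmap, spec, condition = "control",
                             seed = 1L, biases = NULL, loop_bin = 5000) {
    validObject(spec)
    set.seed(seed)
    frags <- fragments(fragmap)
    n <- length(frags)
    if (is.null(biases))
        biases <- stats::rlnorm(n, meanlog = 0, sdlog = spec@biasSd)
    stopifnot(length(biases) == n)
    chr <- .chromOf(frags)
    mid <- .midpoints(frags)
    bnd <- spec@boundaries
    bnd$beta_active <- if (nrow(bnd)) .activeBeta(bnd, condition) else numeric()
    trip <- vector("list", spec@nChrom)
    for (k in seq_along(.chromNames(spec))) {
        c0 <- .chromNames(spec)[k]
        sel <- which(chr == c0)
        m <- mid[sel]
        nf <- length(sel)
        hi <- findInterval(m + spec@maxDist, m)
        cnt <- hi - seq_len(nf)
        ii <- rep.int(seq_len(nf), cnt)
        jj <- sequence(cnt, from = seq_len(nf) + 1L)
        d <- m[jj] - m[ii]
        logE <- log(biases[sel][ii]) + log(biases[sel][jj]) -
            spec@alpha * log(d / spec@d0)
        b <- bnd[bnd$chrom == c0, , drop = FALSE]
        if (nrow(b)) {
            cumlb <- c(0, cumsum(log(b$beta_active)))
            ## boundaries strictly between the two midpoints
            nlt <- function(x) findInterval(x - 1e-9, b$pos)
            nle <- function(x) findInterval(x, b$pos)
            logE <- logE + cumlb[nlt(m[jj]) + 1L] - cumlb[nle(m[ii]) + 1L]
        }
        lp <- spec@loops[spec@loops$chrom == c0, , drop = FALSE]
        if (nrow(lp)) {
            for (r in seq_len(nrow(lp))) {
                w1 <- which(abs(m - lp$pos1[r]) <= loop_bin / 2)
                w2 <- which(abs(m - lp$pos2[r]) <= loop_bin / 2)
                hitpair <- (ii %in% w1 & jj %in% w2) |
                           (ii %in% w2 & jj %in% w1)
                logE[hitpair] <- logE[hitpair] + log(lp$lambda[r])
            }
        }
        E <- exp(logE)
        E <- E * (spec@depth / sum(E))
        o <- stats::rpois(length(E), E)
        keep <- o > 0L
        trip[[k]] <- data.frame(i = sel[ii[keep]], j = sel[jj[keep]],
                                value = as.numeric(o[keep]))
    }
    tr <- do.call(rbind, trip)
    rownames(tr) <- NULL
    cm <- .newContactMatrix(fragments(fragmap), tr)
    truth <- new("TruthSet", boundaries = bnd, loops = spec@loops,
                 biases = biases,
                 peakClasses = data.frame(chrom = character(),
                                          pos = numeric(),
                                          class = character(),
                                          kind = character()))
    list(contacts = cm, truth = truth)
}

#' Expected contact counts by direct evaluation (reference model)
#'
#' Evaluates the generative expectation for given fragment pairs, without
#' the per-chromosome depth calibration (A = 1).  Used for model-closure
#' checks.
#'
#' @param fragmap a [FragmentMap].
#' @param spec a [SyntheticSpec].
#' @param condition condition name.
#' @param biases per-fragment biases.
#' @param i,j fragment index vectors (same chromosome, i != j).
#' @return numeric expectations.
#' @export
expectedContacts <- function(fragmap, spec, condition, biases, i, j) {
    frags <- fragments(fragmap)
    mid <- .midpoints(frags)
    chr <- .chromOf(frags)
    stopifnot(all(chr[i] == chr[j]))
    bnd <- spec@boundaries
    beta <- if (nrow(bnd)) .activeBeta(bnd, condition) else numeric()
    out <- numeric(length(i))
    for (k in seq_along(i)) {
        lo <- min(mid[i[k]], mid[j[k]]); hi <- max(mid[i[k]], mid[j[k]])
        cross <- which(bnd$chrom == chr[i[k]] & bnd$pos > lo & bnd$pos < hi)
        out[k] <- biases[i[k]] * biases[j[k]] *
            ((hi - lo) / spec@d0)^(-spec@alpha) * prod(beta[cross])
    }
    out
}

#' Simulate insulator-protein binding peaks
#'
#' Each site (implanted boundary or decoy) carries a cobinding class over
#' the ordered alphabet M, C, I, F, S; a protein's peak file contains
#' `[pos-pad, pos+pad)` iff the letter is in the site's class.  The
#' Cp190-KO condition drops all C peaks and the CTCF-KO condition all F
#' peaks; `coop_loss_prob` optionally drops companion letters at affected
#' sites (cooperative loss).
#'
#' @param truth a [TruthSet] from [simulateContacts()].
#' @param class_mix character vector of class labels, one per truth
#'   boundary (letters in M,C,I,F,S order).
#' @param decoys data.frame(chrom, pos, class) of non-boundary bound sites
#'   (may be empty).
#' @param pad summit extension in bp (default 300).
#' @param coop_loss_prob probability of dropping each companion peak at
#'   sites that lose C (Cp190-KO) or F (CTCF-KO) (default 0).
#' @param seed RNG seed (used only for cooperative loss).
#' @return list with `peaks` (condition -> protein -> GRanges), `sites`
#'   (data.frame chrom, pos, class, kind) and `truth` (input truth with
#'   `peakClasses` filled).
#' @export
simulateBinding <- function(truth, class_mix, decoys = NULL, pad = 300,
                            coop_loss_prob = 0, seed = 1L) {
    set.seed(seed)
    bnd <- truth@boundaries
    if (length(class_mix) != nrow(bnd))
        stop("class_mix must label every boundary")
    sites <- data.frame(chrom = bnd$chrom, pos = bnd$pos,
                        class = class_mix,
                        kind = "boundary", stringsAsFactors = FALSE)
    if (!is.null(decoys) && nrow(decoys)) {
        sites <- rbind(sites, data.frame(chrom = decoys$chrom,
                                         pos = decoys$pos,
                                         class = decoys$class,
                                         kind = "decoy"))
    }
    sites <- sites[order(sites$chrom, sites$pos), ]
    rownames(sites) <- NULL
    gap <- unlist(tapply(sites$pos, sites$chrom, function(p)
        if (length(p) > 1) diff(p) else numeric()))
    if (length(gap) && any(gap < 2 * pad + 100))
        stop("implanted summits closer than ", 2 * pad + 100, " bp overlap")
    proteins <- c("M", "C", "I", "F", "S")
    conditions <- c("control", "Cp190KO", "CTCFKO")
    dropped <- list(control = "", Cp190KO = "C", CTCFKO = "F")
    peaks <- lapply(conditions, function(cond) {
        present <- lapply(strsplit(sites$class, ""), setdiff,
                          y = dropped[[cond]])
        if (coop_loss_prob > 0 && nzchar(dropped[[cond]])) {
            affected <- grepl(dropped[[cond]], sites$class, fixed = TRUE)
            present[affected] <- lapply(present[affected], function(p)
                p[stats::runif(length(p)) >= coop_loss_prob])
        }
        out <- lapply(proteins, function(pr) {
            hit <- vapply(present, function(p) pr %in% p, logical(1))
            if (!any(hit)) return(GRanges())
            GRanges(sites$chrom[hit],
                    IRanges(pmax(sites$pos[hit] - pad + 1, 1),
                            sites$pos[hit] + pad))
        })
        names(out) <- proteins
        out
    })
    names(peaks) <- conditions
    truth@peakClasses <- sites
    list(peaks = peaks, sites = sites, truth = truth)
}

#' Simulate ChIP coverage tracks and an expression count table
#'
#' Per-protein, per-condition coverage is a flat background with
#' flat-topped enrichment of height `peak_height` over each site bound by
#' the protein in that condition (mild multiplicative noise).  Gene counts
#' are negative-binomial with designated TSS-high (top-quartile mean) and
#' TSS-low genes.
#'
#' @param truth a [TruthSet] with `peakClasses` filled (see
#'   [simulateBinding()]).
#' @param spec a [SyntheticSpec].
#' @param seed RNG seed.
#' @param peak_height coverage at bound sites (default 10).
#' @param background baseline coverage (default 1).
#' @param pad peak half-width in bp (default 300).
#' @param n_genes number of genes (default 200).
#' @param nb_size negative-binomial dispersion parameter (default 10).
#' @return list with `coverage` (condition -> protein -> GRanges with
#'   `score`), `genes` (data.frame gene, chrom, tss, group, count,
#'   count_cp190ko, count_ctcfko) and `library_sizes`.
#' @export
simulateCoverageAndExpression <- function(truth, spec, seed = 1L,
                                          peak_height = 10, background = 1,
                                          pad = 300, n_genes = 200,
                                          nb_size = 10) {
    set.seed(seed)
    sites <- truth@peakClasses
    if (!nrow(sites)) stop("truth has no labelled peak sites; run simulateBinding first")
    proteins <- c("M", "C", "I", "F", "S")
    conditions <- c("control", "Cp190KO", "CTCFKO")
    dropped <- list(control = "", Cp190KO = "C", CTCFKO = "F")
    chroms <- .chromNames(spec)
    coverage <- lapply(conditions, function(cond) {
        out <- lapply(proteins, function(pr) {
            hit <- grepl(pr, sites$class, fixed = TRUE)
            if (identical(pr, dropped[[cond]])) hit[] <- FALSE
            segs <- list()
            for (chr in chroms) {
                p <- sites$pos[hit & sites$chrom == chr]
                p <- sort(p)
                bkg_start <- c(1, p + pad + 1)
                bkg_end <- c(p - pad, spec@chromLength)
                ok <- bkg_start <= bkg_end
                segs[[chr]] <- rbind(
                    data.frame(chrom = chr, start = bkg_start[ok],
                               end = bkg_end[ok], score = background),
                    if (length(p)) data.frame(chrom = chr, start = p - pad + 1,
                               end = p + pad,
                               score = peak_height *
                                   stats::runif(length(p), 0.95, 1.05))
                    else NULL)
            }
            df <- do.call(rbind, segs)
            gr <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
            GenomicRanges::sort(gr)
        })
        names(out) <- proteins
        out
    })
    names(coverage) <- conditions
    ## genes: TSS positions away from nothing in particular
    gchr <- sample(chroms, n_genes, replace = TRUE)
    gtss <- round(stats::runif(n_genes, 2000, spec@chromLength - 2000))
    group <- sample(rep(c("high", "mid", "low"),
                        c(ceiling(n_genes / 4), n_genes - 2 * ceiling(n_genes / 4),
                          ceiling(n_genes / 4))))
    mu <- c(high = 2000, mid = 50, low = 0.5)[group]
    genes <- data.frame(
        gene = sprintf("gene%03d", seq_len(n_genes)),
        chrom = gchr, tss = gtss, group = group,
        count = stats::rnbinom(n_genes, size = nb_size, mu = mu),
        count_cp190ko = stats::rnbinom(n_genes, size = nb_size, mu = mu),
        count_ctcfko = stats::rnbinom(n_genes, size = nb_size, mu = mu))
    libsz <- lapply(coverage, function(byprot) vapply(byprot, function(gr)
        sum(as.numeric(width(gr)) * gr$score), numeric(1)))
    list(coverage = coverage, genes = genes, library_sizes = libsz)
}
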