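test_that("gamma equals the generating exponent on noiseless power law", {
    for (alpha in c(1.0, 0.85)) {
        cm <- flatPowerLawCM(alpha)
        gt <- fitGamma(cm, rep(1, 60), d_min = 5e4, d_max = 5e5,
                       n_logbins = 40, min_bins = 5)
        g <- gammaValues(gt)
        expect_true(any(fragments(gt)$defined))
        expect_lt(max(abs(g - alpha), na.rm = TRUE), 1e-3)
    }
    expect_error(fitGamma(flatPowerLawCM(1)), "bias")
})

test_that("fragments with too few informative bins are undefined", {
    ## 5 fragments only: at most 4 distances -> fewer than min_bins bins
    fm <- uniformFragMap(5, 5e4)
    pr <- t(utils::combn(5, 2))
    mid <- (start(fragments(fm)) + end(fragments(fm))) / 2
    d <- mid[pr[, 2]] - mid[pr[, 1]]
    cm <- makeCM(fm, pr[, 1], pr[, 2], (d / 1e4)^-1 * 10)
    gt <- fitGamma(cm, rep(1, 5), d_min = 5e4, d_max = 5e5,
                   n_logbins = 40, min_bins = 5)
    expect_true(all(!fragments(gt)$defined))
    expect_true(all(is.na(gammaValues(gt))))
})

test_that("boundary-adjacent fragments score high gamma (AUROC)", {
    W <- 2e5
    bnd <- do.call(rbind, lapply(1:2, function(k) data.frame(
        chrom = sprintf("chr%d", k), pos = seq_len(4) * W, beta = 0.2,
        label = "none")))
    spec <- syntheticSpec(n_chrom = 2, chrom_length = 1e6,
                          mean_fragment = 1000, depth = 2e6,
                          max_dist = 6e5, boundaries = bnd)
    fm <- simulateGenome(spec, seed = 1)
    sim <- simulateContacts(fm, spec, "control", seed = 101)
    bal <- icNormalize(sim$contacts)
    gt <- fitGamma(sim$contacts, biases(bal), d_min = 1e4, d_max = 1e5,
                   bias_window = 21)
    fr <- fragments(gt)
    g <- fr$gamma
    mid <- (start(fr) + end(fr)) / 2
    chr <- as.character(seqnames(fr))
    d2b <- rep(Inf, length(fr))
    for (r in seq_len(nrow(bnd))) {
        sel <- chr == bnd$chrom[r]
        d2b[sel] <- pmin(d2b[sel], abs(mid[sel] - bnd$pos[r]))
    }
    adj <- which(d2b <= 2000 & !is.na(g))
    midd <- which(d2b > W / 4 & d2b < W / 2 & !is.na(g))
    expect_gt(aurocOf(g[adj], g[midd]), 0.9)
})

test_that("region gamma assignment follows the window weighting rules", {
    fm <- uniformFragMap(10, 1000)
    fr <- fragments(fm)
    fr$gamma <- c(2, 1, 3, rep(1.5, 7))
    fr$n_bins <- 6L; fr$contacts <- 100; fr$defined <- TRUE
    gt <- new("GammaTrack", fragments = fr, params = list())
    ## region inside one fragment takes that fragment's gamma
    r1 <- GRanges("chr1", IRanges(1200, 1500))
    expect_equal(assignRegionGamma(gt, r1)$gamma, 1)
    ## window split 100/100 bp across gammas 1 and 3 -> 2
    r2 <- GRanges("chr1", IRanges(1901, 2100))
    expect_equal(assignRegionGamma(gt, r2)$gamma, 2)
    ## undefined fragments renormalize the weights
    fr2 <- fr; fr2$defined[2] <- FALSE; fr2$gamma[2] <- NA
    gt2 <- new("GammaTrack", fragments = fr2, params = list())
    expect_equal(assignRegionGamma(gt2, r2)$gamma, 3)  # only frag 3 defined
    ## region outside the map errors
    expect_error(assignRegionGamma(gt, GRanges("chr1", IRanges(9000, 12000))),
                 "outside")
})

test_that("region gamma equals brute-force window enumeration", {
    set.seed(13)
    fm <- uniformFragMap(50, 997)  # deliberately awkward width
    fr <- fragments(fm)
    fr$gamma <- rnorm(50, 1, 0.3)
    fr$gamma[sample(50, 5)] <- NA
    fr$defined <- !is.na(fr$gamma)
    fr$n_bins <- 6L; fr$contacts <- 1
    gt <- new("GammaTrack", fragments = fr, params = list())
    starts <- sample(1:45000, 200)
    regs <- GRanges("chr1", IRanges(starts, starts + sample(100:900, 200, TRUE)))
    got <- assignRegionGamma(gt, regs)$gamma
    ## oracle: enumerate 200-bp windows at 100-bp steps, weighted mean
    oracle <- vapply(seq_along(regs), function(k) {
        s <- start(regs)[k]; e <- end(regs)[k]
        ws <- if (e - s + 1 < 200) s else seq(s, e - 200 + 1, by = 100)
        vals <- vapply(ws, function(w0) {
            w1 <- min(w0 + 199, e)
            wsum <- 0; gsum <- 0
            for (f in seq_along(fr)) {
                ov <- max(0, min(w1, end(fr)[f]) - max(w0, start(fr)[f]) + 1)
                if (ov > 0 && fr$defined[f]) {
                    wsum <- wsum + ov
                    gsum <- gsum + ov * fr$gamma[f]
                }
            }
            if (wsum == 0) NA_real_ else gsum / wsum
        }, numeric(1))
        if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("delta gamma is the knockout minus control difference", {
    fm <- uniformFragMap(10, 1000)
    fr <- fragments(fm)
    fr$gamma <- rep(3, 10); fr$n_bins <- 6L; fr$contacts <- 1
    fr$defined <- TRUE
    con <- new("GammaTrack", fragments = fr, params = list())
    fr2 <- fr; fr2$gamma <- rep(1, 10)
    ko <- new("GammaTrack", fragments = fr2, params = list())
    regs <- GRanges("chr1", IRanges(c(1500, 4200), c(2500, 5100)))
    dg <- deltaGamma(ko, con, regs)
    expect_equal(dg$dgamma, c(-2, -2))
    ## identical tracks -> zero
    expect_equal(deltaGamma(con, con, regs)$dgamma, c(0, 0))
    ## undefined on either side -> NA
    fr3 <- fr2; fr3$defined[2:5] <- FALSE; fr3$gamma[2:5] <- NA
    ko2 <- new("GammaTrack", fragments = fr3, params = list())
    expect_true(is.na(deltaGamma(ko2, con, regs)$dgamma[1]))
})

test_that("TAD border calling uses a strict genome-wide percentile", {
    fm <- uniformFragMap(200, 1000)
    fr <- fragments(fm)
    fr$gamma <- rep(1, 200); fr$n_bins <- 6L; fr$contacts <- 1
    fr$defined <- TRUE
    flat <- new("GammaTrack", fragments = fr, params = list())
    expect_length(borders(callTadBorders(flat)), 0)  # strict inequality

    ## ~5% exceed the nearest-rank threshold on continuous data
    set.seed(3)
    fr$gamma <- rnorm(200)
    gt <- new("GammaTrack", fragments = fr, params = list())
    thr <- nearestRankPercentile(fr$gamma, 95)
    expect_equal(sum(fr$gamma > thr), 10)
    ## qualifying fragments with a one-fragment gap merge into one border
    fr$gamma <- rep(0, 200); fr$gamma[c(50, 52)] <- 10
    gt2 <- new("GammaTrack", fragments = fr, params = list())
    bd <- borders(callTadBorders(gt2))
    expect_length(bd, 1)
    expect_equal(start(bd), 49001)
    expect_equal(end(bd), 52000)
    expect_error(callTadBorders(new("GammaTrack",
                                    fragments = fr[1:50], params = list())),
                 "100 defined")
})

test_that("implanted boundaries are recovered by border calling", {
    pos <- c(8e5, 2.4e6)
    bnd <- data.frame(chrom = rep(sprintf("chr%d", 1:5), each = 2),
                      pos = rep(pos, 5), beta = 0.2, label = "none")
    spec <- syntheticSpec(n_chrom = 5, chrom_length = 3.2e6,
                          mean_fragment = 2000, depth = 2e6,
                          max_dist = 2e5, boundaries = bnd)
    fm <- simulateGenome(spec, seed = 7)
    sim <- simulateContacts(fm, spec, "control", seed = 8)
    gt <- fitGamma(sim$contacts, biases(icNormalize(sim$contacts)),
                   d_min = 1e4, d_max = 1e5, bias_window = 21)
    bd <- borders(callTadBorders(gt))
    hit <- vapply(seq_len(nrow(bnd)), function(r) {
        sel <- as.character(seqnames(bd)) == bnd$chrom[r]
        if (!any(sel)) return(Inf)
        min(pmax(start(bd)[sel] - bnd$pos[r], bnd$pos[r] - end(bd)[sel], 0))
    }, numeric(1))
    expect_gte(sum(hit <= 4000), 9)  # within 2 fragments
})

test_that("border reconciliation is greedy nearest-first within tolerance", {
    mkset <- function(mids, rep) {
        new("BorderSet",
            borders = GRanges("chr1", IRanges(mids - 500, mids + 500),
                              score = rep(1, length(mids))),
            replicate = rep)
    }
    ## 10,000 vs 11,500 -> one consensus at 10,750
    cons <- reconcileBorders(mkset(10000, "r1"), mkset(11500, "r2"))
    expect_length(borders(cons), 1)
    expect_equal(start(borders(cons)), floor((10000 + 11500) / 2))
    ## 10,000 vs 12,500 -> none
    expect_length(borders(reconcileBorders(mkset(10000, "r1"),
                                           mkset(12500, "r2"))), 0)
    ## each border matched at most once; count equals optimal matching
    set.seed(5)
    m1 <- sort(sample(seq(1e4, 5e5, by = 100), 40))
    m2 <- sort(sample(seq(1e4, 5e5, by = 100), 40))
    cons2 <- reconcileBorders(mkset(m1, "r1"), mkset(m2, "r2"), tol = 2000)
    ## brute-force optimal bipartite matching count via greedy on sorted
    ## distance list (equivalent for non-degenerate spacing)
    cand <- expand.grid(a = seq_along(m1), b = seq_along(m2))
    cand$d <- abs(m1[cand$a] - m2[cand$b])
    cand <- cand[cand$d <= 2000, ]
    cand <- cand[order(cand$d), ]
    ua <- logical(40); ub <- logical(40); nmatch <- 0
    for (r in seq_len(nrow(cand))) {
        if (!ua[cand$a[r]] && !ub[cand$b[r]]) {
            ua[cand$a[r]] <- ub[cand$b[r]] <- TRUE
            nmatch <- nmatch + 1
        }
    }
    expect_length(borders(cons2), nmatch)
})

test_that("border overlap statistics report both directions", {
    b <- GRanges("chr1", IRanges((1:10) * 1e4, (1:10) * 1e4 + 100))
    p <- GRanges("chr1", IRanges((1:7) * 1e4, (1:7) * 1e4 + 50))
    st <- borderOverlapStats(b, p)
    expect_equal(st$n_borders, 10)
    expect_equal(st$n_overlapping_bound, 7)
    expect_equal(st$pct_borders_bound, 70)
    expect_equal(st$pct_bound_at_borders, 100)
    ## disjoint and identical sets
    q <- GenomicRanges::shift(b, 5000)
    expect_equal(borderOverlapStats(b, q)$pct_borders_bound, 0)
    expect_equal(borderOverlapStats(b, b)$pct_borders_bound, 100)
})

test_that("gamma tracks round-trip through TSV", {
    fm <- uniformFragMap(20, 1000)
    fr <- fragments(fm)
    fr$gamma <- rnorm(20); fr$gamma[3] <- NA
    fr$n_bins <- 6L; fr$contacts <- 10
    fr$defined <- !is.na(fr$gamma)
    gt <- new("GammaTrack", fragments = fr, params = list())
    f <- withr::local_tempfile(fileext = ".tsv")
    writeGammaTrack(gt, f)
    back <- readGammaTrack(f)
    expect_equal(gammaValues(back), fr$gamma)
    expect_equal(fragments(back)$defined, fr$defined)
    expect_equal(start(fragments(back)), start(fr))
})
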