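test_that("binning follows the midpoint rule and conserves counts", {
    ## fragments with midpoints 2100 and 7900 -> bins 1 and 2 at 5 kb
    fm <- fragmentMap(data.frame(chrom = "chr1",
                                 start = c(0, 4200, 11600),
                                 end = c(4200, 11600, 10e3 + 5e3)))
    cm <- makeCM(fm, 1, 2, 3)
    b <- binContacts(cm, 5000)
    expect_equal(triplets(b), data.frame(i = 1L, j = 2L, value = 3))
    expect_error(binContacts(cm, 0), "positive")
})

test_that("binning a random matrix matches the brute-force oracle", {
    set.seed(11)
    fm <- smallSim(seed = 3, n_chrom = 1, chrom_length = 2e5,
                   mean_fragment = 4000, depth = 5e4)$fm
    frg <- fragments(fm)
    n <- length(frg)
    idx <- t(utils::combn(n, 2))
    pick <- sample(nrow(idx), 200)
    cm <- makeCM(fm, idx[pick, 1], idx[pick, 2], rpois(200, 4))
    binsize <- 25e3
    out <- binContacts(cm, binsize)
    ## oracle: loop over triplets, assign to midpoint bins
    mid <- (start(frg) + end(frg)) / 2
    nb <- length(anchors(out))
    oracle <- matrix(0, nb, nb)
    tr <- triplets(cm)
    for (r in seq_len(nrow(tr))) {
        bi <- floor((mid[tr$i[r]] - 1) / binsize) + 1
        bj <- floor((mid[tr$j[r]] - 1) / binsize) + 1
        lo <- min(bi, bj); hi <- max(bi, bj)
        oracle[lo, hi] <- oracle[lo, hi] + tr$value[r]
    }
    got <- matrix(0, nb, nb)
    tro <- triplets(out)
    got[cbind(tro$i, tro$j)] <- tro$value
    expect_equal(got, oracle)
    expect_equal(sum(tro$value), sum(tr$value))  # conservation
})

test_that("iterative correction balances and matches an IPF oracle", {
    ## constant off-diagonal matrix is already balanced
    fm <- uniformFragMap(4, 1000)
    pr <- t(utils::combn(4, 2))
    cm <- makeCM(fm, pr[, 1], pr[, 2], rep(6, 6))
    bal <- icNormalize(cm, min_row_sum = 1)
    v <- biases(bal)
    expect_true(max(abs(v / v[1] - 1)) < 1e-4)
    expect_true(max(abs(triplets(bal)$value /
                        triplets(bal)$value[1] - 1)) < 1e-4)

    ## 3x3 example vs dense iterative-proportional-fitting oracle
    fm3 <- uniformFragMap(3, 1000)
    cm3 <- makeCM(fm3, c(1, 1, 2), c(2, 3, 3), c(2, 4, 8))
    bal3 <- icNormalize(cm3, min_row_sum = 1, tol = 1e-8, max_iter = 2000)
    W <- denseCM(cm3); diag(W) <- 0
    b <- rep(1, 3)
    for (it in 1:10000) {
        s <- rowSums(W / outer(b, b))
        if (max(abs(s / mean(s) - 1)) < 1e-12) break
        b <- b * sqrt(s / mean(s))
    }
    Wb <- W / outer(b, b)
    Wb <- Wb / mean(rowSums(Wb))  # scale to row sums ~1, as icNormalize does
    got <- denseCM(bal3)
    expect_equal(got[upper.tri(got)], Wb[upper.tri(Wb)], tolerance = 1e-5)

    ## zero-count row is masked and absent from the output
    cmz <- makeCM(uniformFragMap(3, 1000), 1, 2, 10)
    balz <- icNormalize(cmz, min_row_sum = 1)
    expect_equal(maskedAnchors(balz), 3L)
    expect_true(all(triplets(balz)$i != 3 & triplets(balz)$j != 3))
    expect_true(is.na(biases(balz)[3]))
})

test_that("row sums of the balanced matrix are equal within tolerance", {
    sim <- smallSim(seed = 5, n_chrom = 1, chrom_length = 5e5,
                    mean_fragment = 2000, depth = 5e5)
    bal <- icNormalize(sim$cm, tol = 1e-5)
    W <- denseCM(bal); diag(W) <- 0
    keep <- setdiff(seq_len(nrow(W)), maskedAnchors(bal))
    rs <- rowSums(W)[keep]
    expect_lt(max(abs(rs / mean(rs) - 1)), 1e-4)
})

test_that("decay fit is exact on noiseless power law and flat input", {
    cm <- flatPowerLawCM(1.0)
    bal <- new("ContactMatrix", anchors = anchors(cm),
               triplets = triplets(cm), state = "balanced",
               binsize = NA_real_, mask = integer(), biases = numeric(),
               diagnostics = list())
    dm <- fitDecay(bal, d_min = 5e4, d_max = 5e5, n_logbins = 40)
    expect_lt(abs(decayExponent(dm) - 1.0), 1e-6)

    flat <- flatPowerLawCM(0)
    balf <- new("ContactMatrix", anchors = anchors(flat),
                triplets = triplets(flat), state = "balanced",
                binsize = NA_real_, mask = integer(), biases = numeric(),
                diagnostics = list())
    dmf <- fitDecay(balf, d_min = 5e4, d_max = 5e5, n_logbins = 40)
    expect_lt(abs(decayExponent(dmf)), 1e-6)

    expect_error(fitDecay(bal, d_min = 4e5, d_max = 4.2e5, n_logbins = 20),
                 "non-empty")
    expect_error(fitDecay(cm), "balanced")
})

test_that("decay exponent is recovered from Poisson-sampled input", {
    sim <- smallSim(seed = 17, n_chrom = 1, chrom_length = 1e6,
                    mean_fragment = 1000, depth = 1e6, bias_sd = 0)
    bal <- icNormalize(sim$cm)
    dm <- fitDecay(bal, d_min = 1e4, d_max = 4e5)
    expect_lt(abs(decayExponent(dm) - 0.85), 0.05)
})

test_that("joint normalization equalizes per-stratum totals", {
    fm <- uniformFragMap(40, 5000)
    cmA <- binContacts(makeCM(fm, rep(1:30, 3),
                              rep(1:30, 3) + rep(c(1, 3, 6), each = 30),
                              rpois(90, 20) + 1), 10000)
    trB <- triplets(cmA); trB$value <- trB$value * 2
    cmB <- new("ContactMatrix", anchors = anchors(cmA), triplets = trB,
               state = "raw", binsize = 10000, mask = integer(),
               biases = numeric(), diagnostics = list())
    out <- jointNormalize(list(cmA, cmB))
    expect_equal(triplets(out[[1]])$value, triplets(out[[2]])$value,
                 tolerance = 1e-12)
    expect_equal(contactState(out[[1]]), "joint")

    ## identical samples unchanged
    out2 <- jointNormalize(list(cmA, cmA))
    expect_equal(triplets(out2[[1]])$value, triplets(cmA)$value,
                 tolerance = 1e-12)

    ## three random samples vs brute-force per-stratum rescaling oracle
    set.seed(21)
    mats <- lapply(1:3, function(k) {
        i <- sample(1:20, 60, TRUE); j <- sample(1:20, 60, TRUE)
        keep <- i != j
        tr <- insuscreen:::.canonicalTriplets(i[keep], j[keep],
                                              rpois(sum(keep), 30) + 1)
        new("ContactMatrix", anchors = anchors(cmA), triplets = tr,
            state = "raw", binsize = 10000, mask = integer(),
            biases = numeric(), diagnostics = list())
    })
    outs <- jointNormalize(mats)
    ## oracle: offset strata, geometric-mean totals
    strat <- function(tr) tr$j - tr$i
    allstr <- sort(unique(unlist(lapply(mats, function(m) strat(triplets(m))))))
    for (s in allstr) {
        tot <- vapply(mats, function(m)
            sum(triplets(m)$value[strat(triplets(m)) == s]), numeric(1))
        gm <- exp(mean(log(tot[tot > 0])))
        for (k in 1:3) {
            got <- sum(triplets(outs[[k]])$value[strat(triplets(outs[[k]])) == s])
            if (tot[k] > 0) expect_equal(got, gm, tolerance = 1e-8)
        }
    }
    expect_error(jointNormalize(list(cmA)), "two samples")
})

test_that("correlation clustering matches a brute-force oracle", {
    set.seed(31)
    fm <- uniformFragMap(200, 5000)
    bins <- binAxis(fm, 5000)
    mk <- function() {
        i <- sample(1:200, 900, TRUE); j <- sample(1:200, 900, TRUE)
        tr <- insuscreen:::.canonicalTriplets(i, j, rpois(900, 12))
        new("ContactMatrix", anchors = bins, triplets = tr,
            state = "raw", binsize = 5000, mask = integer(),
            biases = numeric(), diagnostics = list())
    }
    A <- mk(); B <- mk()
    res <- correlationCluster(list(a = A, b = B), min_count = 2,
                              max_sep = 1.6e6)
    ## oracle: merge filtered pairs by key, spearman by hand
    filt <- function(cm) {
        tr <- triplets(cm)
        mid <- (start(anchors(cm)) + end(anchors(cm))) / 2
        tr <- tr[tr$value >= 2 & tr$i != tr$j &
                 abs(mid[tr$j] - mid[tr$i]) <= 1.6e6, ]
        tr
    }
    fa <- filt(A); fb <- filt(B)
    m <- merge(fa, fb, by = c("i", "j"))
    rho <- cor(rank(m$value.x), rank(m$value.y))
    expect_equal(res$correlation["a", "b"], rho, tolerance = 1e-12)
    expect_equal(as.matrix(res$distance)["a", "b"], 1 - abs(rho),
                 tolerance = 1e-12)

    ## sample vs itself -> distance 0
    res2 <- correlationCluster(list(x = A, y = A))
    expect_equal(as.matrix(res2$distance)["x", "y"], 0)

    ## diagonal-only differences vanish when the diagonal is dropped
    trd <- rbind(triplets(A), data.frame(i = 1:5, j = 1:5, value = 99))
    Ad <- new("ContactMatrix", anchors = anchors(A), triplets =
              insuscreen:::.canonicalTriplets(trd$i, trd$j, trd$value),
              state = "raw", binsize = 5000, mask = integer(),
              biases = numeric(), diagnostics = list())
    res3 <- correlationCluster(list(x = A, y = Ad), drop_diagonal = TRUE)
    expect_equal(as.matrix(res3$distance)["x", "y"], 0)

    expect_error(correlationCluster(list(x = A, y = B), min_count = 1e9),
                 "surviving")
})
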