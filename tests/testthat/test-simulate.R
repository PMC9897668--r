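test_that("synthetic genomes have the expected fragment count and are seeded", {
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 1e6, mean_fragment = 256)
    fm <- simulateGenome(spec, seed = 7)
    n <- length(fragments(fm))
    expect_gt(n, 3906 * 0.9)
    expect_lt(n, 3906 * 1.1)
    fm2 <- simulateGenome(spec, seed = 7)
    expect_identical(start(fragments(fm)), start(fragments(fm2)))
    expect_error(syntheticSpec(chrom_length = 256, mean_fragment = 256),
                 "shorter")
})

test_that("expected contacts follow the generative formula", {
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                          mean_fragment = 2000, bias_sd = 0,
                          boundaries = data.frame(chrom = "chr1", pos = 1e5,
                                                  beta = 0.2, label = "none"))
    fm <- simulateGenome(spec, seed = 3)
    frg <- fragments(fm)
    n <- length(frg)
    v <- rep(1, n)
    mid <- (start(frg) + end(frg)) / 2
    ## pairs straddling the boundary carry exactly beta x the plain decay
    left <- max(which(mid < 9e4)); right <- min(which(mid > 1.1e5))
    inner <- which(mid > 1.05e5)[1:2]
    e_cross <- expectedContacts(fm, spec, "control", v, left, right)
    d <- mid[right] - mid[left]
    expect_equal(e_cross, 0.2 * (d / 1e4)^(-0.85), tolerance = 1e-12)
    e_plain <- expectedContacts(fm, spec, "control", v, inner[1], inner[2])
    expect_equal(e_plain,
                 ((mid[inner[2]] - mid[inner[1]]) / 1e4)^(-0.85),
                 tolerance = 1e-12)
    ## knockout semantics: a "none" boundary stays active in every condition
    expect_equal(expectedContacts(fm, spec, "Cp190KO", v, left, right),
                 e_cross)
})

test_that("simulated counts match the expectation model (Poisson closure)", {
    bnd <- data.frame(chrom = "chr1", pos = c(7e4, 1.4e5),
                      beta = c(0.3, 0.6), label = c("Cp190", "both"))
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                          mean_fragment = 2000, depth = 3e5,
                          bias_sd = 0.3, boundaries = bnd, max_dist = 2e5)
    fm <- simulateGenome(spec, seed = 11)
    sim <- simulateContacts(fm, spec, "control", seed = 12)
    frg <- fragments(fm)
    n <- length(frg)
    ## oracle: expectation for every pair by direct evaluation + calibration
    pr <- t(utils::combn(n, 2))
    E <- expectedContacts(fm, spec, "control", sim$truth@biases,
                          pr[, 1], pr[, 2])
    E <- E * spec@depth / sum(E)
    obs <- denseCM(sim$contacts)[cbind(pr[, 1], pr[, 2])]
    ## total conserved within 0.1% in expectation; Poisson noise ~1/sqrt(N)
    expect_lt(abs(sum(obs) - spec@depth) / spec@depth, 0.01)
    ## standardized residuals behave like Poisson
    z <- (obs - E) / sqrt(pmax(E, 1e-12))
    big <- E > 5
    expect_lt(abs(mean(z[big])), 0.1)
    expect_lt(abs(sd(z[big]) - 1), 0.15)
})

test_that("boundary attenuation is monotone in beta and condition-dependent", {
    mkE <- function(beta, condition, label) {
        spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                              mean_fragment = 2000, bias_sd = 0,
                              boundaries = data.frame(chrom = "chr1",
                                                      pos = 1e5, beta = beta,
                                                      label = label))
        fm <- simulateGenome(spec, seed = 5)
        frg <- fragments(fm)
        mid <- (start(frg) + end(frg)) / 2
        i <- max(which(mid < 9.5e4)); j <- min(which(mid > 1.05e5))
        expectedContacts(fm, spec, condition, rep(1, length(frg)), i, j)
    }
    e <- vapply(c(0.1, 0.4, 0.7, 1.0), mkE, numeric(1),
                condition = "control", label = "none")
    expect_true(all(diff(e) > 0))   # cross-boundary contacts rise with beta
    ## "both" boundaries are inactive in both knockouts, active in control
    expect_lt(mkE(0.2, "control", "both"), mkE(0.2, "Cp190KO", "both"))
    expect_equal(mkE(0.2, "Cp190KO", "both"), mkE(0.2, "CTCFKO", "both"))
    expect_equal(mkE(0.2, "CTCFKO", "both"), mkE(1, "control", "both"))
})

test_that("loop pairs multiply expectations by lambda", {
    spec0 <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                           mean_fragment = 2000, bias_sd = 0, depth = 1e6,
                           max_dist = 2e5)
    fm <- simulateGenome(spec0, seed = 9)
    frg <- fragments(fm)
    mid <- (start(frg) + end(frg)) / 2
    ## anchor the loop at actual fragment midpoints
    p1 <- mid[which.min(abs(mid - 5e4))]; p2 <- mid[which.min(abs(mid - 1.5e5))]
    loops <- data.frame(chrom = "chr1", pos1 = p1, pos2 = p2, lambda = 5)
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                          mean_fragment = 2000, bias_sd = 0, depth = 1e6,
                          loops = loops, max_dist = 2e5)
    v <- rep(1, length(frg))
    s1 <- simulateContacts(fm, spec, "control", seed = 10, biases = v)
    s0 <- simulateContacts(fm, spec0, "control", seed = 10, biases = v)
    a1 <- which(abs(mid - p1) <= 2500); a2 <- which(abs(mid - p2) <= 2500)
    d1 <- denseCM(s1$contacts); d0 <- denseCM(s0$contacts)
    ratio <- sum(d1[a1, a2]) / sum(d0[a1, a2])
    ## calibration shifts A slightly; ratio approx lambda within Poisson noise
    expect_gt(ratio, 3.5)
    expect_lt(ratio, 7)
})

test_that("binding simulation places class-consistent peaks per condition", {
    bnd <- data.frame(chrom = "chr1", pos = c(5e4, 1.5e5), beta = 0.2,
                      label = c("Cp190", "CTCF"))
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                          mean_fragment = 2000, boundaries = bnd)
    fm <- simulateGenome(spec, seed = 1)
    sim <- simulateContacts(fm, spec, "control", seed = 2)
    bind <- simulateBinding(sim$truth, c("MCIFS", "MCS"),
                            decoys = data.frame(chrom = "chr1", pos = 1e5,
                                                class = "S"))
    pk <- bind$peaks
    ## MCIFS site appears in all five control files
    for (p in c("M", "C", "I", "F", "S"))
        expect_true(any(abs(start(pk$control[[p]]) - (5e4 - 299)) < 2))
    ## S-only decoy appears only in the Su(Hw) file
    atDecoy <- vapply(pk$control, function(g)
        any(abs((start(g) + end(g)) / 2 - 1e5) < 400), logical(1))
    expect_equal(unname(atDecoy), c(FALSE, FALSE, FALSE, FALSE, TRUE))
    ## Cp190-KO drops all C peaks, CTCF-KO all F peaks
    expect_length(pk$Cp190KO$C, 0)
    expect_length(pk$CTCFKO$F, 0)
    expect_length(pk$Cp190KO$M, 2)

    ## summits closer than the pad rule -> error
    bnd2 <- data.frame(chrom = "chr1", pos = c(5e4, 5.03e4), beta = 0.2,
                       label = c("none", "none"))
    spec2 <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                           mean_fragment = 2000, boundaries = bnd2)
    sim2 <- simulateContacts(simulateGenome(spec2, seed = 1), spec2,
                             "control", seed = 2)
    expect_error(simulateBinding(sim2$truth, c("M", "C")), "closer")
})

test_that("coverage tracks and expression tables are reproducible", {
    bnd <- data.frame(chrom = "chr1", pos = 1e5, beta = 0.2, label = "none")
    spec <- syntheticSpec(n_chrom = 1, chrom_length = 2e5,
                          mean_fragment = 2000, boundaries = bnd)
    fm <- simulateGenome(spec, seed = 1)
    sim <- simulateContacts(fm, spec, "control", seed = 2)
    bind <- simulateBinding(sim$truth, "MC")
    cov1 <- simulateCoverageAndExpression(bind$truth, spec, seed = 5,
                                          peak_height = 10, n_genes = 40)
    cov2 <- simulateCoverageAndExpression(bind$truth, spec, seed = 5,
                                          peak_height = 10, n_genes = 40)
    expect_identical(cov1$genes, cov2$genes)
    expect_equal(cov1$coverage$control$M$score,
                 cov2$coverage$control$M$score)
    ## region signal at the peak is about the peak height
    reg <- GRanges("chr1", IRanges(1e5 - 299, 1e5 + 300))
    sc <- regionSignal(cov1$coverage$control$M, reg)
    expect_gt(sc, 9); expect_lt(sc, 11)
    ## a zero-count gene lands in the bottom quartile
    g <- tssActivityClasses(cov1$genes)
    expect_true(all(g$activity[g$count == 0] == "low"))
})
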