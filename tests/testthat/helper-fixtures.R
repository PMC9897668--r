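## Shared fixture builders: everything is generated in code at test time.

library(GenomicRanges)
library(IRanges)

## a FragmentMap of uniform fragments
uniformFragMap <- function(n_frag = 60, frag_width = 5e4, chroms = "chr1") {
    df <- do.call(rbind, lapply(chroms, function(c0)
        data.frame(chrom = c0, start = (seq_len(n_frag) - 1) * frag_width,
                   end = seq_len(n_frag) * frag_width)))
    fragmentMap(df)
}

## a ContactMatrix from explicit triplets on a given axis
makeCM <- function(axis, i, j, value, state = "raw", binsize = NA_real_) {
    anchors <- if (is(axis, "FragmentMap")) fragments(axis) else axis
    new("ContactMatrix", anchors = anchors,
        triplets = data.frame(i = as.integer(i), j = as.integer(j),
                              value = as.numeric(value)),
        state = state, binsize = binsize, mask = integer(),
        biases = numeric(), diagnostics = list())
}

## noiseless power-law matrix on a uniform fragment grid; every distance
## bin of a 40-bin log grid over [fw, 10*fw] holds a single distance, so
## slope estimators are exact on this input
flatPowerLawCM <- function(alpha, n_frag = 60, fw = 5e4, d_cap = 5e5,
                           scale = 100) {
    fm <- uniformFragMap(n_frag, fw)
    frg <- fragments(fm)
    mid <- (start(frg) + end(frg)) / 2
    pr <- t(utils::combn(n_frag, 2))
    d <- mid[pr[, 2]] - mid[pr[, 1]]
    keep <- d <= d_cap
    makeCM(fm, pr[keep, 1], pr[keep, 2], (d[keep] / 1e4)^(-alpha) * scale)
}

## dense symmetric matrix from a ContactMatrix (oracle-side view)
denseCM <- function(cm) {
    n <- length(anchors(cm))
    m <- matrix(0, n, n)
    tr <- triplets(cm)
    for (r in seq_len(nrow(tr))) {
        m[tr$i[r], tr$j[r]] <- m[tr$i[r], tr$j[r]] + tr$value[r]
        if (tr$i[r] != tr$j[r])
            m[tr$j[r], tr$i[r]] <- m[tr$j[r], tr$i[r]] + tr$value[r]
    }
    m
}

## one-sided hypergeometric tail (P[X >= x]) by direct lchoose enumeration;
## the independent oracle for Fisher's exact test
hyperTailGE <- function(x, white, black, drawn) {
    ks <- x:min(white, drawn)
    ks <- ks[ks >= max(0, drawn - black)]
    sum(exp(lchoose(white, ks) + lchoose(black, drawn - ks) -
            lchoose(white + black, drawn)))
}

## Mann-Whitney AUROC
aurocOf <- function(pos, neg) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

## standard synthetic genome + one condition, small but realistic
smallSim <- function(seed = 1, n_chrom = 2, chrom_length = 1e6,
                     mean_fragment = 1000, boundaries = NULL,
                     condition = "control", depth = 2e6, max_dist = 5e5,
                     bias_sd = 0.3) {
    spec <- syntheticSpec(n_chrom = n_chrom, chrom_length = chrom_length,
                          mean_fragment = mean_fragment, depth = depth,
                          max_dist = max_dist, bias_sd = bias_sd,
                          boundaries = boundaries)
    fm <- simulateGenome(spec, seed = seed)
    sim <- simulateContacts(fm, spec, condition, seed = seed + 1)
    list(spec = spec, fm = fm, cm = sim$contacts, truth = sim$truth)
}
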