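---
title: "Screening for chromatin insulators from Hi-C: models and methods"
author: "insuscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for chromatin insulators from Hi-C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chromatin insulators are DNA elements that limit contacts between the
chromosomal regions on their two sides.  Genome-wide, candidate insulators
can be found by comparing Hi-C contact maps of wild-type cells with maps
from cells lacking an insulator protein (here: Cp190 or CTCF knockouts):
a genuine insulator limits contact crossing in the wild type and loses
that ability when a protein it depends on is removed.  `insuscreen`
implements this topological screen as a reusable pipeline and ships a
synthetic Hi-C generator with implanted ground truth, so every statistical
property of the screen can be verified end to end.

## The contact model and the distance-scaling factor gamma

Hi-C contact frequency between two loci decays with their genomic
distance d approximately as a power law, `E[o] ~ d^-alpha`.  Most locus
pairs follow this global decay; pairs separated by a contact-limiting
element fall below it.  The per-fragment distance-scaling factor gamma
quantifies this: fragments whose contact profile sits at or above the
global expectation get gamma close to the global exponent; fragments
whose contacts are systematically scarcer than predicted get higher
gamma ("harder to cross").

`fitGamma` estimates gamma per restriction fragment as follows:

1. Contacts of a fragment with partners at distances in `[d_min, d_max]`
   (defaults 10 kb and 500 kb) are aggregated into log-spaced distance
   bins.  The bin mean is the contact sum divided by the number of
   *possible* partners in the bin, so unobserved pairs count as zeros.
   The bin's representative distance is the mean log distance of its
   observed pairs, which makes the estimator exact on noiseless
   power-law input.
2. A weighted least-squares line through `(log d, log mean)` is fitted
   **anchored on the intercept of the pooled global decay fit**.  This
   anchoring is essential: a contact-limiting element suppresses a
   neighbouring fragment's contacts by a roughly constant factor across
   distances, which a free-intercept slope cannot see at all.  With the
   anchored fit, a uniform deficit registers as a steeper effective
   decay, exactly matching the screen's notion of "observed contacts
   lower than predicted by the global model".
3. Fragments with fewer than `min_bins` informative bins are undefined
   (masked, never zero-filled).

### Bias correction inside the gamma fit

Matrix-balancing (IC) biases cannot be used directly to correct the
per-pair counts here, for two reasons we verified on synthetic data:

* raw row sums depend on the local restriction-fragment geometry (how
  close the nearest midpoints sit), which adds a large spurious
  per-fragment component (about 18% on typical synthetic genomes), and
* balancing absorbs the smooth topological depletion around
  contact-limiting elements — precisely the signal gamma must measure.

`fitGamma` therefore re-estimates fragment-autonomous biases internally:
each fragment's band contacts are compared with the distance-matched
global expectation (removing the geometry artifact), and the resulting
level is divided by its running median over `bias_window` fragments per
chromosome.  Technical biases are fragment-autonomous (high-frequency
along the genome) while topological depletion varies smoothly over tens
of kilobases, so the high-pass keeps the former and leaves the latter in
the data.  The window must stay *below* the width of the topological
dip: once the window exceeds the dip, the running median no longer
tracks it and the dip leaks into the bias estimate, cancelling the
signal (we verified the sign of this effect explicitly).  The default
(51 fragments) suits DpnII-scale fragments; the synthetic tests use 21
at their 2-kb fragment scale.  The residual smooth fluctuation of the
running median over the true lognormal biases (sd
`bias_sd * 1.25 / sqrt(bias_window)`) is the estimator's noise floor.
The IC bias vector is still a required input — it defines which
fragments are masked.

## Regions, delta-gamma and the empirical-FDR screen

Insulator-protein bound regions get a gamma by segmenting each region
into 200-bp windows sliding at 100-bp steps; a window's gamma is the
overlap-weighted mean over the defined fragments it covers, and the
region's gamma is the maximum window value.  `deltaGamma` is the
region-level `gamma_KO - gamma_control`; strongly negative values mean
the region lost contact-limiting activity in the knockout.

The screen, run once per knockout:

1. Sample `n = 344` random regions not bound by any profiled protein
   (lengths resampled from the bound-region length distribution, placed
   over defined-gamma territory only).  Their delta-gamma distribution
   is the null.
2. Empirical FDR thresholds are the nearest-rank bottom 5th/10th/15th
   percentiles of the null.
3. Per cobinding class, a one-sided Fisher exact test compares the
   class's share of regions at or below the bottom-10% threshold with
   the null's share; classes with `p < 1e-4` are significant.
4. A region is called at FDR level f iff its class is significant for
   that knockout and its delta-gamma is at or below the level-f
   threshold.  Calls are nested; dependence is Cp190/CTCF/both by which
   knockout(s) call the region.

Regions with undefined delta-gamma are excluded from class and null
counts, never imputed.  Ties at a threshold count as called (<=).

## The synthetic generator

`simulateContacts` draws Poisson counts with expectation

    E[o_ij] = A * v_i * v_j * (d_ij/d0)^-alpha * prod(beta_k) * lambda

where the product runs over implanted boundaries strictly between the
fragment midpoints that are active in the simulated condition
(`Cp190`-labelled boundaries are inactivated in the Cp190 knockout,
`CTCF` in the CTCF knockout, `both` in either, `none` never), lambda
applies to loop anchor-anchor pairs (anchors widened to one 5-kb bin),
v is a lognormal per-fragment bias and A is calibrated per chromosome
so the expected total equals the sequencing depth.  Defaults:
`alpha = 0.85`, `bias_sd = 0.3`, `depth = 2e6` per chromosome,
`d0 = 10 kb`, `mean_fragment = 256 bp` (DpnII-like geometric lengths).

What the generator emulates: power-law decay, multiplicative technical
biases, Poisson sampling, knockout-dependent boundary attenuation,
optional loops, cobinding peak sets over five proteins (M, C, I, F, S),
flat-top ChIP coverage with condition-dependent peak loss, and
negative-binomial expression counts.  What it does not emulate: real
sequence context (GC, mappability), ligation artifacts at short range,
domain-level contact enrichment beyond boundary attenuation, replicate
structure of real libraries, or overdispersed contact counts (Poisson by
default).  Passing tests therefore demonstrate the pipeline's
statistical correctness under the stated model, not performance on any
particular real dataset.

One property of the per-crossing attenuation model deserves emphasis:
between two control positions, an *active* boundary suppresses contacts
without any loops being present, so the looping test's no-loop
calibration uses topologically neutral sites (`beta = 1`).  With active
boundaries the test would report insulator-pair excess that is an
artifact of the generative model, not of looping.

## Problem sizes used by the tests and the acceptance script

All synthetic studies run at desk scale, chosen once from the
estimator's resolution and coverage arguments:

* **Recovery screen**: 50 chromosomes x 1.05 Mb, 2-kb fragments, 300
  sites (40/40/20 dependent, 100 independent, 100 decoys) spaced 150 kb,
  beta 0.2, depth 2e6/chromosome; gamma fit over [10 kb, 100 kb] with
  `bias_window = 21`.  The 150-kb spacing and the 35-kb null exclusion
  pad keep random regions outside the influence zone of any deleted
  boundary, which spans the gamma fit band; with the function's 1-kb
  default pad the null would be contaminated by genuine neighbourhood
  signal at these site densities.
* **FDR calibration**: global-null genomes (boundaries labelled `none`)
  over 20 seeds; thresholds from one 344-region sample, evaluated on an
  independent sample.
* **Boundary detection**: 200-kb domains for the AUROC check; a
  five-chromosome, 10-boundary genome for border recovery; a 9-point
  beta grid with five boundaries per beta and six seeds for the
  monotonicity check.
* **Crossing/looping**: one boundary per 6-Mb chromosome for the
  crossing-curve study (isolation keeps the joint-normalization strata
  undistorted by the knockout, so control-region curves stay centred on
  zero — with dense strong boundaries the per-stratum rescaling would
  shift them systematically); 36
  neutral sites with adjacent-pair loops of lambda 5 for the looping
  test, anchors snapped to 5-kb bin centres (the generator widens loop
  anchors to one bin, so off-centre anchors would split the boost
  across bins).

Larger fragments (1-2 kb instead of 256 bp) keep the per-fragment
contact counts realistic at megabase chromosome sizes; all rules that
reference fragment units (border merge gaps, "within 2 fragments")
scale with them.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in every file, 1-based closed
  GRanges in memory.
* Percentiles are nearest-rank on observed values; the TAD-border
  threshold uses strict `>`, the FDR thresholds use `<=`.
* Duplicate contact triplets are summed after canonicalizing `i <= j`;
  negative values are rejected at parse time.
* IC balancing excludes the diagonal, masks rows with raw sum below
  `min_row_sum = 10`, converges on the relative spread of row sums
  (tol 1e-5, max 200 iterations) and flags non-convergence.
* Joint normalization equalizes per-stratum totals to the geometric
  mean across samples (strata: bin offsets for binned axes, log-distance
  bins otherwise; diagonal and inter-chromosomal entries are their own
  strata).  Strata with zero totals are left untouched.
* `reconcileBorders` matches greedily nearest-first, ties toward the
  lower coordinate, each border used at most once.
* One shared random-region set serves both knockouts by default (each
  knockout still gets its own delta-gamma null values from it); drawing
  separate sets is the caller's choice.
* Replicate crossing curves are combined after region-averaging by
  default (`combineCrossingCurves`); pooling regions first is available.
* The crossing curve is mutant minus control, so loss of insulation is
  positive; offsets 1-2 are flagged low-confidence but kept.
* The looping verdict requires the insulator pairs to beat all three
  distance-matched controls (greater median and one-sided rank-sum
  p < 0.05) in every separation group; fully tied groups carry no
  evidence and count against looping.
* Wilcoxon/Spearman tests use the normal approximation (`exact =
  FALSE`), so tied data never error.

## Known limitations

* Gamma's absolute scale depends on the fit band and the anchoring, so
  only relative ordering and within-pipeline thresholds are meaningful;
  all screen rules are quantile-based for this reason.
* A knockout that removes many boundaries shifts the genome-wide gamma
  baseline; the empirical null absorbs this shift, but per-region
  delta-gamma values should not be compared across screens run with
  different fit bands.
* The bias high-pass cannot separate technical from topological
  variation at spatial scales near `bias_window`; dense boundary
  landscapes (spacing comparable to the window) compress the signal.
* Chromosome ends within `d_max` of a fragment have one-sided partner
  geometry; their gamma is noisier and border calls there should be
  treated with caution.
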