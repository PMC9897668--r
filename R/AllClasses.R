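#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' FragmentMap: restriction fragments tiling a genome
#'
#' Ordered, gapless restriction fragments (e.g. DpnII fragments) per
#' chromosome.  Fragments are the native resolution unit of the Hi-C assay
#' and the unit at which the distance-scaling factor gamma is fitted.
#' Coordinates are stored 1-based closed (GRanges convention); all file
#' readers/writers convert to and from 0-based half-open BED.
#'
#' @slot fragments A [GenomicRanges::GRanges] sorted by position, with an
#'   integer `index` metadata column running 1..n across the genome.
#'
#' @export
setClass("FragmentMap", slots = c(fragments = "GRanges"))

setValidity("FragmentMap", function(object) {
    gr <- object@fragments
    if (length(gr) == 0L) return("FragmentMap is empty")
    if (is.null(gr$index)) return("fragments need an 'index' column")
    if (!identical(gr$index, seq_along(gr)))
        return("fragment indices must run 1..n in coordinate order")
    for (chr in unique(as.character(seqnames(gr)))) {
        f <- gr[seqnames(gr) == chr]
        if (start(f)[1] != 1L)
            return(sprintf("fragments on %s do not start at position 0", chr))
        if (length(f) > 1L) {
            if (any(start(f)[-1] != end(f)[-length(f)] + 1L))
                return(sprintf("fragments on %s are not gapless/contiguous", chr))
        }
    }
    TRUE
})

#' ContactMatrix: sparse symmetric Hi-C contacts
#'
#' Upper-triangle sparse triplets (i <= j) over a fragment-level or
#' uniform-bin axis, together with the normalization state, the set of
#' masked (excluded) axis elements and, after iterative correction, the
#' per-element multiplicative bias vector.
#'
#' @slot anchors GRanges axis table (fragments or uniform bins), with an
#'   `index` column 1..n.
#' @slot triplets data.frame with integer columns `i`, `j` (i <= j, no
#'   duplicate keys) and numeric `value` >= 0.
#' @slot state one of `"raw"`, `"balanced"` (iterative correction) or
#'   `"joint"` (distance-stratified joint normalization).
#' @slot binsize bin size in bp for uniform-bin axes, `NA` for fragment axes.
#' @slot mask integer indices of masked axis elements.
#' @slot biases numeric per-element bias vector (length 0 before balancing).
#' @slot diagnostics list of fit/convergence diagnostics.
#'
#' @export
setClass("ContactMatrix", slots = c(
    anchors     = "GRanges",
    triplets    = "data.frame",
    state       = "character",
    binsize     = "numeric",
    mask        = "integer",
    biases      = "numeric",
    diagnostics = "list"
))

setValidity("ContactMatrix", function(object) {
    tr <- object@triplets
    if (!all(c("i", "j", "value") %in% names(tr)))
        return("triplets must have columns i, j, value")
    if (nrow(tr)) {
        if (any(tr$i > tr$j)) return("triplets must be canonical (i <= j)")
        if (any(tr$value < 0)) return("contact values must be >= 0")
        if (anyDuplicated(tr[, c("i", "j")])) return("duplicate (i, j) keys")
        n <- length(object@anchors)
        if (any(tr$i < 1L) || any(tr$j > n))
            return("triplet indices outside the axis")
    }
    if (!object@state %in% c("raw", "balanced", "joint"))
        return("state must be raw/balanced/joint")
    TRUE
})

#' DecayModel: global power-law contact decay
#'
#' @slot exponent scaling exponent alpha (contact ~ d^-alpha).
#' @slot intercept log-intercept of the fitted line.
#' @slot dRange fitted distance range (bp), c(d_min, d_max).
#' @slot binTable per-distance-bin diagnostics (mean contact per possible
#'   pair, representative distance, pair counts).
#'
#' @export
setClass("DecayModel", slots = c(
    exponent  = "numeric",
    intercept = "numeric",
    dRange    = "numeric",
    binTable  = "data.frame"
))

setValidity("DecayModel", function(object) {
    if (!is.finite(object@exponent)) return("exponent must be finite")
    if (object@dRange[1] >= object@dRange[2]) return("d_min must be < d_max")
    TRUE
})

#' GammaTrack: per-fragment distance-scaling factors
#'
#' gamma_i is the negative log-log slope of fragment i's bias-corrected
#' contact decay; high gamma marks fragments that chromatin contacts find
#' hard to cross.  Fragments with too few informative distance bins are
#' undefined (masked, never zero-filled).
#'
#' @slot fragments GRanges with metadata columns `gamma`, `n_bins`,
#'   `contacts`, `defined`.
#' @slot params list of the fit parameters used.
#'
#' @export
setClass("GammaTrack", slots = c(fragments = "GRanges", params = "list"))

setValidity("GammaTrack", function(object) {
    mc <- mcols(object@fragments)
    need <- c("gamma", "n_bins", "contacts", "defined")
    if (!all(need %in% names(mc)))
        return("fragments need gamma, n_bins, contacts, defined columns")
    if (any(!is.na(mc$gamma[!mc$defined])))
        return("undefined fragments must carry NA gamma, never a value")
    TRUE
})

#' BorderSet: TAD borders called from a gamma track
#'
#' @slot borders GRanges of non-overlapping border intervals with a
#'   `score` column holding the peak gamma.
#' @slot replicate replicate identifier.
#'
#' @export
setClass("BorderSet", slots = c(borders = "GRanges", replicate = "character"))

#' CobindingCatalog: insulator-protein cobinding classes
#'
#' Regions labelled by which insulator proteins co-occupy them, using the
#' ordered single-letter alphabet M (Mod(mdg4)), C (Cp190), I (Ibf1),
#' F (CTCF), S (Su(Hw)).
#'
#' @slot regions GRanges with metadata columns `class`, `excluded` and
#'   `merged` (TRUE when one peak bridged two previously separate groups).
#' @slot proteins the ordered class alphabet.
#'
#' @export
setClass("CobindingCatalog",
         slots = c(regions = "GRanges", proteins = "character"))

setValidity("CobindingCatalog", function(object) {
    cls <- object@regions$class
    if (is.null(cls) || any(is.na(cls)) || any(!nzchar(cls)))
        return("every region needs one non-empty class label")
    ok <- vapply(strsplit(cls, ""), function(x) {
        pos <- match(x, object@proteins)
        !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
    }, logical(1))
    if (!all(ok)) return("class letters must be ordered over the alphabet")
    TRUE
})

#' SyntheticSpec: parameters of the synthetic Hi-C experiment
#'
#' @slot nChrom number of chromosomes.
#' @slot chromLength chromosome length (bp).
#' @slot meanFragment mean restriction-fragment length (bp).
#' @slot alpha power-law decay exponent.
#' @slot biasSd log-sd of the lognormal per-fragment biases.
#' @slot depth expected total contacts per chromosome.
#' @slot d0 reference distance (bp) of the decay law.
#' @slot maxDist maximal simulated pair distance (bp); contacts beyond it
#'   have negligible expectation and are not drawn.
#' @slot boundaries data.frame(chrom, pos, beta, label) of implanted
#'   boundaries; beta in (0, 1] is the per-crossing attenuation and label
#'   in Cp190/CTCF/both/none states which knockout inactivates it.
#' @slot loops data.frame(chrom, pos1, pos2, lambda) of implanted loop
#'   anchor pairs (lambda >= 1).
#'
#' @export
setClass("SyntheticSpec", slots = c(
    nChrom       = "integer",
    chromLength  = "numeric",
    meanFragment = "numeric",
    alpha        = "numeric",
    biasSd       = "numeric",
    depth        = "numeric",
    d0           = "numeric",
    maxDist      = "numeric",
    boundaries   = "data.frame",
    loops        = "data.frame"
))

setValidity("SyntheticSpec", function(object) {
    b <- object@boundaries
    if (nrow(b)) {
        if (any(b$beta <= 0 | b$beta > 1)) return("beta must be in (0, 1]")
        if (!all(b$label %in% c("Cp190", "CTCF", "both", "none")))
            return("boundary labels must be Cp190/CTCF/both/none")
        if (any(b$pos < 1 | b$pos > object@chromLength))
            return("boundary positions outside chromosome")
        o <- order(b$chrom, b$pos)
        if (!identical(o, seq_len(nrow(b))))
            return("boundaries must be sorted by (chrom, pos)")
    }
    if (nrow(object@loops) && any(object@loops$lambda < 1))
        return("loop strength lambda must be >= 1")
    if (object@depth <= 0) return("depth must be positive")
    if (object@chromLength < 10 * object@meanFragment)
        return("chromosome shorter than 10 mean fragment lengths")
    TRUE
})

#' TruthSet: ground truth of a synthetic experiment
#'
#' @slot boundaries implanted boundaries (chrom, pos, beta, label, active).
#' @slot loops implanted loop pairs.
#' @slot biases the per-fragment multiplicative biases used.
#' @slot peakClasses data.frame(chrom, pos, class, kind) of synthetic
#'   cobinding sites (boundaries and decoys).
#'
#' @export
setClass("TruthSet", slots = c(
    boundaries  = "data.frame",
    loops       = "data.frame",
    biases      = "numeric",
    peakClasses = "data.frame"
))

#' ScreenResult: outcome of the delta-gamma insulator screen
#'
#' @slot classStats per class, per knockout: counts, Fisher p, significance.
#' @slot thresholds named list (per knockout) of empirical FDR thresholds at
#'   5/10/15 percent.
#' @slot regions per-region table: class, delta-gamma per knockout, FDR
#'   level at which the region is called, dependence label.
#' @slot params screen parameters.
#'
#' @export
setClass("ScreenResult", slots = c(
    classStats = "data.frame",
    thresholds = "list",
    regions    = "data.frame",
    params     = "list"
))

#' CrossingCurve: contact-crossing difference curve
#'
#' Mean mutant-minus-control contact difference between symmetric bin pairs
#' flanking candidate insulators, per offset; positive values mean the
#' mutant crosses the regions more freely (insulation lost).
#'
#' @slot offsets offsets in bins (1..K).
#' @slot mean mean difference per offset across regions.
#' @slot se standard error per offset.
#' @slot n number of regions contributing per offset.
#' @slot perRegion regions x offsets matrix of differences (NA where an
#'   offset falls outside the chromosome).
#' @slot binsize bin size in bp.
#' @slot lowConfidence logical flag per offset (close-range estimates are
#'   less reliable and flagged, not removed).
#'
#' @export
setClass("CrossingCurve", slots = c(
    offsets       = "integer",
    mean          = "numeric",
    se            = "numeric",
    n             = "integer",
    perRegion     = "matrix",
    binsize       = "numeric",
    lowConfidence = "logical"
))
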