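#' @include AllClasses.R
NULL

#' Accessors for insuscreen classes
#'
#' Small accessor family: slot access stays behind functions.
#'
#' @param x An object.
#' @param ... Unused.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x, ...) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("anchors", function(x, ...) standardGeneric("anchors"))

#' @rdname accessors
#' @export
setGeneric("triplets", function(x, ...) standardGeneric("triplets"))

#' @rdname accessors
#' @export
setGeneric("contactState", function(x) standardGeneric("contactState"))

#' @rdname accessors
#' @export
setGeneric("biases", function(x) standardGeneric("biases"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("maskedAnchors", function(x) standardGeneric("maskedAnchors"))

#' @rdname accessors
#' @export
setGeneric("gammaValues", function(x) standardGeneric("gammaValues"))

#' @rdname accessors
#' @export
setGeneric("borders", function(x) standardGeneric("borders"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x, ...) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x, ...) standardGeneric("classCounts"))

#' @rdname accessors
#' @export
setGeneric("truthBoundaries", function(x) standardGeneric("truthBoundaries"))

#' @rdname accessors
#' @export
setGeneric("truthLoops", function(x) standardGeneric("truthLoops"))

#' @rdname accessors
#' @export
setGeneric("decayExponent", function(x) standardGeneric("decayExponent"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("fragments", "FragmentMap", function(x, ...) x@fragments)

#' @rdname accessors
#' @export
setMethod("fragments", "GammaTrack", function(x, ...) x@fragments)

#' @rdname accessors
#' @export
setMethod("anchors", "ContactMatrix", function(x, ...) x@anchors)

#' @rdname accessors
#' @export
setMethod("triplets", "ContactMatrix", function(x, ...) x@triplets)

#' @rdname accessors
#' @export
setMethod("contactState", "ContactMatrix", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("biases", "ContactMatrix", function(x) x@biases)

#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binsize)

#' @rdname accessors
#' @export
setMethod("maskedAnchors", "ContactMatrix", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("gammaValues", "GammaTrack", function(x) x@fragments$gamma)

#' @rdname accessors
#' @export
setMethod("borders", "BorderSet", function(x) x@borders)

#' @rdname accessors
#' @export
setMethod("regions", "CobindingCatalog", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("regions", "ScreenResult", function(x, ...) x@regions)

#' @rdname accessors
#' @export
setMethod("classLabels", "CobindingCatalog", function(x) x@regions$class)

#' @rdname accessors
#' @export
setMethod("classCounts", "CobindingCatalog", function(x, ...) {
    tab <- table(x@regions$class)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    sort(cnt, decreasing = TRUE)
})

#' @rdname accessors
#' @export
setMethod("truthBoundaries", "TruthSet", function(x) x@boundaries)

#' @rdname accessors
#' @export
setMethod("truthLoops", "TruthSet", function(x) x@loops)

#' @rdname accessors
#' @export
setMethod("decayExponent", "DecayModel", function(x) x@exponent)

## ---- show ----------------------------------------------------------------

setMethod("show", "FragmentMap", function(object) {
    gr <- object@fragments
    cat(sprintf("FragmentMap: %d fragments on %d chromosome(s), mean length %.0f bp\n",
                length(gr), length(unique(as.character(seqnames(gr)))),
                mean(width(gr))))
})

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix: %d axis elements (%s), %d non-zero pairs, state=%s\n",
                length(object@anchors),
                if (is.na(object@binsize)) "fragment axis"
                else sprintf("%g-bp bins", object@binsize),
                nrow(object@triplets), object@state))
    if (length(object@mask))
        cat(sprintf("  %d masked axis elements\n", length(object@mask)))
})

setMethod("show", "DecayModel", function(object) {
    cat(sprintf("DecayModel: alpha = %.4f over [%g, %g] bp (%d bins)\n",
                object@exponent, object@dRange[1], object@dRange[2],
                nrow(object@binTable)))
})

setMethod("show", "GammaTrack", function(object) {
    d <- object@fragments$defined
    cat(sprintf("GammaTrack: %d fragments, %d defined (%.1f%%); gamma median %.3f\n",
                length(d), sum(d), 100 * mean(d),
                stats::median(object@fragments$gamma[d])))
})

setMethod("show", "BorderSet", function(object) {
    cat(sprintf("BorderSet [%s]: %d borders\n", object@replicate,
                length(object@borders)))
})

setMethod("show", "CobindingCatalog", function(object) {
    cat(sprintf("CobindingCatalog: %d regions, %d classes (alphabet %s)\n",
                length(object@regions),
                length(unique(object@regions$class)),
                paste(object@proteins, collapse = "")))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d chrom x %g bp, mean fragment %g bp, ",
                       "alpha=%g, bias sd=%g, depth=%g/chrom\n"),
                object@nChrom, object@chromLength, object@meanFragment,
                object@alpha, object@biasSd, object@depth))
    cat(sprintf("  %d boundaries, %d loops\n",
                nrow(object@boundaries), nrow(object@loops)))
})

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet: %d boundaries, %d loops, %d labelled peak sites\n",
                nrow(object@boundaries), nrow(object@loops),
                nrow(object@peakClasses)))
})

setMethod("show", "ScreenResult", function(object) {
    cat(sprintf("ScreenResult: %d regions, %d classes\n",
                nrow(object@regions), nrow(object@classStats) / 2))
    called <- object@regions$called_at != "none"
    cat(sprintf("  %d regions called (dependence: %s)\n", sum(called),
                paste(names(table(object@regions$dependence[called])),
                      table(object@regions$dependence[called]),
                      sep = "=", collapse = ", ")))
})

setMethod("show", "CrossingCurve", function(object) {
    cat(sprintf("CrossingCurve: %d offsets x %g bp bins, %d regions\n",
                length(object@offsets), object@binsize, nrow(object@perRegion)))
})
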