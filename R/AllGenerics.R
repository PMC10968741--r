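#' @include AllClasses.R
NULL

#' Accessors for scheme and signal containers
#'
#' \code{bValues} returns the unique b-values of a scheme; \code{bVector}
#' the expanded measurement b-vector (ascending, repeats contiguous);
#' \code{nMeasurements} its length. \code{signalValues} returns the
#' realization matrix of a \linkS4class{SignalSet} and \code{provenance}
#' its provenance tag.
#'
#' @param object An \linkS4class{AcquisitionScheme}, \linkS4class{SignalSet}
#'   or \linkS4class{DWIVolume}.
#' @return See individual descriptions.
#' @name scheme-accessors
#' @examples
#' sch <- defaultScheme()
#' nMeasurements(sch)   # 35
#' head(bVector(sch))
NULL

#' @rdname scheme-accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname scheme-accessors
#' @export
setGeneric("bVector", function(object) standardGeneric("bVector"))

#' @rdname scheme-accessors
#' @export
setGeneric("nMeasurements", function(object) standardGeneric("nMeasurements"))

#' @rdname scheme-accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname scheme-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Accessors for IVIM parameter objects
#'
#' Extract individual parameters or the full named vector
#' \code{c(s0, f, dstar, d)} from an \linkS4class{IVIMParams} or a
#' \linkS4class{FitResult}.
#'
#' @param object An \linkS4class{IVIMParams} or \linkS4class{FitResult}.
#' @return A single numeric, or a named length-4 numeric for
#'   \code{paramVector}.
#' @name param-accessors
#' @examples
#' p <- IVIMParams(1, 0.12, 0.01, 0.001)
#' perfusionFraction(p)
#' paramVector(p)
NULL

#' @rdname param-accessors
#' @export
setGeneric("s0", function(object) standardGeneric("s0"))

#' @rdname param-accessors
#' @export
setGeneric("perfusionFraction",
           function(object) standardGeneric("perfusionFraction"))

#' @rdname param-accessors
#' @export
setGeneric("pseudoDiffusion",
           function(object) standardGeneric("pseudoDiffusion"))

#' @rdname param-accessors
#' @export
setGeneric("diffusion", function(object) standardGeneric("diffusion"))

#' @rdname param-accessors
#' @export
setGeneric("paramVector", function(object) standardGeneric("paramVector"))
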