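#' @include scheme.R
NULL

#' Construct IVIM parameters
#'
#' @param s0 Baseline signal intensity (> 0).
#' @param f Perfusion fraction in [0, 1].
#' @param dstar Pseudo-diffusion coefficient, mm^2/s (>= 0).
#' @param d Diffusion coefficient, mm^2/s (>= 0).
#' @return An \linkS4class{IVIMParams} object.
#' @examples
#' IVIMParams(1, 0.12, 0.01, 0.001)
#' @export
IVIMParams <- function(s0, f, dstar, d) {
    new("IVIMParams", s0 = as.numeric(s0), f = as.numeric(f),
        dstar = as.numeric(dstar), d = as.numeric(d))
}

#' @rdname param-accessors
#' @export
setMethod("s0", "IVIMParams", function(object) object@s0)

#' @rdname param-accessors
#' @export
setMethod("perfusionFraction", "IVIMParams", function(object) object@f)

#' @rdname param-accessors
#' @export
setMethod("pseudoDiffusion", "IVIMParams", function(object) object@dstar)

#' @rdname param-accessors
#' @export
setMethod("diffusion", "IVIMParams", function(object) object@d)

#' @rdname param-accessors
#' @export
setMethod("paramVector", "IVIMParams", function(object)
    c(s0 = object@s0, f = object@f, dstar = object@dstar, d = object@d))

setMethod("show", "IVIMParams", function(object) {
    cat(sprintf("IVIMParams: S0 = %g, f = %g, D* = %g mm^2/s, D = %g mm^2/s\n",
                object@s0, object@f, object@dstar, object@d))
    invisible(NULL)
})

.asB <- function(scheme) {
    if (is(scheme, "AcquisitionScheme")) bVector(scheme)
    else as.numeric(scheme)
}

#' Bi-exponential IVIM forward model
#'
#' Evaluates
#' \deqn{S(b) = S_0 (f e^{-D^* b} + (1 - f) e^{-D b})}
#' for every measurement of a scheme (or a raw b-vector). Repeated
#' measurements of the same b-value are identical; the output follows the
#' scheme's canonical ordering.
#'
#' @param params \linkS4class{IVIMParams}.
#' @param scheme \linkS4class{AcquisitionScheme} or numeric b-vector
#'   (s/mm^2).
#' @return Numeric signal vector, one element per measurement.
#' @examples
#' ivimSignal(IVIMParams(1, 0.1, 0.012, 0.001), c(0, 200))
#' @export
ivimSignal <- function(params, scheme) {
    stopifnot(is(params, "IVIMParams"))
    validObject(params)
    b <- .asB(scheme)
    params@s0 * (params@f * exp(-params@dstar * b) +
                 (1 - params@f) * exp(-params@d * b))
}

#' Mono-exponential decay model
#'
#' The single-compartment model \eqn{s_0 e^{-D b}} used by both stages of
#' the segmented estimators.
#'
#' @param s0Component Amplitude (>= 0).
#' @param dCoeff Decay coefficient, mm^2/s (>= 0).
#' @param scheme \linkS4class{AcquisitionScheme} or numeric b-vector.
#' @return Numeric signal vector.
#' @examples
#' monoexpSignal(2, 0.001, 1000)  # 2 * exp(-1)
#' @export
monoexpSignal <- function(s0Component, dCoeff, scheme) {
    if (!is.numeric(s0Component) || length(s0Component) != 1L ||
        s0Component < 0)
        stop("'s0Component' must be a single non-negative number")
    if (!is.numeric(dCoeff) || length(dCoeff) != 1L || dCoeff < 0)
        stop("'dCoeff' must be a single non-negative number")
    s0Component * exp(-dCoeff * .asB(scheme))
}
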