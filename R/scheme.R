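#' @include AllGenerics.R
NULL

#' Construct an acquisition scheme
#'
#' Builds an \linkS4class{AcquisitionScheme} from b-values and repetition
#' counts. Entries are sorted into the canonical order (ascending b,
#' repeats contiguous) regardless of input order.
#'
#' @param bvalues Numeric vector of unique non-negative b-values (s/mm^2).
#' @param repeats Positive integer repetition count, recycled to
#'   \code{length(bvalues)}.
#' @return An \linkS4class{AcquisitionScheme}.
#' @examples
#' AcquisitionScheme(c(0, 10, 1000), c(5, 3, 3))
#' @export
AcquisitionScheme <- function(bvalues, repeats = 1L) {
    repeats <- as.integer(rep_len(repeats, length(bvalues)))
    ord <- order(bvalues)
    new("AcquisitionScheme", bvalues = as.numeric(bvalues[ord]),
        repeats = repeats[ord])
}

#' The default 35-measurement whole-brain IVIM scheme
#'
#' Five b = 0 measurements plus ten nonzero b-values
#' (10, 20, 50, 80, 120, 200, 500, 700, 1000, 1200 s/mm^2), each measured
#' in three orthogonal directions. The model is isotropic, so directions
#' are represented as three identically distributed repeats per nonzero b.
#'
#' @return An \linkS4class{AcquisitionScheme} with 35 measurements.
#' @examples
#' nMeasurements(defaultScheme())  # 35
#' @export
defaultScheme <- function() {
    AcquisitionScheme(c(0, 10, 20, 50, 80, 120, 200, 500, 700, 1000, 1200),
                      c(5L, rep(3L, 10L)))
}

#' @rdname scheme-accessors
#' @export
setMethod("bValues", "AcquisitionScheme", function(object) object@bvalues)

#' @rdname scheme-accessors
#' @export
setMethod("bVector", "AcquisitionScheme",
          function(object) rep(object@bvalues, object@repeats))

#' @rdname scheme-accessors
#' @export
setMethod("nMeasurements", "AcquisitionScheme",
          function(object) sum(object@repeats))

setMethod("show", "AcquisitionScheme", function(object) {
    cat(sprintf("AcquisitionScheme: %d measurements, %d shells (max b = %g s/mm^2)\n",
                nMeasurements(object), length(object@bvalues),
                max(object@bvalues)))
    cat("  b:      ", paste(format(object@bvalues), collapse = " "), "\n")
    cat("  repeats:", paste(format(object@repeats,
                                   width = nchar(format(object@bvalues))),
                            collapse = " "), "\n")
    invisible(NULL)
})
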