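#' @include ivim-model.R
NULL

#' Gaussian channel noise level for a target b0 SNR
#'
#' Maps a reference b0 intensity and a target SNR to the standard
#' deviation of the real and imaginary Gaussian noise channels:
#' \code{sigma = s0Reference / snr}. At high SNR the magnitude signal then
#' has mean/sd ratio approximately equal to \code{snr} at b = 0.
#'
#' @param s0Reference Reference b0 intensity (> 0).
#' @param snr Target SNR (> 0).
#' @return The channel standard deviation.
#' @examples
#' sigmaForSNR(1, 20)  # 0.05
#' @export
sigmaForSNR <- function(s0Reference, snr) {
    if (!is.numeric(s0Reference) || length(s0Reference) != 1L ||
        s0Reference <= 0)
        stop("'s0Reference' must be a single positive number")
    if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
        stop("'snr' must be a single positive number")
    s0Reference / snr
}

#' Construct a noise specification
#'
#' @param snr Target b0 SNR.
#' @param s0Reference Reference b0 intensity the SNR refers to (the ground
#'   truth S0 in simulations).
#' @param seed Integer seed, or NA to draw from the current RNG stream.
#' @return A \linkS4class{NoiseSpec}.
#' @examples
#' noiseSpec(20, seed = 1)
#' @export
noiseSpec <- function(snr, s0Reference = 1, seed = NA_integer_) {
    new("NoiseSpec", snr = as.numeric(snr),
        sigma = sigmaForSNR(s0Reference, snr), seed = as.integer(seed))
}

#' Construct a signal set
#'
#' @param values Numeric matrix (realizations x measurements) or a vector
#'   interpreted as a single realization.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param provenance \code{"noiseless"}, \code{"noised"} or
#'   \code{"averaged"}.
#' @return A \linkS4class{SignalSet}.
#' @export
signalSet <- function(values, scheme, provenance = "noiseless") {
    if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
    new("SignalSet", values = values, scheme = scheme,
        provenance = provenance)
}

#' Replicate a noiseless model signal into a signal set
#'
#' @param params \linkS4class{IVIMParams} ground truth.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param n Number of identical rows.
#' @return A noiseless \linkS4class{SignalSet} with \code{n} rows.
#' @examples
#' cleanSignalSet(IVIMParams(1, 0.12, 0.01, 0.001), defaultScheme(), 4)
#' @export
cleanSignalSet <- function(params, scheme, n = 1L) {
    s <- ivimSignal(params, scheme)
    signalSet(matrix(s, nrow = n, ncol = length(s), byrow = TRUE), scheme,
              "noiseless")
}

#' @rdname scheme-accessors
#' @export
setMethod("signalValues", "SignalSet", function(object) object@values)

#' @rdname scheme-accessors
#' @export
setMethod("provenance", "SignalSet", function(object) object@provenance)

#' @rdname scheme-accessors
#' @export
setMethod("nMeasurements", "SignalSet",
          function(object) ncol(object@values))

setMethod("show", "SignalSet", function(object) {
    cat(sprintf("SignalSet: %d realization(s) x %d measurements [%s]\n",
                nrow(object@values), ncol(object@values),
                object@provenance))
    invisible(NULL)
})

## Rician magnitude of a clean value matrix: sqrt((S + Nr)^2 + Ni^2),
## Nr, Ni iid N(0, sigma). Draws Nr first, then Ni, column-major, so the
## realization stream is reproducible for a fixed matrix shape.
.ricianize <- function(values, sigma) {
    n <- length(values)
    nr <- matrix(stats::rnorm(n, 0, sigma), nrow(values), ncol(values))
    ni <- matrix(stats::rnorm(n, 0, sigma), nrow(values), ncol(values))
    sqrt((values + nr)^2 + ni^2)
}

#' Add Rician noise to a noiseless signal set
#'
#' Replaces every element S by the magnitude
#' \eqn{\sqrt{(S + N_r)^2 + N_i^2}} with independent zero-mean Gaussian
#' \eqn{N_r, N_i} of standard deviation \code{sigma(spec)}. Deterministic
#' given the spec's seed.
#'
#' @param clean A noiseless \linkS4class{SignalSet}.
#' @param spec A \linkS4class{NoiseSpec}.
#' @return A \linkS4class{SignalSet} with provenance \code{"noised"}.
#' @examples
#' cs <- cleanSignalSet(IVIMParams(1, 0.12, 0.01, 0.001), defaultScheme(), 10)
#' addRicianNoise(cs, noiseSpec(20, seed = 1))
#' @export
addRicianNoise <- function(clean, spec) {
    stopifnot(is(clean, "SignalSet"), is(spec, "NoiseSpec"))
    validObject(spec)
    if (clean@provenance != "noiseless")
        stop("'clean' must have provenance 'noiseless'")
    if (!is.na(spec@seed)) set.seed(spec@seed)
    signalSet(.ricianize(clean@values, spec@sigma), clean@scheme, "noised")
}

#' Average disjoint groups of realizations
#'
#' Emulates voxel clustering: consecutive disjoint groups of
#' \code{groupSize} rows are replaced by their column-wise arithmetic
#' mean, reducing the row count by the group size (e.g. 8 = 2x2x2,
#' 27 = 3x3x3, 64 = 4x4x4 neighbourhoods).
#'
#' @param noised A \linkS4class{SignalSet}.
#' @param groupSize Integer >= 2 dividing the number of rows.
#' @return A \linkS4class{SignalSet} with provenance \code{"averaged"}.
#' @examples
#' cs <- cleanSignalSet(IVIMParams(1, 0.12, 0.01, 0.001), defaultScheme(), 16)
#' ns <- addRicianNoise(cs, noiseSpec(20, seed = 1))
#' averageRealizations(ns, 8)
#' @export
averageRealizations <- function(noised, groupSize) {
    stopifnot(is(noised, "SignalSet"))
    groupSize <- as.integer(groupSize)
    if (length(groupSize) != 1L || groupSize < 2L)
        stop("'groupSize' must be a single integer >= 2")
    n <- nrow(noised@values)
    if (n %% groupSize != 0L)
        stop(sprintf(
            "number of realizations (%d) is not divisible by groupSize (%d); choose a compatible realization count",
            n, groupSize))
    g <- rep(seq_len(n %/% groupSize), each = groupSize)
    avg <- rowsum(noised@values, g, reorder = FALSE) / groupSize
    dimnames(avg) <- NULL
    signalSet(avg, noised@scheme, "averaged")
}
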