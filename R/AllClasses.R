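#' @import methods
NULL

## Central S4 classes. Validity methods enforce the physical constraints the
## rest of the package relies on; accessors live next to the class they serve.

#' IVIM model parameters
#'
#' The four-parameter tuple of the bi-exponential intravoxel incoherent
#' motion (IVIM) model: baseline signal \eqn{S_0}, perfusion fraction
#' \eqn{f}, pseudo-diffusion coefficient \eqn{D^*} and tissue diffusion
#' coefficient \eqn{D}. Used both as simulation ground truth and as the
#' parameter set of a fit result.
#'
#' @slot s0 Baseline signal intensity at b = 0 (unitless, > 0).
#' @slot f Perfusion fraction in [0, 1] (unitless).
#' @slot dstar Pseudo-diffusion coefficient in mm^2/s (>= 0).
#' @slot d Diffusion coefficient in mm^2/s (>= 0).
#'
#' @details \code{dstar} is typically an order of magnitude larger than
#' \code{d} in perfused tissue; the class does not enforce
#' \code{dstar > d} because fitted estimates may legitimately violate it.
#'
#' @examples
#' IVIMParams(s0 = 1, f = 0.12, dstar = 0.01, d = 0.001)
#' @export
setClass("IVIMParams",
    representation(s0 = "numeric", f = "numeric", dstar = "numeric",
                   d = "numeric"),
    validity = function(object) {
        for (sl in c("s0", "f", "dstar", "d")) {
            v <- slot(object, sl)
            if (length(v) != 1L || !is.finite(v))
                return(sprintf("'%s' must be a single finite number", sl))
        }
        if (object@s0 <= 0) return("'s0' must be positive")
        if (object@f < 0 || object@f > 1) return("'f' must lie in [0, 1]")
        if (object@dstar < 0) return("'dstar' must be non-negative")
        if (object@d < 0) return("'d' must be non-negative")
        TRUE
    })

#' Diffusion-weighting acquisition scheme
#'
#' An ordered list of b-values with repetition counts describing one
#' measurement vector. The canonical ordering is ascending b with repeats
#' contiguous; all signal vectors and 4D volumes in the package follow it.
#'
#' @slot bvalues Strictly increasing unique b-values in s/mm^2 (>= 0).
#' @slot repeats Positive integer repetition count per b-value.
#' @export
setClass("AcquisitionScheme",
    representation(bvalues = "numeric", repeats = "integer"),
    validity = function(object) {
        b <- object@bvalues; r <- object@repeats
        if (length(b) == 0L) return("scheme must contain at least one b-value")
        if (length(b) != length(r))
            return("'bvalues' and 'repeats' lengths differ")
        if (any(!is.finite(b)) || any(b < 0))
            return("b-values must be finite and non-negative")
        if (is.unsorted(b, strictly = TRUE))
            return("b-values must be unique and ascending")
        if (any(r < 1L)) return("repeats must be positive integers")
        if (!any(b == 0)) return("scheme must contain a b = 0 entry")
        ## b0-only schemes are allowed (repeated-b0 SNR fixtures); any
        ## diffusion-weighted scheme needs >= 2 shells for segmented fitting
        if (sum(b > 0) == 1L)
            return("scheme must contain at least two distinct nonzero b-values (or none)")
        TRUE
    })

#' Matrix of signal realizations
#'
#' Rows are realizations (simulated voxels), columns are the measurements of
#' an \linkS4class{AcquisitionScheme} in canonical order. Provenance records
#' whether the values are noiseless model evaluations, Rician-noised
#' magnitudes, or averages of noised realizations.
#'
#' @slot values Numeric matrix, n_realizations x total measurements.
#' @slot scheme The \linkS4class{AcquisitionScheme} the columns follow.
#' @slot provenance One of \code{"noiseless"}, \code{"noised"},
#'   \code{"averaged"}.
#' @export
setClass("SignalSet",
    representation(values = "matrix", scheme = "AcquisitionScheme",
                   provenance = "character"),
    validity = function(object) {
        if (!is.numeric(object@values)) return("'values' must be numeric")
        if (ncol(object@values) != nMeasurements(object@scheme))
            return(sprintf("column count (%d) must equal scheme measurements (%d)",
                           ncol(object@values), nMeasurements(object@scheme)))
        if (!object@provenance %in% c("noiseless", "noised", "averaged"))
            return("provenance must be 'noiseless', 'noised' or 'averaged'")
        if (object@provenance %in% c("noised", "averaged") &&
            any(object@values < 0))
            return("magnitude (noised/averaged) signals must be non-negative")
        TRUE
    })

#' Rician noise specification
#'
#' Target b0 signal-to-noise ratio and the Gaussian component standard
#' deviation applied to the real and imaginary channels, with
#' \code{sigma = s0_reference / snr}.
#'
#' @slot snr Target SNR at b = 0 (> 0).
#' @slot sigma Standard deviation of each Gaussian noise channel (> 0).
#' @slot seed Integer random seed (NA for "leave the RNG stream alone").
#' @export
setClass("NoiseSpec",
    representation(snr = "numeric", sigma = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@snr <= 0) return("'snr' must be positive")
        ## sigma = 0 (snr = Inf) is the exact zero-noise limit
        if (object@sigma < 0) return("'sigma' must be non-negative")
        TRUE
    })

#' Candidate grids for the segmented grid-search estimator
#'
#' Each slot is a strictly increasing vector of candidate values. Stage 1
#' searches \code{s0SlowGrid} x \code{dGrid} on the high-b measurements;
#' stage 2 searches \code{s0FastGrid} x \code{dStarGrid} on the low-b
#' residual. Overlap of the \code{d} and \code{dstar} grids is permitted.
#'
#' @slot s0SlowGrid,dGrid,s0FastGrid,dStarGrid Numeric candidate grids.
#' @export
setClass("GridSpec",
    representation(s0SlowGrid = "numeric", dGrid = "numeric",
                   s0FastGrid = "numeric", dStarGrid = "numeric"),
    validity = function(object) {
        for (sl in c("s0SlowGrid", "dGrid", "s0FastGrid", "dStarGrid")) {
            g <- slot(object, sl)
            if (length(g) < 2L)
                return(sprintf("'%s' must contain at least 2 values", sl))
            if (any(!is.finite(g)) || is.unsorted(g, strictly = TRUE))
                return(sprintf("'%s' must be finite and strictly increasing", sl))
        }
        TRUE
    })

#' Box constraints and initial values for the curve-fit estimators
#'
#' Lower/upper bounds and initial values for each of \code{s0}, \code{f},
#' \code{dstar}, \code{d}, used by the bounded Levenberg-Marquardt fits.
#' The \code{s0} bounds also constrain the per-stage amplitudes of the
#' segmented curve fit (the stage-2 amplitude lower bound is 0).
#'
#' @slot lower,upper,init Named numeric vectors with elements
#'   \code{s0, f, dstar, d}.
#' @export
setClass("FitBounds",
    representation(lower = "numeric", upper = "numeric", init = "numeric"),
    validity = function(object) {
        nm <- c("s0", "f", "dstar", "d")
        for (sl in c("lower", "upper", "init")) {
            v <- slot(object, sl)
            if (!identical(names(v), nm))
                return(sprintf("'%s' must be named %s", sl,
                               paste(nm, collapse = ", ")))
        }
        if (any(object@lower >= object@upper))
            return("each lower bound must be below its upper bound")
        if (any(object@init < object@lower | object@init > object@upper))
            return("initial values must lie within the bounds")
        TRUE
    })

#' Result of a single IVIM fit
#'
#' @slot params Estimated \linkS4class{IVIMParams}.
#' @slot method One of \code{"grid_search"}, \code{"segmented"},
#'   \code{"one_step"}.
#' @slot converged Logical optimizer status (grid search is always TRUE).
#' @slot boundary Named logical, TRUE where the estimate sits on a grid
#'   endpoint or fit bound.
#' @slot sse Sum of squared residuals of the composed model over all
#'   measurements.
#' @export
setClass("FitResult",
    representation(params = "IVIMParams", method = "character",
                   converged = "logical", boundary = "logical",
                   sse = "numeric"),
    validity = function(object) {
        if (!object@method %in% c("grid_search", "segmented", "one_step"))
            return("unknown method tag")
        if (!identical(names(object@boundary), c("s0", "f", "dstar", "d")))
            return("'boundary' must be named s0, f, dstar, d")
        if (object@sse < 0) return("'sse' must be non-negative")
        TRUE
    })

#' Monte-Carlo study configuration
#'
#' Everything needed to run the simulation study: ground truth, acquisition
#' scheme, SNR sweep, realization count, voxel-averaging factors, estimator
#' selection and estimator settings. \code{nRealizations} must be divisible
#' by every averaging factor.
#'
#' @slot groundTruth \linkS4class{IVIMParams} used to generate every
#'   realization.
#' @slot scheme \linkS4class{AcquisitionScheme}.
#' @slot snrLevels Numeric vector of SNR levels (> 0).
#' @slot nRealizations Realizations per SNR level.
#' @slot averagingFactors Integer vector; 1 means single-voxel.
#' @slot methods Subset of \code{c("grid_search", "segmented", "one_step")}.
#' @slot seed Master integer seed; per-SNR substreams are derived from it.
#' @slot grids \linkS4class{GridSpec} for the grid search.
#' @slot bounds \linkS4class{FitBounds} for the curve fits.
#' @slot threshold Segmentation b-value threshold in s/mm^2.
#' @export
setClass("SimulationConfig",
    representation(groundTruth = "IVIMParams", scheme = "AcquisitionScheme",
                   snrLevels = "numeric", nRealizations = "integer",
                   averagingFactors = "integer", methods = "character",
                   seed = "integer", grids = "GridSpec", bounds = "FitBounds",
                   threshold = "numeric"),
    validity = function(object) {
        if (any(object@snrLevels <= 0)) return("SNR levels must be positive")
        if (object@nRealizations < 1L)
            return("'nRealizations' must be positive")
        if (any(object@averagingFactors < 1L))
            return("averaging factors must be >= 1")
        bad <- object@averagingFactors[
            object@nRealizations %% object@averagingFactors != 0L]
        if (length(bad))
            return(sprintf(
                "nRealizations (%d) must be divisible by every averaging factor (offending: %s); choose a compatible n",
                object@nRealizations, paste(bad, collapse = ", ")))
        if (!length(object@methods) ||
            !all(object@methods %in% c("grid_search", "segmented", "one_step")))
            return("methods must be a non-empty subset of grid_search, segmented, one_step")
        TRUE
    })

#' 4D diffusion-weighted volume
#'
#' A 4D array (x, y, z, measurement) whose 4th axis follows an
#' \linkS4class{AcquisitionScheme} in canonical order, with a 4x4 affine
#' and an optional brain mask.
#'
#' @slot data 4D numeric array.
#' @slot scheme \linkS4class{AcquisitionScheme} aligned to the 4th axis.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot mask Logical 3D array matching the spatial shape (may be all-TRUE).
#' @export
setClass("DWIVolume",
    representation(data = "array", scheme = "AcquisitionScheme",
                   affine = "matrix", mask = "array"),
    validity = function(object) {
        dm <- dim(object@data)
        if (length(dm) != 4L) return("'data' must be a 4D array")
        if (dm[4L] != nMeasurements(object@scheme))
            return(sprintf("4th-axis length (%d) must equal scheme measurements (%d)",
                           dm[4L], nMeasurements(object@scheme)))
        if (!identical(dim(object@affine), c(4L, 4L)))
            return("'affine' must be a 4x4 matrix")
        if (!is.logical(object@mask) || !identical(dim(object@mask), dm[1:3]))
            return("'mask' must be a logical array matching the spatial shape")
        TRUE
    })

#' Per-voxel SNR map with summary statistics
#'
#' @slot map 3D array of per-voxel SNR (NA where undefined, i.e. zero
#'   b0 variance or outside the mask).
#' @slot average,med,minimum,maximum Summary statistics over defined,
#'   masked voxels.
#' @slot nDefined Number of voxels entering the summaries.
#' @export
setClass("SNRSummary",
    representation(map = "array", average = "numeric", med = "numeric",
                   minimum = "numeric", maximum = "numeric",
                   nDefined = "integer"))

#' Estimate classification report
#'
#' Counts and percentages of voxelwise estimates falling in the
#' physiological ranges, following closed-interval semantics for the
#' perfusion fraction range and half-open semantics for the
#' pseudo-diffusion range.
#'
#' @slot nTotal Voxels classified.
#' @slot nFOutliers Voxels with near-zero perfusion fraction.
#' @slot pctFInRange Percent with f in the closed inclusion interval.
#' @slot pctDstarInRange Percent with D* in the half-open inclusion interval.
#' @slot nBoundaryDstar Voxels whose D* estimate sits on a configured bound.
#' @slot fOutlierThreshold,fRange,dstarRange The thresholds used.
#' @export
setClass("ClassificationReport",
    representation(nTotal = "integer", nFOutliers = "integer",
                   pctFInRange = "numeric", pctDstarInRange = "numeric",
                   nBoundaryDstar = "integer", fOutlierThreshold = "numeric",
                   fRange = "numeric", dstarRange = "numeric"),
    validity = function(object) {
        if (object@pctFInRange < 0 || object@pctFInRange > 100 ||
            object@pctDstarInRange < 0 || object@pctDstarInRange > 100)
            return("percentages must lie in [0, 100]")
        if (object@nFOutliers > object@nTotal ||
            object@nBoundaryDstar > object@nTotal)
            return("counts cannot exceed nTotal")
        TRUE
    })

#' Digital phantom specification
#'
#' Nested-shell phantom (CSF core, grey-matter shell, white-matter
#' exterior) with per-compartment IVIM parameters, generated at a target
#' b0 SNR on a given acquisition scheme.
#'
#' @slot shape Integer 3-vector of spatial dimensions (each <= 64).
#' @slot compartments Named list of \linkS4class{IVIMParams} with elements
#'   \code{csf}, \code{gm}, \code{wm}.
#' @slot snr Target b0 SNR; \code{Inf} disables noise.
#' @slot seed Integer seed.
#' @slot scheme \linkS4class{AcquisitionScheme}.
#' @slot partialVolume Logical; linear mixing at shell interfaces.
#' @export
setClass("PhantomSpec",
    representation(shape = "integer", compartments = "list", snr = "numeric",
                   seed = "integer", scheme = "AcquisitionScheme",
                   partialVolume = "logical"),
    validity = function(object) {
        if (length(object@shape) != 3L || any(object@shape < 4L))
            return("'shape' must be three dimensions, each >= 4")
        if (any(object@shape > 64L))
            return("'shape' dimensions must not exceed 64 (desk-scale phantom)")
        if (!identical(sort(names(object@compartments)),
                       c("csf", "gm", "wm")))
            return("'compartments' must be a named list: csf, gm, wm")
        for (p in object@compartments)
            if (!is(p, "IVIMParams")) return("compartments must be IVIMParams")
        if (object@snr <= 0) return("'snr' must be positive")
        TRUE
    })
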