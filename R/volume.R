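#' @include monte-carlo.R
NULL

#' Construct a 4D DWI volume
#'
#' @param data 4D numeric array (x, y, z, measurement), 4th axis in
#'   canonical scheme order.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param affine 4x4 voxel-to-world transform; the default mirrors a
#'   1 x 1 x 2 mm acquisition.
#' @param mask Logical 3D array, or NULL for all-TRUE.
#' @return A \linkS4class{DWIVolume}.
#' @export
dwiVolume <- function(data, scheme, affine = diag(c(1, 1, 2, 1)),
                      mask = NULL) {
    if (is.null(mask))
        mask <- array(TRUE, dim(data)[1:3])
    new("DWIVolume", data = data, scheme = scheme,
        affine = affine, mask = mask)
}

#' @rdname scheme-accessors
#' @export
setMethod("nMeasurements", "DWIVolume",
          function(object) dim(object@data)[4L])

setMethod("show", "DWIVolume", function(object) {
    dm <- dim(object@data)
    cat(sprintf("DWIVolume: %d x %d x %d x %d (%d masked voxels)\n",
                dm[1L], dm[2L], dm[3L], dm[4L], sum(object@mask)))
    show(object@scheme)
    invisible(NULL)
})

## Flatten the spatial dimensions: voxels x measurements.
.voxelMatrix <- function(volume) {
    dm <- dim(volume@data)
    matrix(volume@data, prod(dm[1:3]), dm[4L])
}

#' Per-voxel SNR map from repeated b0 measurements
#'
#' For each voxel, SNR is the mean of the b = 0 measurements divided by
#' their sample standard deviation (n - 1 denominator by default; with
#' only 5 b0 measurements the denominator choice is material). Voxels
#' with zero b0 variance are undefined (NA) and excluded from the
#' summaries, which are computed over the volume's mask.
#'
#' @param volume \linkS4class{DWIVolume} whose scheme contains at least
#'   two b = 0 measurements.
#' @param denominator \code{"n-1"} (sample sd, default) or \code{"n"}.
#' @return An \linkS4class{SNRSummary}.
#' @examples
#' b0 <- makeB0Series(5, trueSignal = 1, snr = 20, shape = c(8, 8, 8),
#'                    seed = 1)
#' snrMap(b0)
#' @export
snrMap <- function(volume, denominator = c("n-1", "n")) {
    denominator <- match.arg(denominator)
    stopifnot(is(volume, "DWIVolume"))
    b0Idx <- which(bVector(volume@scheme) == 0)
    nb0 <- length(b0Idx)
    if (nb0 < 2L)
        stop("SNR mapping requires at least two b = 0 measurements")
    V <- .voxelMatrix(volume)[, b0Idx, drop = FALSE]
    mu <- rowMeans(V)
    ss <- rowSums((V - mu)^2)
    sd <- sqrt(ss / if (denominator == "n-1") nb0 - 1L else nb0)
    snr <- ifelse(sd > 0, mu / sd, NA_real_)
    map <- array(snr, dim(volume@data)[1:3])
    sel <- volume@mask & !is.na(map)
    vals <- map[sel]
    if (!length(vals)) {
        warning("no voxel has nonzero b0 variance; SNR undefined everywhere")
        return(new("SNRSummary", map = map, average = NA_real_,
                   med = NA_real_, minimum = NA_real_, maximum = NA_real_,
                   nDefined = 0L))
    }
    new("SNRSummary", map = map, average = mean(vals),
        med = stats::median(vals), minimum = min(vals),
        maximum = max(vals), nDefined = length(vals))
}

setMethod("show", "SNRSummary", function(object) {
    cat(sprintf(
        "SNRSummary over %d voxels: average = %.4g, median = %.4g, min = %.4g, max = %.4g\n",
        object@nDefined, object@average, object@med, object@minimum,
        object@maximum))
    invisible(NULL)
})

#' ROI-averaged, per-voxel-normalized signal
#'
#' Each ROI voxel's measurement vector is divided by that voxel's maximum
#' across measurements, then the normalized vectors are averaged across
#' voxels, yielding one signal vector with maximum close to 1. The result
#' is invariant to per-voxel positive rescaling of the input.
#'
#' @param volume \linkS4class{DWIVolume}.
#' @param labels 3D integer label map matching the spatial shape.
#' @param roiId Label value selecting the ROI.
#' @return Numeric vector of length \code{nMeasurements(volume)}.
#' @export
roiAverageSignal <- function(volume, labels, roiId) {
    stopifnot(is(volume, "DWIVolume"))
    if (!identical(dim(labels), dim(volume@data)[1:3]))
        stop("'labels' must match the spatial shape of the volume")
    sel <- as.vector(labels == roiId & volume@mask)
    if (!any(sel))
        stop(sprintf("ROI %s is empty within the mask", format(roiId)))
    V <- .voxelMatrix(volume)[sel, , drop = FALSE]
    mx <- apply(V, 1L, max)
    ok <- mx > 0
    if (!any(ok))
        stop(sprintf("ROI %s contains no voxel with positive signal",
                     format(roiId)))
    if (!all(ok))
        warning(sprintf("dropping %d zero-signal voxel(s) from ROI %s",
                        sum(!ok), format(roiId)))
    colMeans(V[ok, , drop = FALSE] / mx[ok])
}

#' Voxelwise IVIM parameter maps
#'
#' Fits every masked voxel independently with the chosen estimator after
#' per-voxel maximum normalization (each voxel's vector is divided by its
#' maximum, matching the ROI fitting convention). Unmasked voxels carry
#' the NA sentinel. Note the normalized S0 map is in units of the
#' per-voxel maximum, i.e. close to 1 in well-behaved voxels.
#'
#' @param volume \linkS4class{DWIVolume}.
#' @param method Estimator name.
#' @param grids,bounds,threshold Estimator settings.
#' @param normalize Per-voxel maximum normalization (default TRUE).
#' @return Named list of 3D arrays: \code{s0, f, dstar, d, sse},
#'   logical \code{converged} and the four boundary-flag maps.
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(8, 8, 4), snr = Inf))
#' maps <- fitVolume(ph$volume, "grid_search")
#' @export
fitVolume <- function(volume, method = c("grid_search", "segmented",
                                         "one_step"),
                      grids = defaultGridSpec(),
                      bounds = defaultFitBounds(), threshold = 250,
                      normalize = TRUE) {
    method <- match.arg(method)
    stopifnot(is(volume, "DWIVolume"))
    dm <- dim(volume@data)[1:3]
    sel <- as.vector(volume@mask)
    V <- .voxelMatrix(volume)[sel, , drop = FALSE]
    if (normalize && nrow(V)) {
        mx <- apply(V, 1L, max)
        bad <- mx <= 0
        mx[bad] <- 1
        V <- V / mx
    }
    est <- fitSignalSet(signalSet(V, volume@scheme, "noiseless"), method,
                        grids, bounds, threshold)
    blank <- function(proto) array(proto, dm)
    maps <- list(s0 = blank(NA_real_), f = blank(NA_real_),
                 dstar = blank(NA_real_), d = blank(NA_real_),
                 sse = blank(NA_real_), converged = blank(NA),
                 s0Boundary = blank(NA), fBoundary = blank(NA),
                 dstarBoundary = blank(NA), dBoundary = blank(NA))
    for (nm in names(maps))
        maps[[nm]][sel] <- est[[nm]]
    maps
}

#' Classify perfusion-fraction and pseudo-diffusion estimates
#'
#' Counts near-zero perfusion-fraction outliers (f below the outlier
#' threshold), the percentage of f estimates inside the closed inclusion
#' interval, and the percentage of D* estimates inside the half-open
#' inclusion interval [min, max). Optionally counts D* estimates sitting
#' on configured estimation bounds.
#'
#' @param fMap,dstarMap Arrays (or vectors) of estimates with a common
#'   shape.
#' @param mask Optional logical array of the same shape; NA estimates are
#'   always excluded.
#' @param fOutlier Near-zero threshold for f (default 0.02, the lower
#'   edge of the inclusion range).
#' @param fRange Closed inclusion interval for f.
#' @param dstarRange Half-open inclusion interval for D*.
#' @param dstarBounds Optional numeric bounds (e.g. grid endpoints);
#'   estimates within relative tolerance 1e-9 of any of them are counted
#'   as boundary hits.
#' @return A \linkS4class{ClassificationReport}.
#' @examples
#' classifyEstimates(c(0.01, 0.02, 0.25, 0.26),
#'                   c(0.005, 0.006, 0.049, 0.05))
#' @export
classifyEstimates <- function(fMap, dstarMap, mask = NULL,
                              fOutlier = 0.02, fRange = c(0.02, 0.25),
                              dstarRange = c(0.006, 0.05),
                              dstarBounds = NULL) {
    if (!identical(dim(fMap), dim(dstarMap)) ||
        length(fMap) != length(dstarMap))
        stop("'fMap' and 'dstarMap' must share their shape")
    if (is.null(mask)) mask <- rep(TRUE, length(fMap))
    else if (!identical(dim(mask), dim(fMap)) &&
             length(mask) != length(fMap))
        stop("'mask' must share the maps' shape")
    sel <- as.vector(mask) & !is.na(as.vector(fMap)) &
        !is.na(as.vector(dstarMap))
    f <- as.vector(fMap)[sel]
    ds <- as.vector(dstarMap)[sel]
    n <- length(f)
    if (!n) stop("no defined voxels to classify")
    nBnd <- 0L
    if (!is.null(dstarBounds))
        nBnd <- sum(vapply(ds, function(v)
            any(abs(v - dstarBounds) <= 1e-9 * pmax(1, abs(dstarBounds))),
            logical(1L)))
    new("ClassificationReport",
        nTotal = n,
        nFOutliers = sum(f < fOutlier),
        pctFInRange = 100 * mean(f >= fRange[1L] & f <= fRange[2L]),
        pctDstarInRange = 100 * mean(ds >= dstarRange[1L] &
                                     ds < dstarRange[2L]),
        nBoundaryDstar = as.integer(nBnd),
        fOutlierThreshold = fOutlier, fRange = fRange,
        dstarRange = dstarRange)
}

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport over %d estimates:\n", object@nTotal))
    cat(sprintf("  f < %.3g (near-zero outliers): %d (%.2f%%)\n",
                object@fOutlierThreshold, object@nFOutliers,
                100 * object@nFOutliers / object@nTotal))
    cat(sprintf("  f in [%.3g, %.3g]: %.2f%%\n", object@fRange[1L],
                object@fRange[2L], object@pctFInRange))
    cat(sprintf("  D* in [%.3g, %.3g): %.2f%%\n", object@dstarRange[1L],
                object@dstarRange[2L], object@pctDstarInRange))
    cat(sprintf("  D* at estimation bounds: %d\n", object@nBoundaryDstar))
    invisible(NULL)
})
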