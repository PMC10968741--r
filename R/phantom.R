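#' @include volume.R
NULL

#' Specify a digital IVIM phantom
#'
#' Nested-shell geometry: a CSF core, a grey-matter shell and a
#' white-matter exterior inside an ellipsoidal "brain", with background
#' outside. Compartment defaults use literature-scale tissue parameters
#' (all at S0 = 1): GM f = 0.09, D* = 0.0036, D = 0.00065; WM f = 0.16,
#' D* = 0.00517, D = 0.00079. The CSF values (f = 0.05, D* = 0.01,
#' D = 0.003) are conventional placeholders: CSF is dominated by free
#' water and its perfusion parameters are synthetic, not literature fits.
#'
#' @param shape Integer 3-vector of spatial dimensions (<= 64 each).
#' @param compartments Named list of \linkS4class{IVIMParams}
#'   (\code{csf}, \code{gm}, \code{wm}).
#' @param snr Target b0 SNR (default 20); \code{Inf} disables noise.
#' @param seed Integer seed.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param partialVolume Linear mixing of compartment signals at shell
#'   interfaces (off by default; labels stay crisp either way).
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(shape = c(16, 16, 8))
#' @export
phantomSpec <- function(shape = c(32L, 32L, 16L),
                        compartments = list(
                            csf = IVIMParams(1, 0.05, 0.01, 0.003),
                            gm = IVIMParams(1, 0.09, 0.0036, 0.00065),
                            wm = IVIMParams(1, 0.16, 0.00517, 0.00079)),
                        snr = 20, seed = 1L, scheme = defaultScheme(),
                        partialVolume = FALSE) {
    new("PhantomSpec", shape = as.integer(shape),
        compartments = compartments, snr = as.numeric(snr),
        seed = as.integer(seed), scheme = scheme,
        partialVolume = isTRUE(partialVolume))
}

## Normalized ellipsoidal radius per voxel (1 at the brain surface).
.phantomRadius <- function(shape) {
    ax <- lapply(shape, function(n) {
        c0 <- (n + 1) / 2
        ((seq_len(n) - c0) / (0.5 * n * 0.92))^2
    })
    r2 <- outer(outer(ax[[1L]], ax[[2L]], `+`), ax[[3L]], `+`)
    sqrt(r2)
}

## Label codes: 0 background, 1 CSF (core), 2 GM (shell), 3 WM (exterior).
.phantomLabels <- function(r) {
    lab <- array(0L, dim(r))
    lab[r <= 1] <- 3L
    lab[r <= 0.65] <- 2L
    lab[r <= 0.35] <- 1L
    lab
}

#' Generate a synthetic 4D DWI phantom
#'
#' Builds the nested-shell phantom of \code{\link{phantomSpec}}: each
#' voxel's noiseless signal follows the bi-exponential model with its
#' compartment's parameters, and Rician noise is applied at the target
#' b0 SNR. Deterministic given the spec's seed. With \code{outDir} set,
#' writes \code{dwi.nii.gz}, \code{labels.nii.gz}, \code{dwi.bval},
#' \code{dwi.bvec} and a \code{phantom.yaml} spec echo.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param outDir Optional output directory.
#' @return List with \code{volume} (\linkS4class{DWIVolume}, masked to
#'   the brain), \code{labels} (integer 3D array) and, when written,
#'   \code{paths}.
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(12, 12, 6), seed = 2))
#' table(ph$labels)
#' @export
makePhantom <- function(spec = phantomSpec(), outDir = NULL) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    r <- .phantomRadius(spec@shape)
    labels <- .phantomLabels(r)
    m <- nMeasurements(spec@scheme)
    sigs <- rbind(ivimSignal(spec@compartments$csf, spec@scheme),
                  ivimSignal(spec@compartments$gm, spec@scheme),
                  ivimSignal(spec@compartments$wm, spec@scheme))
    nvox <- prod(spec@shape)
    clean <- matrix(0, nvox, m)
    inBrain <- as.vector(labels > 0)
    clean[inBrain, ] <- sigs[as.vector(labels)[inBrain], , drop = FALSE]
    if (spec@partialVolume) {
        ## linear cross-fade of compartment signals across a thin band
        ## around each shell interface (width in normalized radius units)
        w <- 0.04
        rv <- as.vector(r)
        for (iface in list(c(0.35, 1L, 2L), c(0.65, 2L, 3L))) {
            band <- which(abs(rv - iface[1L]) < w & inBrain)
            if (length(band)) {
                a <- (rv[band] - (iface[1L] - w)) / (2 * w)
                clean[band, ] <- (1 - a) * sigs[rep(iface[2L],
                                                    length(band)), ] +
                    a * sigs[rep(iface[3L], length(band)), ]
            }
        }
    }
    if (is.finite(spec@snr)) {
        set.seed(spec@seed)
        noised <- .ricianize(clean, sigmaForSNR(1, spec@snr))
    } else noised <- clean
    vol <- dwiVolume(array(noised, c(spec@shape, m)), spec@scheme,
                     affine = diag(c(1, 1, 2, 1)), mask = labels > 0L)
    out <- list(volume = vol, labels = labels, spec = spec)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(dwi = file.path(outDir, "dwi.nii.gz"),
                      labels = file.path(outDir, "labels.nii.gz"),
                      bval = file.path(outDir, "dwi.bval"),
                      bvec = file.path(outDir, "dwi.bvec"),
                      spec = file.path(outDir, "phantom.yaml"))
        writeDWI(vol, paths$dwi, paths$bval, paths$bvec)
        .writeNiftiArray(labels, vol@affine, paths$labels)
        yaml::write_yaml(list(
            shape = spec@shape, snr = spec@snr, seed = spec@seed,
            partial_volume = spec@partialVolume,
            compartments = lapply(spec@compartments, function(p)
                as.list(paramVector(p)))), paths$spec)
        out$paths <- paths
    }
    out
}

#' Generate a repeated-b0 series
#'
#' A constant 3D signal observed through \code{nVolumes} independent
#' Rician noisings: the fixture for SNR-map estimation from repeated
#' b = 0 acquisitions.
#'
#' @param nVolumes Number of b0 volumes (>= 2).
#' @param trueSignal Constant underlying intensity.
#' @param snr Target SNR; \code{Inf} disables noise.
#' @param shape Integer 3-vector.
#' @param seed Integer seed.
#' @return A \linkS4class{DWIVolume} whose scheme is b = 0 repeated
#'   \code{nVolumes} times.
#' @examples
#' makeB0Series(5, 1, 20, c(8, 8, 8), seed = 1)
#' @export
makeB0Series <- function(nVolumes = 5L, trueSignal = 1, snr = 20,
                         shape = c(16L, 16L, 16L), seed = 1L) {
    nVolumes <- as.integer(nVolumes)
    if (nVolumes < 2L) stop("'nVolumes' must be at least 2")
    sch <- AcquisitionScheme(0, nVolumes)
    nvox <- prod(shape)
    clean <- matrix(trueSignal, nvox, nVolumes)
    if (is.finite(snr)) {
        set.seed(as.integer(seed))
        vals <- .ricianize(clean, sigmaForSNR(trueSignal, snr))
    } else vals <- clean
    dwiVolume(array(vals, c(shape, nVolumes)), sch)
}
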