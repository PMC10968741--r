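#' @include phantom.R
NULL

#' Read and write FSL-style bval/bvec sidecars
#'
#' \code{writeBval} emits the expanded b-vector as one space-separated
#' line; \code{writeBvec} emits three lines (x, y, z components), using
#' unit axes cycled per repeat for nonzero b-values and all-zero columns
#' for b0 (the synthetic model is isotropic, so directions only label
#' repeats). \code{readBval}/\code{readBvec} parse the same formats.
#' \code{schemeFromBvals} groups a raw b-vector into shells, treating
#' values within \code{tol} s/mm^2 of each other as the same shell
#' (scanner bval files jitter); each shell's b-value is the rounded mean
#' of its members.
#'
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param path File path.
#' @param bvals Numeric vector of per-measurement b-values.
#' @param tol Shell grouping tolerance, s/mm^2.
#' @return \code{readBval}: numeric vector. \code{readBvec}: 3 x n
#'   matrix. \code{schemeFromBvals}: \linkS4class{AcquisitionScheme}.
#' @name bval-io
#' @examples
#' p <- tempfile(fileext = ".bval")
#' writeBval(defaultScheme(), p)
#' identical(schemeFromBvals(readBval(p)), defaultScheme())
NULL

#' @rdname bval-io
#' @export
writeBval <- function(scheme, path) {
    writeLines(paste(format(bVector(scheme), trim = TRUE,
                            scientific = FALSE), collapse = " "), path)
    invisible(path)
}

#' @rdname bval-io
#' @export
readBval <- function(path) {
    if (!file.exists(path)) stop("bval file not found: ", path)
    as.numeric(scan(path, quiet = TRUE))
}

#' @rdname bval-io
#' @export
writeBvec <- function(scheme, path) {
    b <- bVector(scheme)
    axes <- diag(3)
    vec <- matrix(0, 3L, length(b))
    nz <- which(b > 0)
    if (length(nz))
        vec[, nz] <- t(axes[((seq_along(nz) - 1L) %% 3L) + 1L, ,
                            drop = FALSE])
    writeLines(apply(vec, 1L, function(row)
        paste(format(row, trim = TRUE), collapse = " ")), path)
    invisible(path)
}

#' @rdname bval-io
#' @export
readBvec <- function(path) {
    if (!file.exists(path)) stop("bvec file not found: ", path)
    rows <- lapply(readLines(path), function(l)
        as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]]))
    rows <- rows[vapply(rows, length, integer(1L)) > 0L]
    if (length(rows) != 3L) stop("bvec file must contain three rows: ", path)
    do.call(rbind, rows)
}

#' @rdname bval-io
#' @export
schemeFromBvals <- function(bvals, tol = 1) {
    if (!length(bvals)) stop("empty b-value vector")
    ord <- sort(bvals)
    groupStart <- c(TRUE, diff(ord) > tol)
    gid <- cumsum(groupStart)
    centres <- round(tapply(ord, gid, mean))
    counts <- as.integer(table(gid))
    ## rounded group means may still collide; merge if so
    if (anyDuplicated(centres)) {
        fac <- factor(centres, levels = unique(centres))
        counts <- as.integer(tapply(counts, fac, sum))
        centres <- unique(centres)
    }
    AcquisitionScheme(as.numeric(centres), counts)
}

## Which shell does each raw measurement belong to (by grouping tol)?
.shellAssignment <- function(bvals, scheme, tol = 1) {
    vapply(bvals, function(b) {
        i <- which.min(abs(bValues(scheme) - b))
        if (abs(bValues(scheme)[i] - b) > tol + 0.5)
            stop(sprintf("b-value %g matches no shell", b))
        i
    }, integer(1L))
}

.writeNiftiArray <- function(arr, affine, path, datatype = "float") {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Read a 4D DWI dataset
#'
#' Reads a NIfTI-1 volume with its bval (and optional bvec) sidecars,
#' reconstructs the acquisition scheme by shell grouping and reorders the
#' 4th axis into the canonical order (ascending b, repeats contiguous).
#'
#' @param niftiPath Path to the 4D NIfTI file.
#' @param bvalPath Path to the bval file (entry count must equal the
#'   4th-axis length).
#' @param bvecPath Optional bvec path (validated, not otherwise used: the
#'   pipeline treats directions as repeats).
#' @param mask Optional logical 3D array.
#' @param tol Shell grouping tolerance, s/mm^2.
#' @return A \linkS4class{DWIVolume}.
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath = NULL, mask = NULL,
                    tol = 1) {
    if (!file.exists(niftiPath)) stop("NIfTI file not found: ", niftiPath)
    img <- RNifti::readNifti(niftiPath)
    dm <- dim(img)
    if (length(dm) != 4L)
        stop(sprintf("expected a 4D volume, got %d dimensions", length(dm)))
    bvals <- readBval(bvalPath)
    if (length(bvals) != dm[4L])
        stop(sprintf("bval count (%d) does not match 4th-axis length (%d)",
                     length(bvals), dm[4L]))
    if (!is.null(bvecPath)) {
        bvec <- readBvec(bvecPath)
        if (ncol(bvec) != dm[4L])
            stop(sprintf("bvec column count (%d) does not match 4th-axis length (%d)",
                         ncol(bvec), dm[4L]))
    }
    scheme <- schemeFromBvals(bvals, tol)
    shell <- .shellAssignment(bvals, scheme, tol)
    ord <- order(shell)  # stable: canonical ascending-b order
    arr <- array(as.array(img), dm)[, , , ord, drop = FALSE]
    dwiVolume(arr, scheme, affine = unclass(RNifti::xform(img)),
              mask = mask)
}

#' Write a DWI volume with its sidecars
#'
#' @param volume \linkS4class{DWIVolume}.
#' @param niftiPath,bvalPath,bvecPath Output paths.
#' @return The NIfTI path, invisibly.
#' @export
writeDWI <- function(volume, niftiPath, bvalPath = NULL, bvecPath = NULL) {
    stopifnot(is(volume, "DWIVolume"))
    ## float64 payload: simulated volumes round-trip losslessly
    .writeNiftiArray(volume@data, volume@affine, niftiPath,
                     datatype = "double")
    if (!is.null(bvalPath)) writeBval(volume@scheme, bvalPath)
    if (!is.null(bvecPath)) writeBvec(volume@scheme, bvecPath)
    invisible(niftiPath)
}

#' Write parameter maps as NIfTI files
#'
#' One float32 NIfTI-1 file per map, named \code{<name>.nii.gz}, all
#' sharing one affine.
#'
#' @param maps Named list of equally shaped 3D arrays (logical maps are
#'   written as 0/1).
#' @param affine 4x4 transform.
#' @param outDir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
writeMaps <- function(maps, affine, outDir) {
    if (!length(maps) || is.null(names(maps)) || any(names(maps) == ""))
        stop("'maps' must be a non-empty named list")
    dm <- dim(maps[[1L]])
    if (any(!vapply(maps, function(m) identical(dim(m), dm), logical(1L))))
        stop("all maps must share the same shape")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(names(maps), function(nm) {
        arr <- maps[[nm]]
        if (is.logical(arr)) arr <- array(as.numeric(arr), dim(arr))
        .writeNiftiArray(arr, affine, file.path(outDir,
                                                paste0(nm, ".nii.gz")))
    }, character(1L))
    paths
}

#' Serialize a classification report
#'
#' @param report A \linkS4class{ClassificationReport}.
#' @param jsonPath,csvPath Optional output paths.
#' @return The report as a plain list, invisibly.
#' @export
writeClassificationReport <- function(report, jsonPath = NULL,
                                      csvPath = NULL) {
    stopifnot(is(report, "ClassificationReport"))
    lst <- list(n_total = report@nTotal,
                n_f_outliers = report@nFOutliers,
                pct_f_outliers = 100 * report@nFOutliers / report@nTotal,
                pct_f_in_range = report@pctFInRange,
                pct_dstar_in_range = report@pctDstarInRange,
                n_boundary_dstar = report@nBoundaryDstar,
                f_outlier_threshold = report@fOutlierThreshold,
                f_range = report@fRange, dstar_range = report@dstarRange)
    if (!is.null(jsonPath))
        jsonlite::write_json(lst, jsonPath, auto_unbox = TRUE, digits = NA)
    if (!is.null(csvPath)) {
        flat <- lst
        flat$f_range <- paste(lst$f_range, collapse = ";")
        flat$dstar_range <- paste(lst$dstar_range, collapse = ";")
        utils::write.csv(as.data.frame(flat), csvPath, row.names = FALSE)
    }
    invisible(lst)
}

.knownConfigKeys <- list(
    simulation = c("ground_truth", "snr_levels", "snr_min", "snr_max",
                   "snr_step", "n_realizations", "averaging_factors",
                   "methods", "seed", "threshold", "average_directions"),
    grids = c("s0_slow", "d", "s0_fast", "d_star"),
    bounds = c("lower", "upper", "init"),
    phantom = c("shape", "snr", "seed", "partial_volume", "compartments"),
    output = c("dir"), log_level = NULL)

.gridFromYaml <- function(x, fallback) {
    if (is.null(x)) return(fallback)
    makeGrid(x[["min"]], x[["max"]], as.integer(x[["count"]]),
             if (is.null(x[["spacing"]])) "linear" else x[["spacing"]])
}

#' Read and validate a YAML study configuration
#'
#' Sections: \code{simulation} (ground truth, SNR sweep given as
#' \code{snr_levels} or \code{snr_min}/\code{snr_max}/\code{snr_step},
#' realization count, averaging factors, methods, seed, threshold),
#' \code{grids} (per-grid \code{min}/\code{max}/\code{count}/
#' \code{spacing}), \code{bounds} (\code{lower}/\code{upper}/\code{init}
#' maps), \code{phantom} and \code{output}. Unknown keys are rejected;
#' every section is validated against its class invariants before any
#' computation starts.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return List with elements \code{config}
#'   (\linkS4class{SimulationConfig}), \code{phantom}
#'   (\linkS4class{PhantomSpec} or NULL) and \code{output}.
#' @export
readStudyConfig <- function(path, seed = NULL) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    unknown <- setdiff(names(y), names(.knownConfigKeys))
    if (length(unknown))
        stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    for (sec in intersect(names(y), names(.knownConfigKeys))) {
        bad <- setdiff(names(y[[sec]]), .knownConfigKeys[[sec]])
        if (length(bad) && !is.null(.knownConfigKeys[[sec]]))
            stop(sprintf("unknown key(s) in section '%s': %s", sec,
                         paste(bad, collapse = ", ")))
    }
    sim <- y$simulation
    gt <- if (is.null(sim[["ground_truth"]])) IVIMParams(1, 0.12, 0.01, 0.001)
          else do.call(IVIMParams, sim[["ground_truth"]])
    snr <- if (!is.null(sim[["snr_levels"]])) as.numeric(sim[["snr_levels"]])
           else if (!is.null(sim[["snr_min"]]))
               seq(sim[["snr_min"]], sim[["snr_max"]],
                   by = if (is.null(sim[["snr_step"]])) 1 else sim[["snr_step"]])
           else 15:50
    g <- y$grids
    ## note [[ ]] indexing throughout: $ would partial-match, e.g. an
    ## absent "d" key against "d_star"
    grids <- gridSpec(
        s0SlowGrid = .gridFromYaml(g[["s0_slow"]],
                                   defaultGridSpec()@s0SlowGrid),
        dGrid = .gridFromYaml(g[["d"]], defaultGridSpec()@dGrid),
        s0FastGrid = .gridFromYaml(g[["s0_fast"]],
                                   defaultGridSpec()@s0FastGrid),
        dStarGrid = .gridFromYaml(g[["d_star"]],
                                  defaultGridSpec()@dStarGrid))
    bounds <- if (is.null(y$bounds)) defaultFitBounds()
        else fitBounds(lower = unlist(y$bounds[["lower"]]),
                       upper = unlist(y$bounds[["upper"]]),
                       init = unlist(y$bounds[["init"]]))
    cfg <- simulationConfig(
        groundTruth = gt, snrLevels = snr,
        nRealizations = if (is.null(sim[["n_realizations"]])) 17280L
                        else as.integer(sim[["n_realizations"]]),
        averagingFactors = if (is.null(sim[["averaging_factors"]]))
                               c(1L, 8L, 27L, 64L)
                           else as.integer(sim[["averaging_factors"]]),
        methods = if (is.null(sim[["methods"]]))
                      c("grid_search", "segmented", "one_step")
                  else sim[["methods"]],
        seed = if (!is.null(seed)) as.integer(seed)
               else if (is.null(sim[["seed"]])) 1L else as.integer(sim[["seed"]]),
        grids = grids, bounds = bounds,
        threshold = if (is.null(sim[["threshold"]])) 250
                    else as.numeric(sim[["threshold"]]))
    ph <- NULL
    if (!is.null(y$phantom)) {
        p <- y$phantom
        comp <- if (is.null(p[["compartments"]])) phantomSpec()@compartments
            else lapply(p[["compartments"]], function(cp)
                do.call(IVIMParams, cp))
        ph <- phantomSpec(
            shape = if (is.null(p[["shape"]])) c(32L, 32L, 16L)
                    else as.integer(p[["shape"]]),
            compartments = comp,
            snr = if (is.null(p[["snr"]])) 20 else p[["snr"]],
            seed = if (is.null(p[["seed"]])) 1L else as.integer(p[["seed"]]),
            partialVolume = isTRUE(p[["partial_volume"]]))
    }
    list(config = cfg, phantom = ph, output = y$output)
}
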