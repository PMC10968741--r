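#' @include noise.R
NULL

#' Build a candidate grid
#'
#' @param min,max Grid endpoints (min < max).
#' @param n Number of points (>= 2).
#' @param spacing \code{"linear"} or \code{"log"} (log requires min > 0).
#' @return Strictly increasing numeric vector of length \code{n}.
#' @examples
#' makeGrid(1e-3, 0.1, 5, "log")
#' @export
makeGrid <- function(min, max, n, spacing = c("linear", "log")) {
    spacing <- match.arg(spacing)
    if (!(min < max)) stop("'min' must be below 'max'")
    if (n < 2L) stop("'n' must be at least 2")
    if (spacing == "linear") seq(min, max, length.out = n)
    else {
        if (min <= 0) stop("log spacing requires min > 0")
        exp(seq(log(min), log(max), length.out = n))
    }
}

#' @param s0SlowGrid,dGrid,s0FastGrid,dStarGrid Strictly increasing
#'   candidate vectors (see \linkS4class{GridSpec}).
#' @rdname defaultGridSpec
#' @export
gridSpec <- function(s0SlowGrid, dGrid, s0FastGrid, dStarGrid) {
    new("GridSpec", s0SlowGrid = s0SlowGrid, dGrid = dGrid,
        s0FastGrid = s0FastGrid, dStarGrid = dStarGrid)
}

#' Default search grids for the segmented grid-search estimator
#'
#' Stage 1 (high-b, slow compartment): amplitude on [0.3, 1.5], 121 linear
#' points; D on [1e-4, 3e-3] mm^2/s, 117 linear points. Stage 2 (low-b
#' residual, fast compartment): amplitude on [0, 0.6], 121 linear points;
#' D* on [1e-3, 0.1] mm^2/s, 151 log-spaced points. The ranges bracket
#' literature grey-matter values with headroom; note that the D* upper
#' limit materially affects apparent D* RMSE at low SNR because noisy
#' estimates pile up on the grid boundary (see the package vignette).
#'
#' @return A \linkS4class{GridSpec}.
#' @examples
#' defaultGridSpec()
#' @export
defaultGridSpec <- function() {
    gridSpec(s0SlowGrid = makeGrid(0.3, 1.5, 121L),
             dGrid = makeGrid(1e-4, 3e-3, 117L),
             s0FastGrid = makeGrid(0, 0.6, 121L),
             dStarGrid = makeGrid(1e-3, 0.1, 151L, "log"))
}

#' @param lower,upper,init Named numeric vectors (\code{s0, f, dstar, d}).
#' @rdname defaultFitBounds
#' @export
fitBounds <- function(lower, upper, init) {
    nm <- c("s0", "f", "dstar", "d")
    new("FitBounds", lower = lower[nm], upper = upper[nm], init = init[nm])
}

#' Default box constraints for the curve-fit estimators
#'
#' s0 in (0, 2], f in [0, 1], D* in [1e-4, 0.15] mm^2/s, D in
#' [1e-5, 5e-3] mm^2/s; one-step initial values (1, 0.1, 1e-2, 1e-3).
#' The ranges bracket literature grey-matter values with headroom and are
#' fully configurable; as for the grids, the D* upper bound drives the
#' apparent D* RMSE at low SNR.
#'
#' @return A \linkS4class{FitBounds}.
#' @examples
#' defaultFitBounds()
#' @export
defaultFitBounds <- function() {
    fitBounds(lower = c(s0 = 1e-6, f = 0, dstar = 1e-4, d = 1e-5),
              upper = c(s0 = 2, f = 1, dstar = 0.15, d = 5e-3),
              init  = c(s0 = 1, f = 0.1, dstar = 1e-2, d = 1e-3))
}

#' Split a scheme at the segmentation threshold
#'
#' Above roughly 250 s/mm^2 the perfusion compartment has decayed below
#' the noise floor, so the segmented estimators fit the slow compartment
#' on the high-b measurements only. Returns the measurement indices on
#' either side of the threshold (b = 0 falls in the low set).
#'
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param threshold Split b-value in s/mm^2.
#' @return List with integer index vectors \code{high} (b > threshold) and
#'   \code{low} (b < threshold), relative to the canonical measurement
#'   order.
#' @examples
#' str(splitScheme(defaultScheme()))
#' @export
splitScheme <- function(scheme, threshold = 250) {
    b <- .asB(scheme)
    high <- which(b > threshold)
    low <- which(b < threshold)
    if (!length(high) || !length(low))
        stop(sprintf(
            "threshold %g leaves an empty %s-b set; scheme unusable for segmented fitting",
            threshold, if (length(high)) "low" else "high"))
    list(high = high, low = low)
}

## Exhaustive least-squares grid fit of s0 * exp(-d * b) for a matrix of
## signals (rows). The SSE is expanded as
##   sum(s^2) + s0^2 * sum(e^2) - 2 * s0 * (e . s),  e = exp(-d b),
## so the argmin over the Cartesian grid reduces to matrix products.
## Grid pairs are ordered d-major ascending, s0 ascending within d, and
## the first minimum is taken: ties break to smallest d, then smallest s0.
.gridFitMonoexpMany <- function(S, b, s0Grid, dGrid, blockSize = 1024L) {
    E <- exp(-outer(dGrid, b))            # nd x m
    e2 <- rowSums(E * E)
    A <- E %*% t(S)                       # nd x n cross terms
    nd <- length(dGrid); ns <- length(s0Grid); n <- ncol(A)
    s0rep <- rep(s0Grid, times = nd)      # inner index: s0
    drep <- rep(seq_len(nd), each = ns)   # outer index: d
    cg <- s0rep^2 * rep(e2, each = ns)
    best <- integer(n)
    for (st in seq(1L, n, by = blockSize)) {
        en <- min(st + blockSize - 1L, n)
        sse <- cg - 2 * (A[drep, st:en, drop = FALSE] * s0rep)
        best[st:en] <- max.col(-t(sse), ties.method = "first")
    }
    dIdx <- (best - 1L) %/% ns + 1L
    sIdx <- (best - 1L) %% ns + 1L
    s0Hat <- s0Grid[sIdx]; dHat <- dGrid[dIdx]
    resid <- S - s0Hat * exp(-outer(dHat, b))
    list(s0 = s0Hat, d = dHat, sse = rowSums(resid * resid),
         s0Boundary = sIdx == 1L | sIdx == ns,
         dBoundary = dIdx == 1L | dIdx == nd)
}

## Rician negative log-likelihood grid fit (single signal). Non-default
## alternative objective for the grid search; requires the noise sigma.
.gridFitMonoexpRician <- function(s, b, s0Grid, dGrid, sigma) {
    s <- pmax(s, .Machine$double.eps)
    bestNll <- Inf; bestI <- 1L; bestJ <- 1L
    for (j in seq_along(dGrid)) {
        e <- exp(-dGrid[j] * b)
        for (i in seq_along(s0Grid)) {
            m <- s0Grid[i] * e
            z <- s * m / sigma^2
            ## log I0 via the exponentially scaled Bessel function
            nll <- -sum(log(s / sigma^2) - (s^2 + m^2) / (2 * sigma^2) +
                        log(besselI(z, 0, expon.scaled = TRUE)) + z)
            if (nll < bestNll) { bestNll <- nll; bestI <- i; bestJ <- j }
        }
    }
    list(s0 = s0Grid[bestI], d = dGrid[bestJ],
         sse = sum((s - s0Grid[bestI] * exp(-dGrid[bestJ] * b))^2),
         s0Boundary = bestI %in% c(1L, length(s0Grid)),
         dBoundary = bestJ %in% c(1L, length(dGrid)))
}

#' Exhaustive grid fit of a mono-exponential decay
#'
#' Evaluates every (s0, d) pair on the Cartesian grid and returns the
#' least-squares minimizer of \eqn{\sum (s_k - s_0 e^{-d b_k})^2}
#' (maximum likelihood under Gaussian residuals). Ties break to the
#' smallest d, then the smallest s0. With \code{objective = "rician"} the
#' Rician negative log-likelihood is minimized instead (requires
#' \code{sigma}).
#'
#' @param signal Numeric signal vector.
#' @param b Numeric b-vector of the same length.
#' @param s0Grid,dGrid Strictly increasing candidate grids.
#' @param objective \code{"ls"} (default) or \code{"rician"}.
#' @param sigma Noise standard deviation, required for the Rician
#'   objective.
#' @return List with \code{s0}, \code{d}, \code{sse}, \code{s0Boundary},
#'   \code{dBoundary}.
#' @examples
#' b <- c(500, 700, 1000, 1200)
#' gridFitMonoexp(0.9 * exp(-0.001 * b), b,
#'                s0Grid = seq(0.5, 1.2, by = 0.1),
#'                dGrid = seq(5e-4, 2e-3, by = 5e-4))
#' @export
gridFitMonoexp <- function(signal, b, s0Grid, dGrid,
                           objective = c("ls", "rician"), sigma = NULL) {
    objective <- match.arg(objective)
    if (length(signal) != length(b) || length(signal) < 2L)
        stop("'signal' and 'b' must have equal length >= 2")
    if (length(s0Grid) < 2L || length(dGrid) < 2L ||
        is.unsorted(s0Grid, strictly = TRUE) ||
        is.unsorted(dGrid, strictly = TRUE))
        stop("grids must be strictly increasing with at least 2 values")
    if (objective == "rician") {
        if (is.null(sigma) || sigma <= 0)
            stop("the Rician objective requires a positive 'sigma'")
        return(.gridFitMonoexpRician(signal, b, s0Grid, dGrid, sigma))
    }
    out <- .gridFitMonoexpMany(matrix(signal, nrow = 1L), b, s0Grid, dGrid)
    lapply(out, `[`, 1L)
}

.newFitResult <- function(s0, f, dstar, d, method, converged, boundary,
                          sse) {
    new("FitResult",
        params = IVIMParams(max(s0, .Machine$double.xmin), min(max(f, 0), 1),
                            max(dstar, 0), max(d, 0)),
        method = method, converged = converged,
        boundary = boundary, sse = sse)
}

## SSE of the composed two-compartment model over all measurements.
.composedSSE <- function(signal, b, s0Fast, dstar, s0Slow, d) {
    fit <- s0Fast * exp(-dstar * b) + s0Slow * exp(-d * b)
    sum((signal - fit)^2)
}

#' Segmented grid-search IVIM fit
#'
#' Two-stage exhaustive search. Stage 1 grid-fits a mono-exponential
#' (slow amplitude, D) to the measurements above the threshold. Stage 2
#' subtracts the stage-1 curve from the low-b measurements and grid-fits
#' the residual (fast amplitude, D*); residuals may be negative and are
#' fitted as-is. The perfusion fraction is the stage-2 amplitude divided
#' by the sum of both amplitudes, and S0 is that sum.
#'
#' @param signal Numeric measurement vector in canonical scheme order.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param grids \linkS4class{GridSpec}.
#' @param threshold Segmentation threshold, s/mm^2.
#' @param objective Grid objective, \code{"ls"} or \code{"rician"}.
#' @param sigma Noise sd for the Rician objective.
#' @return A \linkS4class{FitResult} with method \code{"grid_search"}.
#' @examples
#' sch <- defaultScheme()
#' sig <- ivimSignal(IVIMParams(1, 0.12, 0.01, 0.001), sch)
#' fitGridSegmented(sig, sch)
#' @export
fitGridSegmented <- function(signal, scheme, grids = defaultGridSpec(),
                             threshold = 250,
                             objective = c("ls", "rician"), sigma = NULL) {
    objective <- match.arg(objective)
    validObject(grids)
    b <- .asB(scheme)
    if (length(signal) != length(b))
        stop("'signal' length must match the scheme")
    idx <- splitScheme(scheme, threshold)
    st1 <- gridFitMonoexp(signal[idx$high], b[idx$high], grids@s0SlowGrid,
                          grids@dGrid, objective, sigma)
    r <- signal[idx$low] - st1$s0 * exp(-st1$d * b[idx$low])
    ## stage 2 is always least squares: residuals are signed, so the
    ## Rician magnitude likelihood does not apply to them
    st2 <- gridFitMonoexp(r, b[idx$low], grids@s0FastGrid, grids@dStarGrid)
    tot <- st1$s0 + st2$s0
    fHat <- if (tot > 0) st2$s0 / tot else 0
    .newFitResult(tot, fHat, st2$d, st1$d, "grid_search", TRUE,
                  c(s0 = st1$s0Boundary || st2$s0Boundary,
                    f = st2$s0Boundary || fHat <= 0 || fHat >= 1,
                    dstar = st2$dBoundary, d = st1$dBoundary),
                  .composedSSE(signal, b, st2$s0, st2$d, st1$s0, st1$d))
}

## Bounded Levenberg-Marquardt mono-exponential fit.
.lmMonoexp <- function(signal, b, init, lower, upper) {
    fit <- minpack.lm::nls.lm(
        par = init, lower = lower, upper = upper,
        fn = function(p) signal - p[1L] * exp(-p[2L] * b),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    list(par = fit$par, converged = fit$info %in% 1:4)
}

.atBound <- function(value, bound, rtol = 1e-6) {
    abs(value - bound) <= rtol * max(1, abs(bound))
}

#' Segmented bounded curve-fit IVIM estimation
#'
#' Mirrors \code{\link{fitGridSegmented}} with bounded nonlinear least
#' squares (Levenberg-Marquardt with box constraints) in place of the
#' exhaustive grids: stage 1 fits (slow amplitude, D) on the high-b
#' measurements, stage 2 fits (fast amplitude, D*) on the low-b residual,
#' and f and S0 are composed from the two amplitudes. With
#' \code{stage2 = "fraction"} the second stage instead fits (f, D*) to the
#' raw low-b signal with the stage-1 curve held fixed.
#'
#' @param signal Numeric measurement vector.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param bounds \linkS4class{FitBounds}.
#' @param threshold Segmentation threshold, s/mm^2.
#' @param stage2 \code{"residual"} (default) or \code{"fraction"}.
#' @return A \linkS4class{FitResult} with method \code{"segmented"}.
#'   Boundary flags mark estimates within relative tolerance 1e-6 of a
#'   bound; \code{converged} reflects the optimizer status of both stages.
#' @examples
#' sch <- defaultScheme()
#' sig <- ivimSignal(IVIMParams(1, 0.12, 0.01, 0.001), sch)
#' fitCurveSegmented(sig, sch)
#' @export
fitCurveSegmented <- function(signal, scheme, bounds = defaultFitBounds(),
                              threshold = 250,
                              stage2 = c("residual", "fraction")) {
    stage2 <- match.arg(stage2)
    validObject(bounds)
    b <- .asB(scheme)
    if (length(signal) != length(b))
        stop("'signal' length must match the scheme")
    idx <- splitScheme(scheme, threshold)
    lo <- bounds@lower; up <- bounds@upper; ini <- bounds@init
    st1 <- .lmMonoexp(signal[idx$high], b[idx$high],
                      c(ini[["s0"]], ini[["d"]]),
                      c(lo[["s0"]], lo[["d"]]), c(up[["s0"]], up[["d"]]))
    s0Slow <- st1$par[1L]; dHat <- st1$par[2L]
    bLow <- b[idx$low]
    if (stage2 == "residual") {
        r <- signal[idx$low] - s0Slow * exp(-dHat * bLow)
        st2 <- .lmMonoexp(r, bLow,
                          c(ini[["s0"]] * ini[["f"]], ini[["dstar"]]),
                          c(0, lo[["dstar"]]), c(up[["s0"]], up[["dstar"]]))
        s0Fast <- st2$par[1L]; dstarHat <- st2$par[2L]
        tot <- s0Slow + s0Fast
        fHat <- if (tot > 0) s0Fast / tot else 0
        s0Bnd <- .atBound(s0Slow, lo[["s0"]]) || .atBound(s0Slow, up[["s0"]]) ||
            .atBound(s0Fast, 0) || .atBound(s0Fast, up[["s0"]])
        fBnd <- .atBound(s0Fast, 0) || fHat <= 0 || fHat >= 1
    } else {
        ## fit (f, dstar) on the raw low-b signal, stage-1 curve fixed:
        ## model = s0Slow/(1-f) * f * exp(-dstar b) + s0Slow * exp(-d b)
        sLow <- signal[idx$low]
        fUp <- min(up[["f"]], 1 - 1e-8)
        fit2 <- minpack.lm::nls.lm(
            par = c(ini[["f"]], ini[["dstar"]]),
            lower = c(lo[["f"]], lo[["dstar"]]),
            upper = c(fUp, up[["dstar"]]),
            fn = function(p) sLow - (s0Slow / (1 - p[1L]) * p[1L] *
                exp(-p[2L] * bLow) + s0Slow * exp(-dHat * bLow)),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        st2 <- list(par = fit2$par, converged = fit2$info %in% 1:4)
        fHat <- st2$par[1L]; dstarHat <- st2$par[2L]
        tot <- s0Slow / (1 - fHat)
        s0Fast <- tot * fHat
        s0Bnd <- .atBound(s0Slow, lo[["s0"]]) || .atBound(s0Slow, up[["s0"]])
        fBnd <- .atBound(fHat, lo[["f"]]) || .atBound(fHat, fUp)
    }
    .newFitResult(tot, fHat, dstarHat, dHat, "segmented",
                  st1$converged && st2$converged,
                  c(s0 = s0Bnd, f = fBnd,
                    dstar = .atBound(dstarHat, lo[["dstar"]]) ||
                            .atBound(dstarHat, up[["dstar"]]),
                    d = .atBound(dHat, lo[["d"]]) ||
                        .atBound(dHat, up[["d"]])),
                  .composedSSE(signal, b, s0Fast, dstarHat, s0Slow, dHat))
}

#' One-step four-parameter IVIM curve fit
#'
#' Bounded nonlinear least squares of the full bi-exponential model in
#' (S0, f, D*, D) over all measurements simultaneously, started from the
#' fixed initial values in \code{bounds} (no data-dependent
#' initialization).
#'
#' @param signal Numeric measurement vector.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param bounds \linkS4class{FitBounds}.
#' @return A \linkS4class{FitResult} with method \code{"one_step"}.
#' @examples
#' sch <- defaultScheme()
#' sig <- ivimSignal(IVIMParams(1, 0.12, 0.01, 0.001), sch)
#' fitOneStep(sig, sch)
#' @export
fitOneStep <- function(signal, scheme, bounds = defaultFitBounds()) {
    validObject(bounds)
    b <- .asB(scheme)
    if (length(signal) != length(b))
        stop("'signal' length must match the scheme")
    lo <- bounds@lower; up <- bounds@upper
    fit <- minpack.lm::nls.lm(
        par = bounds@init, lower = lo, upper = up,
        fn = function(p) signal - p[1L] * (p[2L] * exp(-p[3L] * b) +
            (1 - p[2L]) * exp(-p[4L] * b)),
        control = minpack.lm::nls.lm.control(maxiter = 400))
    p <- fit$par
    bnd <- vapply(c("s0", "f", "dstar", "d"), function(nm)
        .atBound(p[[nm]], lo[[nm]]) || .atBound(p[[nm]], up[[nm]]),
        logical(1L))
    .newFitResult(p[["s0"]], p[["f"]], p[["dstar"]], p[["d"]], "one_step",
                  fit$info %in% 1:4, bnd, fit$deviance)
}

#' @rdname param-accessors
#' @export
setMethod("paramVector", "FitResult",
          function(object) paramVector(object@params))

setMethod("show", "FitResult", function(object) {
    p <- paramVector(object)
    cat(sprintf("FitResult [%s]%s: S0 = %.4g, f = %.4g, D* = %.4g, D = %.4g\n",
                object@method,
                if (object@converged) "" else " (not converged)",
                p["s0"], p["f"], p["dstar"], p["d"]))
    if (any(object@boundary))
        cat("  at boundary:", paste(names(object@boundary)[object@boundary],
                                    collapse = ", "), "\n")
    cat(sprintf("  SSE = %.4g\n", object@sse))
    invisible(NULL)
})

## Vectorized segmented grid search over the rows of a signal matrix.
## Identical estimates to calling fitGridSegmented() row by row.
.fitGridSegmentedMany <- function(S, b, grids, threshold = 250) {
    high <- which(b > threshold); low <- which(b < threshold)
    if (!length(high) || !length(low))
        stop("threshold leaves an empty b-subset")
    st1 <- .gridFitMonoexpMany(S[, high, drop = FALSE], b[high],
                               grids@s0SlowGrid, grids@dGrid)
    r <- S[, low, drop = FALSE] - st1$s0 * exp(-outer(st1$d, b[low]))
    st2 <- .gridFitMonoexpMany(r, b[low], grids@s0FastGrid,
                               grids@dStarGrid)
    tot <- st1$s0 + st2$s0
    f <- ifelse(tot > 0, st2$s0 / tot, 0)
    fit <- st2$s0 * exp(-outer(st2$d, b)) + st1$s0 * exp(-outer(st1$d, b))
    data.frame(method = "grid_search", s0 = tot, f = f, dstar = st2$d,
               d = st1$d, converged = TRUE,
               s0Boundary = st1$s0Boundary | st2$s0Boundary,
               fBoundary = st2$s0Boundary | f <= 0 | f >= 1,
               dstarBoundary = st2$dBoundary, dBoundary = st1$dBoundary,
               sse = rowSums((S - fit)^2))
}

.fitResultRow <- function(fr) {
    p <- paramVector(fr)
    data.frame(method = fr@method, s0 = p[["s0"]], f = p[["f"]],
               dstar = p[["dstar"]], d = p[["d"]],
               converged = fr@converged,
               s0Boundary = fr@boundary[["s0"]],
               fBoundary = fr@boundary[["f"]],
               dstarBoundary = fr@boundary[["dstar"]],
               dBoundary = fr@boundary[["d"]], sse = fr@sse)
}

#' Fit every realization of a signal set
#'
#' Applies one estimator to each row of a \linkS4class{SignalSet} and
#' returns one row of estimates per realization. The grid search uses a
#' vectorized exhaustive evaluation that returns estimates identical to
#' fitting each row individually.
#'
#' @param set A \linkS4class{SignalSet}.
#' @param method \code{"grid_search"}, \code{"segmented"} or
#'   \code{"one_step"}.
#' @param grids \linkS4class{GridSpec} (grid search).
#' @param bounds \linkS4class{FitBounds} (curve fits).
#' @param threshold Segmentation threshold, s/mm^2.
#' @return A data.frame with columns \code{method, s0, f, dstar, d,
#'   converged, s0Boundary, fBoundary, dstarBoundary, dBoundary, sse}.
#' @examples
#' cs <- cleanSignalSet(IVIMParams(1, 0.12, 0.01, 0.001), defaultScheme(), 3)
#' fitSignalSet(addRicianNoise(cs, noiseSpec(20, seed = 1)), "grid_search")
#' @export
fitSignalSet <- function(set, method = c("grid_search", "segmented",
                                         "one_step"),
                         grids = defaultGridSpec(),
                         bounds = defaultFitBounds(), threshold = 250) {
    method <- match.arg(method)
    stopifnot(is(set, "SignalSet"))
    S <- set@values
    b <- bVector(set@scheme)
    if (method == "grid_search")
        return(.fitGridSegmentedMany(S, b, grids, threshold))
    rows <- lapply(seq_len(nrow(S)), function(i) {
        sig <- S[i, ]
        fr <- if (method == "segmented")
            fitCurveSegmented(sig, set@scheme, bounds, threshold)
        else fitOneStep(sig, set@scheme, bounds)
        .fitResultRow(fr)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
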