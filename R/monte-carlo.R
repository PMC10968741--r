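#' @include estimators.R
NULL

#' Relative root-mean-square error in percent
#'
#' \code{100 * sqrt(mean((estimates - truth)^2)) / truth}, the accuracy
#' measure used throughout the simulation study.
#'
#' @param estimates Non-empty numeric vector of parameter estimates.
#' @param truth True parameter value (nonzero).
#' @return Relative RMSE in percent.
#' @examples
#' relativeRMSE(c(0.9, 1.1), 1)  # 10
#' @export
relativeRMSE <- function(estimates, truth) {
    if (!length(estimates)) stop("'estimates' must be non-empty")
    if (!is.numeric(truth) || length(truth) != 1L || truth == 0)
        stop("'truth' must be a single nonzero number (relative measure undefined at 0)")
    100 * sqrt(mean((estimates - truth)^2)) / truth
}

## Monte-Carlo standard error of the relative RMSE, by the delta method on
## the mean squared error: var(MSE) = (m4 - m2^2) / n.
.relativeRMSE_SE <- function(estimates, truth) {
    n <- length(estimates)
    if (n < 2L) return(NA_real_)
    sq <- (estimates - truth)^2
    m2 <- mean(sq)
    if (m2 <= 0) return(0)
    vm2 <- (mean(sq^2) - m2^2) / n
    100 * sqrt(vm2) / (2 * sqrt(m2) * abs(truth))
}

#' Assemble a Monte-Carlo study configuration
#'
#' Defaults reproduce the study conditions: ground truth
#' (S0 = 1, f = 0.12, D* = 0.01, D = 0.001), the 35-measurement scheme,
#' 36 integer SNR levels 15..50, 17,280 realizations per level (divisible
#' by 8, 27 and 64), averaging factors 1/8/27/64 and all three
#' estimators. Reduce \code{nRealizations} and \code{snrLevels} for
#' desk-scale runs; Monte-Carlo standard errors are reported per cell so
#' scaled-down results can be compared honestly.
#'
#' @param groundTruth \linkS4class{IVIMParams}.
#' @param scheme \linkS4class{AcquisitionScheme}.
#' @param snrLevels Numeric vector of SNR levels.
#' @param nRealizations Realizations per SNR level; must be divisible by
#'   every averaging factor.
#' @param averagingFactors Integer vector (1 = single voxel).
#' @param methods Estimators to run.
#' @param seed Master seed; per-SNR substreams derive from it.
#' @param grids,bounds Estimator settings.
#' @param threshold Segmentation threshold, s/mm^2.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(snrLevels = 20, nRealizations = 216,
#'                  averagingFactors = c(1, 8), methods = "grid_search")
#' @export
simulationConfig <- function(groundTruth = IVIMParams(1, 0.12, 0.01, 0.001),
                             scheme = defaultScheme(),
                             snrLevels = 15:50,
                             nRealizations = 17280L,
                             averagingFactors = c(1L, 8L, 27L, 64L),
                             methods = c("grid_search", "segmented",
                                         "one_step"),
                             seed = 1L,
                             grids = defaultGridSpec(),
                             bounds = defaultFitBounds(),
                             threshold = 250) {
    new("SimulationConfig", groundTruth = groundTruth, scheme = scheme,
        snrLevels = as.numeric(snrLevels),
        nRealizations = as.integer(nRealizations),
        averagingFactors = as.integer(averagingFactors), methods = methods,
        seed = as.integer(seed), grids = grids, bounds = bounds,
        threshold = as.numeric(threshold))
}

## Deterministic per-SNR substream seed, kept below 2^31. Keyed on the
## SNR value itself so a partial re-run of a subset of levels reproduces
## the full run's realizations for those levels.
.substreamSeed <- function(seed, snr) {
    key <- if (is.finite(snr)) round(1000 * as.numeric(snr)) else 0
    as.integer((as.numeric(seed) + 104729 * key) %% 2147483647)
}

.rmseRows <- function(est, truthVec, method, snr, k, subset) {
    do.call(rbind, lapply(names(truthVec), function(pn) {
        e <- est[[pn]]
        data.frame(method = method, parameter = pn, snr = snr,
                   averaging = k,
                   rmse = relativeRMSE(e, truthVec[[pn]]),
                   mcSE = .relativeRMSE_SE(e, truthVec[[pn]]),
                   nEffective = length(e), subset = subset)
    }))
}

#' Run the Monte-Carlo accuracy study
#'
#' For every SNR level, draws \code{nRealizations} Rician-noised copies of
#' the ground-truth signal, optionally averages them in disjoint groups,
#' fits every realization with every configured estimator, and tabulates
#' the relative RMSE of each parameter. Fully deterministic given the
#' configuration seed; realizations are independent, so any execution
#' order gives results identical to the sequential run.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param keepEstimates If TRUE, the per-realization estimate tables are
#'   attached as attribute \code{"estimates"} (a list indexed by
#'   \code{snr<level>.avg<factor>.<method>}).
#' @param verbose Log one line per (snr, averaging, method) block.
#' @return A data.frame (the RMSE table) with columns \code{method,
#'   parameter, snr, averaging, rmse, mcSE, nEffective}, computed over all
#'   realizations (non-converged fits included with their best iterate). A
#'   converged-only companion table is attached as attribute
#'   \code{"convergedOnly"}.
#' @examples
#' cfg <- simulationConfig(snrLevels = 20, nRealizations = 64,
#'                         averagingFactors = c(1, 8),
#'                         methods = "grid_search", seed = 7)
#' runStudy(cfg)
#' @export
runStudy <- function(config, keepEstimates = FALSE, verbose = FALSE) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    truthVec <- paramVector(config@groundTruth)
    clean <- cleanSignalSet(config@groundTruth, config@scheme,
                            config@nRealizations)
    allRows <- list(); convRows <- list(); keep <- list()
    for (si in seq_along(config@snrLevels)) {
        snr <- config@snrLevels[si]
        spec <- noiseSpec(snr, s0Reference = s0(config@groundTruth),
                          seed = .substreamSeed(config@seed, snr))
        noised <- addRicianNoise(clean, spec)
        for (k in config@averagingFactors) {
            set <- if (k == 1L) noised else averageRealizations(noised, k)
            for (m in config@methods) {
                t0 <- proc.time()[["elapsed"]]
                est <- fitSignalSet(set, m, config@grids, config@bounds,
                                    config@threshold)
                key <- sprintf("snr%g.avg%d.%s", snr, k, m)
                allRows[[key]] <- .rmseRows(est, truthVec, m, snr, k, "all")
                conv <- est[est$converged, , drop = FALSE]
                if (nrow(conv))
                    convRows[[key]] <- .rmseRows(conv, truthVec, m, snr, k,
                                                 "converged")
                if (keepEstimates) keep[[key]] <- est
                if (verbose)
                    message(sprintf(
                        "snr=%g avg=%d method=%s n=%d converged=%d wall=%.2fs",
                        snr, k, m, nrow(est), sum(est$converged),
                        proc.time()[["elapsed"]] - t0))
            }
        }
    }
    out <- do.call(rbind, allRows)
    rownames(out) <- NULL
    out$subset <- NULL
    convergedOnly <- do.call(rbind, convRows)
    if (!is.null(convergedOnly)) {
        rownames(convergedOnly) <- NULL
        convergedOnly$subset <- NULL
    }
    attr(out, "convergedOnly") <- convergedOnly
    if (keepEstimates) attr(out, "estimates") <- keep
    out
}

.parameterLabels <- c(s0 = "S0", f = "f", dstar = "D*", d = "D")

#' Lay out an RMSE table at one SNR level
#'
#' Reshapes the long RMSE table into the report layout: one block per
#' averaging factor ("single voxel", then k = 2x2x2 etc.), four parameter
#' rows per block, one column per method.
#'
#' @param table RMSE table from \code{\link{runStudy}}.
#' @param snr The SNR level to report.
#' @param file Optional path; the layout is written there as CSV.
#' @return The layout data.frame (invisibly when written to file).
#' @examples
#' cfg <- simulationConfig(snrLevels = 20, nRealizations = 64,
#'                         averagingFactors = 1, methods = "grid_search")
#' exportRMSETable(runStudy(cfg), 20)
#' @export
exportRMSETable <- function(table, snr, file = NULL) {
    if (is.null(table) || !nrow(table)) stop("empty RMSE table")
    sub <- table[table$snr == snr, , drop = FALSE]
    if (!nrow(sub))
        stop(sprintf("SNR %g not present; available levels: %s", snr,
                     paste(sort(unique(table$snr)), collapse = ", ")))
    methods <- intersect(c("grid_search", "segmented", "one_step"),
                         unique(sub$method))
    factors <- sort(unique(sub$averaging))
    blocks <- lapply(factors, function(k) {
        blk <- data.frame(
            averaging = if (k == 1L) "single voxel"
                        else sprintf("%d (%s)", k,
                                     paste(rep(round(k^(1 / 3)), 3L),
                                           collapse = " x ")),
            parameter = .parameterLabels)
        for (m in methods) {
            cell <- vapply(names(.parameterLabels), function(pn) {
                v <- sub$rmse[sub$method == m & sub$parameter == pn &
                              sub$averaging == k]
                if (length(v)) v[1L] else NA_real_
            }, numeric(1L))
            blk[[m]] <- round(cell, 2L)
        }
        blk
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    if (!is.null(file)) {
        utils::write.csv(out, file, row.names = FALSE)
        return(invisible(out))
    }
    out
}

#' Plot relative RMSE against SNR
#'
#' One panel per parameter, one curve per method, at a fixed averaging
#' factor.
#'
#' @param table RMSE table from \code{\link{runStudy}}.
#' @param averaging Averaging factor to display.
#' @param file Optional output path (.png or .svg), written via
#'   \code{ggplot2::ggsave}.
#' @return The ggplot object (invisibly when written to file).
#' @examples
#' cfg <- simulationConfig(snrLevels = c(20, 40), nRealizations = 32,
#'                         averagingFactors = 1, methods = "grid_search")
#' plotRMSEvsSNR(runStudy(cfg))
#' @export
plotRMSEvsSNR <- function(table, averaging = 1, file = NULL) {
    sub <- table[table$averaging == averaging, , drop = FALSE]
    if (!nrow(sub))
        stop(sprintf("averaging factor %g not present in the table",
                     averaging))
    sub$parameter <- factor(.parameterLabels[sub$parameter],
                            levels = .parameterLabels)
    p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$snr, y = .data$rmse,
                                           colour = .data$method)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::facet_wrap(~parameter, scales = "free_y") +
        ggplot2::labs(x = "SNR", y = "relative RMSE [%]",
                      colour = "method",
                      title = sprintf("Averaging factor %g", averaging)) +
        ggplot2::theme_bw()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
        return(invisible(p))
    }
    p
}
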