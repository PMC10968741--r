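test_that("relative RMSE follows its definition", {
    expect_equal(relativeRMSE(c(1, 1, 1), 1), 0)
    expect_equal(relativeRMSE(c(0.9, 1.1), 1), 10)
    expect_equal(relativeRMSE(1.2, 1), 20)
    expect_equal(relativeRMSE(c(0.0008, 0.0012), 0.001), 20)
    expect_error(relativeRMSE(numeric(), 1), "non-empty")
    expect_error(relativeRMSE(c(1, 2), 0), "nonzero")
})

test_that("the study is deterministic and reproducible per SNR level", {
    cfg <- simulationConfig(snrLevels = c(20, 35), nRealizations = 48,
                            averagingFactors = 1, methods = "grid_search",
                            seed = 9L)
    a <- runStudy(cfg)
    b <- runStudy(cfg)
    expect_identical(a$rmse, b$rmse)

    ## partial re-run of one level reproduces its rows exactly
    cfg35 <- simulationConfig(snrLevels = 35, nRealizations = 48,
                              averagingFactors = 1,
                              methods = "grid_search", seed = 9L)
    c <- runStudy(cfg35)
    expect_identical(c$rmse, a$rmse[a$snr == 35])

    ## a different master seed moves the estimates
    cfgS <- simulationConfig(snrLevels = c(20, 35), nRealizations = 48,
                             averagingFactors = 1,
                             methods = "grid_search", seed = 10L)
    expect_false(identical(runStudy(cfgS)$rmse, a$rmse))
})

test_that("a zero-noise study recovers within quantization error", {
    cfg <- simulationConfig(snrLevels = Inf, nRealizations = 8,
                            averagingFactors = 1,
                            methods = c("grid_search", "one_step"),
                            seed = 2L)
    tab <- runStudy(cfg)
    grid <- tab[tab$method == "grid_search", ]
    ## grid search: quantization only (D* log-grid step is ~3.1%)
    expect_true(all(grid$rmse <= 4))
    one <- tab[tab$method == "one_step", ]
    expect_true(all(one$rmse < 0.02))
})

test_that("averaging 64 realizations improves every parameter", {
    cfg <- simulationConfig(snrLevels = 20, nRealizations = 1728,
                            averagingFactors = c(1, 64),
                            methods = "grid_search", seed = 13L)
    tab <- runStudy(cfg)
    for (pn in c("s0", "f", "dstar", "d")) {
        r1 <- tab$rmse[tab$parameter == pn & tab$averaging == 1]
        r64 <- tab$rmse[tab$parameter == pn & tab$averaging == 64]
        expect_lt(r64, r1)
    }
    ## S0 improvement lies between the 1/sqrt(k) and 1/k regimes
    s1 <- tab$rmse[tab$parameter == "s0" & tab$averaging == 1]
    s64 <- tab$rmse[tab$parameter == "s0" & tab$averaging == 64]
    expect_lt(s64, s1 / sqrt(64) * 1.5)
    expect_gt(s64, s1 / 64 / 1.5)
    ## bookkeeping of the effective sample size
    expect_identical(unique(tab$nEffective[tab$averaging == 64]), 27L)
})

test_that("the RMSE table exports in the report layout", {
    cfg <- simulationConfig(snrLevels = 20, nRealizations = 216,
                            averagingFactors = c(1, 8, 27),
                            methods = c("grid_search", "segmented",
                                        "one_step"), seed = 3L)
    tab <- runStudy(cfg)
    layout <- exportRMSETable(tab, 20)
    expect_identical(nrow(layout), 12L)  # 3 blocks x 4 parameters
    expect_identical(colnames(layout),
                     c("averaging", "parameter", "grid_search",
                       "segmented", "one_step"))
    expect_identical(layout$averaging[1], "single voxel")
    expect_true(all(is.finite(as.matrix(layout[, 3:5]))))

    ## single-method table: one value column, 4 rows per block
    cfg1 <- simulationConfig(snrLevels = 20, nRealizations = 32,
                             averagingFactors = 1,
                             methods = "grid_search", seed = 3L)
    lay1 <- exportRMSETable(runStudy(cfg1), 20)
    expect_identical(dim(lay1), c(4L, 3L))

    expect_error(exportRMSETable(tab, 99), "available")
    expect_error(exportRMSETable(tab[0, ], 20), "empty|available")

    ## CSV round trip
    f <- tempfile(fileext = ".csv")
    exportRMSETable(tab, 20, f)
    expect_true(file.exists(f))
    expect_identical(nrow(utils::read.csv(f)), 12L)
})

test_that("the converged-only companion table is emitted", {
    cfg <- simulationConfig(snrLevels = 18, nRealizations = 24,
                            averagingFactors = 1, methods = "one_step",
                            seed = 23L)
    tab <- runStudy(cfg)
    conv <- attr(tab, "convergedOnly")
    expect_false(is.null(conv))
    expect_true(all(conv$nEffective <= tab$nEffective[1]))
})

test_that("RMSE-vs-SNR plotting builds and writes figures", {
    cfg <- simulationConfig(snrLevels = c(20, 30, 40), nRealizations = 16,
                            averagingFactors = 1, methods = "grid_search",
                            seed = 5L)
    tab <- runStudy(cfg)
    p <- plotRMSEvsSNR(tab, 1)
    expect_s3_class(p, "ggplot")
    f <- tempfile(fileext = ".png")
    plotRMSEvsSNR(tab, 1, f)
    expect_true(file.exists(f) && file.size(f) > 0)
    expect_error(plotRMSEvsSNR(tab, 27), "not present")

    ## degenerate single-SNR table still builds
    cfg1 <- simulationConfig(snrLevels = 20, nRealizations = 8,
                             averagingFactors = 1,
                             methods = "grid_search", seed = 5L)
    expect_s3_class(plotRMSEvsSNR(runStudy(cfg1), 1), "ggplot")
})

test_that("configuration validation guards incompatible settings", {
    expect_error(simulationConfig(nRealizations = 100,
                                  averagingFactors = c(1, 27)),
                 "divisible")
    expect_error(simulationConfig(methods = "magic"), "methods")
    expect_error(simulationConfig(snrLevels = c(-2, 20)), "positive")
})
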