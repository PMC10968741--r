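## Independent brute-force oracles and small shared fixtures.
## The oracles deliberately use plain nested loops and the naive SSE
## formula so they share no code path with the package's vectorized
## grid search.

## Exhaustive least-squares mono-exponential grid fit, naive triple loop.
## Strict '<' keeps the first minimum: ties break to smallest d (outer
## loop ascending), then smallest s0 (inner loop ascending).
bruteForceGridFit <- function(signal, b, s0Grid, dGrid) {
    best <- Inf
    bestS0 <- NA_real_
    bestD <- NA_real_
    for (d in dGrid) {
        e <- exp(-d * b)
        for (s0v in s0Grid) {
            sse <- sum((signal - s0v * e)^2)
            if (sse < best) {
                best <- sse
                bestS0 <- s0v
                bestD <- d
            }
        }
    }
    list(s0 = bestS0, d = bestD, sse = best)
}

## Two-stage brute force mirroring the segmented grid-search definition.
bruteForceSegmented <- function(signal, b, grids, threshold = 250) {
    high <- b > threshold
    low <- b < threshold
    st1 <- bruteForceGridFit(signal[high], b[high], grids@s0SlowGrid,
                             grids@dGrid)
    r <- signal[low] - st1$s0 * exp(-st1$d * b[low])
    st2 <- bruteForceGridFit(r, b[low], grids@s0FastGrid, grids@dStarGrid)
    tot <- st1$s0 + st2$s0
    c(s0 = tot, f = if (tot > 0) st2$s0 / tot else 0, dstar = st2$d,
      d = st1$d)
}

## Small grids keep exhaustive checks quick while containing the exact
## ground-truth decomposition S0_slow = 0.88, S0_fast = 0.12.
smallGrids <- function() {
    gridSpec(s0SlowGrid = seq(0.4, 1.2, by = 0.04),
             dGrid = seq(2e-4, 2e-3, by = 1e-4),
             s0FastGrid = seq(0, 0.4, by = 0.02),
             dStarGrid = exp(seq(log(2e-3), log(0.05), length.out = 18)))
}

groundTruthParams <- function() IVIMParams(1, 0.12, 0.01, 0.001)

## One noisy realization matrix at a given SNR from the default setup.
noisyRealizations <- function(n, snr = 20, seed = 42L) {
    clean <- cleanSignalSet(groundTruthParams(), defaultScheme(), n)
    addRicianNoise(clean, noiseSpec(snr, seed = seed))
}
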