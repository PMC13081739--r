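# shared fixtures built in code

S1 <- keySequence(c(4, 7, 3, 8, 6, 2, 5, 1))
S2_COMP <- keySequence(c(4, 7, 2, 8, 6, 3, 5, 1))
S2_INCOMP <- keySequence(c(8, 6, 3, 5, 1, 4, 7, 2))

# TPatternSet straight from an array, bypassing the GLM
makeTps <- function(arr, roi = "roi", subject = "sub-01", group = "COMP") {
    new("TPatternSet", t = arr, roiName = roi, subject = subject,
        group = group, centered = FALSE)
}

# random patterns: stable condition component (SD stableSd) plus
# independent run noise (SD runSd)
randomTps <- function(nVoxels, nRuns, stableSd = 0, runSd = 1, ...) {
    stable <- matrix(rnorm(nVoxels * 8, 0, stableSd), nVoxels, 8)
    arr <- array(rnorm(nVoxels * 8 * nRuns, 0, runSd),
                 c(nVoxels, 8, nRuns)) + as.vector(stable)
    makeTps(arr, ...)
}

# scanner-style timeline for the compatible sequence
scannerTimeline <- function(seed = 1, runId = 1) {
    buildTimeline(S2_COMP, repetitions = 12, rsi = c(1.5, 2.5),
                  restCount = 3, restDuration = 10, runId = runId,
                  seed = seed)
}

# small pipeline configuration used by pipeline-level tests
tinyConfig <- function(nPerGroup = 3L, nVoxels = 16L, seed = 1L, ...) {
    pipelineConfig(sim = simulationConfig(nPerGroup = nPerGroup,
                                          nVoxels = nVoxels, seed = seed),
                   seed = seed, ...)
}

# from-scratch cell-means sums-of-squares oracle for the mixed design
anovaOracle <- function(Y, group) {
    group <- factor(group)
    N <- nrow(Y); w <- ncol(Y); g <- nlevels(group)
    grand <- mean(Y)
    ssG <- 0
    for (lev in levels(group))
        ssG <- ssG + sum(group == lev) * w *
            (mean(Y[group == lev, ]) - grand)^2
    ssS <- 0
    for (i in 1:N)
        ssS <- ssS + w * (mean(Y[i, ]) - mean(Y[group == group[i], ]))^2
    ssW <- 0
    for (c in 1:w) ssW <- ssW + N * (mean(Y[, c]) - grand)^2
    ssI <- 0
    for (lev in levels(group)) for (c in 1:w) {
        cell <- mean(Y[group == lev, c])
        ssI <- ssI + sum(group == lev) *
            (cell - mean(Y[group == lev, ]) - mean(Y[, c]) + grand)^2
    }
    # residual: per observation deviation from cell mean and subject effect
    ssE <- 0
    for (i in 1:N) for (c in 1:w) {
        cell <- mean(Y[group == group[i], c])
        subjDev <- mean(Y[i, ]) - mean(Y[group == group[i], ])
        ssE <- ssE + (Y[i, c] - cell - subjDev)^2
    }
    list(ssG = ssG, ssS = ssS, ssW = ssW, ssI = ssI, ssE = ssE,
         fG = (ssG / (g - 1)) / (ssS / (N - g)),
         fW = (ssW / (w - 1)) / (ssE / ((N - g) * (w - 1))),
         fI = (ssI / ((g - 1) * (w - 1))) / (ssE / ((N - g) * (w - 1))))
}
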