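#' Simulation configuration
#'
#' Parameters of the synthetic multivoxel / BOLD / behavioural generator.
#' The defaults mirror the study design being emulated: two groups of 30
#' subjects, 8 scanner runs of 96 cues (12 cycles of the 8-element sequence)
#' with three 10-s rest periods, TR = 2 s, and a jittered 1.5-2.5 s
#' response-to-stimulus interval. Pattern amplitudes are in arbitrary units
#' relative to \code{runSd} (the SD of the run-specific pattern perturbation)
#' and \code{sigmaNoise} (the scanner noise SD).
#'
#' The amplitude structure encodes the effects the analysis is designed to
#' detect: shared key tuning (\code{ampKey}) and ordinal-position tuning
#' (\code{ampOrd}); extra pattern reliability at the sequence edges,
#' positions I and VIII (\code{ampEdge}); a compatible-group-specific
#' reliability boost at positions II-IV, around the first novel element
#' (\code{ampCompNovel}); and an incompatible-group-specific boost at
#' position I (\code{ampIncompFirst}). Each boost adds a zero-mean
#' condition-specific stable pattern component with SD equal to the
#' amplitude, so expected univariate mean activity is identical across
#' conditions and the effects are purely multivariate.
#'
#' @param nPerGroup subjects per group (default 30).
#' @param nVoxels voxels per ROI (default 60).
#' @param nRuns scanner runs (default 8).
#' @param tr repetition time, seconds (default 2).
#' @param ampKey,ampOrd key- and ordinal-tuning pattern SDs (a.u.).
#' @param ampEdge edge-reliability boost SD at positions I and VIII.
#' @param ampCompNovel compatible-group boost SD at positions II-IV.
#' @param ampIncompFirst incompatible-group boost SD at position I.
#' @param runSd SD of the run-specific pattern perturbation (a.u.).
#' @param sigmaNoise scanner noise SD (a.u.).
#' @param ar1Phi AR(1) coefficient of the scanner noise, in [0, 1).
#' @param driftAmp amplitude of the low-frequency scanner drift (two cosines
#'   with periods above the 128 s high-pass cutoff).
#' @param repetitions sequence cycles per scanner run (default 12).
#' @param restCount,restDuration rest periods per run (default 3 x 10 s).
#' @param rsi jittered RSI bounds, seconds (default c(1.5, 2.5)).
#' @param seed integer seed.
#' @return a list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nPerGroup = 30L, nVoxels = 60L, nRuns = 8L,
                             tr = 2, ampKey = 0.5, ampOrd = 0.5,
                             ampEdge = 1, ampCompNovel = 1.2,
                             ampIncompFirst = 1.2, runSd = 1,
                             sigmaNoise = 1, ar1Phi = 0.3, driftAmp = 1,
                             repetitions = 12L, restCount = 3L,
                             restDuration = 10, rsi = c(1.5, 2.5),
                             seed = 1L) {
    cfg <- list(nPerGroup = as.integer(nPerGroup),
                nVoxels = as.integer(nVoxels), nRuns = as.integer(nRuns),
                tr = tr, ampKey = ampKey, ampOrd = ampOrd, ampEdge = ampEdge,
                ampCompNovel = ampCompNovel, ampIncompFirst = ampIncompFirst,
                runSd = runSd, sigmaNoise = sigmaNoise, ar1Phi = ar1Phi,
                driftAmp = driftAmp, repetitions = as.integer(repetitions),
                restCount = as.integer(restCount),
                restDuration = restDuration, rsi = rsi,
                seed = as.integer(seed))
    amps <- c(cfg$ampKey, cfg$ampOrd, cfg$ampEdge, cfg$ampCompNovel,
              cfg$ampIncompFirst, cfg$runSd, cfg$sigmaNoise, cfg$driftAmp)
    if (any(amps < 0)) stop("all amplitudes must be >= 0")
    if (cfg$ar1Phi < 0 || cfg$ar1Phi >= 1) stop("ar1Phi must be in [0, 1)")
    if (cfg$nVoxels < 2L) stop("nVoxels must be >= 2")
    class(cfg) <- "simulationConfig"
    cfg
}

# positions receiving group-specific reliability boosts
.boostPositions <- function(group) {
    switch(group,
           COMP = 2:4,      # around the first novel element
           INCOMP = 1L,     # first sequence element
           integer(0))
}

#' Ground-truth multivoxel patterns for one subject and ROI
#'
#' The stable (run-invariant) pattern of condition c is a sum of independent
#' zero-mean Gaussian voxel patterns: key tuning (shared across conditions
#' with the same key), ordinal tuning, an edge component at positions I and
#' VIII, and the group-specific boosts. The run-specific perturbation is
#' iid Gaussian per voxel/condition/run with SD \code{runSd}, so the
#' split-half reliability of condition c is
#' \eqn{amp_c^2 / (amp_c^2 + runSd^2)} with \eqn{amp_c^2} the total stable
#' variance of that condition.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param group "COMP" or "INCOMP".
#' @param seq a \linkS4class{KeySequence} mapping ordinal positions to keys
#'   (defaults to the group's study sequence).
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return list with \code{stablePattern} (voxels x 8), \code{runSd}
#'   (per-condition SD of the run perturbation), \code{group}, \code{seq}.
#' @export
makeGroundTruth <- function(config, group = c("COMP", "INCOMP"),
                            seq = NULL, seed = config$seed) {
    group <- match.arg(group)
    if (is.null(seq)) {
        sq <- studySequences()
        seq <- if (group == "COMP") sq$comp else sq$incomp
    }
    set.seed(as.integer(seed))
    V <- config$nVoxels
    keyBasis <- matrix(stats::rnorm(V * 8L), V, 8L)   # one pattern per key
    ordBasis <- matrix(stats::rnorm(V * 8L), V, 8L)   # one per position
    stable <- matrix(0, V, 8L)
    kv <- keys(seq)
    for (c in 1:8)
        stable[, c] <- config$ampKey * keyBasis[, kv[c]] +
            config$ampOrd * ordBasis[, c]
    for (c in c(1L, 8L))
        stable[, c] <- stable[, c] + config$ampEdge * stats::rnorm(V)
    boostAmp <- if (group == "COMP") config$ampCompNovel else config$ampIncompFirst
    for (c in .boostPositions(group))
        stable[, c] <- stable[, c] + boostAmp * stats::rnorm(V)
    list(stablePattern = stable, runSd = rep(config$runSd, 8L),
         group = group, seq = seq)
}

#' Simulate one BOLD run from ground-truth patterns
#'
#' Each cue of condition c contributes the condition's (stable +
#' run-specific) voxel amplitudes, convolved with the canonical HRF on a
#' 16-bins-per-TR microtime grid. Additive noise is AR(1)-filtered Gaussian
#' with marginal SD \code{sigmaNoise}, plus a slow drift made of two cosines
#' with periods above the high-pass cutoff. Scan length is the last event
#' end plus a 16 s tail.
#'
#' @param truth output of \code{\link{makeGroundTruth}}.
#' @param timeline an \linkS4class{EventTimeline} whose cues carry ordinal
#'   positions 1-8.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @param regressors optional precomputed HRF-convolved condition regressor
#'   matrix for this timeline (timepoints x 8), e.g. the condition columns
#'   of an already-built design matrix.
#' @return list with \code{data} (timepoints x voxels), \code{tr},
#'   \code{timeline}, and \code{amplitudes} (the voxels x 8 matrix actually
#'   used, stable + run perturbation).
#' @export
simulateBoldRun <- function(truth, timeline, config, seed = config$seed,
                            regressors = NULL) {
    ev <- events(timeline)
    if (!any(ev$event_type == "cue")) stop("timeline contains no cue events")
    set.seed(as.integer(seed))
    V <- nrow(truth$stablePattern)
    nT <- scanLength(timeline, config$tr)
    amps <- truth$stablePattern +
        matrix(stats::rnorm(V * 8L), V, 8L) *
            rep(truth$runSd, each = V)
    X <- if (is.null(regressors)) conditionRegressors(timeline, config$tr, nT)
         else regressors
    signal <- X %*% t(amps)
    noise <- matrix(0, nT, V)
    if (config$sigmaNoise > 0) {
        innov <- matrix(stats::rnorm(nT * V), nT, V)
        phi <- config$ar1Phi
        noise <- if (phi > 0) {
            matrix(stats::filter(innov, phi, method = "recursive"), nT, V)
        } else innov
        noise <- noise * config$sigmaNoise * sqrt(1 - phi^2)
    }
    drift <- 0
    if (config$driftAmp > 0) {
        tt <- (seq_len(nT) - 1L) * config$tr
        p1 <- 2 * nT * config$tr       # periods below 1/128 Hz equivalent
        p2 <- nT * config$tr
        ph <- stats::runif(2L, 0, 2 * pi)
        drift <- config$driftAmp *
            (cos(2 * pi * tt / p1 + ph[1L]) + cos(2 * pi * tt / p2 + ph[2L]))
    }
    list(data = signal + noise + drift, tr = config$tr,
         timeline = timeline, amplitudes = amps)
}

#' Simulate block-level behavioural data for one subject
#'
#' Response time follows an exponential learning curve over the cumulative
#' block index, RT(b) = asymptote + gain * exp(-rate * b), plus a subject
#' offset, a section-specific group offset (the incompatible group is slower
#' at the session-2 pre-test), and Gaussian block noise. Accuracy is high
#' and stable. Section block counts follow the study design: 4 random,
#' 20 training, 2 slow, 4 test (session 1); 4 pre-test, 8 scanner runs,
#' 8 post-test (session 2).
#'
#' @param config a \code{\link{simulationConfig}} (only the seed is used by
#'   default).
#' @param group "COMP" or "INCOMP".
#' @param subject subject label.
#' @param asymptote,gain,rate exponential learning-curve parameters
#'   (seconds, seconds, per block).
#' @param subjectSd SD of the subject-level RT offset (seconds).
#' @param noiseSd SD of per-block RT noise (seconds).
#' @param pretestOffset group RT offset (seconds) added for the INCOMP group
#'   during the pre-test section; default equals one subject-level SD.
#' @param accuracyMean,accuracySd accuracy level and block noise (percent).
#' @param seed integer seed.
#' @return data.frame with columns subject, group, section, block, mean_rt,
#'   accuracy.
#' @export
simulateBehavior <- function(config, group = c("COMP", "INCOMP"),
                             subject = "sub-01", asymptote = 0.35,
                             gain = 0.25, rate = 0.15, subjectSd = 0.05,
                             noiseSd = 0.02, pretestOffset = 0.05,
                             accuracyMean = 97.5, accuracySd = 1,
                             seed = config$seed) {
    group <- match.arg(group)
    set.seed(as.integer(seed))
    sections <- c(random = 4L, training = 20L, slow = 2L, test = 4L,
                  pretest = 4L, mri = 8L, posttest = 8L)
    subjOff <- stats::rnorm(1L, 0, subjectSd)
    rows <- list()
    b <- 0L
    for (s in names(sections)) {
        nb <- sections[[s]]
        blocks <- seq_len(nb)
        if (s == "random") {
            rt <- asymptote + gain + subjOff +
                stats::rnorm(nb, 0, noiseSd)   # no sequence learning
        } else {
            rt <- asymptote + gain * exp(-rate * (b + blocks)) + subjOff +
                stats::rnorm(nb, 0, noiseSd)
            b <- b + nb
        }
        if (s == "pretest" && group == "INCOMP") rt <- rt + pretestOffset
        acc <- pmin(100, pmax(0, accuracyMean + stats::rnorm(nb, 0, accuracySd)))
        rows[[s]] <- data.frame(subject = subject, group = group,
                                section = s, block = blocks,
                                mean_rt = rt, accuracy = acc)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write simulated ROI data to a portable container
#'
#' Long-format tab-separated t-pattern tables with a JSON sidecar describing
#' subject, group, ROI, array shape and seed; readable from any language.
#'
#' @param tps a \linkS4class{TPatternSet}.
#' @param path TSV path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @param seed seed recorded in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeTPatterns <- function(tps, path, seed = NA_integer_) {
    arr <- tValues(tps)
    d <- dim(arr)
    long <- data.frame(voxel = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                       condition = rep(rep(1:8, each = d[1L]), times = d[3L]),
                       run = rep(seq_len(d[3L]), each = d[1L] * 8L),
                       t = as.vector(arr))
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    side <- list(subject = tps@subject, group = tps@group,
                 roi = tps@roiName, n_voxels = d[1L], n_conditions = d[2L],
                 n_runs = d[3L], centered = tps@centered, seed = seed)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeTPatterns
#' @export
readTPatterns <- function(path) {
    long <- utils::read.table(path, sep = "\t", header = TRUE)
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    arr <- array(NA_real_, c(side$n_voxels, side$n_conditions, side$n_runs))
    arr[cbind(long$voxel, long$condition, long$run)] <- long$t
    new("TPatternSet", t = arr, roiName = side$roi, subject = side$subject,
        group = side$group, centered = isTRUE(side$centered))
}

#' Export a simulated run as NIfTI volumes plus an ROI mask
#'
#' Writes the time x voxel matrix as a 4-D NIfTI image (voxels laid out
#' along the first axis) together with a binary ROI mask covering them, for
#' interoperability with volumetric neuroimaging tools. Requires the RNifti
#' package.
#'
#' @param run output of \code{\link{simulateBoldRun}}.
#' @param dataPath,maskPath output file paths (.nii or .nii.gz).
#' @return invisible list of the two paths.
#' @export
writeBoldNifti <- function(run, dataPath, maskPath) {
    if (!requireNamespace("RNifti", quietly = TRUE))
        stop("the RNifti package is required for NIfTI export")
    Y <- run$data
    V <- ncol(Y); nT <- nrow(Y)
    arr <- array(0, c(V, 1L, 1L, nT))
    arr[, 1L, 1L, ] <- t(Y)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(2.5, 2.5, 2.5, run$tr)
    RNifti::writeNifti(img, dataPath)
    mask <- array(1, c(V, 1L, 1L))
    RNifti::writeNifti(RNifti::asNifti(mask), maskPath)
    invisible(list(data = dataPath, mask = maskPath))
}

#' @rdname writeBoldNifti
#' @param dataPath,maskPath paths written by \code{writeBoldNifti}.
#' @return \code{readBoldNifti}: list with \code{data} (time x voxels within
#'   the mask) and \code{tr}.
#' @export
readBoldNifti <- function(dataPath, maskPath) {
    if (!requireNamespace("RNifti", quietly = TRUE))
        stop("the RNifti package is required for NIfTI import")
    img <- RNifti::readNifti(dataPath)
    mask <- RNifti::readNifti(maskPath)
    keep <- which(as.vector(mask) > 0.5)
    d <- dim(img)
    mat <- matrix(img, prod(d[1:3]), d[4L])
    list(data = t(mat[keep, , drop = FALSE]),
         tr = RNifti::pixdim(img)[4L])
}
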