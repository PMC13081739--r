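#' @import methods
NULL

#' KeySequence: an 8-element cyclic motor sequence
#'
#' An ordered cycle of the eight key identifiers (1 = left little finger,
#' 8 = right little finger; thumbs unused) defining one serial reaction time
#' task (SRTT) sequence. The sequence is treated as a cycle: the position
#' after VIII is I.
#'
#' @slot keys integer vector of length 8, a permutation of 1:8.
#' @exportClass KeySequence
setClass("KeySequence", representation(keys = "integer"))

setValidity("KeySequence", function(object) {
    k <- object@keys
    if (length(k) != 8L)
        return("a KeySequence must have exactly 8 elements")
    if (anyNA(k) || !setequal(k, 1:8))
        return("keys must be a permutation of 1..8")
    TRUE
})

#' CompatibilityReport: position-wise overlap between two sequences
#'
#' Quantifies schema compatibility as the fraction of key/ordinal-position
#' pairings shared between two sequences.
#'
#' @slot matchedPositions integer, ordinal positions (1-8) where both
#'   sequences carry the same key.
#' @slot overlapFraction numeric in [0, 1], matched positions / 8.
#' @slot preservedPairings integer, number of matched positions.
#' @exportClass CompatibilityReport
setClass("CompatibilityReport",
    representation(matchedPositions = "integer",
                   overlapFraction = "numeric",
                   preservedPairings = "integer"))

setValidity("CompatibilityReport", function(object) {
    n <- length(object@matchedPositions)
    if (object@preservedPairings != n)
        return("preservedPairings must equal length(matchedPositions)")
    if (abs(object@overlapFraction - n / 8) > 1e-12)
        return("overlapFraction must equal preservedPairings / 8")
    TRUE
})

#' EventTimeline: cue and rest events for one run or block
#'
#' Per-run table of events with onsets (seconds from run start), durations,
#' key identity and ordinal position for cues, and the response-to-stimulus
#' interval (RSI) specification used to generate it.
#'
#' @slot events data.frame with columns onset, duration, event_type
#'   ("cue", "rest" or "rest_keypress"), key, ordinal_position,
#'   repetition_index, run_id. Non-cue rows carry NA key/position.
#' @slot rsiMode "fixed" or "jittered".
#' @slot rsiMin,rsiMax numeric, RSI bounds in seconds (equal when fixed).
#' @exportClass EventTimeline
setClass("EventTimeline",
    representation(events = "data.frame",
                   rsiMode = "character",
                   rsiMin = "numeric",
                   rsiMax = "numeric"))

setValidity("EventTimeline", function(object) {
    ev <- object@events
    need <- c("onset", "duration", "event_type", "key", "ordinal_position",
              "repetition_index", "run_id")
    if (!all(need %in% names(ev)))
        return(paste("events must have columns:", paste(need, collapse = ", ")))
    if (is.unsorted(ev$onset, strictly = TRUE))
        return("onsets must be strictly increasing")
    cues <- ev[ev$event_type == "cue", ]
    if (nrow(cues) %% 8L != 0L)
        return("cue count must be a multiple of 8")
    # every consecutive group of 8 cues is one full cycle of the sequence
    if (nrow(cues) > 0L) {
        cyc <- matrix(cues$key, nrow = 8L)
        if (!all(apply(cyc, 2L, function(x) setequal(x, 1:8))))
            return("each consecutive group of 8 cues must use every key once")
    }
    if (!object@rsiMode %in% c("fixed", "jittered"))
        return("rsiMode must be 'fixed' or 'jittered'")
    TRUE
})

#' DesignMatrix: first-level GLM design for one run
#'
#' Time-by-regressor matrix with one canonical-HRF-convolved column per
#' key/ordinal-position condition, optional nuisance columns (rest-period
#' keypresses, motion), a discrete-cosine drift basis spanning periods at or
#' above the high-pass cutoff, and an intercept.
#'
#' @slot matrix numeric matrix, timepoints x regressors.
#' @slot labels character, one label per column.
#' @slot tr numeric, repetition time in seconds.
#' @slot highpassCutoff numeric, high-pass cutoff period in seconds.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
    representation(matrix = "matrix", labels = "character",
                   tr = "numeric", highpassCutoff = "numeric"))

setValidity("DesignMatrix", function(object) {
    if (ncol(object@matrix) != length(object@labels))
        return("labels must match design columns")
    if (sum(startsWith(object@labels, "cond_")) != 8L)
        return("design must contain exactly 8 condition columns")
    if (object@tr <= 0) return("tr must be positive")
    TRUE
})

#' GlmFit: per-voxel GLM estimates for one run
#'
#' @slot betas numeric matrix, regressors x voxels.
#' @slot residualVariance numeric, per-voxel residual variance.
#' @slot dof numeric, residual degrees of freedom (timepoints - rank).
#' @slot tValues numeric matrix, 8 condition regressors x voxels.
#' @slot labels character, design column labels.
#' @slot whitening character, "none" or "ar1".
#' @slot phi numeric, estimated lag-1 autocorrelation used for prewhitening
#'   (0 when whitening = "none").
#' @exportClass GlmFit
setClass("GlmFit",
    representation(betas = "matrix", residualVariance = "numeric",
                   dof = "numeric", tValues = "matrix",
                   labels = "character", whitening = "character",
                   phi = "numeric"))

#' TPatternSet: voxels x conditions x runs t-value array for one ROI
#'
#' The multivoxel pattern container feeding the representational similarity
#' analysis: one t-value vector across ROI voxels per key/ordinal-position
#' condition and run.
#'
#' @slot t numeric array, voxels x 8 conditions x runs.
#' @slot roiName,subject,group character metadata.
#' @slot centered logical, whether condition means have been removed per
#'   voxel and run.
#' @exportClass TPatternSet
setClass("TPatternSet",
    representation(t = "array", roiName = "character",
                   subject = "character", group = "character",
                   centered = "logical"))

setValidity("TPatternSet", function(object) {
    d <- dim(object@t)
    if (length(d) != 3L) return("t must be a 3-d array (voxels x conditions x runs)")
    if (d[2L] != 8L) return("t must have 8 conditions")
    if (d[3L] < 2L) return("at least 2 runs are required")
    if (d[1L] < 1L) return("ROI must contain at least one voxel")
    if (!all(is.finite(object@t))) return("t contains non-finite values")
    TRUE
})

#' SplitScheme: split-half partitions of the runs
#'
#' All subsets of floor(n/2) runs, each paired with its complement. For the
#' 8-run design this yields the 70 combinations over which split-half
#' correlations are averaged.
#'
#' @slot nRuns integer, total number of runs.
#' @slot subsets integer matrix, floor(nRuns/2) rows, one column per subset,
#'   in lexicographic order.
#' @exportClass SplitScheme
setClass("SplitScheme",
    representation(nRuns = "integer", subsets = "matrix"))

setValidity("SplitScheme", function(object) {
    n <- object@nRuns
    k <- n %/% 2L
    if (n < 2L) return("nRuns must be >= 2")
    if (nrow(object@subsets) != k)
        return("subsets must have floor(nRuns/2) rows")
    if (ncol(object@subsets) != choose(n, k))
        return("subsets must enumerate all choose(n, k) combinations")
    TRUE
})

#' SimilarityProfile: split-half similarity per ordinal position
#'
#' Eight Fisher-z similarity values (one per key/ordinal-position pairing)
#' for one subject and ROI, obtained by averaging split-half Pearson
#' correlations over all run partitions and Fisher-transforming the mean.
#'
#' @slot z numeric length 8, Fisher-z similarity per ordinal position.
#' @slot rMean numeric length 8, pre-transform mean correlations.
#' @slot nIterations integer length 8, split iterations used per condition.
#' @slot roiName,subject,group character metadata.
#' @exportClass SimilarityProfile
setClass("SimilarityProfile",
    representation(z = "numeric", rMean = "numeric",
                   nIterations = "integer", roiName = "character",
                   subject = "character", group = "character"))

setValidity("SimilarityProfile", function(object) {
    if (length(object@z) != 8L || length(object@rMean) != 8L)
        return("z and rMean must have length 8")
    if (!all(is.finite(object@z))) return("z must be finite (after clamping)")
    if (any(abs(object@z - atanh(pmin(pmax(object@rMean, -(1 - 1e-7)),
                                      1 - 1e-7))) > 1e-9))
        return("z must equal atanh(clamped rMean)")
    TRUE
})
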