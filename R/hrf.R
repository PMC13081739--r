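#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used throughout: a difference of two gamma densities
#' with response peak at 6 s, undershoot peak at 16 s, unit dispersions and
#' a peak-to-undershoot ratio of 6, rescaled so its maximum is 1. This is
#' the dominant convention for event-related BOLD modelling.
#'
#' @param t numeric vector of times in seconds (values < 0 return 0).
#' @param peak time-to-peak of the positive lobe (shape of the first gamma;
#'   rate 1), default 6.
#' @param undershoot shape of the undershoot gamma, default 16.
#' @param ratio peak-to-undershoot amplitude ratio, default 6.
#' @return numeric vector, HRF values with maximum 1.
#' @examples
#' h <- canonicalHrf(seq(0, 32, by = 0.1))
#' @export
canonicalHrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
    h <- stats::dgamma(t, shape = peak, rate = 1) -
        stats::dgamma(t, shape = undershoot, rate = 1) / ratio
    h[t < 0] <- 0
    h / .hrfPeakValue(peak, undershoot, ratio)
}

# dense-grid maximum used to normalize the HRF to peak 1; memoized since the
# shape parameters rarely change
.hrfCache <- new.env(parent = emptyenv())
.hrfPeakValue <- function(peak, undershoot, ratio) {
    key <- paste(peak, undershoot, ratio, sep = "|")
    if (is.null(.hrfCache[[key]])) {
        tg <- seq(0, 32, by = 1 / 256)
        hg <- stats::dgamma(tg, shape = peak, rate = 1) -
            stats::dgamma(tg, shape = undershoot, rate = 1) / ratio
        .hrfCache[[key]] <- max(hg)
    }
    .hrfCache[[key]]
}

# HRF-convolved condition regressors sampled on the TR grid.
# Events are unit impulses at cue onsets on a microtime grid (microtime bins
# per TR), convolved with the canonical HRF and sampled at the first
# microtime bin of each TR. Shared by the BOLD simulator and the design
# matrix builder so that noiseless recovery is exact.
conditionRegressors <- function(timeline, tr, nTimepoints, microtime = 16L,
                                conditions = 1:8) {
    ev <- events(timeline)
    cues <- ev[ev$event_type == "cue", ]
    dt <- tr / microtime
    nMicro <- nTimepoints * microtime
    hk <- canonicalHrf(seq(0, 32, by = dt))
    sampleIdx <- (seq_len(nTimepoints) - 1L) * microtime + 1L
    out <- matrix(0, nTimepoints, length(conditions))
    for (j in seq_along(conditions)) {
        on <- cues$onset[cues$ordinal_position == conditions[j]]
        if (length(on) == 0L) next
        x <- numeric(nMicro)
        for (o in on) {
            i0 <- floor(o / dt) + 1L
            idx <- i0:min(nMicro, i0 + length(hk) - 1L)
            x[idx] <- x[idx] + hk[seq_along(idx)]
        }
        out[, j] <- x[sampleIdx]
    }
    colnames(out) <- paste0("cond_", conditions)
    out
}

# impulse regressor for arbitrary onsets (nuisance events)
impulseRegressor <- function(onsets, tr, nTimepoints, microtime = 16L) {
    dt <- tr / microtime
    nMicro <- nTimepoints * microtime
    hk <- canonicalHrf(seq(0, 32, by = dt))
    x <- numeric(nMicro)
    for (o in onsets) {
        i0 <- floor(o / dt) + 1L
        idx <- i0:min(nMicro, i0 + length(hk) - 1L)
        x[idx] <- x[idx] + hk[seq_along(idx)]
    }
    x[(seq_len(nTimepoints) - 1L) * microtime + 1L]
}

# discrete-cosine drift basis spanning periods >= cutoff (excluding the
# constant, which is the intercept)
dctDriftBasis <- function(nTimepoints, tr, cutoff = 128) {
    K <- floor(2 * nTimepoints * tr / cutoff)
    if (K < 1L) return(matrix(numeric(0), nTimepoints, 0))
    tt <- seq_len(nTimepoints) - 1L
    B <- sapply(seq_len(K), function(k)
        cos(pi * k * (2 * tt + 1) / (2 * nTimepoints)))
    B <- matrix(B, nTimepoints, K)
    colnames(B) <- paste0("drift_", seq_len(K))
    B
}

# number of scan timepoints for a timeline: last event end + 16 s tail
scanLength <- function(timeline, tr) {
    ev <- events(timeline)
    as.integer(ceiling((max(ev$onset + ev$duration) + 16) / tr))
}
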