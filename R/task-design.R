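#' Construct a KeySequence
#'
#' @param keys integer vector of length 8; a permutation of 1:8 where 1 is the
#'   left little finger and 8 the right little finger.
#' @return a \linkS4class{KeySequence}.
#' @examples
#' s1 <- keySequence(c(4, 7, 3, 8, 6, 2, 5, 1))
#' @export
keySequence <- function(keys) {
    keys <- as.integer(keys)
    new("KeySequence", keys = keys)
}

#' @describeIn keySequence accessor for the key vector.
#' @param x a KeySequence.
#' @export
setMethod("keys", "KeySequence", function(x) x@keys)

setMethod("show", "KeySequence", function(object) {
    cat("KeySequence:", paste(object@keys, collapse = "-"), "\n")
})

#' Swap two keys throughout a sequence
#'
#' Every occurrence of key \code{a} becomes \code{b} and vice versa; this is
#' how the second-session sequence is derived from the first (the two swapped
#' keys are the "novel" keys).
#'
#' @param x a \linkS4class{KeySequence}.
#' @param a,b key identifiers in 1..8.
#' @return a new \linkS4class{KeySequence}; the input is unmodified.
#' @examples
#' s1 <- keySequence(c(4, 7, 3, 8, 6, 2, 5, 1))
#' keys(swapKeys(s1, 2, 3))  # 4 7 2 8 6 3 5 1
#' @export
setMethod("swapKeys", "KeySequence", function(x, a, b) {
    a <- as.integer(a); b <- as.integer(b)
    if (length(a) != 1L || length(b) != 1L || anyNA(c(a, b)) ||
        !all(c(a, b) %in% 1:8))
        stop("key identifiers must be single integers in 1..8")
    k <- x@keys
    k2 <- k
    k2[k == a] <- b
    k2[k == b] <- a
    keySequence(k2)
})

#' Rotate a sequence (change its starting point)
#'
#' Cyclic rotation: element at cyclic index \code{i + offset} of the input
#' becomes element \code{i} of the output. Changing the starting point is the
#' schema-compatibility manipulation that distinguishes the two groups.
#'
#' @param x a \linkS4class{KeySequence}.
#' @param offset any integer, taken modulo 8.
#' @return a rotated \linkS4class{KeySequence}.
#' @examples
#' s2 <- keySequence(c(4, 7, 2, 8, 6, 3, 5, 1))
#' keys(rotateSequence(s2, 3))  # 8 6 3 5 1 4 7 2
#' @export
setMethod("rotateSequence", "KeySequence", function(x, offset) {
    off <- as.integer(offset) %% 8L
    idx <- ((seq_len(8L) - 1L + off) %% 8L) + 1L
    keySequence(x@keys[idx])
})

#' Ordinal overlap (schema compatibility) between two sequences
#'
#' Counts the ordinal positions at which both sequences carry the same key,
#' i.e. the key/ordinal-position pairings preserved between them. The overlap
#' fraction is the field's schema-compatibility measure.
#'
#' @param x,y \linkS4class{KeySequence} objects.
#' @return a \linkS4class{CompatibilityReport}.
#' @examples
#' s1 <- keySequence(c(4, 7, 3, 8, 6, 2, 5, 1))
#' comp <- swapKeys(s1, 2, 3)
#' ordinalOverlap(comp, s1)  # 75% overlap
#' @export
setMethod("ordinalOverlap", signature("KeySequence", "KeySequence"),
    function(x, y) {
        m <- which(x@keys == y@keys)
        new("CompatibilityReport",
            matchedPositions = as.integer(m),
            overlapFraction = length(m) / 8,
            preservedPairings = length(m))
    })

setMethod("show", "CompatibilityReport", function(object) {
    cat("CompatibilityReport:", object@preservedPairings,
        "preserved key/position pairings (",
        sprintf("%.1f%%", 100 * object@overlapFraction), ")\n")
    if (object@preservedPairings > 0L)
        cat("  matched ordinal positions:",
            paste(object@matchedPositions, collapse = ", "), "\n")
})

#' @describeIn ordinalOverlap overlap fraction accessor.
#' @param report a CompatibilityReport.
#' @export
overlapFraction <- function(report) report@overlapFraction

#' @describeIn ordinalOverlap matched ordinal positions accessor.
#' @export
matchedPositions <- function(report) report@matchedPositions

#' Build an event timeline for one run or block
#'
#' Generates the cue/rest event table for a run of the sequential SRTT.
#' Cues follow full cycles of the sequence; rest periods are inserted at
#' randomly chosen sequence-repetition boundaries (never after the final
#' repetition) or appended at the end of the block.
#'
#' In the scanner the response-to-stimulus interval (RSI) is jittered
#' uniformly within \code{rsi} bounds, so the drawn value is used directly as
#' the cue-to-cue interval. With a fixed RSI (out-of-scanner, self-paced
#' blocks where RSI may be 0) a nominal response time \code{soaBase} is added
#' so that onsets remain strictly increasing.
#'
#' @param seq a \linkS4class{KeySequence}.
#' @param repetitions number of full sequence cycles (12 for scanner runs,
#'   8 for out-of-scanner blocks).
#' @param rsi either a single number (fixed RSI, seconds) or a length-2
#'   vector \code{c(min, max)} for uniform jitter (1.5-2.5 s in the scanner).
#' @param restCount number of rest periods to insert (3 for scanner runs).
#' @param restDuration rest duration in seconds (10 in the scanner, 15 for
#'   out-of-scanner blocks).
#' @param restPlacement "between" (random repetition boundaries) or "end"
#'   (a single trailing rest after the block).
#' @param runId integer run/block identifier stored with each event.
#' @param soaBase nominal response time (seconds) added to fixed RSIs.
#' @param seed integer seed; the timeline is deterministic given the seed.
#' @return an \linkS4class{EventTimeline}.
#' @examples
#' s2 <- keySequence(c(4, 7, 2, 8, 6, 3, 5, 1))
#' tl <- buildTimeline(s2, repetitions = 12, rsi = c(1.5, 2.5),
#'                     restCount = 3, restDuration = 10, seed = 1)
#' nCues(tl)  # 96
#' @export
buildTimeline <- function(seq, repetitions, rsi = c(1.5, 2.5),
                          restCount = 0L, restDuration = 10,
                          restPlacement = c("between", "end"),
                          runId = 1L, soaBase = 0.5, seed = NULL) {
    stopifnot(is(seq, "KeySequence"))
    repetitions <- as.integer(repetitions)
    if (repetitions < 1L) stop("repetitions must be >= 1")
    restPlacement <- match.arg(restPlacement)
    restCount <- as.integer(restCount)
    if (restPlacement == "between" && restCount >= repetitions)
        stop("config error: restCount must be smaller than repetitions")
    if (!is.null(seed)) set.seed(as.integer(seed))

    jittered <- length(rsi) == 2L && rsi[2L] > rsi[1L]
    nCue <- 8L * repetitions
    gaps <- if (jittered) {
        stats::runif(nCue, rsi[1L], rsi[2L])
    } else {
        rep(rsi[1L] + soaBase, nCue)
    }

    restAfterRep <- integer(0)
    if (restCount > 0L && restPlacement == "between") {
        # boundaries between repetitions r and r+1, excluding the final one
        restAfterRep <- sort(sample(seq_len(repetitions - 1L), restCount))
    }

    kseq <- rep(seq@keys, repetitions)
    ords <- rep(1:8, repetitions)
    reps <- rep(seq_len(repetitions), each = 8L)

    onset <- numeric(0); duration <- numeric(0); etype <- character(0)
    key <- integer(0); ordp <- integer(0); ridx <- integer(0)
    t <- 0
    for (i in seq_len(nCue)) {
        onset <- c(onset, t); duration <- c(duration, 0)
        etype <- c(etype, "cue"); key <- c(key, kseq[i])
        ordp <- c(ordp, ords[i]); ridx <- c(ridx, reps[i])
        t <- t + gaps[i]
        if (i %% 8L == 0L && (i %/% 8L) %in% restAfterRep) {
            onset <- c(onset, t); duration <- c(duration, restDuration)
            etype <- c(etype, "rest"); key <- c(key, NA_integer_)
            ordp <- c(ordp, NA_integer_); ridx <- c(ridx, reps[i])
            t <- t + restDuration
        }
    }
    if (restCount > 0L && restPlacement == "end") {
        for (j in seq_len(restCount)) {
            onset <- c(onset, t); duration <- c(duration, restDuration)
            etype <- c(etype, "rest"); key <- c(key, NA_integer_)
            ordp <- c(ordp, NA_integer_); ridx <- c(ridx, repetitions)
            t <- t + restDuration
        }
    }

    ev <- data.frame(onset = onset, duration = duration, event_type = etype,
                     key = key, ordinal_position = ordp,
                     repetition_index = ridx, run_id = as.integer(runId))
    new("EventTimeline", events = ev,
        rsiMode = if (jittered) "jittered" else "fixed",
        rsiMin = rsi[1L], rsiMax = if (jittered) rsi[2L] else rsi[1L])
}

#' @describeIn buildTimeline event table accessor.
#' @param x an EventTimeline.
#' @export
setMethod("events", "EventTimeline", function(x) x@events)

#' @export
setMethod("nCues", "EventTimeline",
    function(x) sum(x@events$event_type == "cue"))

setMethod("show", "EventTimeline", function(object) {
    ev <- object@events
    cat(sprintf("EventTimeline: %d cues, %d rests, %.1f s, RSI %s [%g, %g] s\n",
                sum(ev$event_type == "cue"), sum(ev$event_type == "rest"),
                max(ev$onset + ev$duration), object@rsiMode,
                object@rsiMin, object@rsiMax))
})

#' Write / read event tables (BIDS-events-style TSV)
#'
#' Tab-separated with columns onset, duration, event_type, key,
#' ordinal_position, repetition_index, run_id; missing values written as
#' "n/a" per the BIDS events dialect.
#'
#' @param timeline an \linkS4class{EventTimeline}.
#' @param path file path of the TSV.
#' @return \code{writeEvents} returns \code{path} invisibly;
#'   \code{readEvents} returns an \linkS4class{EventTimeline}.
#' @export
writeEvents <- function(timeline, path) {
    ev <- events(timeline)
    out <- ev
    for (cl in names(out)) {
        v <- as.character(out[[cl]])
        v[is.na(v)] <- "n/a"
        out[[cl]] <- v
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEvents
#' @param rsiMode,rsiMin,rsiMax RSI metadata to attach on read (not stored in
#'   the TSV itself).
#' @export
readEvents <- function(path, rsiMode = "jittered", rsiMin = 1.5, rsiMax = 2.5) {
    ev <- utils::read.table(path, sep = "\t", header = TRUE,
                            na.strings = "n/a", stringsAsFactors = FALSE)
    ev$key <- as.integer(ev$key)
    ev$ordinal_position <- as.integer(ev$ordinal_position)
    ev$repetition_index <- as.integer(ev$repetition_index)
    ev$run_id <- as.integer(ev$run_id)
    new("EventTimeline", events = ev, rsiMode = rsiMode,
        rsiMin = rsiMin, rsiMax = rsiMax)
}

#' Study sequence definitions
#'
#' Convenience constructor for the three sequences of the schema design:
#' the session-1 sequence, the compatible session-2 sequence obtained by
#' swapping the two novel keys, and the incompatible variant obtained by
#' additionally shifting the starting point.
#'
#' @param s1 integer vector, the session-1 sequence
#'   (default \code{c(4,7,3,8,6,2,5,1)}).
#' @param swapPair the two novel keys swapped between sessions (default 2, 3).
#' @param compOffset,incompOffset rotation offsets applied to the swapped
#'   sequence for the compatible and incompatible groups (defaults 0 and 3).
#' @return list with KeySequences \code{s1}, \code{comp}, \code{incomp} and
#'   their \linkS4class{CompatibilityReport}s vs \code{s1}.
#' @export
studySequences <- function(s1 = c(4, 7, 3, 8, 6, 2, 5, 1),
                           swapPair = c(2, 3),
                           compOffset = 0L, incompOffset = 3L) {
    s1 <- keySequence(s1)
    s2 <- swapKeys(s1, swapPair[1L], swapPair[2L])
    comp <- rotateSequence(s2, compOffset)
    incomp <- rotateSequence(s2, incompOffset)
    list(s1 = s1, comp = comp, incomp = incomp,
         compReport = ordinalOverlap(comp, s1),
         incompReport = ordinalOverlap(incomp, s1))
}
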