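#' Center t-patterns across conditions
#'
#' Per voxel and per run, subtracts the mean t-value over the eight
#' conditions, so that each voxel's condition profile is expressed relative
#' to its run mean. Centering is idempotent and removes any voxel-specific
#' run offset.
#'
#' @param x a \linkS4class{TPatternSet}.
#' @return a centered \linkS4class{TPatternSet}.
#' @export
setMethod("centerConditions", "TPatternSet", function(x) {
    arr <- x@t
    m <- apply(arr, c(1L, 3L), mean)        # voxels x runs
    arr <- sweep(arr, c(1L, 3L), m)
    initialize(x, t = arr, centered = TRUE)
})

#' Enumerate all split-half partitions of the runs
#'
#' All subsets of size floor(n/2), each paired with its complement, in
#' lexicographic order. For the 8-run design this gives the 70 combinations
#' of 8 runs divided into two groups of 4; for odd run counts (a subject
#' with an excluded run) the halves have sizes floor(n/2) and ceil(n/2).
#'
#' @param nRuns number of runs (>= 2).
#' @param k subset size, default floor(nRuns/2).
#' @return a \linkS4class{SplitScheme}.
#' @examples
#' splitCount(enumerateSplitHalves(8))  # 70
#' @export
enumerateSplitHalves <- function(nRuns, k = nRuns %/% 2L) {
    nRuns <- as.integer(nRuns)
    if (nRuns < 2L) stop("nRuns must be >= 2")
    subsets <- utils::combn(nRuns, as.integer(k))
    new("SplitScheme", nRuns = nRuns, subsets = subsets)
}

#' @describeIn enumerateSplitHalves number of enumerated subsets.
#' @param scheme a SplitScheme.
#' @export
splitCount <- function(scheme) ncol(scheme@subsets)

setMethod("show", "SplitScheme", function(object) {
    cat(sprintf("SplitScheme: %d runs, %d split-half subsets of size %d\n",
                object@nRuns, ncol(object@subsets), nrow(object@subsets)))
})

#' Split-half pattern similarity per key/ordinal-position pairing
#'
#' For every enumerated partition of the runs into two halves, t-value
#' vectors are averaged within each half, and for each condition the Pearson
#' correlation between the two averaged voxel vectors is computed.
#' Correlations are averaged across all partitions and the mean is Fisher
#' transformed (z = atanh(r), with r clamped to +/-(1 - 1e-7)), yielding one
#' similarity value per key/ordinal-position pairing.
#'
#' Conditions are mean-centered per voxel and run first (unless the input is
#' already centered). Partitions for which an averaged vector has zero
#' variance are skipped for that condition and the number of iterations
#' actually used is recorded; if every partition is skipped for some
#' condition an error is raised.
#'
#' @param x a \linkS4class{TPatternSet}.
#' @param scheme a \linkS4class{SplitScheme}; defaults to the exhaustive
#'   enumeration for the set's run count.
#' @param transform "mean-r" (default: average r across partitions, then
#'   Fisher transform) or "mean-z" (transform each partition's r, average z).
#' @param center centre conditions first (default TRUE; skipped if already
#'   centered).
#' @return a \linkS4class{SimilarityProfile}.
#' @export
patternSimilarity <- function(x, scheme = NULL,
                              transform = c("mean-r", "mean-z"),
                              center = TRUE) {
    stopifnot(is(x, "TPatternSet"))
    transform <- match.arg(transform)
    if (center && !x@centered) x <- centerConditions(x)
    arr <- x@t
    d <- dim(arr)
    V <- d[1L]; R <- d[3L]
    if (V < 2L) stop("at least 2 voxels are required")
    if (is.null(scheme)) scheme <- enumerateSplitHalves(R)
    if (scheme@nRuns != R) stop("split scheme does not match the run count")
    S <- scheme@subsets
    M <- ncol(S)
    # membership matrices: runs x subsets, for subset and complement halves
    A <- matrix(0, R, M); for (j in seq_len(M)) A[S[, j], j] <- 1
    B <- 1 - A
    A <- sweep(A, 2L, colSums(A), "/")
    B <- sweep(B, 2L, colSums(B), "/")
    TT <- matrix(arr, V * 8L, R)                 # (voxel,cond) x run
    MA <- TT %*% A                               # half means, (V*8) x M
    MB <- TT %*% B
    dim(MA) <- c(V, 8L * M); dim(MB) <- c(V, 8L * M)
    # Pearson per condition x split, vectorized over the voxel axis
    ca <- MA - rep(colMeans(MA), each = V)
    cb <- MB - rep(colMeans(MB), each = V)
    num <- colSums(ca * cb)
    den <- sqrt(colSums(ca^2) * colSums(cb^2))
    rMat <- matrix(num / den, 8L, M)             # NaN where degenerate
    rMat[matrix(den == 0, 8L, M)] <- NA_real_
    nIter <- as.integer(rowSums(!is.na(rMat)))
    if (any(nIter == 0L))
        stop("all split iterations degenerate (zero variance) for condition(s): ",
             paste(which(nIter == 0L), collapse = ", "))
    clamp <- function(r) pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    if (transform == "mean-r") {
        rMean <- rowMeans(rMat, na.rm = TRUE)
        z <- atanh(clamp(rMean))
    } else {
        z <- rowMeans(atanh(clamp(rMat)), na.rm = TRUE)
        rMean <- tanh(z)
    }
    new("SimilarityProfile", z = as.numeric(z), rMean = as.numeric(rMean),
        nIterations = nIter, roiName = x@roiName, subject = x@subject,
        group = x@group)
}

#' @export
setMethod("zValues", "SimilarityProfile", function(x) x@z)

setMethod("show", "SimilarityProfile", function(object) {
    cat(sprintf("SimilarityProfile '%s' (%s, %s)\n", object@roiName,
                object@subject, object@group))
    cat("  z:", paste(sprintf("%.3f", object@z), collapse = " "), "\n")
})

#' Edge-effect contrast
#'
#' Mean similarity of the first and last ordinal positions minus the mean of
#' the interior positions: \code{mean(z[c(1, 8)]) - mean(z[2:7])}. Positive
#' values indicate elevated pattern similarity at the sequence edges.
#'
#' @param x a \linkS4class{SimilarityProfile} or a numeric length-8 vector
#'   of z values.
#' @return scalar contrast value.
#' @export
setMethod("edgeEffectContrast", "SimilarityProfile",
    function(x) edgeEffectContrast(x@z))

#' @rdname edgeEffectContrast
#' @export
setMethod("edgeEffectContrast", "numeric", function(x) {
    if (length(x) != 8L) stop("a full 8-position profile is required")
    mean(x[c(1L, 8L)]) - mean(x[2:7])
})

#' Similarity profiles as a long table
#'
#' @param profiles list of \linkS4class{SimilarityProfile} objects.
#' @return data.frame with columns subject, group, roi, ordinal_position,
#'   z, r_mean, n_iterations.
#' @export
similarityTable <- function(profiles) {
    do.call(rbind, lapply(profiles, function(p)
        data.frame(subject = p@subject, group = p@group, roi = p@roiName,
                   ordinal_position = 1:8, z = p@z, r_mean = p@rMean,
                   n_iterations = p@nIterations)))
}

#' @rdname similarityTable
#' @param table a similarity table.
#' @param path TSV output path.
#' @export
writeSimilarityTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
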