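#' Build a first-level design matrix for one run
#'
#' One column per key/ordinal-position condition: unit impulses (0 ms
#' duration) at cue onsets on a 16-bins-per-TR microtime grid, convolved with
#' the canonical double-gamma HRF and sampled at the first microtime bin of
#' each TR. Nuisance columns are added for rest-period keypresses (only if
#' present in the timeline) and for motion parameters (if supplied), followed
#' by a discrete-cosine drift basis spanning periods at or above the
#' high-pass cutoff and an intercept.
#'
#' @param timeline an \linkS4class{EventTimeline} for the run.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @param motion optional matrix/data.frame with 6 realignment-parameter
#'   columns, one row per scan.
#' @param nTimepoints number of scans; defaults to the timeline duration plus
#'   a 16 s tail so the last haemodynamic response is sampled.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(timeline, tr, cutoff = 128, motion = NULL,
                              nTimepoints = NULL) {
    stopifnot(is(timeline, "EventTimeline"), tr > 0)
    if (is.null(nTimepoints)) nTimepoints <- scanLength(timeline, tr)
    ev <- events(timeline)
    present <- sort(unique(ev$ordinal_position[ev$event_type == "cue"]))
    missing <- setdiff(1:8, present)
    if (length(missing) > 0L)
        stop("condition(s) absent from timeline: ",
             paste(missing, collapse = ", "))
    X <- conditionRegressors(timeline, tr, nTimepoints)
    labels <- colnames(X)

    restPress <- ev$onset[ev$event_type == "rest_keypress"]
    if (length(restPress) > 0L) {
        X <- cbind(X, impulseRegressor(restPress, tr, nTimepoints))
        labels <- c(labels, "rest_keypress")
    }
    if (!is.null(motion)) {
        motion <- as.matrix(motion)
        if (nrow(motion) != nTimepoints || ncol(motion) != 6L)
            stop("motion must be a 6-column matrix with one row per scan")
        X <- cbind(X, motion)
        labels <- c(labels, paste0("motion_", 1:6))
    }
    drift <- dctDriftBasis(nTimepoints, tr, cutoff)
    if (ncol(drift) > 0L) {
        X <- cbind(X, drift)
        labels <- c(labels, colnames(drift))
    }
    X <- cbind(X, 1)
    labels <- c(labels, "intercept")
    colnames(X) <- labels
    new("DesignMatrix", matrix = X, labels = labels, tr = tr,
        highpassCutoff = cutoff)
}

setMethod("show", "DesignMatrix", function(object) {
    cat(sprintf("DesignMatrix: %d timepoints x %d regressors (tr = %g s, high-pass %g s)\n",
                nrow(object@matrix), ncol(object@matrix), object@tr,
                object@highpassCutoff))
    cat("  columns:", paste(object@labels, collapse = ", "), "\n")
})

#' @describeIn buildDesignMatrix the numeric design matrix.
#' @param design a DesignMatrix.
#' @export
designMatrix <- function(design) design@matrix

# OLS fit returning what we need; X must be full rank (checked by caller)
.olsFit <- function(X, Y, qrX = NULL) {
    if (is.null(qrX)) qrX <- qr(X)
    beta <- qr.coef(qrX, Y)
    res <- Y - X %*% beta
    dof <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / dof
    R <- qr.R(qrX)
    XtXinv <- chol2inv(R)[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
    list(beta = beta, res = res, dof = dof, sigma2 = sigma2,
         diagXtXinv = diag(XtXinv))
}

#' Fit a per-voxel GLM to one run
#'
#' Ordinary least squares per voxel. With \code{whitening = "ar1"} the lag-1
#' autocorrelation of the OLS residuals is estimated once per run (pooled over
#' voxels) and both data and design are prewhitened with the corresponding
#' first-difference transform before refitting (Cochrane-Orcutt style).
#' t-values are returned for the 8 condition columns only.
#'
#' @param data numeric matrix, timepoints x voxels (or a list with an element
#'   \code{data}, as returned by \code{\link{simulateBoldRun}}).
#' @param design a \linkS4class{DesignMatrix} with rows matching the data.
#' @param whitening "none" or "ar1".
#' @return a \linkS4class{GlmFit}.
#' @export
fitGlm <- function(data, design, whitening = c("none", "ar1")) {
    whitening <- match.arg(whitening)
    if (is.list(data) && !is.matrix(data)) data <- data$data
    Y <- as.matrix(data)
    X <- design@matrix
    if (nrow(Y) != nrow(X))
        stop("design rows (", nrow(X), ") must match data timepoints (",
             nrow(Y), ")")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- design@labels[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("design matrix is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    fit <- .olsFit(X, Y, qrX)
    phi <- 0
    if (whitening == "ar1") {
        r <- fit$res
        phi <- sum(r[-1L, , drop = FALSE] * r[-nrow(r), , drop = FALSE]) /
            sum(r^2)
        n <- nrow(X)
        Wy <- rbind(sqrt(1 - phi^2) * Y[1L, , drop = FALSE],
                    Y[-1L, , drop = FALSE] - phi * Y[-n, , drop = FALSE])
        Wx <- rbind(sqrt(1 - phi^2) * X[1L, , drop = FALSE],
                    X[-1L, , drop = FALSE] - phi * X[-n, , drop = FALSE])
        fit <- .olsFit(Wx, Wy)
    }
    condIdx <- which(startsWith(design@labels, "cond_"))
    se <- sqrt(outer(fit$diagXtXinv[condIdx], fit$sigma2))
    tv <- fit$beta[condIdx, , drop = FALSE] / se
    new("GlmFit", betas = fit$beta, residualVariance = fit$sigma2,
        dof = as.numeric(fit$dof), tValues = tv,
        labels = design@labels, whitening = whitening, phi = phi)
}

setMethod("show", "GlmFit", function(object) {
    cat(sprintf("GlmFit: %d regressors x %d voxels, dof = %g, whitening = %s (phi = %.3f)\n",
                nrow(object@betas), ncol(object@betas), object@dof,
                object@whitening, object@phi))
})

#' @describeIn fitGlm condition-regressor betas (8 x voxels).
#' @param fit a GlmFit.
#' @export
conditionBetas <- function(fit) {
    fit@betas[startsWith(fit@labels, "cond_"), , drop = FALSE]
}

#' Assemble per-run t-patterns into a TPatternSet
#'
#' Stacks the 8 condition t-vectors of each run into the voxels x conditions
#' x runs array consumed by the representational similarity analysis.
#'
#' @param fits list of \linkS4class{GlmFit} objects, one per retained run.
#' @param voxels optional integer indices selecting ROI voxels (default all).
#' @param roiName,subject,group character metadata.
#' @return a \linkS4class{TPatternSet}.
#' @export
assembleTPatterns <- function(fits, voxels = NULL, roiName = "roi",
                              subject = "sub-01", group = "COMP") {
    if (length(fits) < 2L) stop("at least 2 runs are required")
    nv <- vapply(fits, function(f) ncol(f@tValues), integer(1))
    if (length(unique(nv)) != 1L)
        stop("runs have differing voxel counts: ",
             paste(unique(nv), collapse = ", "))
    if (is.null(voxels)) voxels <- seq_len(nv[1L])
    if (length(voxels) == 0L) stop("empty ROI: no voxels selected")
    arr <- array(NA_real_, c(length(voxels), 8L, length(fits)))
    for (r in seq_along(fits))
        arr[, , r] <- t(fits[[r]]@tValues[, voxels, drop = FALSE])
    if (!all(is.finite(arr)))
        stop("non-finite t-values in assembled patterns")
    new("TPatternSet", t = arr, roiName = roiName, subject = subject,
        group = group, centered = FALSE)
}

#' @export
setMethod("tValues", "TPatternSet", function(x) x@t)

setMethod("show", "TPatternSet", function(object) {
    d <- dim(object@t)
    cat(sprintf("TPatternSet '%s' (%s, %s): %d voxels x %d conditions x %d runs%s\n",
                object@roiName, object@subject, object@group,
                d[1L], d[2L], d[3L],
                if (object@centered) ", centered" else ""))
})

#' Motion-based run exclusion screen
#'
#' A run is excluded if its maximum absolute translation exceeds 5 mm
#' (about two voxels) in any of the three directions; the comparison is a
#' strict inequality, so exactly 5.0 mm is retained.
#'
#' @param motionMax numeric matrix or data.frame, runs x 3, maximum absolute
#'   translation (mm) per axis for each run.
#' @param thresholdMm exclusion threshold in mm (default 5).
#' @return logical vector, TRUE for runs to keep.
#' @examples
#' motionScreen(rbind(c(0.4, 0.3, 0.5), c(6, 0.2, 0.1)))  # TRUE FALSE
#' @export
motionScreen <- function(motionMax, thresholdMm = 5) {
    m <- as.matrix(motionMax)
    if (ncol(m) != 3L) stop("motionMax must have three columns (x, y, z)")
    apply(abs(m), 1L, max) <= thresholdMm  # exclude only if strictly greater
}
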