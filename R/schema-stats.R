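#' Mixed two-factor ANOVA (one between-subject, one within-subject factor)
#'
#' Classical mixed-design sums-of-squares decomposition for a design with
#' one between-subject factor (group) and one within-subject factor with
#' complete data per subject: the group effect is tested against the
#' subjects-within-groups mean square, the within effect and the interaction
#' against the within-by-subjects(group) mean square. Sphericity is handled
#' with the Greenhouse-Geisser epsilon computed from the pooled
#' double-centered within-subject covariance,
#' \eqn{\epsilon_{GG} = (tr \tilde S)^2 / ((w-1)\, tr \tilde S^2)}, and the
#' multi-group Huynh-Feldt epsilon
#' \eqn{\epsilon_{HF} = ((N-g+1)(w-1)\epsilon_{GG} - 2) /
#' ((w-1)(N-g-(w-1)\epsilon_{GG}))} capped at 1. The correction actually
#' applied follows \code{\link{sphericityRule}}. Partial eta squared is
#' SS_effect / (SS_effect + SS_error).
#'
#' @param values numeric matrix, subjects x within-factor levels (complete).
#' @param group factor or character vector, one group label per subject
#'   (two or more groups; at least 2 subjects per group).
#' @return data.frame with one row per effect (\code{group}, \code{within},
#'   \code{group:within}) and columns effect, df1, df2, ss, F, p, peta2,
#'   epsGG, epsHF, epsUsed, df1Corr, df2Corr, pCorr. For the between effect
#'   the epsilon columns are NA and pCorr equals p.
#' @export
mixedAnova <- function(values, group) {
    Y <- as.matrix(values)
    if (anyNA(Y)) stop("missing cells are not supported")
    group <- factor(group)
    if (nlevels(group) < 2L) stop("at least two groups are required")
    if (any(table(group) < 2L)) stop("each group needs at least 2 subjects")
    if (nrow(Y) != length(group)) stop("group labels must match rows")
    N <- nrow(Y); w <- ncol(Y); g <- nlevels(group)

    subjMean <- rowMeans(Y)
    grand <- mean(Y)
    groupMeans <- as.numeric(tapply(subjMean, group, mean))
    nj <- as.numeric(table(group))

    # between-subject stratum
    ssGroup <- w * sum(nj * (groupMeans - grand)^2)
    ssSubj <- w * sum((subjMean - groupMeans[as.integer(group)])^2)
    dfGroup <- g - 1L
    dfSubj <- N - g

    # within-subject stratum
    colMean <- colMeans(Y)
    ssWithin <- N * sum((colMean - grand)^2)
    cellMeans <- apply(Y, 2L, function(col) tapply(col, group, mean))
    cellMeans <- matrix(cellMeans, g, w)
    ssCells <- sum(rep(nj, times = w) * (as.vector(cellMeans) - grand)^2)
    ssInter <- ssCells - ssGroup - ssWithin
    # within-by-subjects(group) residual: data minus cell mean minus
    # subject deviation from its group mean
    fitted <- cellMeans[cbind(rep(as.integer(group), times = w),
                              rep(1:w, each = N))]
    dim(fitted) <- c(N, w)
    resid <- Y - fitted - (subjMean - groupMeans[as.integer(group)])
    ssErrW <- sum(resid^2)
    dfWithin <- w - 1L
    dfInter <- (g - 1L) * (w - 1L)
    dfErrW <- (N - g) * (w - 1L)

    msGroup <- ssGroup / dfGroup; msSubj <- ssSubj / dfSubj
    msWithin <- ssWithin / dfWithin; msInter <- ssInter / dfInter
    msErrW <- ssErrW / dfErrW
    fGroup <- msGroup / msSubj
    fWithin <- msWithin / msErrW
    fInter <- msInter / msErrW

    # pooled double-centered covariance for the epsilons
    Sw <- matrix(0, w, w)
    for (lev in levels(group)) {
        Yg <- Y[group == lev, , drop = FALSE]
        Yg <- sweep(Yg, 2L, colMeans(Yg))
        Sw <- Sw + crossprod(Yg)
    }
    Sw <- Sw / (N - g)
    C <- diag(w) - 1 / w
    St <- C %*% Sw %*% C
    epsGG <- sum(diag(St))^2 / ((w - 1) * sum(St^2))
    epsHF <- ((N - g + 1) * (w - 1) * epsGG - 2) /
        ((w - 1) * (N - g - (w - 1) * epsGG))
    epsHF <- min(epsHF, 1)
    epsUsed <- sphericityRule(epsGG, epsHF)

    pGroup <- stats::pf(fGroup, dfGroup, dfSubj, lower.tail = FALSE)
    pWithin <- stats::pf(fWithin, dfWithin, dfErrW, lower.tail = FALSE)
    pInter <- stats::pf(fInter, dfInter, dfErrW, lower.tail = FALSE)
    pWithinC <- stats::pf(fWithin, dfWithin * epsUsed, dfErrW * epsUsed,
                          lower.tail = FALSE)
    pInterC <- stats::pf(fInter, dfInter * epsUsed, dfErrW * epsUsed,
                         lower.tail = FALSE)

    data.frame(
        effect = c("group", "within", "group:within"),
        df1 = c(dfGroup, dfWithin, dfInter),
        df2 = c(dfSubj, dfErrW, dfErrW),
        ss = c(ssGroup, ssWithin, ssInter),
        ssError = c(ssSubj, ssErrW, ssErrW),
        F = c(fGroup, fWithin, fInter),
        p = c(pGroup, pWithin, pInter),
        peta2 = c(ssGroup / (ssGroup + ssSubj),
                  ssWithin / (ssWithin + ssErrW),
                  ssInter / (ssInter + ssErrW)),
        epsGG = c(NA, epsGG, epsGG),
        epsHF = c(NA, epsHF, epsHF),
        epsUsed = c(NA, epsUsed, epsUsed),
        df1Corr = c(dfGroup, dfWithin * epsUsed, dfInter * epsUsed),
        df2Corr = c(dfSubj, dfErrW * epsUsed, dfErrW * epsUsed),
        pCorr = c(pGroup, pWithinC, pInterC),
        stringsAsFactors = FALSE)
}

#' Sphericity-correction selection rule
#'
#' Greenhouse-Geisser correction is applied when its epsilon is at most
#' 0.75; otherwise the Huynh-Feldt epsilon (capped at 1) is used. Corrected
#' degrees of freedom are epsilon times the uncorrected ones.
#'
#' @param epsilonGG,epsilonHF Greenhouse-Geisser and Huynh-Feldt epsilons.
#' @return the epsilon to use.
#' @examples
#' sphericityRule(0.6, 0.7)   # 0.6 (GG branch)
#' sphericityRule(0.9, 1.1)   # 1.0 (HF capped)
#' @export
sphericityRule <- function(epsilonGG, epsilonHF) {
    if (epsilonGG <= 0.75) epsilonGG else min(epsilonHF, 1)
}

#' Independent-samples t-test with a Levene gate
#'
#' Two-sided independent-samples t-test. Equal variances are assumed
#' (pooled, Student) when Levene's test (deviations from the group mean) is
#' non-significant at alpha = 0.05; otherwise the Welch test with
#' Satterthwaite degrees of freedom is used. Cohen's d uses the pooled SD
#' and is positive when the first group's mean is larger.
#'
#' @param a,b numeric vectors, the two groups' values (n >= 2 each).
#' @return list of class \code{tTestResult} with elements t, df, p,
#'   cohensD, variant ("student" or "welch"), levenP.
#' @export
independentT <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (stats::var(a) == 0 && stats::var(b) == 0)
        stop("zero variance in both groups")
    vals <- c(a, b)
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(vals ~ grp, center = mean)
    levP <- lev[["Pr(>F)"]][1L]
    welch <- is.finite(levP) && levP < 0.05
    tt <- stats::t.test(a, b, var.equal = !welch)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, cohensD = (mean(a) - mean(b)) / sp,
                variant = if (welch) "welch" else "student",
                levenP = levP)
    class(res) <- "tTestResult"
    res
}

#' Paired-samples t-test
#'
#' One-sample t-test on the paired differences, two-sided. Zero-variance
#' differences (which would give an infinite t) raise an error.
#'
#' @param a,b numeric vectors of equal length, paired per subject.
#' @return list of class \code{tTestResult} with t, df, p, cohensD (of the
#'   differences), variant = "paired".
#' @export
pairedT <- function(a, b) {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    if (length(a) < 2L) stop("at least 2 pairs are required")
    d <- a - b
    if (stats::var(d) == 0) {
        if (all(d == 0)) {
            # identical pairs: no effect, define t = 0 rather than 0/0
            res <- list(t = 0, df = length(d) - 1, p = 1, cohensD = 0,
                        variant = "paired", levenP = NA_real_)
            class(res) <- "tTestResult"
            return(res)
        }
        stop("zero variance of the paired differences")
    }
    tt <- stats::t.test(d)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, cohensD = mean(d) / stats::sd(d),
                variant = "paired", levenP = NA_real_)
    class(res) <- "tTestResult"
    res
}

#' @export
print.tTestResult <- function(x, ...) {
    cat(sprintf("%s t = %.3f, df = %.2f, p = %.4g, d = %.3f\n",
                x$variant, x$t, x$df, x$p, x$cohensD))
    invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values with running-minimum enforcement, with
#' rejection decisions at q = 0.05.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param q FDR level for the rejection decisions (default 0.05).
#' @return list with \code{pRaw}, \code{pAdjusted}, \code{rejected}.
#' @export
bhFdr <- function(p, q = 0.05) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    adj <- stats::p.adjust(p, method = "BH")
    list(pRaw = p, pAdjusted = adj, rejected = adj < q)
}

#' Convert partial eta squared to Cohen's f
#'
#' \eqn{f = \sqrt{\eta_p^2 / (1 - \eta_p^2)}}, the effect-size conversion
#' used for ANOVA power analysis.
#'
#' @param partialEta2 numeric in [0, 1).
#' @return Cohen's f.
#' @examples
#' eta2ToCohenF(0.128)  # 0.383
#' @export
eta2ToCohenF <- function(partialEta2) {
    if (any(partialEta2 < 0 | partialEta2 >= 1))
        stop("partial eta squared must lie in [0, 1)")
    sqrt(partialEta2 / (1 - partialEta2))
}

#' Group-by-block ANOVA on behavioural data
#'
#' Reshapes a block-level behavioural dataset (one row per subject, section
#' and block) to wide subject-by-block form for one task section and
#' delegates to \code{\link{mixedAnova}} with within-subject factor block.
#'
#' @param behav data.frame as produced by \code{\link{simulateBehavior}}
#'   (columns subject, group, section, block and the measure).
#' @param section task section to analyse ("pretest", "mri", ...).
#' @param measure "mean_rt" or "accuracy".
#' @return the \code{\link{mixedAnova}} result data.frame.
#' @export
behaviouralAnova <- function(behav, section, measure = "mean_rt") {
    d <- behav[behav$section == section, , drop = FALSE]
    if (nrow(d) == 0L) stop("no rows for section: ", section)
    wide <- stats::reshape(
        d[, c("subject", "group", "block", measure)],
        idvar = c("subject", "group"), timevar = "block",
        direction = "wide")
    Y <- as.matrix(wide[, -(1:2), drop = FALSE])
    mixedAnova(Y, wide$group)
}
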