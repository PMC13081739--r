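test_that("mixed ANOVA matches the cell-means oracle on a 6-subject toy", {
    Y <- matrix(c(3.1, 4.0, 5.2,
                  2.8, 3.9, 4.6,
                  3.5, 4.4, 5.8,
                  4.2, 4.1, 4.0,
                  4.8, 4.6, 4.3,
                  3.9, 4.2, 4.4), 6, 3, byrow = TRUE)
    grp <- rep(c("A", "B"), each = 3)
    res <- mixedAnova(Y, grp)
    o <- anovaOracle(Y, grp)
    expect_equal(res$ss, c(o$ssG, o$ssW, o$ssI), tolerance = 1e-10)
    expect_equal(res$ssError, c(o$ssS, o$ssE, o$ssE), tolerance = 1e-10)
    expect_equal(res$F, c(o$fG, o$fW, o$fI), tolerance = 1e-10)
    expect_equal(res$df1, c(1, 2, 2))
    expect_equal(res$df2, c(4, 8, 8))
})

test_that("mixed ANOVA matches the oracle and aov on unbalanced random data", {
    set.seed(23)
    for (rep in 1:5) {
        n1 <- sample(4:8, 1); n2 <- sample(4:8, 1); w <- sample(3:8, 1)
        Y <- matrix(rnorm((n1 + n2) * w), n1 + n2, w)
        grp <- rep(c("A", "B"), c(n1, n2))
        res <- mixedAnova(Y, grp)
        o <- anovaOracle(Y, grp)
        expect_equal(res$F, c(o$fG, o$fW, o$fI), tolerance = 1e-10)
        d <- data.frame(y = as.vector(Y),
                        subj = factor(rep(seq_len(n1 + n2), w)),
                        grp = factor(rep(grp, w)),
                        pos = factor(rep(seq_len(w), each = n1 + n2)))
        a <- summary(aov(y ~ grp * pos + Error(subj / pos), data = d))
        expect_equal(res$F[1], a[[1]][[1]]$`F value`[1], tolerance = 1e-8)
        expect_equal(res$F[2:3], a[[2]][[1]]$`F value`[1:2],
                     tolerance = 1e-8)
    }
})

test_that("epsilons agree with car's sphericity corrections", {
    set.seed(24)
    Y <- matrix(rnorm(18 * 5), 18, 5) %*% matrix(rnorm(25), 5, 5)
    grp <- rep(c("A", "B"), each = 9)
    res <- mixedAnova(Y, grp)
    s <- summary(car::Anova(lm(Y ~ factor(grp)),
                            idata = data.frame(pos = factor(1:5)),
                            idesign = ~pos, type = 3),
                 multivariate = FALSE)
    adj <- s$pval.adjustments
    expect_equal(res$epsGG[2], unname(adj[1, "GG eps"]), tolerance = 1e-8)
    expect_equal(min(1, unname(adj[1, "HF eps"])), res$epsHF[2],
                 tolerance = 1e-8)
})

test_that("exactly compound-symmetric data yield a unit GG epsilon", {
    set.seed(25)
    n <- 12; w <- 4
    Z <- matrix(rnorm(n * w), n, w)
    Z <- sweep(Z, 2, colMeans(Z))
    # whiten so the sample covariance is exactly the identity
    Z <- Z %*% solve(chol(crossprod(Z) / (n - 2)))
    Y <- rbind(Z[1:6, ], Z[7:12, ])
    grp <- rep(c("A", "B"), each = 6)
    # make the pooled within-group covariance spherical by whitening the
    # pooled centered matrix directly
    Yc <- rbind(sweep(Y[1:6, ], 2, colMeans(Y[1:6, ])),
                sweep(Y[7:12, ], 2, colMeans(Y[7:12, ])))
    Yw <- Yc %*% solve(chol(crossprod(Yc) / (n - 2)))
    res <- mixedAnova(Yw, grp)
    expect_equal(res$epsGG[2], 1, tolerance = 1e-10)
    expect_true(res$epsGG[2] >= 1 / (w - 1) - 1e-12)
})

test_that("with two within levels the interaction F equals the squared t on differences", {
    set.seed(26)
    Y <- matrix(rnorm(20 * 2), 20, 2)
    grp <- rep(c("A", "B"), each = 10)
    res <- mixedAnova(Y, grp)
    dscore <- Y[, 1] - Y[, 2]
    tt <- t.test(dscore[grp == "A"], dscore[grp == "B"], var.equal = TRUE)
    expect_equal(res$F[3], unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$p[3], tt$p.value, tolerance = 1e-8)
})

test_that("group labels shuffled within one pool give nominal type-I error", {
    set.seed(27)
    hits <- replicate(1000, {
        Y <- matrix(rnorm(40 * 4), 40, 4)
        mixedAnova(Y, rep(c("A", "B"), 20))$p[1] < 0.05
    })
    ci <- qbinom(c(0.025, 0.975), 1000, 0.05)
    expect_true(sum(hits) >= ci[1] && sum(hits) <= ci[2])
})

test_that("degenerate ANOVA inputs raise errors", {
    Y <- matrix(rnorm(12), 4, 3)
    expect_error(mixedAnova(Y, rep("A", 4)), "two groups")
    expect_error(mixedAnova(Y, c("A", "A", "A", "B")), "at least 2")
    Yna <- Y; Yna[2, 2] <- NA
    expect_error(mixedAnova(Yna, rep(c("A", "B"), 2)), "missing")
})

test_that("the sphericity rule follows the 0.75 threshold with an HF cap", {
    expect_equal(sphericityRule(0.6, 0.8), 0.6)
    expect_equal(sphericityRule(0.9, 1.1), 1.0)
    expect_equal(sphericityRule(0.9, 0.95), 0.95)
    expect_equal(sphericityRule(0.75, 0.9), 0.75)  # boundary: GG branch
})

test_that("independent t matches hand arithmetic and reports its variant", {
    r <- independentT(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$t, -3.674, tolerance = 1e-3)
    expect_equal(r$df, 4)
    expect_equal(r$variant, "student")
    same <- independentT(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_error(independentT(rep(1, 3), rep(1, 3)), "zero variance")
    expect_error(independentT(1, c(2, 3)), "at least 2")
})

test_that("Cohen's d is positive when the first group's mean is larger", {
    expect_gt(independentT(c(5, 6, 7), c(1, 2, 3))$cohensD, 0)
    expect_lt(independentT(c(1, 2, 3), c(5, 6, 7))$cohensD, 0)
    expect_equal(independentT(c(5, 6, 7), c(1, 2, 3))$cohensD,
                 (6 - 2) / 1)
})

test_that("heteroscedastic groups trigger the Welch branch via Levene", {
    set.seed(28)
    variants <- replicate(500, {
        a <- rnorm(30, sd = 1); b <- rnorm(30, sd = 4)
        independentT(a, b)$variant
    })
    expect_gt(mean(variants == "welch"), 0.9)
    # fractional degrees of freedom under Welch
    set.seed(29)
    r <- independentT(rnorm(30, sd = 1), rnorm(30, sd = 6))
    expect_true(r$df < 58 && r$df != round(r$df))
})

test_that("paired t matches the from-scratch formula and guards zero variance", {
    a <- c(2.1, 3.3, 1.8, 4.0, 2.9)
    b <- c(1.5, 2.9, 2.0, 3.1, 2.2)
    r <- pairedT(a, b)
    d <- a - b
    expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
    expect_equal(r$df, 4)
    expect_equal(pairedT(a, a)$t, 0)                 # identical pairs
    expect_error(pairedT(c(1, 2, 3), c(0, 1, 2)), "zero variance")
    expect_error(pairedT(a, b[1:3]), "equal length")
})

test_that("BH adjustment equals the hand step-up formula and is order-invariant", {
    # hand oracle: p(i) * n / i with running minimum from the largest p down
    bhOracle <- function(p) {
        n <- length(p); o <- order(p, decreasing = TRUE)
        ro <- order(o)
        pmin(1, cummin(p[o] * n / (n:1)))[ro]
    }
    p <- c(0.01, 0.02, 0.03, 0.04)
    expect_equal(bhFdr(p)$pAdjusted, rep(0.04, 4))
    expect_equal(bhFdr(p)$pAdjusted, bhOracle(p))
    expect_equal(bhFdr(0.013)$pAdjusted, 0.013)
    expect_equal(bhFdr(rep(1, 5))$pAdjusted, rep(1, 5))
    expect_false(any(bhFdr(rep(1, 5))$rejected))
    set.seed(30)
    p2 <- runif(20)
    perm <- sample(20)
    expect_equal(bhFdr(p2)$pAdjusted[perm], bhFdr(p2[perm])$pAdjusted)
    expect_equal(bhFdr(p2)$pAdjusted, bhOracle(p2))
    expect_true(all(bhFdr(p2)$pAdjusted >= p2))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial eta squared converts to Cohen's f", {
    expect_equal(round(eta2ToCohenF(0.128), 3), 0.383)
    expect_equal(eta2ToCohenF(0), 0)
    expect_equal(eta2ToCohenF(0.5), 1)
    expect_error(eta2ToCohenF(1), "\\[0, 1\\)")
})

test_that("behavioural ANOVA detects a calibrated pre-test group offset with power", {
    cfg <- simulationConfig(seed = 1)
    simPre <- function(offset, seed) {
        set.seed(seed)
        rows <- lapply(seq_len(48), function(i) {
            g <- if (i <= 24) "COMP" else "INCOMP"
            simulateBehavior(cfg, g, subject = sprintf("s%02d", i),
                             subjectSd = 0.05, pretestOffset = offset,
                             seed = sample.int(1e8, 1))
        })
        behaviouralAnova(do.call(rbind, rows), "pretest")
    }
    set.seed(31)
    hitsAlt <- replicate(120, simPre(0.05, sample.int(1e8, 1))$p[1] < 0.05)
    expect_gt(mean(hitsAlt), 0.8)
})

test_that("null behavioural group effects and flat learning reject at the nominal rate", {
    cfg <- simulationConfig(seed = 1)
    set.seed(32)
    pG <- pB <- numeric(150)
    for (i in 1:150) {
        rows <- lapply(seq_len(24), function(j) {
            g <- if (j <= 12) "COMP" else "INCOMP"
            simulateBehavior(cfg, g, subject = sprintf("s%02d", j),
                             gain = 0,          # flat learning curves
                             pretestOffset = 0, # no group offset
                             seed = sample.int(1e8, 1))
        })
        res <- behaviouralAnova(do.call(rbind, rows), "pretest")
        pG[i] <- res$p[1]
        pB[i] <- res$pCorr[2]
    }
    ciG <- qbinom(c(0.025, 0.975), 150, 0.05)
    expect_true(sum(pG < 0.05) >= ciG[1] && sum(pG < 0.05) <= ciG[2])
    expect_true(sum(pB < 0.05) <= ciG[2] + 1)   # block effect also null
})

test_that("the follow-up battery controls false discoveries under a full null", {
    set.seed(33)
    anyRej <- replicate(1000, {
        Y <- matrix(rnorm(24 * 8), 24, 8)
        p <- vapply(1:8, function(c)
            independentT(Y[1:12, c], Y[13:24, c])$p, numeric(1))
        any(bhFdr(p)$rejected)
    })
    # under the complete null FDR equals the familywise rate ~ alpha
    ci <- qbinom(c(0.025, 0.975), 1000, 0.05)
    expect_true(sum(anyRej) >= ci[1] - 2 && sum(anyRej) <= ci[2] + 2)
})
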