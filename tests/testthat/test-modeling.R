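stdToy <- function(n = 20, p = 5, seed = 2) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", seq_len(n)),
                                sprintf("v%d", seq_len(p))))
    x
}

test_that("preprocessing round-trips and freezes training parameters", {
    set.seed(4)
    mat <- matrix(rpois(6 * 8, 100), 6, 8,
                  dimnames = list(sprintf("v%d", 1:6), sprintf("s%d", 1:8)))
    pp <- preprocessIntensities(mat)
    ## invert with the stored parameters -> original log2(x + 1)
    back <- sweep(sweep(pp$x, 2, pp$params$scale, "*"), 2,
                  pp$params$center, "+")
    expect_equal(back, t(log2(mat + 1)), tolerance = 1e-12)
    expect_equal(unname(colMeans(pp$x)), rep(0, 6), tolerance = 1e-12)
    expect_equal(unname(apply(pp$x, 2, sd)), rep(1, 6), tolerance = 1e-12)

    ## a zero column stays all zero (constant VOC gets SD 1)
    mat0 <- rbind(mat, vz = 0)
    pp0 <- preprocessIntensities(mat0)
    expect_identical(unname(pp0$x[, "vz"]), rep(0, 8))
    expect_identical(pp0$params$scale[["vz"]], 1)

    ## held-out samples are standardized with *training* means:
    ## two training samples with log2(x+1) = 3 and 5 => center 4, sd sqrt(2)
    train <- matrix(c(2^3 - 1, 2^5 - 1), 1, 2,
                    dimnames = list("v1", c("a", "b")))
    prm <- preprocessIntensities(train)$params
    held <- matrix(2^4 - 1, 1, 1, dimnames = list("v1", "new"))
    z <- preprocessIntensities(held, params = prm)$x
    expect_equal(unname(z[1, 1]), (4 - 4) / sqrt(2))
    held2 <- matrix(2^6 - 1, 1, 1, dimnames = list("v1", "new"))
    z2 <- preprocessIntensities(held2, params = prm)$x
    expect_equal(unname(z2[1, 1]), (6 - 4) / sqrt(2))
})

test_that("PCA variance fractions match direct eigendecomposition", {
    for (seed in 1:5) {
        x <- stdToy(10, 5, seed)
        res <- pcaBreath(x)
        ev <- eigen(cov(x), symmetric = TRUE)$values
        expect_equal(res$varExplained, (ev / sum(ev))[seq_along(res$varExplained)],
                     tolerance = 1e-9)
        expect_true(all(diff(res$varExplained) <= 1e-12))
        expect_lte(sum(res$varExplained), 1 + 1e-9)
        ## orthonormal loadings, uncorrelated scores
        expect_equal(crossprod(res$loadings),
                     diag(ncol(res$loadings)), tolerance = 1e-9,
                     ignore_attr = TRUE)
        cc <- cor(res$scores)
        expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    }
})

test_that("two perfectly correlated VOCs load on a single component", {
    set.seed(9)
    v <- rnorm(15)
    x <- cbind(a = v, b = 3 * v + 2)
    res <- pcaBreath(x)
    expect_equal(res$varExplained[1], 1, tolerance = 1e-9)
    expect_error(pcaBreath(matrix(1, 4, 2)), "rank 0")
})

test_that("PCA reports per-component group tests when labels are given", {
    x <- stdToy(16, 4, seed = 7)
    isCase <- rep(c(TRUE, FALSE), each = 8)
    x[isCase, 1] <- x[isCase, 1] + 5
    res <- pcaBreath(x, isCase)
    expect_length(res$componentP, ncol(res$scores))
    expect_lt(res$componentP[[1]], 0.01)
})

test_that("the first PLS weight vector is proportional to X'(y - ybar)", {
    x <- stdToy(25, 6, seed = 3)
    y <- rep(c(1, 0), c(10, 15))
    fit <- plsdaFit(x, y, nComponents = 2)
    w1 <- fit@weights[, 1]
    ref <- drop(crossprod(x, y - mean(y)))
    ref <- ref / sqrt(sum(ref^2))
    expect_equal(unname(w1), unname(ref), tolerance = 1e-9)
    ## training scores are reproduced by applying the fit to training X
    Tnew <- x %*% fit@weights %*%
        solve(crossprod(fit@loadings, fit@weights))
    expect_equal(unname(Tnew), unname(fit@trainingScores), tolerance = 1e-9)
})

test_that("full-rank PLS equals the least-squares solution", {
    set.seed(11)
    x <- stdToy(30, 4, seed = 11)
    y <- rep(c(1, 0), 15)
    fit <- plsdaFit(x, y, nComponents = 4)
    ols <- coef(lm(I(y - mean(y)) ~ x - 1))
    expect_equal(unname(fit@coefficients), unname(ols), tolerance = 1e-9)
})

test_that("one-component PLS on univariate X is simple linear regression", {
    set.seed(13)
    x <- matrix(rnorm(20), dimnames = list(NULL, "v1"))
    x <- scale(x)[, , drop = FALSE]
    y <- rep(c(0, 1), 10)
    fit <- plsdaFit(x, y, nComponents = 1)
    slope <- coef(lm(y ~ x))[2]
    expect_equal(unname(fit@coefficients), unname(slope), tolerance = 1e-9)
})

test_that("PLS-DA separates a class-coded column and predicts prevalence at the mean", {
    set.seed(14)
    y <- rep(c(1, 0), c(7, 13))
    x <- cbind(sig = y + 0, noise = rnorm(20))
    x <- scale(x)
    rownames(x) <- sprintf("s%d", 1:20)
    fit <- plsdaFit(x, y, nComponents = 2)
    prob <- plsdaPredict(fit, x, standardized = TRUE)
    expect_gte(min(prob[y == 1]), 0.99)
    expect_equal(unname(aurocStat(prob[y == 1], prob[y == 0])[["auroc"]]), 1)
    ## all-mean sample: prediction collapses to the training prevalence
    z <- matrix(0, 1, 2, dimnames = list("mean", colnames(x)))
    expect_equal(unname(plsdaPredict(fit, z, standardized = TRUE)),
                 mean(y), tolerance = 1e-12)
    ## monotone in the coefficient sign
    stopifnot(fit@coefficients[["sig"]] > 0)
    up <- z; up[1, "sig"] <- 1
    dn <- z; dn[1, "sig"] <- -1
    expect_gt(plsdaPredict(fit, up, standardized = TRUE),
              plsdaPredict(fit, dn, standardized = TRUE))
    expect_error(plsdaFit(x, rep(1, 20)), "both classes")
    expect_error(plsdaPredict(fit, z[, 1, drop = FALSE],
                              standardized = TRUE), "VOC set")
})
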