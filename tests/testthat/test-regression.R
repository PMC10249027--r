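test_that("min-max scaler maps training data to [0,1] and round-trips", {
    withr::with_seed(20, {
        X <- cbind(rnorm(10), runif(10, 5, 9), rep(3, 10))
        sc <- fitMinmax(X)
        Z <- applyMinmax(X, sc)
        expect_true(all(Z >= 0 & Z <= 1))
        expect_equal(apply(Z[, 1:2], 2, min), c(0, 0), ignore_attr = TRUE)
        expect_equal(apply(Z[, 1:2], 2, max), c(1, 1), ignore_attr = TRUE)
        expect_equal(Z[, 3], rep(0, 10))     # constant feature maps to 0
        expect_equal(invertMinmax(Z, sc), X, tolerance = 1e-12,
                     ignore_attr = TRUE)
    })
})

test_that("elastic-net loss matches a term-by-term evaluation", {
    withr::with_seed(21, {
        X <- matrix(rnorm(12), 4, 3); y <- rnorm(4); b <- rnorm(3)
        expect_equal(enLoss(X, y, b, 0.2, alpha = 0.7, rho = 0.3),
                     bruteEnLoss(X, y, b, 0.2, 0.7, 0.3))
    })
    # with beta = 0 and intercept = mean(y) only the residual term remains:
    # half the population variance of y
    y <- c(1, 2, 6)
    expect_equal(enLoss(matrix(0, 3, 2), y, c(0, 0), mean(y), 1, 0.5),
                 mean((y - mean(y))^2) / 2)
    # exact interpolation at alpha = 0 gives zero loss
    expect_equal(enLoss(matrix(0:2), 0:2 * 2, 2, 0, 0, 0.5), 0)
    expect_error(enLoss(matrix(0, 3, 2), 1:3, 1, 0, 1, 0.5), "shape error")
})

test_that("fitElasticNet recovers the OLS limit and the null limit", {
    X <- matrix(0:2, ncol = 1)
    m <- fitElasticNet(X, c(0, 1, 2), alpha = 1e-12, rho = 0.5)
    expect_equal(coef(m), 1, tolerance = 1e-6)
    expect_equal(intercept(m), 0, tolerance = 1e-6)
    expect_equal(predict(m, X), c(0, 1, 2), tolerance = 1e-6)
    withr::with_seed(22, {
        X2 <- matrix(rnorm(40), 10, 4); y2 <- rnorm(10)
        m2 <- fitElasticNet(X2, y2, alpha = 1e4, rho = 0.5)
        expect_equal(coef(m2), rep(0, 4))
        expect_equal(predict(m2, X2), rep(mean(y2), 10))
    })
    expect_error(fitElasticNet(matrix(c(1, NA), 2, 1), 1:2, 1, 1), "data error")
    expect_error(fitElasticNet(matrix(1:4, 2), 1:2, -1, 0.5), "parameter")
})

test_that("fits satisfy KKT optimality and beat random perturbations", {
    withr::with_seed(23, {
        X <- matrix(rnorm(20 * 8), 20, 8)
        y <- X %*% c(1.5, -1, 0, 0, 0.5, 0, 0, 0) + rnorm(20, sd = 0.2)
        for (pars in list(c(0.05, 1), c(0.02, 0.5), c(0.1, 0.1))) {
            m <- fitElasticNet(X, y, pars[1], pars[2])
            res <- WaveletCalib:::kktResidual(X, y, coef(m), intercept(m),
                                             pars[1], pars[2])
            expect_lt(max(res), 1e-6)
        }
        m <- fitElasticNet(X, y, 0.05, 0.5)
        L0 <- enLoss(X, y, coef(m), intercept(m), 0.05, 0.5)
        pert <- replicate(10000, {
            d <- rnorm(8, sd = 0.01)
            enLoss(X, y, coef(m) + d, intercept(m) + rnorm(1, sd = 0.01),
                   0.05, 0.5)
        })
        expect_true(all(pert >= L0 - 1e-12))
    })
})

test_that("monotone sparsity: nonzero count non-increasing in alpha at rho=1", {
    withr::with_seed(24, {
        X <- matrix(rnorm(30 * 10), 30, 10)
        y <- X %*% rnorm(10) + rnorm(30, sd = 0.3)
        nz <- sapply(10^seq(-4, 1, length.out = 12), function(a)
            sum(coef(fitElasticNet(X, y, a, 1)) != 0))
        expect_true(all(diff(nz) <= 0))
    })
})

test_that("ENCV recovers a planted single-feature signal", {
    withr::with_seed(25, {
        X <- matrix(rnorm(50 * 10), 50, 10)
        y <- 3 * X[, 7]
        m <- fitEncv(X, y, seed = 1)
        Xnew <- matrix(rnorm(40 * 10), 40, 10)
        expect_gte(rSquared(3 * Xnew[, 7], predict(m, Xnew)), 0.99)
        mass <- abs(coef(m)) / sum(abs(coef(m)))
        expect_gt(mass[7], 0.9)
    })
})

test_that("ENCV degenerate grid equals the direct fit with a full-data scaler", {
    withr::with_seed(26, {
        X <- matrix(runif(30 * 5), 30, 5)
        y <- X %*% c(1, 0, 2, 0, 0) + rnorm(30, sd = 0.1)
        m1 <- fitEncv(X, y, grid = list(alpha = 0.01, rho = 0.7),
                      folds = 3, seed = 0, scaling = TRUE)
        sc <- fitMinmax(X)
        m2 <- fitElasticNet(applyMinmax(X, sc), y, 0.01, 0.7)
        expect_equal(coef(m1), coef(m2), tolerance = 1e-9)
        expect_equal(intercept(m1), intercept(m2), tolerance = 1e-9)
    })
})

test_that("ENCV is deterministic under a fixed seed", {
    withr::with_seed(27, {
        X <- matrix(rnorm(25 * 6), 25, 6)
        y <- X %*% rnorm(6) + rnorm(25, sd = 0.2)
    })
    g <- list(alpha = 10^seq(-3, 0, length.out = 5), rho = c(0.5, 1))
    m1 <- fitEncv(X, y, grid = g, seed = 42)
    m2 <- fitEncv(X, y, grid = g, seed = 42)
    expect_identical(cvTable(m1), cvTable(m2))
    expect_identical(coef(m1), coef(m2))
    expect_identical(c(m1@alpha, m1@rho), c(m2@alpha, m2@rho))
})

test_that("ENCV ties break to the sparsest (largest alpha, then rho) model", {
    # penalties large enough to zero every model: all CV errors tie exactly
    withr::with_seed(31, {
        X <- matrix(rnorm(20), 10, 2)
        y <- rnorm(10)
    })
    m <- fitEncv(X, y, grid = list(alpha = c(1e3, 1e4), rho = c(0.5, 1)),
                 folds = 2, seed = 0)
    expect_equal(m@alpha, 1e4)
    expect_equal(m@rho, 1)
    expect_equal(coef(m), c(0, 0))
})

test_that("ENCV fits its scaler strictly inside each training fold", {
    withr::with_seed(28, {
        X <- matrix(rnorm(20 * 4), 20, 4)
        y <- X %*% c(1, -1, 0, 0) + rnorm(20, sd = 0.1)
        X[3, 2] <- 50    # extreme value in one sample
        m <- fitEncv(X, y, grid = list(alpha = 0.05, rho = 1), folds = 4,
                     seed = 5, diagnostics = TRUE)
        info <- attr(m, "foldInfo")
        for (fold in info) {
            tr <- fold$train
            expect_equal(fold$scaler$min,
                         apply(X[tr, , drop = FALSE], 2, min))
            expect_equal(fold$scaler$range,
                         apply(X[tr, , drop = FALSE], 2, max) -
                             apply(X[tr, , drop = FALSE], 2, min))
            # the fold holding out the extreme sample must not have seen it
            if (3 %in% fold$validation)
                expect_lt(fold$scaler$min[2] + fold$scaler$range[2], 50)
        }
    })
})

test_that("predict matches an explicit dot-product loop and checks shapes", {
    withr::with_seed(29, {
        X <- matrix(rnorm(15), 5, 3)
        m <- new("ENModel", beta = c(0.5, -1, 2), intercept = 0.3,
                 alpha = 0.1, rho = 1,
                 scaler = WaveletCalib:::.disabledScaler(),
                 cvTable = data.frame(), seed = NA_integer_)
        manual <- sapply(1:5, function(i) sum(X[i, ] * m@beta) + 0.3)
        expect_equal(predict(m, X), manual)
        expect_error(predict(m, X[, 1:2]), "shape error")
        m0 <- new("ENModel", beta = rep(0, 3), intercept = 1.5, alpha = 1,
                  rho = 1, scaler = WaveletCalib:::.disabledScaler(),
                  cvTable = data.frame(), seed = NA_integer_)
        expect_equal(predict(m0, X), rep(1.5, 5))
    })
})

test_that("model archives round-trip through JSON", {
    withr::with_seed(30, {
        X <- matrix(runif(40), 10, 4)
        y <- X %*% c(2, 0, -1, 0) + rnorm(10, sd = 0.05)
        m <- fitEncv(X, y, grid = list(alpha = c(0.01, 0.1), rho = c(0.5, 1)),
                     folds = 3, seed = 3)
        path <- withr::local_tempfile(fileext = ".json")
        writeENModel(m, path)
        back <- readENModel(path)
        expect_equal(coef(back), coef(m))
        expect_equal(intercept(back), intercept(m))
        expect_equal(back@scaler$min, m@scaler$min, ignore_attr = TRUE)
        expect_equal(predict(back, X), predict(m, X))
    })
})
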