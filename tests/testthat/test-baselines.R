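test_that("prominence peak finding matches constructed cases", {
    expect_identical(nrow(findPeaksProminence(rep(1, 50), 0.01)), 0L)
    # single Gaussian peak of height 1
    sp <- peakSpectrum(100, 50, 1)
    pk <- findPeaksProminence(absorbance(sp), 0.06)
    expect_identical(pk$index, 50L)
    expect_equal(pk$prominence, 1, tolerance = 1e-6)
    # two peaks separated by a valley: smaller one has prominence to valley
    x <- c(0, 1, 0.4, 0.8, 0)
    pk2 <- findPeaksProminence(x, 0)
    expect_identical(pk2$index, c(2L, 4L))
    expect_equal(pk2$prominence, c(1, 0.4))
    # plateau summit reported at its midpoint
    x3 <- c(0, 1, 1, 1, 0)
    expect_identical(findPeaksProminence(x3, 0)$index, 3L)
})

test_that("overlap removal follows the +/- halfwidth boundary exactly", {
    pure <- peakSpectrum(1000, 500, 1, id = "monomer")
    refNear <- peakSpectrum(1000, 505, 1, id = "refA")
    refFar <- peakSpectrum(1000, 511, 1, id = "refB")
    selNear <- selectMonomerPeaks(pure, list(refNear))
    expect_identical(nrow(retainedPeaks(selNear)), 0L)
    expect_identical(removedPeaks(selNear)$conflict, "refA")
    selFar <- selectMonomerPeaks(pure, list(refFar))
    expect_identical(retainedPeaks(selFar)$index, 500L)
    # flat spectrum selects nothing
    flat <- Spectrum(rep(0.5, 1000), wavenumbers(pure))
    expect_identical(nrow(retainedPeaks(selectMonomerPeaks(flat, list()))), 0L)
    expect_error(selectMonomerPeaks(pure, list(peakSpectrum(90, 50, 1))),
                 "shape error")
})

test_that("peak selection is idempotent and reference-order independent", {
    pure <- peakSpectrum(600, c(100, 300, 500), c(1, 0.8, 0.5), id = "m")
    r1 <- peakSpectrum(600, 305, 1, id = "a")
    r2 <- peakSpectrum(600, 502, 1, id = "b")
    s12 <- selectMonomerPeaks(pure, list(r1, r2))
    s21 <- selectMonomerPeaks(pure, list(r2, r1))
    expect_identical(retainedPeaks(s12)$index, retainedPeaks(s21)$index)
    expect_identical(retainedPeaks(s12)$index, 100L)
    expect_setequal(removedPeaks(s12)$index, removedPeaks(s21)$index)
})

test_that("peak regression is exact on noiseless Beer-Lambert data", {
    withr::with_seed(50, {
        l <- 300
        y <- runif(20, 0.2, 1)
        pure <- exp(-(seq_len(l) - 150)^2 / 18)
        ds <- SpectralSet(outer(y, pure), seq(4000, 600, length.out = l), y,
                          monomerLabel = "m")
        sel <- selectMonomerPeaks(Spectrum(pure, wavenumbers(ds), "m"), list())
        fit <- peakRegression(ds, sel, "per_peak")
        expect_equal(fit$r2_insample, 1, tolerance = 1e-9)
        expect_gte(fit$r2_cv, 0.999)
        # closed-form simple regression slope at the peak column
        x <- spectraMatrix(ds)[, 150]
        cf <- stats::lm(y ~ x)$coefficients
        expect_equal(unname(cf["x"]), stats::cov(x, y) / stats::var(x),
                     tolerance = 1e-10)
    })
})

test_that("permuted targets destroy cross-validated peak R2", {
    withr::with_seed(51, {
        l <- 120
        y <- runif(30, 0.2, 1)
        pure <- exp(-(seq_len(l) - 60)^2 / 18)
        X <- outer(y, pure) + matrix(rnorm(30 * l, sd = 0.01), 30, l)
        grid <- seq(4000, 600, length.out = l)
        sel <- selectMonomerPeaks(Spectrum(pure, grid, "m"), list())
        r2s <- replicate(100, {
            dsP <- SpectralSet(X, grid, sample(y), monomerLabel = "m")
            peakRegression(dsP, sel, "per_peak")$r2_cv[1]
        })
        expect_lte(mean(r2s), 0.1)
    })
})

test_that("collinear peaks combined reproduce the single-peak predictions", {
    withr::with_seed(52, {
        y <- runif(15, 0.2, 1)
        l <- 200
        pure <- exp(-(seq_len(l) - 80)^2 / 8) + exp(-(seq_len(l) - 140)^2 / 8)
        ds <- SpectralSet(outer(y, pure), seq(4000, 600, length.out = l), y,
                          monomerLabel = "m")
        sel <- selectMonomerPeaks(Spectrum(pure, wavenumbers(ds), "m"), list())
        expect_identical(nrow(retainedPeaks(sel)), 2L)
        comb <- peakRegression(ds, sel, "combined")
        single <- peakRegression(ds, sel, "per_peak")
        expect_equal(comb$r2_insample, single$r2_insample[1],
                     tolerance = 1e-9)
    })
})

test_that("PLS selects one component on rank-1 data and is seeded", {
    withr::with_seed(53, {
        u <- rnorm(25); v <- rnorm(40)
        X <- outer(u, v)
        y <- 2 * u + 1
        m <- fitPlsCv(X, y, maxComponents = 5, seed = 0)
        expect_identical(m$ncomp, 1L)
        expect_gte(rSquared(y, predictPls(m, X)), 0.999)
        m2 <- fitPlsCv(X, y, maxComponents = 5, seed = 0)
        expect_identical(m$ncomp, m2$ncomp)
        expect_equal(m$cvTable, m2$cvTable)
        # degenerate grid reduces to a plain fit
        m1 <- fitPlsCv(X, y, maxComponents = 1, seed = 3)
        expect_identical(m1$ncomp, 1L)
        expect_error(fitPlsCv(X, y, maxComponents = 30),
                     "maxComponents exceeds")
    })
})
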