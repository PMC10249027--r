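test_that("containers validate their invariants", {
    expect_error(Spectrum(c(1, 2), c(1, 2, 3)), "lengths differ")
    expect_error(Spectrum(c(1, NA), c(1, 2)), "finite")
    expect_error(Spectrum(c(1, 2, 3), c(1, 3, 2)), "monotone")
    expect_error(SpectralSet(matrix(1, 2, 3), c(3, 2, 1), c(-1, 1)),
                 "non-negative")
    ds <- tinyDataset()
    expect_s4_class(ds, "SpectralSet")
    expect_identical(dim(spectraMatrix(ds)), c(6L, 32L))
    expect_identical(length(getSpectrum(ds, 2)), 32L)
})

test_that("delimited write/read round-trips a dataset", {
    ds <- tinyDataset()
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSpectra(ds, path)
    back <- readSpectra(path, monomerLabel = "tiny")
    expect_equal(spectraMatrix(back), spectraMatrix(ds), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(concentrations(back), concentrations(ds))
    expect_equal(wavenumbers(back), wavenumbers(ds))
    expect_identical(sampleIds(back), sampleIds(ds))
})

test_that("reader reports format, parse and shape errors with location", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,conc,1000,999", "a,0.5,0.1,0.2"), path)
    expect_error(readSpectra(path), "target column 'concentration'")
    writeLines(c("sample_id,concentration,1000,999",
                 "a,0.5,0.1,oops"), path)
    expect_error(readSpectra(path), "row 1, column '999'")
    writeLines(c("sample_id,concentration,1000,999",
                 "a,0.5,0.1,0.2", "b,0.6,0.3,"), path)
    expect_error(readSpectra(path), "row 2, column '999'")
})

test_that("workbook sheets are read through the python bridge", {
    ds <- tinyDataset(s = 3, l = 8)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeSpectra(ds, tsv)
    xlsx <- withr::local_tempfile(fileext = ".xlsx")
    script <- withr::local_tempfile(fileext = ".py")
    writeLines(c(
        "import sys, csv, openpyxl",
        "wb = openpyxl.Workbook(); ws = wb.active; ws.title = 'tiny'",
        "for row in csv.reader(open(sys.argv[1]), delimiter='\\t'):",
        "    ws.append([float(v) if v.replace('.','',1).replace('-','',1).isdigit() else v for v in row])",
        "wb.save(sys.argv[2])"), script)
    status <- system2("python", c(script, tsv, xlsx), stdout = FALSE)
    expect_identical(status, 0L)
    back <- readSpectra(xlsx, format = "workbook", monomerLabel = "tiny")
    expect_equal(spectraMatrix(back), spectraMatrix(ds), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(concentrations(back), concentrations(ds), tolerance = 1e-12)
})

test_that("transposed layouts (wavenumbers down the first column) are detected", {
    ds <- tinyDataset(s = 3, l = 8)
    path <- withr::local_tempfile(fileext = ".tsv")
    m <- rbind(concentration = concentrations(ds), t(spectraMatrix(ds)))
    df <- data.frame(key = c("concentration",
                             format(wavenumbers(ds), trim = TRUE)), m)
    names(df) <- c("key", sampleIds(ds))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    back <- readSpectra(path, monomerLabel = "tiny")
    expect_equal(unname(spectraMatrix(back)), unname(spectraMatrix(ds)),
                 tolerance = 1e-9)
    expect_equal(concentrations(back), concentrations(ds), tolerance = 1e-12)
})

test_that("bin-mean resampling matches hand-computed means and identities", {
    # 6-point source binned 2:1: bins {1,2},{3,4},{5,6} -> means
    src <- Spectrum(c(1, 2, 3, 4, 5, 6), 1:6)
    out <- resampleToGrid(src, c(1.5, 3.5, 5.5))
    expect_equal(absorbance(out), c(1.5, 3.5, 5.5))
    # identity on the same grid
    sp <- getSpectrum(tinyDataset(), 1)
    expect_equal(absorbance(resampleToGrid(sp, wavenumbers(sp))),
                 absorbance(sp))
    # constant spectra stay constant on any coarser grid
    const <- Spectrum(rep(2.5, 20), seq(4000, 600, length.out = 20))
    expect_equal(absorbance(resampleToGrid(const,
                     seq(3800, 800, length.out = 7))), rep(2.5, 7))
    expect_error(resampleToGrid(src, c(0.5, 3)), "range error")
})

test_that("dataset summary uses the n-1 standard deviation", {
    mk <- function(y) SpectralSet(matrix(1, length(y), 3), c(3, 2, 1), y,
                                  monomerLabel = "m")
    sm <- summarizeDataset(mk(c(0.1, 0.2, 0.6)))
    expect_equal(sm$mean, 0.3)
    expect_equal(sm$sd, sqrt(0.07))          # ss = 0.14, var = 0.14/2
    expect_equal(c(sm$max, sm$min), c(0.6, 0.1))
    sm2 <- summarizeDataset(mk(c(0.5, 0.5)))
    expect_equal(c(sm2$mean, sm2$sd, sm2$max, sm2$min), c(0.5, 0, 0.5, 0.5))
    # brute-force agreement on random targets
    withr::with_seed(4, {
        y <- runif(17)
        sm3 <- summarizeDataset(mk(y))
        expect_equal(sm3$sd, sqrt(sum((y - sum(y) / 17)^2) / 16))
    })
})
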