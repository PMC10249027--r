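# Projection of elastic-net coefficients onto Gaussian approximations of
# their Ricker wavelets, giving interpretable contribution curves.

#' Gaussian width approximating a Ricker wavelet
#'
#' The Gaussian standard deviation used to approximate a Ricker wavelet of
#' width `w` is `sigma = 0.45 w`; on a dense grid this ratio maximizes the
#' cosine similarity between the unit-peak Gaussian and the Ricker shape
#' (continuum optimum 1/sqrt(5) ~ 0.447).
#'
#' @param w Ricker width parameter (> 0).
#' @return `0.45 * w`.
#' @export
gaussianSigma <- function(w) {
    if (any(w <= 0)) stop("parameter error: 'w' must be positive")
    0.45 * w
}

# Effective raw-scale amplitude of each feature's coefficient: with min-max
# scaling the model sees (x - min)/range, so the contribution per unit raw
# absorbance is beta/range; without scaling it is beta itself.
.effectiveAmplitudes <- function(model) {
    beta <- model@beta
    if (isTRUE(model@scaler$enabled)) {
        r <- model@scaler$range
        ifelse(r > 0, beta / r, 0)
    } else beta
}

#' Project model coefficients onto Gaussian contribution curves
#'
#' Every nonzero wavelet coefficient at (width `w`, center `c`) contributes
#' a unit-peak Gaussian centered at `c` with `sigma = 0.45 w` (grid-point
#' units), scaled by the coefficient times its effective scale factor
#' (1/feature-range under min-max scaling, so curves live on the raw
#' absorbance scale; the convention is recorded in the result). Raw-block
#' coefficients contribute single-point terms on the `"raw"` curve. Curves
#' sharing a width are summed; the total is their elementwise sum.
#'
#' @param model an [ENModel-class] (or a list of models, whose effective
#'   coefficient amplitudes are averaged before projection, as when
#'   aggregating the models trained across repeated CV).
#' @param fmap feature map from [featureMap()] matching the model dimension.
#' @param grid wavenumber vector of the underlying spectra.
#' @return a [ContributionCurve-class].
#' @export
projectCoefficients <- function(model, fmap, grid) {
    models <- if (is(model, "ENModel")) list(model) else model
    fm <- as.data.frame(fmap)
    p <- nrow(fm)
    for (m in models)
        if (length(m@beta) != p)
            stop("shape error: model dimension does not match the feature map")
    amp <- rowMeans(vapply(models, .effectiveAmplitudes, numeric(p)))
    l <- length(grid)
    if (max(fm$centerIndex) > l)
        stop("shape error: feature map centers exceed the grid")
    ws <- unique(fm$width[fm$kind == "wavelet"])
    perWidth <- matrix(0, nrow = l, ncol = length(ws) + 1L,
                       dimnames = list(NULL, c("raw", sprintf("w%g", ws))))
    pos <- seq_len(l)
    nz <- which(amp != 0)
    for (j in nz) {
        if (fm$kind[j] == "raw") {
            perWidth[fm$centerIndex[j], "raw"] <-
                perWidth[fm$centerIndex[j], "raw"] + amp[j]
        } else {
            sig <- gaussianSigma(fm$width[j])
            col <- sprintf("w%g", fm$width[j])
            perWidth[, col] <- perWidth[, col] +
                amp[j] * exp(-(pos - fm$centerIndex[j])^2 / (2 * sig^2))
        }
    }
    scaled <- isTRUE(models[[1L]]@scaler$enabled)
    new("ContributionCurve", grid = as.numeric(grid), perWidth = perWidth,
        total = unname(rowSums(perWidth)),
        scaleNote = if (scaled)
            "coefficient / feature range (raw-absorbance scale)"
        else "raw coefficient scale")
}

#' Export contribution curves as delimited text
#'
#' @param curve a [ContributionCurve-class].
#' @param path output file (TSV: wavenumber, per-width columns, total).
#' @return `path`, invisibly.
#' @export
writeContributions <- function(curve, path) {
    df <- data.frame(wavenumber = curve@grid,
                     curve@perWidth, total = curve@total,
                     check.names = FALSE)
    fwrite(df, path, sep = "\t")
    invisible(path)
}

#' Plot contribution curves over the spectrum
#'
#' Draws the total contribution curve (and, lightly, the per-width curves)
#' against wavenumber, optionally overlaying an input spectrum rescaled to
#' the curve amplitude; the wavenumber axis is drawn descending, as spectra
#' are conventionally displayed.
#'
#' @param curve a [ContributionCurve-class].
#' @param spectrum optional [Spectrum-class] on the same grid to overlay.
#' @param file optional output path; `.svg` or `.png` chooses the device.
#' @param main plot title.
#' @return `file` (or NULL when plotting to the active device), invisibly.
#' @export
plotContribution <- function(curve, spectrum = NULL, file = NULL,
                             main = "Coefficient contributions") {
    if (!is.null(file)) {
        if (grepl("\\.png$", file)) grDevices::png(file, 900, 500)
        else grDevices::svg(file, width = 9, height = 5)
        on.exit(grDevices::dev.off())
    }
    g <- curve@grid
    ylim <- range(curve@total, curve@perWidth)
    graphics::plot(g, curve@total, type = "l", lwd = 2, xlim = rev(range(g)),
                   ylim = ylim, xlab = expression(wavenumber ~ (cm^-1)),
                   ylab = "contribution", main = main)
    for (j in seq_len(ncol(curve@perWidth)))
        graphics::lines(g, curve@perWidth[, j], col = "#00000040")
    if (!is.null(spectrum)) {
        a <- absorbance(spectrum)
        scl <- if (max(abs(a)) > 0) max(abs(ylim)) / max(abs(a)) else 1
        graphics::lines(g, a * scl, col = "#D5500080", lty = 2)
        graphics::legend("topleft", bty = "n", lty = c(1, 2),
                         col = c("black", "#D55000"),
                         legend = c("total contribution", "spectrum (scaled)"))
    }
    graphics::abline(h = 0, col = "grey70")
    invisible(file)
}
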