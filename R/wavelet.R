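# Ricker wavelet bank, continuous wavelet transform and feature assembly.
#
# Width units are grid points (~cm^-1 at 1 cm^-1 spacing): the width
# schedule is defined on the vector length l, not on physical wavenumbers.

#' Geometric width schedule for a Ricker wavelet bank
#'
#' Returns `n` widths geometrically spaced between 1 (one grid point) and
#' `l / k`, where `k` controls how wide the widest wavelet is relative to
#' the spectrum length: `w_i = (l/k)^((i-1)/(n-1))`.
#'
#' @param l spectrum length (grid points).
#' @param n number of wavelets (>= 1).
#' @param k widest-wavelet control (> 0); requires `l / k >= 1`.
#' @return numeric vector of `n` widths, `widths[1] == 1`,
#'   `widths[n] == l / k`.
#' @examples
#' widthSchedule(3527, 10, 4)   # 1 ... 881.75
#' @export
widthSchedule <- function(l, n, k) {
    if (n < 1L) stop("parameter error: 'n' must be >= 1")
    if (k <= 0) stop("parameter error: 'k' must be positive")
    wmax <- l / k
    if (wmax < 1)
        stop("parameter error: l/k < 1 (widest wavelet narrower than one point)")
    if (n == 1L) return(1)
    wmax ^ ((seq_len(n) - 1) / (n - 1))
}

#' Discretized Ricker (Mexican-hat) wavelet
#'
#' Evaluates psi(x; w) = 2 / (sqrt(3 w) pi^(1/4)) (1 - (x/w)^2)
#' exp(-x^2 / (2 w^2)) at `m` offsets centered on zero (integer offsets for
#' odd `m`, half-integer for even `m`). The wavelet peaks at x = 0, crosses
#' zero at x = +/- w, and has zero mean in the continuum.
#'
#' @param m support length in points (>= 1).
#' @param w width parameter (> 0), grid-point units.
#' @return numeric vector of length `m`.
#' @export
rickerWavelet <- function(m, w) {
    if (w <= 0) stop("parameter error: 'w' must be positive")
    if (m < 1L) stop("parameter error: 'm' must be >= 1")
    x <- seq_len(m) - 1 - (m - 1) / 2
    amp <- 2 / (sqrt(3 * w) * pi^0.25)
    amp * (1 - (x / w)^2) * exp(-x^2 / (2 * w^2))
}

# Centered "same" convolution with zero padding: out[t] = sum_j h[j] *
# x[t + offset - j] with the kernel center aligned to t. Kernels here are
# symmetric so convolution and correlation coincide; only the alignment of
# even-length supports matters, fixed to the numpy mode="same" convention.
.convSame <- function(x, h) {
    l <- length(x); m <- length(h)
    full <- stats::convolve(x, rev(h), type = "open")
    start <- (m - 1L) %/% 2L + 1L
    full[start:(start + l - 1L)]
}

#' Continuous wavelet transform of a spectrum
#'
#' One coefficient per (width, position): each row is the centered,
#' zero-padded "same" convolution of the absorbance with the Ricker wavelet
#' of that width, truncated to `min(ceiling(10 w), l)` support points.
#'
#' @param spec a [Spectrum-class] or a numeric absorbance vector.
#' @param bank a [WaveletBank-class] with `l` equal to the spectrum length.
#' @return numeric matrix, `length(bank)` rows by `l` columns.
#' @export
cwt <- function(spec, bank) {
    x <- if (is(spec, "Spectrum")) absorbance(spec) else as.numeric(spec)
    if (length(x) != bank@l)
        stop("shape error: spectrum length ", length(x),
             " does not match bank length ", bank@l)
    supports <- supportLengths(bank)
    out <- matrix(0, nrow = length(bank), ncol = bank@l)
    for (i in seq_along(bank@widths)) {
        h <- rickerWavelet(supports[i], bank@widths[i])
        out[i, ] <- .convSame(x, h)
    }
    rownames(out) <- sprintf("w%g", bank@widths)
    out
}

#' Assemble the wavelet-expanded feature vector
#'
#' Concatenates the raw spectrum with the ReLU-rectified (negative values
#' zeroed) wavelet coefficient vector of each width:
#' `[raw | max(0, cwt row 1) | ... | max(0, cwt row n)]`, total length
#' `(n + 1) * l`. The raw block is passed through unmodified; rectification
#' applies to wavelet coefficients only.
#'
#' @param spec a [Spectrum-class] or numeric absorbance vector.
#' @param bank a [WaveletBank-class].
#' @return numeric feature vector of length `(length(bank) + 1) * l`.
#' @export
featurize <- function(spec, bank) {
    x <- if (is(spec, "Spectrum")) absorbance(spec) else as.numeric(spec)
    cc <- cwt(x, bank)
    c(x, as.numeric(t(pmax(cc, 0))))
}

#' Feature map for a wavelet-expanded design
#'
#' Describes every feature index produced by [featurize()]: its kind
#' (`raw` or `wavelet`), wavelet width (NA for raw), and center position as
#' both grid index and wavenumber.
#'
#' @param bank a [WaveletBank-class].
#' @param grid wavenumber vector of length `bank@l` (cm^-1).
#' @return a [S4Vectors::DataFrame] with `(n + 1) * l` rows.
#' @export
featureMap <- function(bank, grid) {
    if (length(grid) != bank@l)
        stop("shape error: grid length does not match bank length")
    l <- bank@l
    n <- length(bank)
    idx <- rep.int(seq_len(l), n + 1L)
    DataFrame(kind = rep(c("raw", rep("wavelet", n)), each = l),
              width = rep(c(NA_real_, bank@widths), each = l),
              centerIndex = idx,
              centerWavenumber = grid[idx])
}

#' Featurize every sample of a dataset
#'
#' @param ds a [SpectralSet-class] or samples-by-points numeric matrix.
#' @param bank a [WaveletBank-class].
#' @return samples-by-`(n+1)l` feature matrix.
#' @export
featurizeMatrix <- function(ds, bank) {
    X <- if (is(ds, "SpectralSet")) spectraMatrix(ds) else as.matrix(ds)
    out <- matrix(0, nrow = nrow(X), ncol = (length(bank) + 1L) * bank@l)
    for (i in seq_len(nrow(X))) out[i, ] <- featurize(X[i, ], bank)
    rownames(out) <- rownames(X)
    out
}

#' Export a feature matrix with its feature-map sidecar
#'
#' @param features feature matrix from [featurizeMatrix()].
#' @param fmap feature map from [featureMap()].
#' @param path output file for the features; the sidecar is written next to
#'   it with suffix `.map.tsv`.
#' @return invisibly, the sidecar path.
#' @export
writeFeatures <- function(features, fmap, path) {
    fwrite(as.data.frame(features), path, sep = "\t")
    side <- paste0(sub("\\.[^.]*$", "", path), ".map.tsv")
    fwrite(cbind(feature = seq_len(nrow(as.data.frame(fmap))),
                 as.data.frame(fmap)), side, sep = "\t")
    invisible(side)
}
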