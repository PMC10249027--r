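# Shared fixtures and independent oracles, built in code at test time.

# Tiny deterministic dataset: ramp + peak spectra with proportional target.
tinyDataset <- function(s = 6, l = 32, seed = 11) {
    withr::with_seed(seed, {
        grid <- seq(4000, 600, length.out = l)
        y <- seq(0.1, 1.1, length.out = s)
        pure <- exp(-(seq_len(l) - l / 2)^2 / 8)
        X <- outer(y, pure) + matrix(rnorm(s * l, sd = 1e-3), s, l)
        SpectralSet(abs(X), grid, y, monomerLabel = "tiny")
    })
}

# Brute-force centered "same" convolution (numpy alignment), O(l * m).
bruteConvSame <- function(x, h) {
    l <- length(x); m <- length(h)
    full <- numeric(l + m - 1L)
    for (k in seq_along(full)) {
        acc <- 0
        for (j in max(1L, k - m + 1L):min(k, l))
            acc <- acc + x[j] * h[k - j + 1L]
        full[k] <- acc
    }
    start <- (m - 1L) %/% 2L + 1L
    full[start:(start + l - 1L)]
}

# Direct evaluation of the elastic-net objective, term by term.
bruteEnLoss <- function(X, y, beta, b0, alpha, rho) {
    r <- 0
    for (i in seq_len(nrow(X)))
        r <- r + (y[i] - sum(X[i, ] * beta) - b0)^2
    pen1 <- 0; pen2 <- 0
    for (j in seq_along(beta)) {
        pen1 <- pen1 + abs(beta[j])
        pen2 <- pen2 + beta[j]^2
    }
    r / (2 * nrow(X)) + alpha * (rho * pen1 + (1 - rho) / 2 * pen2)
}

# Minimal CVResult carrying given per-trial R2 values (for comparison tests).
fakeCVResult <- function(r2, label = "m", nSamples = 10) {
    trials <- length(r2)
    pr <- do.call(rbind, lapply(seq_len(trials), function(t)
        data.frame(trial = t, fold = 1L,
                   sample = paste0("s", seq_len(nSamples)),
                   y_true = seq_len(nSamples), y_pred = seq_len(nSamples))))
    new("CVResult", method = label, seeds = seq_len(trials) - 1L,
        predictions = pr, perTrialR2 = as.numeric(r2), trainIndex = list())
}

# Gaussian-peak Spectrum on an index grid, for peak-selection tests.
peakSpectrum <- function(l, centers, heights, sigma = 3, id = "pure") {
    x <- numeric(l)
    for (i in seq_along(centers))
        x <- x + heights[i] * exp(-(seq_len(l) - centers[i])^2 / (2 * sigma^2))
    Spectrum(x, seq(4000, 600, length.out = l), id)
}
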