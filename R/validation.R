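# Repeated k-fold cross-validation harness, R^2 metric and method
# comparison. A "method" is a factory function(X, y, seed) returning a
# predictor function(Xnew) -> numeric; factories for the package's models
# are provided below. Models (including any inner hyperparameter CV and
# scaler) are trained strictly on fold-in rows.

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about `mean(y_true)`;
#' unbounded below, at most 1.
#'
#' @param yTrue observed values (length >= 2, non-constant).
#' @param yPred predicted values, same length.
#' @return scalar R-squared.
#' @export
rSquared <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
        stop("parameter error: need equal-length vectors of length >= 2")
    sst <- sum((yTrue - mean(yTrue))^2)
    if (sst == 0) stop("undefined-metric error: constant y_true")
    1 - sum((yTrue - yPred)^2) / sst
}

#' Repeated k-fold cross-validation of a modelling method
#'
#' Runs `repeats` trials; each trial shuffles the samples into `k` folds
#' using that trial's seed, trains the method on the fold-in rows only, and
#' predicts the fold-out rows, so every sample is predicted exactly once
#' per trial by a model that never saw it. Per-trial R-squared is computed
#' on the pooled out-of-fold predictions; the mean over trials is the
#' reported metric.
#'
#' @param ds a [SpectralSet-class].
#' @param method factory `function(X, y, seed)` returning a predictor
#'   `function(Xnew)`; see [encvMethod()], [wtEncvMethod()], [plsMethod()].
#' @param k folds per trial (requires `s >= k`).
#' @param repeats number of trials.
#' @param seeds integer seed per trial (default `0:(repeats-1)`).
#' @param label method label stored in the result.
#' @return a [CVResult-class].
#' @export
repeatedCV <- function(ds, method, k = 5, repeats = 5,
                       seeds = seq_len(repeats) - 1L, label = "method") {
    X <- spectraMatrix(ds)
    y <- concentrations(ds)
    s <- nrow(X)
    if (s < k) stop("parameter error: fewer samples than folds")
    if (length(seeds) != repeats)
        stop("parameter error: need one seed per repeat")
    preds <- list(); r2 <- numeric(repeats); trainIdx <- vector("list", repeats)
    for (t in seq_len(repeats)) {
        seed <- as.integer(seeds[t])
        foldId <- with_seed(seed, sample(rep_len(seq_len(k), s)))
        yhat <- numeric(s); trainIdx[[t]] <- vector("list", k)
        for (f in seq_len(k)) {
            tr <- which(foldId != f); va <- which(foldId == f)
            predictor <- method(X[tr, , drop = FALSE], y[tr], seed)
            yhat[va] <- predictor(X[va, , drop = FALSE])
            trainIdx[[t]][[f]] <- tr
        }
        preds[[t]] <- data.frame(trial = t, fold = foldId,
                                 sample = sampleIds(ds),
                                 y_true = y, y_pred = yhat)
        r2[t] <- rSquared(y, yhat)
    }
    new("CVResult", method = label, seeds = as.integer(seeds),
        predictions = do.call(rbind, preds), perTrialR2 = r2,
        trainIndex = trainIdx)
}

#' Compare two methods' repeated-CV results
#'
#' Two-sided paired test on the per-trial R-squared values of two
#' [CVResult-class] objects from the same dataset and seeds. With
#' non-degenerate differences this is the paired t-test; when the
#' differences have zero variance the degenerate limit of the t statistic
#' is used (p = 1 when all differences are zero, p = 0 otherwise).
#'
#' @param a,b [CVResult-class] objects with equal trial counts.
#' @param alphaLevel significance level (default 0.05).
#' @return list with `p_value`, `significant`, `mean_difference` (a - b).
#' @export
compareMethods <- function(a, b, alphaLevel = 0.05) {
    ra <- perTrialR2(a); rb <- perTrialR2(b)
    if (length(ra) != length(rb))
        stop("parameter error: trial counts differ")
    if (nrow(cvPredictions(a)) != nrow(cvPredictions(b)))
        stop("parameter error: results come from different datasets")
    d <- ra - rb
    if (sd(d) == 0) {
        p <- if (all(d == 0)) 1 else 0
    } else {
        p <- t.test(d)$p.value
    }
    list(p_value = p, significant = p < alphaLevel, mean_difference = mean(d))
}

# ---- method factories -----------------------------------------------------

#' Method factories for the validation harness
#'
#' Each factory returns a `function(X, y, seed)` training one of the
#' package's models on raw spectra `X` and returning a predictor
#' `function(Xnew)`. `wtEncvMethod` expands the spectra with a Ricker
#' wavelet bank before the elastic net (the WT-ENCV pipeline);
#' `encvMethod` is the elastic net on the raw spectra; `plsMethod` is PLS
#' with a CV-chosen component count.
#'
#' @param n,k wavelet bank size and widest-wavelet control.
#' @param scaling min-max scale features inside each training fold.
#' @param grid elastic-net hyperparameter grid (default [defaultGrid()]).
#' @param innerFolds folds of the inner hyperparameter CV.
#' @param cvThresh glmnet threshold during the inner CV search.
#' @return a method factory function.
#' @export
wtEncvMethod <- function(n = 10, k = 4, scaling = TRUE, grid = defaultGrid(),
                         innerFolds = 5, cvThresh = 1e-7) {
    function(X, y, seed) {
        bank <- waveletBank(ncol(X), n = n, k = k)
        model <- fitEncv(featurizeMatrix(X, bank), y, grid = grid,
                         folds = innerFolds, seed = seed, scaling = scaling,
                         cvThresh = cvThresh)
        function(Xnew) predict(model, featurizeMatrix(Xnew, bank))
    }
}

#' @rdname wtEncvMethod
#' @export
encvMethod <- function(scaling = TRUE, grid = defaultGrid(), innerFolds = 5,
                       cvThresh = 1e-7) {
    function(X, y, seed) {
        model <- fitEncv(X, y, grid = grid, folds = innerFolds, seed = seed,
                         scaling = scaling, cvThresh = cvThresh)
        function(Xnew) predict(model, Xnew)
    }
}

#' @rdname wtEncvMethod
#' @param maxComponents largest PLS component count tried.
#' @export
plsMethod <- function(maxComponents = 20, innerFolds = 5) {
    function(X, y, seed) {
        maxc <- min(maxComponents, nrow(X) - 1L, ncol(X))
        model <- fitPlsCv(X, y, maxComponents = maxc, folds = innerFolds,
                          seed = seed)
        function(Xnew) predictPls(model, Xnew)
    }
}

#' Export a CV result as delimited text
#'
#' Writes the per-sample prediction table (trial, fold, sample, y_true,
#' y_pred) and returns the per-trial summary.
#'
#' @param result a [CVResult-class].
#' @param path output TSV path.
#' @return data.frame with per-trial and mean R-squared, invisibly.
#' @export
writeCVResult <- function(result, path) {
    fwrite(cvPredictions(result), path, sep = "\t")
    invisible(data.frame(method = result@method,
                         trial = c(seq_along(result@perTrialR2), NA),
                         r2 = c(result@perTrialR2, meanR2(result))))
}
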