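# Min-max scaling and elastic-net calibration (ENCV).
#
# Objective (sample-size normalization fixed to 1/(2s)):
#   L(beta, b) = 1/(2s) ||y - X beta - b||^2
#              + alpha * (rho ||beta||_1 + (1 - rho)/2 ||beta||_2^2)
# The solver is glmnet; because glmnet internally standardizes y by its
# population sd before applying its penalty, its (lambda, alpha) pair is
# reparameterized exactly onto the objective above (see .glmnetParams).

#' @importFrom glmnet glmnet
#' @importFrom withr with_seed
NULL

# ---- min-max scaler -------------------------------------------------------

#' Fit a per-feature min-max scaler
#'
#' Learns per-feature minimum and range on training data so that the
#' training values of each feature map into `[0, 1]`; constant features map
#' to 0.
#'
#' @param X training matrix (samples by features).
#' @return scaler state: list with `enabled`, `min`, `range`.
#' @export
fitMinmax <- function(X) {
    mins <- apply(X, 2L, min)
    list(enabled = TRUE, min = mins, range = apply(X, 2L, max) - mins)
}

#' Apply a fitted min-max scaler
#'
#' @param X matrix to transform.
#' @param scaler state from [fitMinmax()] (a disabled scaler returns `X`
#'   unchanged).
#' @return transformed matrix.
#' @export
applyMinmax <- function(X, scaler) {
    if (!isTRUE(scaler$enabled)) return(X)
    r <- ifelse(scaler$range > 0, scaler$range, 1)
    out <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, r, "/")
    out[, scaler$range == 0] <- 0
    out
}

#' Invert a min-max transform
#'
#' Exact inverse for non-constant features (constant features are restored
#' to their training value).
#'
#' @param X transformed matrix.
#' @param scaler state from [fitMinmax()].
#' @return matrix on the original scale.
#' @export
invertMinmax <- function(X, scaler) {
    if (!isTRUE(scaler$enabled)) return(X)
    r <- ifelse(scaler$range > 0, scaler$range, 0)
    sweep(sweep(X, 2L, r, "*"), 2L, scaler$min, "+")
}

.disabledScaler <- function() list(enabled = FALSE, min = numeric(),
                                   range = numeric())

# ---- elastic-net loss and fit --------------------------------------------

#' Elastic-net loss
#'
#' Evaluates the penalized least-squares objective
#' `1/(2s) ||y - X beta - b||^2 + alpha (rho ||beta||_1 +
#' (1 - rho)/2 ||beta||_2^2)`. With `beta = 0` and `b = mean(y)` the value
#' is half the population variance of `y`.
#'
#' @param X design matrix (s by p).
#' @param y response vector.
#' @param beta coefficient vector (length p).
#' @param intercept scalar intercept.
#' @param alpha penalty strength (>= 0).
#' @param rho l1/l2 balance in `[0, 1]`.
#' @return scalar loss.
#' @export
enLoss <- function(X, y, beta, intercept, alpha, rho) {
    X <- as.matrix(X)
    if (ncol(X) != length(beta) || nrow(X) != length(y))
        stop("shape error: X, y and beta dimensions do not conform")
    r <- y - as.numeric(X %*% beta) - intercept
    sum(r^2) / (2 * length(y)) +
        alpha * (rho * sum(abs(beta)) + (1 - rho) / 2 * sum(beta^2))
}

# Max violation of the subgradient (KKT) stationarity conditions of the
# objective above, on the gradient/correlation scale g = X'(y - yhat)/s.
kktResidual <- function(X, y, beta, intercept, alpha, rho) {
    s <- length(y)
    g <- as.numeric(crossprod(X, y - as.numeric(X %*% beta) - intercept)) / s
    nz <- beta != 0
    viol <- numeric(length(beta))
    viol[nz] <- abs(g[nz] - alpha * rho * sign(beta[nz]) -
                        alpha * (1 - rho) * beta[nz])
    viol[!nz] <- pmax(0, abs(g[!nz]) - alpha * rho)
    c(viol, abs(mean(y - as.numeric(X %*% beta) - intercept)))
}

# Exact mapping of the 1/(2s)-normalized elastic-net objective onto
# glmnet's internal parameterization. glmnet standardizes y by its
# population sd s_y, making its effective l1 scale lambda*alpha_g and its
# effective l2 scale lambda*(1-alpha_g)/s_y on the original y scale; solve
# lambda_g * alpha_g = alpha*rho, lambda_g * (1-alpha_g) = alpha*(1-rho)*s_y.
# Note lambda_g = alpha * (rho + (1-rho) s_y) and alpha_g does not depend
# on alpha, so a whole penalty-strength path shares one glmnet call.
.glmnetParams <- function(alpha, rho, y) {
    sy <- sqrt(mean((y - mean(y))^2))
    lam <- alpha * rho + alpha * (1 - rho) * sy
    list(lambda = lam, alpha = if (lam > 0) alpha * rho / lam else 1)
}

# Coefficient paths (intercept in row 1) for all penalty strengths at one
# rho, via a single warm-started glmnet path call.
.enPath <- function(X, y, alphas, rho, thresh = 1e-9, maxit = 1e6) {
    sy <- sqrt(mean((y - mean(y))^2))
    C <- rho + (1 - rho) * sy
    if (C <= 0) C <- 1
    ord <- order(alphas, decreasing = TRUE)
    fit <- glmnet(X, y, alpha = if (rho + (1 - rho) * sy > 0) rho / C else 1,
                  lambda = C * alphas[ord], standardize = FALSE,
                  intercept = TRUE, thresh = thresh, maxit = maxit)
    cf <- as.matrix(coef(fit))
    out <- matrix(NA_real_, nrow = nrow(cf), ncol = length(alphas))
    out[, ord] <- cf
    out
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Minimizes the 1/(2s)-normalized elastic-net objective (see [enLoss()])
#' with an unpenalized intercept. Single-feature designs are solved by the
#' closed-form soft-threshold solution; otherwise glmnet is used under an
#' exact reparameterization onto this objective. A warning is raised if the
#' subgradient (KKT) optimality residual exceeds `1e-6`.
#'
#' @param X design matrix (s >= 2 rows), all values finite.
#' @param y response vector.
#' @param alpha penalty strength (>= 0).
#' @param rho l1/l2 balance in `[0, 1]`.
#' @param thresh glmnet convergence threshold.
#' @param maxit glmnet iteration cap.
#' @return an [ENModel-class] (scaler disabled; apply scaling upstream or
#'   use [fitEncv()]).
#' @export
fitElasticNet <- function(X, y, alpha, rho, thresh = 1e-12, maxit = 1e7) {
    X <- as.matrix(X)
    if (!all(is.finite(X)) || !all(is.finite(y)))
        stop("data error: non-finite values in X or y")
    if (nrow(X) < 2L) stop("data error: at least 2 samples are required")
    if (alpha < 0 || rho < 0 || rho > 1)
        stop("parameter error: require alpha >= 0 and rho in [0, 1]")
    s <- nrow(X)
    if (ncol(X) == 1L) {
        xc <- X[, 1L] - mean(X); yc <- y - mean(y)
        denom <- mean(xc^2) + alpha * (1 - rho)
        z <- mean(xc * yc)
        b1 <- if (denom > 0) sign(z) * max(0, abs(z) - alpha * rho) / denom else 0
        beta <- b1
        b0 <- mean(y) - b1 * mean(X)
    } else {
        pars <- .glmnetParams(alpha, rho, y)
        fit <- glmnet(X, y, alpha = pars$alpha, lambda = pars$lambda,
                      standardize = FALSE, intercept = TRUE,
                      thresh = thresh, maxit = maxit)
        cf <- coef(fit)
        beta <- as.numeric(cf[-1L])
        b0 <- as.numeric(cf[1L])
    }
    res <- max(kktResidual(X, y, beta, b0, alpha, rho))
    if (res > 1e-6)
        warning(sprintf(paste0("convergence warning: KKT residual %.3g ",
                               "exceeds 1e-6 (alpha=%g, rho=%g)"),
                        res, alpha, rho))
    new("ENModel", beta = beta, intercept = b0, alpha = alpha, rho = rho,
        scaler = .disabledScaler(), cvTable = data.frame(),
        seed = NA_integer_)
}

#' Default hyperparameter grid
#'
#' 20 penalty strengths log-spaced over `1e-4` to `1e1` (suited to min-max
#' scaled features) crossed with six l1/l2 balances.
#'
#' @return list with components `alpha` and `rho`.
#' @export
defaultGrid <- function() {
    list(alpha = 10 ^ seq(-4, 1, length.out = 20),
         rho = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0))
}

#' Elastic net with cross-validated hyperparameters (ENCV)
#'
#' Selects `(alpha, rho)` by minimizing the mean out-of-fold squared error
#' over seeded shuffled k-fold splits, then refits on all data at the
#' selected pair. When `scaling` is on, the min-max scaler is fitted inside
#' each training fold (never on validation rows) and on the full data for
#' the final refit. Ties on CV error resolve to the largest `alpha`, then
#' the largest `rho` (the sparsest model).
#'
#' @param X feature matrix (samples by features).
#' @param y response vector.
#' @param grid list with `alpha` and `rho` vectors (default [defaultGrid()]).
#' @param folds number of CV folds (default 5; requires `s >= folds >= 2`).
#' @param seed integer seed for the fold shuffle.
#' @param scaling fit a per-fold min-max scaler (default TRUE).
#' @param cvThresh glmnet threshold used during CV search (the final refit
#'   always uses the tight default of [fitElasticNet()]).
#' @param diagnostics keep per-fold bookkeeping (indices and scaler states)
#'   in the `foldInfo` attribute of the returned model.
#' @return an [ENModel-class] with the CV table filled in.
#' @export
fitEncv <- function(X, y, grid = defaultGrid(), folds = 5, seed = 0,
                    scaling = TRUE, cvThresh = 1e-9, diagnostics = FALSE) {
    X <- as.matrix(X)
    s <- nrow(X)
    if (folds < 2L || s < folds)
        stop("parameter error: require s >= folds >= 2")
    combos <- expand.grid(alpha = grid$alpha, rho = grid$rho,
                          KEEP.OUT.ATTRS = FALSE)
    foldId <- with_seed(as.integer(seed), sample(rep_len(seq_len(folds), s)))
    errs <- matrix(0, nrow = nrow(combos), ncol = folds)
    foldInfo <- vector("list", folds)
    for (f in seq_len(folds)) {
        trIdx <- which(foldId != f); vaIdx <- which(foldId == f)
        Xtr <- X[trIdx, , drop = FALSE]; Xva <- X[vaIdx, , drop = FALSE]
        sc <- if (scaling) fitMinmax(Xtr) else .disabledScaler()
        Xtr <- applyMinmax(Xtr, sc); Xva <- applyMinmax(Xva, sc)
        ytr <- y[trIdx]
        for (r in grid$rho) {
            rows <- which(combos$rho == r)
            if (ncol(X) == 1L) {
                for (j in rows) {
                    m <- suppressWarnings(
                        fitElasticNet(Xtr, ytr, combos$alpha[j], r))
                    pred <- as.numeric(Xva %*% m@beta) + m@intercept
                    errs[j, f] <- mean((y[vaIdx] - pred)^2)
                }
            } else {
                cf <- .enPath(Xtr, ytr, combos$alpha[rows], r,
                              thresh = cvThresh)
                pred <- cbind(1, Xva) %*% cf
                errs[rows, f] <- colMeans((y[vaIdx] - pred)^2)
            }
        }
        foldInfo[[f]] <- list(train = trIdx, validation = vaIdx, scaler = sc)
    }
    cvErr <- rowMeans(errs)
    best <- which(cvErr <= min(cvErr) + 0)
    best <- best[order(combos$alpha[best], combos$rho[best],
                       decreasing = TRUE)][1L]
    scFull <- if (scaling) fitMinmax(X) else .disabledScaler()
    final <- fitElasticNet(applyMinmax(X, scFull), y,
                           combos$alpha[best], combos$rho[best])
    model <- new("ENModel", beta = final@beta, intercept = final@intercept,
                 alpha = combos$alpha[best], rho = combos$rho[best],
                 scaler = scFull,
                 cvTable = data.frame(alpha = combos$alpha, rho = combos$rho,
                                      cvError = cvErr),
                 seed = as.integer(seed))
    if (diagnostics) attr(model, "foldInfo") <- foldInfo
    model
}

#' @describeIn fitEncv Predict concentrations for new spectra/features. The
#'   model's scaler (if enabled) is applied before the linear map
#'   `scaled(X) beta + intercept`.
#' @param object an [ENModel-class].
#' @param newdata feature matrix with the model's feature dimension.
#' @param ... unused.
#' @export
setMethod("predict", "ENModel", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@beta))
        stop("shape error: feature dimension ", ncol(newdata),
             " does not match model dimension ", length(object@beta))
    Xs <- applyMinmax(newdata, object@scaler)
    as.numeric(Xs %*% object@beta) + object@intercept
})

# ---- persistence ----------------------------------------------------------

#' Save / load an elastic-net model as a self-describing JSON archive
#'
#' The archive records coefficients, intercept, hyperparameters, scaler
#' state, CV table, seed and package version; only nonzero coefficients are
#' stored.
#'
#' @param model an [ENModel-class].
#' @param path output file.
#' @return `path` invisibly (`readENModel` returns the model).
#' @export
writeENModel <- function(model, path) {
    nz <- which(model@beta != 0)
    obj <- list(format = "WaveletCalib-ENModel", version = 1L,
                package_version = as.character(packageVersion("WaveletCalib")),
                p = length(model@beta),
                nonzero_index = nz, nonzero_beta = model@beta[nz],
                intercept = model@intercept, alpha = model@alpha,
                rho = model@rho, seed = model@seed,
                scaler = model@scaler, cv_table = model@cvTable)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname writeENModel
#' @export
readENModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "WaveletCalib-ENModel"))
        stop("not a WaveletCalib model archive: ", path)
    beta <- numeric(obj$p)
    beta[obj$nonzero_index] <- obj$nonzero_beta
    sc <- obj$scaler
    sc$enabled <- isTRUE(sc$enabled)
    if (is.null(sc$min)) sc$min <- numeric()
    if (is.null(sc$range)) sc$range <- numeric()
    cvt <- if (is.null(obj$cv_table) || !length(obj$cv_table)) data.frame()
           else as.data.frame(obj$cv_table)
    new("ENModel", beta = beta, intercept = obj$intercept,
        alpha = obj$alpha, rho = obj$rho, scaler = sc,
        cvTable = cvt, seed = as.integer(obj$seed))
}
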