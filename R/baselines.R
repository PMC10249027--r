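# Comparison methods: conventional peak-based regression and PLS with a
# CV-chosen component count.

#' Local maxima with topographic prominence
#'
#' Finds strict local maxima (plateau summits are reported at their
#' midpoint) and computes each peak's prominence: the drop from the summit
#' to the higher of the two interval minima reached before meeting higher
#' terrain (or the signal boundary) on each side.
#'
#' @param x numeric signal.
#' @param prominence minimum prominence to retain a peak.
#' @return data.frame with columns `index`, `height`, `prominence`.
#' @export
findPeaksProminence <- function(x, prominence = 0) {
    n <- length(x)
    if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                  prominence = numeric()))
    peaks <- integer()
    i <- 2L
    while (i < n) {
        if (x[i] > x[i - 1L]) {
            j <- i
            while (j < n && x[j + 1L] == x[j]) j <- j + 1L
            if (j < n && x[j + 1L] < x[j])
                peaks <- c(peaks, as.integer((i + j) %/% 2L))
            i <- j + 1L
        } else i <- i + 1L
    }
    if (!length(peaks)) return(data.frame(index = integer(),
                                          height = numeric(),
                                          prominence = numeric()))
    prom <- vapply(peaks, function(p) {
        h <- x[p]
        left <- h
        for (q in rev(seq_len(p - 1L))) {
            if (x[q] > h) break
            left <- min(left, x[q])
        }
        right <- h
        for (q in seq(p + 1L, n)) {
            if (x[q] > h) break
            right <- min(right, x[q])
        }
        h - max(left, right)
    }, numeric(1))
    keep <- prom >= prominence
    data.frame(index = peaks[keep], height = x[peaks[keep]],
               prominence = prom[keep])
}

#' Select calibration peaks of a pure-component spectrum
#'
#' Retains the local maxima of the pure spectrum whose prominence meets the
#' threshold, then removes any candidate lying within `overlapHalfwidth`
#' grid points of a peak found (with the same prominence rule) in any
#' reference spectrum, e.g. the co-monomer and the solvent.
#'
#' @param pure pure-component [Spectrum-class].
#' @param references list of reference [Spectrum-class] objects sharing the
#'   grid (their `sampleId`s label the conflicts).
#' @param prominence prominence threshold (default 0.06 absorbance units).
#' @param overlapHalfwidth overlap removal half-window in grid points
#'   (default 10: conflicts span `[peak - 10, peak + 10]`).
#' @return a [PeakSelection-class].
#' @export
selectMonomerPeaks <- function(pure, references = list(), prominence = 0.06,
                               overlapHalfwidth = 10) {
    grid <- wavenumbers(pure)
    for (ref in references)
        if (!isTRUE(all.equal(wavenumbers(ref), grid)))
            stop("shape error: reference grids must match the pure spectrum")
    cand <- findPeaksProminence(absorbance(pure), prominence)
    conflict <- rep(NA_character_, nrow(cand))
    for (ref in references) {
        rp <- findPeaksProminence(absorbance(ref), prominence)
        if (!nrow(rp) || !nrow(cand)) next
        hit <- vapply(cand$index, function(i)
            any(abs(rp$index - i) <= overlapHalfwidth), logical(1))
        conflict[hit & is.na(conflict)] <- sampleIds(ref)
    }
    keep <- is.na(conflict)
    mk <- function(sel, conf = NULL) {
        df <- data.frame(index = cand$index[sel],
                         wavenumber = grid[cand$index[sel]],
                         height = cand$height[sel],
                         prominence = cand$prominence[sel])
        if (!is.null(conf)) df$conflict <- conf
        df
    }
    new("PeakSelection", monomerLabel = sampleIds(pure),
        prominence = prominence,
        overlapHalfwidth = as.integer(overlapHalfwidth),
        retained = mk(keep), removed = mk(!keep, conflict[!keep]))
}

#' Conventional peak-based linear calibration
#'
#' Ordinary least squares of concentration on the absorbance at each
#' retained peak individually (`per_peak`) or on all retained peaks jointly
#' (`combined`), reporting in-sample and k-fold cross-validated R-squared.
#'
#' @param ds a [SpectralSet-class].
#' @param selection a non-empty [PeakSelection-class] on the dataset grid.
#' @param mode `"per_peak"` or `"combined"`.
#' @param folds folds for the CV R-squared.
#' @param seed fold-shuffle seed.
#' @return data.frame with one row per peak (or one `combined` row):
#'   wavenumber, index, r2_insample, r2_cv.
#' @export
peakRegression <- function(ds, selection, mode = c("per_peak", "combined"),
                           folds = 5, seed = 0) {
    mode <- match.arg(mode)
    pk <- retainedPeaks(selection)
    if (!nrow(pk)) stop("selection error: no retained peaks")
    X <- spectraMatrix(ds)[, pk$index, drop = FALSE]
    y <- concentrations(ds)
    cvR2 <- function(Z) {
        foldId <- with_seed(as.integer(seed),
                            sample(rep_len(seq_len(folds), length(y))))
        yhat <- numeric(length(y))
        for (f in seq_len(folds)) {
            tr <- foldId != f
            fit <- lm.fit(cbind(1, Z[tr, , drop = FALSE]), y[tr])
            cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
            yhat[!tr] <- cbind(1, Z[!tr, , drop = FALSE]) %*% cf
        }
        rSquared(y, yhat)
    }
    insampleR2 <- function(Z) {
        fit <- lm.fit(cbind(1, Z), y)
        cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        rSquared(y, as.numeric(cbind(1, Z) %*% cf))
    }
    if (mode == "per_peak") {
        data.frame(wavenumber = pk$wavenumber, index = pk$index,
                   r2_insample = vapply(seq_len(ncol(X)), function(j)
                       insampleR2(X[, j, drop = FALSE]), numeric(1)),
                   r2_cv = vapply(seq_len(ncol(X)), function(j)
                       cvR2(X[, j, drop = FALSE]), numeric(1)))
    } else {
        data.frame(wavenumber = NA_real_, index = NA_integer_,
                   r2_insample = insampleR2(X), r2_cv = cvR2(X))
    }
}

# ---- PLS ------------------------------------------------------------------

#' Partial least squares with CV-chosen component count
#'
#' Selects the number of PLS components (1 to `maxComponents`) minimizing
#' the mean out-of-fold squared error over seeded shuffled folds, then
#' refits on all data. The underlying fit is mixOmics' single-response
#' regression-mode PLS; zero-variance columns are dropped before fitting.
#'
#' @param X samples-by-features matrix.
#' @param y response vector.
#' @param maxComponents largest component count tried (must not exceed
#'   `min(s - 1, p)`).
#' @param folds CV folds.
#' @param seed fold-shuffle seed.
#' @return list of class `plsCv`: `fit` (mixOmics model), `ncomp`,
#'   `keep` (columns used), `cvTable`.
#' @export
fitPlsCv <- function(X, y, maxComponents = 20, folds = 5, seed = 0) {
    X <- as.matrix(X)
    s <- nrow(X)
    if (s < folds) stop("parameter error: fewer samples than folds")
    if (maxComponents > min(s - 1L, ncol(X)))
        stop("parameter error: maxComponents exceeds min(s - 1, p)")
    colnames(X) <- paste0("v", seq_len(ncol(X)))
    foldId <- with_seed(as.integer(seed), sample(rep_len(seq_len(folds), s)))
    errs <- matrix(NA_real_, nrow = maxComponents, ncol = folds)
    for (f in seq_len(folds)) {
        tr <- which(foldId != f); va <- which(foldId == f)
        Xtr <- X[tr, , drop = FALSE]
        keep <- apply(Xtr, 2L, function(v) diff(range(v)) > 0)
        maxcF <- min(maxComponents, length(tr) - 1L, sum(keep))
        # rank-deficient designs support fewer components: back off until
        # the projection is well-posed
        pred <- NULL
        while (is.null(pred) && maxcF >= 1L) {
            pred <- tryCatch({
                fit <- .plsFit(Xtr[, keep, drop = FALSE], y[tr], maxcF)
                .plsPredictAll(fit, X[va, keep, drop = FALSE])
            }, error = function(e) NULL)
            if (is.null(pred)) maxcF <- maxcF - 1L
        }
        if (is.null(pred)) stop("PLS fit failed on fold ", f)
        for (nc in seq_len(maxcF))
            errs[nc, f] <- mean((y[va] - pred[, nc])^2)
    }
    cvErr <- rowMeans(errs, na.rm = TRUE)
    ncomp <- which.min(cvErr)
    keep <- apply(X, 2L, function(v) diff(range(v)) > 0)
    fit <- .plsFit(X[, keep, drop = FALSE], y, ncomp)
    structure(list(fit = fit, ncomp = ncomp, keep = keep,
                   cvTable = data.frame(ncomp = seq_len(maxComponents),
                                        cvError = cvErr)),
              class = "plsCv")
}

.plsFit <- function(X, y, ncomp) {
    mixOmics::pls(X, matrix(y, ncol = 1L, dimnames = list(NULL, "y")),
                  ncomp = ncomp, mode = "regression", scale = TRUE)
}

.plsPredictAll <- function(fit, Xnew) {
    colnames(Xnew) <- colnames(fit$X)
    p <- predict(fit, Xnew)$predict
    matrix(p, nrow = nrow(Xnew))
}

#' Predict from a CV-selected PLS model
#'
#' @param model result of [fitPlsCv()].
#' @param Xnew new samples-by-features matrix.
#' @return numeric predictions.
#' @export
predictPls <- function(model, Xnew) {
    Xnew <- as.matrix(Xnew)
    colnames(Xnew) <- paste0("v", seq_len(ncol(Xnew)))
    .plsPredictAll(model$fit, Xnew[, model$keep, drop = FALSE])[, model$ncomp]
}

#' Export a peak selection as delimited text
#'
#' @param selection a [PeakSelection-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePeakSelection <- function(selection, path) {
    ret <- retainedPeaks(selection); rem <- removedPeaks(selection)
    ret$status <- if (nrow(ret)) "retained" else character()
    ret$conflict <- if (nrow(ret)) NA_character_ else character()
    rem$status <- if (nrow(rem)) "removed" else character()
    fwrite(rbind(ret, rem[names(ret)]), path, sep = "\t")
    invisible(path)
}
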