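#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.finiteNumeric <- function(x) is.numeric(x) && length(x) > 0L && all(is.finite(x))

.strictlyMonotone <- function(x) {
    d <- diff(x)
    all(d > 0) || all(d < 0)
}

# ---- Spectrum -------------------------------------------------------------

#' Single absorbance spectrum on a wavenumber grid
#'
#' A `Spectrum` holds one sample's absorbance values on a strictly monotone
#' wavenumber grid (stored in measured order, conventionally descending
#' 4000 to 600 cm^-1; array index ascending along the stored order).
#'
#' @slot sampleId character scalar identifier.
#' @slot wavenumbers numeric grid in cm^-1, strictly monotone.
#' @slot absorbance numeric absorbance values, same length as the grid.
#'
#' @export
setClass("Spectrum",
    representation(sampleId = "character",
                   wavenumbers = "numeric",
                   absorbance = "numeric"))

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    if (!.finiteNumeric(object@wavenumbers))
        msg <- c(msg, "'wavenumbers' must be non-empty finite numeric")
    if (!.finiteNumeric(object@absorbance))
        msg <- c(msg, "'absorbance' must be non-empty finite numeric")
    if (length(object@wavenumbers) != length(object@absorbance))
        msg <- c(msg, "'wavenumbers' and 'absorbance' lengths differ")
    if (length(object@wavenumbers) > 1L && !.strictlyMonotone(object@wavenumbers))
        msg <- c(msg, "'wavenumbers' must be strictly monotone")
    if (length(msg)) msg else TRUE
})

#' @describeIn Spectrum Constructor.
#' @param absorbance numeric vector of absorbance values.
#' @param wavenumbers numeric wavenumber grid (cm^-1).
#' @param sampleId sample identifier.
#' @export
Spectrum <- function(absorbance, wavenumbers, sampleId = "spectrum") {
    new("Spectrum", sampleId = as.character(sampleId),
        wavenumbers = as.numeric(wavenumbers),
        absorbance = as.numeric(absorbance))
}

#' @describeIn Spectrum Wavenumber grid accessor.
#' @param x a `Spectrum`.
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumbers)

#' @describeIn Spectrum Absorbance accessor.
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)

#' @describeIn Spectrum Sample identifier accessor.
#' @export
setMethod("sampleIds", "Spectrum", function(x) x@sampleId)

setMethod("show", "Spectrum", function(object) {
    wn <- object@wavenumbers
    cat(sprintf("Spectrum '%s': %d points, %.1f to %.1f cm-1\n",
                object@sampleId, length(wn), wn[1L], wn[length(wn)]))
})

#' @describeIn Spectrum Number of grid points.
#' @export
setMethod("length", "Spectrum", function(x) length(x@absorbance))

# ---- SpectralSet ----------------------------------------------------------

#' Spectral calibration dataset
#'
#' A `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment]:
#' rows are wavenumber grid points (rowData column `wavenumber`, cm^-1,
#' in measured order), columns are samples, the single assay `absorbance`
#' holds the spectra, and colData carries the scalar calibration target
#' `concentration` (mmol/g). The dataset-level component label (e.g. the
#' monomer whose concentration is the target) lives in `metadata()`.
#'
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msg <- character()
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'absorbance' is required")
    wn <- rowData(object)$wavenumber
    if (is.null(wn)) {
        msg <- c(msg, "rowData column 'wavenumber' is required")
    } else {
        if (!all(is.finite(wn)))
            msg <- c(msg, "wavenumbers must be finite")
        if (length(wn) > 1L && !.strictlyMonotone(wn))
            msg <- c(msg, "wavenumbers must be strictly monotone")
    }
    y <- colData(object)$concentration
    if (is.null(y)) {
        msg <- c(msg, "colData column 'concentration' is required")
    } else if (!all(is.finite(y)) || any(y < 0)) {
        msg <- c(msg, "concentrations must be finite and non-negative")
    }
    a <- assay(object, "absorbance")
    if (!all(is.finite(a)))
        msg <- c(msg, "absorbance values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectralSet
#'
#' @param absorbance samples-by-wavenumber numeric matrix (one row per
#'   sample; the design-matrix orientation used by the models).
#' @param wavenumbers shared wavenumber grid (cm^-1), length `ncol(absorbance)`.
#' @param concentrations target concentration per sample (mmol/g).
#' @param sampleIds character sample identifiers (default `"s1"..."sn"`).
#' @param monomerLabel label of the quantified component.
#' @return a validated [SpectralSet-class] object.
#' @export
SpectralSet <- function(absorbance, wavenumbers, concentrations,
                        sampleIds = NULL, monomerLabel = "") {
    absorbance <- as.matrix(absorbance)
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(nrow(absorbance)))
    if (nrow(absorbance) != length(concentrations))
        stop("number of spectra and concentrations differ")
    if (ncol(absorbance) != length(wavenumbers))
        stop("spectrum length and wavenumber grid length differ")
    se <- SummarizedExperiment(
        assays = list(absorbance = t(unname(absorbance))),
        rowData = DataFrame(wavenumber = as.numeric(wavenumbers)),
        colData = DataFrame(sample_id = as.character(sampleIds),
                            concentration = as.numeric(concentrations),
                            row.names = make.unique(as.character(sampleIds))))
    out <- new("SpectralSet", se)
    metadata(out)$monomer_label <- as.character(monomerLabel)
    validObject(out)
    out
}

#' @describeIn SpectralSet Shared wavenumber grid (cm^-1).
#' @param x a `SpectralSet`.
#' @export
setMethod("wavenumbers", "SpectralSet", function(x) rowData(x)$wavenumber)

#' @describeIn SpectralSet Samples-by-wavenumber absorbance matrix (the
#'   orientation consumed by the regression modules).
#' @export
setMethod("spectraMatrix", "SpectralSet", function(x) {
    m <- t(assay(x, "absorbance"))
    rownames(m) <- colData(x)$sample_id
    m
})

#' @describeIn SpectralSet Target concentration vector (mmol/g).
#' @export
setMethod("concentrations", "SpectralSet", function(x) colData(x)$concentration)

#' @describeIn SpectralSet Sample identifiers.
#' @export
setMethod("sampleIds", "SpectralSet", function(x) colData(x)$sample_id)

#' @describeIn SpectralSet Label of the quantified component.
#' @export
setMethod("monomerLabel", "SpectralSet", function(x) {
    lbl <- metadata(x)$monomer_label
    if (is.null(lbl)) "" else lbl
})

#' Extract one sample as a Spectrum
#'
#' @param ds a [SpectralSet-class].
#' @param i sample index or sample id.
#' @return a [Spectrum-class].
#' @export
getSpectrum <- function(ds, i) {
    if (is.character(i)) i <- match(i, sampleIds(ds))
    Spectrum(assay(ds, "absorbance")[, i], wavenumbers(ds), sampleIds(ds)[i])
}

setMethod("show", "SpectralSet", function(object) {
    wn <- wavenumbers(object)
    cat(sprintf("SpectralSet '%s': %d samples x %d points (%.1f to %.1f cm-1)\n",
                monomerLabel(object), ncol(object), nrow(object),
                wn[1L], wn[length(wn)]))
    y <- concentrations(object)
    cat(sprintf("  concentration [mmol/g]: mean %.3f, range %.3f-%.3f\n",
                mean(y), min(y), max(y)))
})

# ---- WaveletBank ----------------------------------------------------------

#' Ricker wavelet bank
#'
#' Holds the `n` width parameters of a Ricker (Mexican-hat) wavelet bank for
#' spectra of length `l`, spanning widths 1 to `l/k` (grid-point units), and
#' the per-width truncated support lengths used for convolution.
#'
#' @slot widths strictly increasing width parameters, `widths[1] == 1`,
#'   `widths[n] == l/k`.
#' @slot k widest-wavelet control parameter.
#' @slot l spectrum length the bank applies to.
#'
#' @export
setClass("WaveletBank",
    representation(widths = "numeric", k = "numeric", l = "integer"))

setValidity("WaveletBank", function(object) {
    msg <- character()
    w <- object@widths
    if (length(w) < 1L || any(w <= 0) || any(diff(w) <= 0))
        msg <- c(msg, "'widths' must be positive and strictly increasing")
    if (length(w) >= 1L && abs(w[1L] - 1) > 1e-9)
        msg <- c(msg, "smallest width must equal 1")
    if (object@k <= 0) msg <- c(msg, "'k' must be positive")
    if (object@l < 2L) msg <- c(msg, "'l' must be at least 2")
    if (length(w) >= 2L &&
        abs(w[length(w)] - object@l / object@k) > 1e-6 * object@l)
        msg <- c(msg, "largest width must equal l/k")
    if (length(msg)) msg else TRUE
})

#' @describeIn WaveletBank Constructor; widths follow [widthSchedule()].
#' @param l spectrum length (grid points).
#' @param n number of wavelets.
#' @param k widest-wavelet control; the largest width is `l/k`.
#' @export
waveletBank <- function(l, n = 10, k = 4) {
    new("WaveletBank", widths = widthSchedule(l, n, k),
        k = as.numeric(k), l = as.integer(l))
}

#' @describeIn WaveletBank Width parameters (grid points).
#' @param x a `WaveletBank`.
#' @export
setMethod("widths", "WaveletBank", function(x) x@widths)

#' @describeIn WaveletBank Truncated support length per width:
#'   `min(ceiling(10 * w), l)` points.
#' @export
setMethod("supportLengths", "WaveletBank",
          function(x) pmin(ceiling(10 * x@widths), x@l))

#' @describeIn WaveletBank Number of wavelets in the bank.
#' @export
setMethod("length", "WaveletBank", function(x) length(x@widths))

setMethod("show", "WaveletBank", function(object) {
    cat(sprintf("WaveletBank: n = %d Ricker wavelets for l = %d (k = %g)\n",
                length(object@widths), object@l, object@k))
    cat("  widths:", paste(signif(object@widths, 5), collapse = ", "), "\n")
})

# ---- ENModel --------------------------------------------------------------

#' Fitted elastic-net calibration model
#'
#' Coefficients and intercept of an elastic-net fit of concentration on
#' (possibly wavelet-expanded) spectral features, together with the
#' hyperparameters, the min-max scaler state learned on the training data,
#' and (for CV-selected fits) the per-(alpha, rho) cross-validation table.
#'
#' @slot beta numeric coefficient vector (sparse in practice).
#' @slot intercept numeric scalar.
#' @slot alpha penalty strength (>= 0).
#' @slot rho l1/l2 balance in `[0, 1]` (1 = lasso).
#' @slot scaler list with elements `enabled`, `min`, `range` (per-feature
#'   min-max state; empty when scaling is disabled).
#' @slot cvTable data.frame with columns alpha, rho, cvError (empty for
#'   direct fits).
#' @slot seed integer seed used for CV fold shuffling (NA for direct fits).
#'
#' @export
setClass("ENModel",
    representation(beta = "numeric", intercept = "numeric",
                   alpha = "numeric", rho = "numeric",
                   scaler = "list", cvTable = "data.frame",
                   seed = "integer"))

setValidity("ENModel", function(object) {
    msg <- character()
    if (length(object@intercept) != 1L || !is.finite(object@intercept))
        msg <- c(msg, "'intercept' must be a finite scalar")
    if (object@alpha < 0) msg <- c(msg, "'alpha' must be >= 0")
    if (object@rho < 0 || object@rho > 1) msg <- c(msg, "'rho' must be in [0,1]")
    if (isTRUE(object@scaler$enabled) &&
        length(object@scaler$min) != length(object@beta))
        msg <- c(msg, "scaler state dimension must match 'beta'")
    if (nrow(object@cvTable) > 0) {
        sel <- abs(object@cvTable$alpha - object@alpha) < 1e-12 &
               abs(object@cvTable$rho - object@rho) < 1e-12
        if (any(sel) && min(object@cvTable$cvError) <
            min(object@cvTable$cvError[sel]) - 1e-12)
            msg <- c(msg, "selected (alpha, rho) must minimise cvError")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ENModel Coefficient vector.
#' @param object an `ENModel`.
#' @param ... unused.
#' @export
setMethod("coef", "ENModel", function(object, ...) object@beta)

#' @describeIn ENModel Intercept.
#' @param x an `ENModel`.
#' @export
setMethod("intercept", "ENModel", function(x) x@intercept)

#' @describeIn ENModel Hyperparameter cross-validation table.
#' @export
setMethod("cvTable", "ENModel", function(x) x@cvTable)

setMethod("show", "ENModel", function(object) {
    cat(sprintf(paste0("ENModel: p = %d features, %d nonzero | alpha = %g,",
                       " rho = %g | scaling %s\n"),
                length(object@beta), sum(object@beta != 0),
                object@alpha, object@rho,
                if (isTRUE(object@scaler$enabled)) "on" else "off"))
})

# ---- ContributionCurve ----------------------------------------------------

#' Gaussian-projected coefficient contribution curves
#'
#' Per-width and total contribution curves over the wavenumber grid obtained
#' by projecting elastic-net coefficients onto Gaussian approximations of
#' their Ricker wavelets (sigma = 0.45 w); the raw-spectrum block contributes
#' single-point terms.
#'
#' @slot grid wavenumber vector (cm^-1).
#' @slot perWidth l-by-(n+1) matrix, one column per wavelet width plus one
#'   (`"raw"`) for the unexpanded spectrum block.
#' @slot total elementwise sum of the per-width columns.
#' @slot scaleNote character description of the coefficient scale convention.
#'
#' @export
setClass("ContributionCurve",
    representation(grid = "numeric", perWidth = "matrix",
                   total = "numeric", scaleNote = "character"))

setValidity("ContributionCurve", function(object) {
    msg <- character()
    if (nrow(object@perWidth) != length(object@grid))
        msg <- c(msg, "'perWidth' rows must match grid length")
    if (length(object@total) != length(object@grid))
        msg <- c(msg, "'total' must match grid length")
    if (!isTRUE(all.equal(object@total, unname(rowSums(object@perWidth)),
                          tolerance = 1e-12)))
        msg <- c(msg, "'total' must equal the row sums of 'perWidth'")
    if (length(msg)) msg else TRUE
})

#' @describeIn ContributionCurve Per-width curve matrix.
#' @param x a `ContributionCurve`.
#' @export
setMethod("perWidthCurves", "ContributionCurve", function(x) x@perWidth)

#' @describeIn ContributionCurve Total contribution curve.
#' @export
setMethod("totalCurve", "ContributionCurve", function(x) x@total)

#' @describeIn ContributionCurve Wavenumber grid.
#' @export
setMethod("wavenumbers", "ContributionCurve", function(x) x@grid)

setMethod("show", "ContributionCurve", function(object) {
    peak <- which.max(abs(object@total))
    cat(sprintf(paste0("ContributionCurve: %d points, %d width channels |",
                       " |total| peaks at %.1f cm-1\n"),
                length(object@grid), ncol(object@perWidth),
                object@grid[peak]))
})

# ---- CVResult -------------------------------------------------------------

#' Repeated cross-validation result
#'
#' Out-of-fold predictions, per-trial R-squared and fold bookkeeping from a
#' repeated k-fold cross-validation run of one modelling method.
#'
#' @slot method method label.
#' @slot seeds integer seed per trial.
#' @slot predictions data.frame with columns trial, fold, sample, y_true,
#'   y_pred (each sample appears exactly once per trial).
#' @slot perTrialR2 R-squared of the pooled out-of-fold predictions, one
#'   value per trial.
#' @slot trainIndex nested list `[[trial]][[fold]]` of training-row indices
#'   (for leakage audits).
#'
#' @export
setClass("CVResult",
    representation(method = "character", seeds = "integer",
                   predictions = "data.frame", perTrialR2 = "numeric",
                   trainIndex = "list"))

setValidity("CVResult", function(object) {
    msg <- character()
    if (length(object@seeds) != length(object@perTrialR2))
        msg <- c(msg, "one R2 per trial/seed is required")
    pr <- object@predictions
    if (nrow(pr)) {
        cover <- tapply(pr$sample, pr$trial, function(s)
            length(s) == length(unique(s)))
        if (!all(unlist(cover)))
            msg <- c(msg, "each sample must be predicted exactly once per trial")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CVResult Per-trial R-squared values.
#' @param x a `CVResult`.
#' @export
setMethod("perTrialR2", "CVResult", function(x) x@perTrialR2)

#' @describeIn CVResult Mean R-squared over trials (the reported metric).
#' @export
setMethod("meanR2", "CVResult", function(x) mean(x@perTrialR2))

#' @describeIn CVResult Pooled out-of-fold prediction table.
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult [%s]: %d trials | mean R2 = %.3f (per trial: %s)\n",
                object@method, length(object@seeds), mean(object@perTrialR2),
                paste(sprintf("%.3f", object@perTrialR2), collapse = ", ")))
})

# ---- PeakSelection --------------------------------------------------------

#' Prominence-selected peaks for conventional calibration
#'
#' Peaks of a pure-component spectrum passing a prominence threshold, minus
#' those removed for overlapping a reference component's peaks.
#'
#' @slot monomerLabel component the peaks belong to.
#' @slot prominence prominence threshold used.
#' @slot overlapHalfwidth overlap removal half-window (grid points).
#' @slot retained data.frame: index, wavenumber, height, prominence.
#' @slot removed data.frame: index, wavenumber, height, prominence,
#'   conflict (label of the reference whose peak triggered removal).
#'
#' @export
setClass("PeakSelection",
    representation(monomerLabel = "character", prominence = "numeric",
                   overlapHalfwidth = "integer",
                   retained = "data.frame", removed = "data.frame"))

setValidity("PeakSelection", function(object) {
    msg <- character()
    if (length(intersect(object@retained$index, object@removed$index)))
        msg <- c(msg, "retained and removed peak sets must be disjoint")
    if (nrow(object@retained) &&
        any(object@retained$prominence < object@prominence - 1e-12))
        msg <- c(msg, "retained peaks must meet the prominence threshold")
    if (length(msg)) msg else TRUE
})

#' @describeIn PeakSelection Retained peak table.
#' @param x a `PeakSelection`.
#' @export
setMethod("retainedPeaks", "PeakSelection", function(x) x@retained)

#' @describeIn PeakSelection Removed (overlap-conflicted) peak table.
#' @export
setMethod("removedPeaks", "PeakSelection", function(x) x@removed)

setMethod("show", "PeakSelection", function(object) {
    cat(sprintf(paste0("PeakSelection '%s': %d retained, %d removed ",
                       "(prominence >= %g, overlap +/-%d points)\n"),
                object@monomerLabel, nrow(object@retained),
                nrow(object@removed), object@prominence,
                object@overlapHalfwidth))
})
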