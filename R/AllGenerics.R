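#' @import methods
#' @importFrom stats predict coef sd var t.test lm lm.fit quantile rnorm runif
#' @importFrom utils head read.table write.table packageVersion
NULL

#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("monomerLabel", function(x) standardGeneric("monomerLabel"))

#' @export
setGeneric("widths", function(x) standardGeneric("widths"))

#' @export
setGeneric("supportLengths", function(x) standardGeneric("supportLengths"))

#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))

#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @export
setGeneric("perTrialR2", function(x) standardGeneric("perTrialR2"))

#' @export
setGeneric("meanR2", function(x) standardGeneric("meanR2"))

#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @export
setGeneric("retainedPeaks", function(x) standardGeneric("retainedPeaks"))

#' @export
setGeneric("removedPeaks", function(x) standardGeneric("removedPeaks"))

#' @export
setGeneric("perWidthCurves", function(x) standardGeneric("perWidthCurves"))

#' @export
setGeneric("totalCurve", function(x) standardGeneric("totalCurve"))
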