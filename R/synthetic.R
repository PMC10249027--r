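# Beer-Lambert reaction-monitoring spectrum simulator with known ground
# truth: pure component spectra built from Gaussian/Lorentzian peaks,
# first-order monomer consumption with mass balance into the polymer,
# per-sample baseline drift and additive homoscedastic noise.

#' Wavenumber grids for simulation
#'
#' A descending grid from 4000 to 600 cm^-1 (the conventional FTIR
#' measurement range). The default 3527 points give ~1 cm^-1 spacing and
#' exercise feature-count identities at full scale; the 256-point mini
#' profile keeps tests fast.
#'
#' @param points number of grid points (default 3527).
#' @param from,to grid endpoints in cm^-1.
#' @return numeric wavenumber vector.
#' @export
spectralGrid <- function(points = 3527, from = 4000, to = 600) {
    seq(from, to, length.out = points)
}

#' Component specification for simulation
#'
#' A component is a label plus a peak list; each peak has a center (cm^-1),
#' a width (cm^-1; Gaussian sigma or Lorentzian half-width), a shape and a
#' molar amplitude (absorbance at unit concentration).
#'
#' @param label component name.
#' @param center,width,amplitude numeric vectors, one entry per peak.
#' @param shape `"gaussian"` or `"lorentzian"` per peak (recycled).
#' @return list of class `componentSpec`.
#' @export
componentSpec <- function(label, center, width, amplitude,
                          shape = "gaussian") {
    if (any(width <= 0)) stop("parameter error: peak widths must be > 0")
    if (any(amplitude < 0)) stop("parameter error: amplitudes must be >= 0")
    structure(list(label = label,
                   peaks = data.frame(center = center, width = width,
                                      amplitude = amplitude,
                                      shape = rep_len(shape, length(center)))),
              class = "componentSpec")
}

#' Pure spectrum of a component at unit concentration
#'
#' Sums the component's peak shapes on the grid: Gaussian
#' `a exp(-(v - c)^2 / (2 w^2))` or Lorentzian `a w^2 / ((v - c)^2 + w^2)`.
#'
#' @param comp a [componentSpec()].
#' @param grid wavenumber vector (cm^-1).
#' @return a [Spectrum-class] (zero spectrum for an empty peak list).
#' @export
componentSpectrum <- function(comp, grid) {
    pk <- comp$peaks
    if (nrow(pk) && (any(pk$center < min(grid)) || any(pk$center > max(grid))))
        stop("parameter error: peak center outside the grid span")
    a <- numeric(length(grid))
    for (i in seq_len(nrow(pk))) {
        d <- grid - pk$center[i]
        a <- a + switch(pk$shape[i],
            gaussian = pk$amplitude[i] * exp(-d^2 / (2 * pk$width[i]^2)),
            lorentzian = pk$amplitude[i] * pk$width[i]^2 /
                (d^2 + pk$width[i]^2),
            stop("parameter error: unknown peak shape '", pk$shape[i], "'"))
    }
    Spectrum(a, grid, comp$label)
}

#' Default three-component copolymerization-like system
#'
#' A monomer with a sharp distinctive band (774 cm^-1) and a vinyl-region
#' band (1638 cm^-1) plus bands overlapping the other components, a polymer
#' sharing the carbonyl/CH regions, and a solvent dominated by broad bands.
#'
#' @return named list of three [componentSpec()] objects
#'   (monomer, polymer, solvent).
#' @export
defaultComponents <- function() {
    list(
        monomer = componentSpec("monomer",
            center = c(774, 1638, 1720, 2950),
            width = c(5, 8, 10, 20),
            amplitude = c(1.0, 0.7, 0.5, 0.3)),
        polymer = componentSpec("polymer",
            center = c(698, 1150, 1725, 2951),
            width = c(10, 40, 12, 22),
            amplitude = c(0.3, 0.5, 0.55, 0.35)),
        solvent = componentSpec("solvent",
            center = c(1105, 2885, 3380),
            width = c(60, 35, 130),
            amplitude = c(0.6, 0.4, 0.25)))
}

#' Reaction simulation specification
#'
#' Emulates a pooled calibration set assembled from several reaction runs,
#' as spectra for calibration are collected in practice. Within each run,
#' first-order monomer consumption `c_m(t) = c0 exp(-rate t)` holds with
#' mass balance into the polymer (`c_p = c0 - c_m`) and constant solvent;
#' initial concentration and rate vary across runs, so no single component
#' is a global affine proxy of the target. Per-sample baseline = quadratic
#' polynomial + one broad Gaussian drift, each with coefficients drawn
#' `N(0, baselineAmplitude)`; additive homoscedastic noise with
#' sd = (max clean absorbance) / `snr` unless `noiseSd` is given.
#'
#' @param components named list of [componentSpec()]s; the first is the
#'   monomer (the regression target), the second the polymer, any further
#'   components are held at constant unit concentration.
#' @param c0 initial monomer concentration per run (mmol/g).
#' @param rate first-order rate constant per run (1/min, >= 0); recycled
#'   against `c0`.
#' @param times sampling times within each run (min); sorted internally.
#'   Total sample count is `length(c0) * length(times)`.
#' @param baselineAmplitude sd of the baseline coefficients (absorbance).
#' @param snr signal-to-noise ratio defining the default noise sd.
#' @param noiseSd explicit noise sd (overrides `snr` when non-NULL).
#' @param nonlinearity amplitude of an optional multiplicative
#'   monomer-solvent interaction term (0 = strict Beer-Lambert).
#' @param seed integer seed for baseline and noise draws.
#' @return list of class `reactionSimSpec`.
#' @export
reactionSimSpec <- function(components = defaultComponents(),
                            c0 = c(0.6, 0.8, 1.0, 1.2),
                            rate = c(0.04, 0.03, 0.035, 0.02),
                            times = seq(0, 60, length.out = 15),
                            baselineAmplitude = 0.02, snr = 50,
                            noiseSd = NULL, nonlinearity = 0, seed = 0) {
    if (any(rate < 0)) stop("parameter error: rate constants must be >= 0")
    if (any(c0 < 0)) stop("parameter error: initial concentrations must be >= 0")
    structure(list(components = components, c0 = c0,
                   rate = rep_len(rate, length(c0)), times = sort(times),
                   baselineAmplitude = baselineAmplitude,
                   snr = snr, noiseSd = noiseSd,
                   nonlinearity = nonlinearity, seed = as.integer(seed)),
              class = "reactionSimSpec")
}

#' Simulate a reaction-monitoring spectral dataset
#'
#' Per sampling time, absorbance = sum_i c_i(t) * pure_i(grid) + baseline +
#' noise; the target is the monomer concentration. The ground truth
#' includes the pure spectra, the concentration trajectories, the noise sd
#' used, and the informative-region mask: grid points where the monomer's
#' pure spectrum exceeds 10% of its maximum while every other component
#' stays below 10% of its own.
#'
#' @param spec a [reactionSimSpec()].
#' @param grid wavenumber vector (default [spectralGrid()] at full scale).
#' @return list with `dataset` (a [SpectralSet-class]) and `truth` (list:
#'   `pure` matrix components-by-points, `concentrations` samples-by-
#'   components, `informativeMask` logical, `noiseSd`, `times`).
#' @export
simulateReactionDataset <- function(spec, grid = spectralGrid()) {
    comps <- spec$components
    E <- t(vapply(comps, function(cs)
        absorbance(componentSpectrum(cs, grid)), numeric(length(grid))))
    run <- rep(seq_along(spec$c0), each = length(spec$times))
    tt <- rep(spec$times, times = length(spec$c0))
    cm <- spec$c0[run] * exp(-spec$rate[run] * tt)
    conc <- cbind(monomer = cm, polymer = spec$c0[run] - cm)
    if (length(comps) > 2L)
        for (j in seq(3L, length(comps)))
            conc <- cbind(conc, 1)
    colnames(conc) <- names(comps)[seq_len(ncol(conc))]
    clean <- conc %*% E
    if (spec$nonlinearity != 0 && ncol(conc) >= 3L)
        clean <- clean + spec$nonlinearity *
            (conc[, 1L] * conc[, 3L]) %o% E[1L, ]
    sdNoise <- if (!is.null(spec$noiseSd)) spec$noiseSd
               else max(abs(clean)) / spec$snr
    s <- length(tt); l <- length(grid)
    u <- seq(-1, 1, length.out = l)
    driftCenter <- mean(range(grid)); driftWidth <- diff(range(grid)) / 6
    A <- with_seed(spec$seed, {
        base <- t(vapply(seq_len(s), function(i) {
            cf <- rnorm(4L, sd = spec$baselineAmplitude)
            cf[1L] + cf[2L] * u + cf[3L] * u^2 +
                cf[4L] * exp(-(grid - driftCenter)^2 / (2 * driftWidth^2))
        }, numeric(l)))
        clean + base + matrix(rnorm(s * l, sd = sdNoise), s, l)
    })
    mask <- E[1L, ] > 0.1 * max(E[1L, ])
    for (i in seq_len(nrow(E))[-1L])
        mask <- mask & (E[i, ] < 0.1 * max(E[i, ]))
    ds <- SpectralSet(A, grid, conc[, 1L],
                      sampleIds = sprintf("r%dt%02d", run,
                                          rep(seq_along(spec$times),
                                              length(spec$c0))),
                      monomerLabel = comps[[1L]]$label)
    list(dataset = ds,
         truth = list(pure = E, concentrations = conc,
                      informativeMask = mask, noiseSd = sdNoise,
                      run = run, times = tt))
}

#' Write simulation ground truth as a sidecar file
#'
#' @param truth the `truth` element of [simulateReactionDataset()] output.
#' @param path output TSV path (concentration table plus mask columns).
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    fwrite(as.data.frame(truth$concentrations), path, sep = "\t")
    maskPath <- paste0(sub("\\.[^.]*$", "", path), ".mask.tsv")
    fwrite(data.frame(point = seq_along(truth$informativeMask),
                      informative = truth$informativeMask),
           maskPath, sep = "\t")
    invisible(path)
}
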