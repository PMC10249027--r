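# WaveletCalib

Quantitative calibration of component concentrations from 1-D absorbance
spectra by Ricker-wavelet feature expansion plus sparse elastic-net
regression (WT-ENCV), with an interpretable projection of the regression
coefficients back onto the spectrum.

## The problem

Monitoring a chemical reaction — here, the consumption of a monomer during
free-radical copolymerization — by FTIR requires turning each absorbance
spectrum into a concentration. The Beer–Lambert law makes absorbance linear
in concentration, but in reaction mixtures the bands of monomer, polymer
and solvent overlap at many widths, so single-peak calibration breaks down.
WaveletCalib is for spectroscopists and chemometricians who want a
multivariate calibration that (a) handles overlapping peaks of very
different widths and (b) can be *read*: which spectral regions, at which
peak widths, drive the predicted concentration.

## The method

Each spectrum `x` of length `l` is convolved ("same" alignment,
zero-padded) with a bank of `n` Ricker (Mexican-hat) wavelets

```
psi(t; w) = 2 / (sqrt(3 w) pi^(1/4)) * (1 - (t/w)^2) * exp(-t^2 / (2 w^2))
```

whose widths run geometrically from `w_1 = 1` grid point to `w_n = l / k`
(`k = 4` by default, so the widest wavelet still fits the spectrum; for
`l = 3527`, widths span 1 to 881.75). The wavelet coefficients are
rectified (`max(0, .)`) and concatenated with the raw spectrum into a
feature vector of length `(n + 1) l` — 38,797 features for `l = 3527`,
`n = 10`. Concentration is then regressed on these features by the elastic
net,

```
min  1/(2s) ||y - X b - b0||^2 + alpha * ( rho ||b||_1 + (1 - rho)/2 ||b||_2^2 )
```

with `(alpha, rho)` chosen by five-fold cross-validation and features
min–max scaled inside each training fold. For interpretation, each
surviving coefficient (width `w`, center `c`) is drawn as a Gaussian at
`c` with `sigma = 0.45 w` — the width ratio that maximizes the cosine
similarity between a Gaussian and the Ricker shape — scaled by the
coefficient on the raw-absorbance scale; summing them gives per-width and
total contribution curves over the spectrum.

The package also provides the comparison methods bespoke to this workflow
(elastic net on raw spectra, PLS with CV-chosen components, conventional
prominence-selected peak regression), a leakage-free repeated k-fold
validation harness, and a Beer–Lambert reaction simulator with known
ground truth.

## Worked example

```r
library(WaveletCalib)

sim  <- simulateReactionDataset(reactionSimSpec(seed = 0), spectralGrid(256))
ds   <- sim$dataset
ds
#> SpectralSet 'monomer': 60 samples x 256 points (4000.0 to 600.0 cm-1)
#>   concentration [mmol/g]: mean 0.436, range 0.054-1.200

bank <- waveletBank(length(wavenumbers(ds)), n = 10, k = 4)
bank
#> WaveletBank: n = 10 Ricker wavelets for l = 256 (k = 4)
#>   widths: 1, 1.5874, 2.5198, 4, 6.3496, 10.079, 16, 25.398, 40.317, 64

model <- fitEncv(featurizeMatrix(ds, bank), concentrations(ds), seed = 0)
model
#> ENModel: p = 2816 features, 34 nonzero | alpha = 0.00206914, rho = 0.7 | scaling on

res <- repeatedCV(ds, wtEncvMethod(n = 10), k = 5, repeats = 5,
                  label = "WT10-ENCV")
res
#> CVResult [WT10-ENCV]: 5 trials | mean R2 = 0.992 (per trial: 0.991, 0.991, 0.993, 0.993, 0.989)

curve <- projectCoefficients(model, featureMap(bank, wavenumbers(ds)),
                             wavenumbers(ds))
curve
#> ContributionCurve: 256 points, 11 width channels | |total| peaks at 773.3 cm-1
```

The simulated monomer's distinctive band sits at 774 cm⁻¹; the repeated
five-fold CV (five seeds) gives a mean out-of-fold R² of 0.992, and the
projected coefficients peak at 773.3 cm⁻¹ — the model found the planted
informative band. `plotContribution(curve, getSpectrum(ds, 1))` draws the
curves over a spectrum.

A command-line interface wrapping the same functions is installed at
`inst/scripts/wtencv` (subcommands `simulate`, `featurize`, `train`,
`crossval`, `visualize`, `baseline`; each run writes its artifacts plus a
reproducibility manifest).

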