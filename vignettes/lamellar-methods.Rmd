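---
title: "Models and methods in lamellar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lamellar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lamellar` implements four measurement chains used to characterize
membrane-active peptides: lipid-titration CD binding isotherms, 1-D
lamellar diffraction reduction, contrast-variation scattering-length
density (SLD) analysis with bound-water accounting, and hydration-shell
counting. This vignette is the package's own account of the underlying
models, the design decisions taken where several choices were defensible,
and the limits of what the bundled synthetic-data validation shows.

## The binding isotherm

A peptide titrated with vesicles partitions between solution and
membrane. With `C_pt` the total peptide concentration, `C_Lt` the total
lipid concentration, `n` lipids occluded per bound peptide and `K_D` the
dissociation constant, mass action gives the implicit relation

```
C_Lt = n f_b [ 1 + K_D / (C_pt (1 - f_b)) ] C_pt .
```

Clearing denominators yields a quadratic in the bound fraction,
`n C_pt f^2 - (n C_pt + n K_D + C_Lt) f + C_Lt = 0`. The product of its
roots is `C_Lt / (n C_pt) > 0` and their sum is
`1 + (n K_D + C_Lt) / (n C_pt) > 1 + C_Lt / (n C_pt)`, so the larger root
always exceeds 1: the smaller root is the physical solution and lies in
[0, 1]. `fractionBound()` evaluates it in the cancellation-free form
`2c / (b + sqrt(b^2 - 4ac))`, which remains exact in the stoichiometric
limit `K_D -> 0`.

The observable is the normalized mean residue ellipticity at 222 nm,
linear in the bound fraction between the buffer baseline (`nMRE_min = 1`,
fixed) and a saturation value `nMRE_max` (free). Raw millidegrees are
converted by `MRE = theta / (10 l c N)` with the path length `l` in cm,
the *per-point, dilution-corrected* molar concentration `c` and `N`
residues. Dilution correction is cumulative-volume bookkeeping: after
adding volume `v` of titrant to an initial volume `V0`, the peptide is
diluted by `V0 / (V0 + v)` and the lipid concentration is
`C_titrant v / (V0 + v)`. The exact correction applied to published raw
data is rarely printed; this cumulative rescaling is the natural reading
of "corrected for dilution effects" and is what the simulator and the
fitting likelihood both use, consistently.

### Posterior inference

The fit is Bayesian: a Gaussian likelihood on the nMRE residuals of the
forward model, with the noise SD treated as a free nuisance parameter
(reported noise levels are rarely available, and fixing it would
understate parameter uncertainty). Priors: log-uniform `K_D` over
[1e-9, 1e-2] mol/L, uniform `n` over [1, 200], uniform `nMRE_max` over
(1, 50], half-normal (scale 1 nMRE unit) on the noise SD.

Sampling uses a differential-evolution ensemble (20 walkers for 4
parameters; each proposal is the walker plus `gamma` times the difference
of two walkers from the opposite half-ensemble, `gamma = 2.38 / sqrt(2p)`
with a unit-gamma mode-jumping generation every tenth). The scale is
adapted toward ~25% acceptance during burn-in only. Burn-in is discarded
by an integrated-autocorrelation-time heuristic (10 tau, capped at half
the run); convergence is monitored by split-walker R-hat and non-converged
fits are flagged, never silently returned. Fits are deterministic given a
seed.

Two properties of this posterior deserve emphasis. First, titrations that
stop short of full saturation (the default schedule reaches ~83% bound at
its endpoint) leave a long curved ridge between `K_D`, `n` and
`nMRE_max`: the data constrain the position of the binding transition
well, its decomposition into affinity versus stoichiometry less so. The
ridge mixes slowly (integrated autocorrelation times of several hundred
generations) and is the reason for the long default runs. Second, at
realistic noise (~0.3 nMRE units) single noisy realizations can support
parameter combinations far along the ridge; posterior medians are
faithful summaries of each realization, not guaranteed reproductions of
the planted values. The bundled coverage test quantifies this: across
seeded replicate titrations the central 68% interval covers the planted
`K_D` in well over half of the runs, which is what a calibrated interval
should do.

Curves that never leave the baseline (signal below four times the
point-to-point noise) are flagged `no.binding.detected` and not fitted;
compositions that suppress binding produce exactly this outcome.

Percent helicity uses a two-state interpolation between a random-coil
baseline and a chain-length-corrected helix limit; the constants are
arguments (`mreHelix = -40000 (1 - 2.5/N) + 100 T`,
`mreCoil = 640 - 45 T` by default, `T` in Celsius) because several
published baseline sets are in circulation.

## Diffraction reduction

Traces are converted to momentum transfer with
`Q = 4 pi sin(theta) / lambda` (theta-2theta geometry, so `theta` is half
the detector angle). Peak picking selects local maxima by topographic
prominence above a noise scale estimated robustly (MAD with a Poisson
floor); maxima within one rough FWHM of a stronger one are suppressed
(they are unresolvable), overlapping windows are refined jointly by a
sum-of-Gaussians-plus-linear-background Levenberg-Marquardt fit with
Poisson weights, and refined peaks must clear their local background by
four counting SDs. A flat-noise trace therefore yields an empty peak
list, which downstream code treats as a valid "lamellar order lost"
result rather than an error.

Orders are assigned by nearest-integer ratio to the lowest peak. A base
order above 1 for the lowest peak (needed when the first order is
extinct) is accepted only when base-1 indexing is inconsistent *and* the
alternative halves the residual - otherwise any peak set can be "indexed"
by a sufficiently fine lattice - and assigned orders are capped at 12.
The repeat spacing is `d = 2 pi / slope` from a weighted through-origin
regression of `Q_h` on `h`, with `d`'s SD propagated from the regression;
its residuals flag two-lattice candidates.

Two-lattice decomposition enumerates every assignment of peaks to two
lattices (exact for up to 12 peaks) and keeps the split only if it beats
the single-lattice fit by a margin on a scale-free criterion: the
chi-squared improvement normalized by the two-lattice residual variance
must exceed `log(n)` (the BIC cost of the extra slope) plus a
configurable margin (default 10). This guard is what prevents noise from
being "explained" as a split; coincident spacings are flagged
degenerate.

Structure factors are square roots of background-corrected integrated
counts in windows around each `Q_h`, with a linear background from
flanking strips and SDs from Poisson statistics through the square root
(`sd_F = sd_area / 2F`). Absorption and extinction corrections are
instrument-specific; they enter as pluggable multiplicative functions
(identity by default, a thin-film absorption option provided) and must be
calibrated per instrument for absolute work.

## Phasing, SLD profiles and water accounting

For a centrosymmetric bilayer the phase problem reduces to signs, and
H2O/2H2O exchange determines them: each signed `F(h)` is linear in the
D2O mole fraction `x`. Per order, the sign pattern across contrasts is
found by exhaustive enumeration (the first contrast fixed positive)
minimizing the weighted straight-line residual; the remaining per-order
flip is fixed by the physical anchor that the water difference density is
positive at the unit-cell boundary, i.e. the slope `dF(h)/dx` carries
sign `(-1)^h`.

A plain per-order line fit has a blind spot: when an order's `F` crosses
zero inside the measured `x` range, the smallest-|F| contrast's sign can
be absorbed by the free slope at almost no chi-squared cost. The default
method therefore adds a second stage in which all orders' slopes are tied
to the shared water-envelope transform `A (-1)^h exp(-beta h^2)` (the
inter-bilayer water is one distribution, so one amplitude and one width
generate every order's x-response); with the slope fixed per order, only
the intercept is free and a flipped sign can no longer be compensated.
Orders whose best and second-best patterns are statistically tied, or
whose slope is smaller than its SD, are flagged `phase.ambiguous`. The
plain per-order method remains available (`method = "linear"`).

Profiles are cosine syntheses `rho(z) = (2/d) sum_h F(h) cos(2 pi h z/d)`
on a 512-point grid per period, even by construction, truncated at the
observed `hmax` (5 in the reference datasets) with no apodization by
default. The unmeasurable mean (`h = 0`) term is omitted, so profiles are
relative and integrate to zero over one period; the object records
whether a profile is relative or amplitude-calibrated.

That missing mean term dictates how component areas are measured: the
"integral" of a label distribution in a mean-free, band-limited profile
is not the literal trapezoid (which is zero over the period) but the
`h -> 0` extrapolation of its transform. `fitGaussianComponents()`
therefore evaluates its model *through the same truncated cosine
coefficients* as the data profile - truncation then introduces no bias
and a noiseless planted component set is recovered exactly - and can
equivalently fit in structure-factor space, which weights each measured
order by its own SD (profile points are correlated combinations of the
few measured amplitudes, so per-point profile weights understate the
information in precise high orders). Mirrored pairs share center, width
and area; centers and widths can be pinned; widths are bounded below at
the grid resolution.

Amplitude calibration divides the known integrated scattering length of a
d7 acyl label (`labelFraction x 7 x (b_2H - b_H)` per lipid, with
`b_2H - b_H = 1.041e-4` Angstrom) by the fitted label area of the
labeled-minus-unlabeled difference. Because the label is x-independent,
the differences at every shared contrast measure the same `F_label(h)`
and are pooled by inverse variance. The calibration fit is bounded to
physically sensible label geometries (center within the inner quarter
cell, FWHM in [5, 30] Angstrom); an acyl-chain label cannot sit in the
inter-bilayer water region, and the bound is what keeps the
`h -> 0` extrapolation stable when only the low orders carry label
signal. Note the error amplification inherent to the subsequent
accounting: the excess-water signal is a minority share of the total
exchanged scattering length, so a given relative error on the
calibration scale is magnified several-fold in the recovered
waters-per-peptide count. This is a property of the measurement design,
not of the implementation, and the Monte-Carlo resampling SD reports it
honestly.

Water accounting counts 2 exchangeable protons per water and `N_x`
(default 57, with +/-2 carried in propagation) per peptide:
`w_P = [B/(x db) - N_x r - 2 w_L]/(2 r)` with `w_L = 9.4` waters per
lipid treated as exact by default (its published uncertainty is not
available; an SD argument exists). The spatial water-difference profile
is returned alongside, so users can window inter-bilayer versus
intramembrane water themselves; the accounting integrates the full unit
cell.

Uncertainties propagate by Monte-Carlo resampling: `n = 100` mock
structure-factor sets drawn within +/-1 SD, each pushed through the same
deterministic chain (for the water count: phasing, differencing,
calibration and the envelope fit are all inside the resampling loop).
Each mock fit starts from the point estimate - the standard resampling
protocol - and chronic mock failures (> 20%) flag the aggregate. One
caveat is intrinsic to mirrored-pair models: the model is even in the
pair center, so the parameter space folds at zero. When the data barely
distinguish a small center from zero (heavily overlapped pairs, few
informative orders), mock estimates pile up at the fold and the ensemble
mean of |center| is biased low even though the width and area remain
well determined. The ensemble SD makes this visible; treat
small-|center| means near their own SD as "consistent with a small or
zero splitting".

## The synthetic-data generator

`bilayerModel()` builds a Gaussian-component unit cell loosely shaped on
a fluid phosphatidylcholine bilayer: mirrored headgroup maxima at +/-20
Angstrom (SD 3), a terminal-methyl trough at the center, a wrapped
inter-bilayer water envelope at the cell boundary (SD 4.5 Angstrom) whose
amplitude is linear in the D2O fraction, a peptide envelope, and an
optional d7 label pair (+/-1.87 Angstrom, FWHM 15, by default). Component
areas are scattering length per lipid; the water envelope carries
`(w_L + w_P r)` waters per lipid with `b(H2O) = -1.68e-5` Angstrom plus
`2 x db` per water of exchange contrast. The peptide's exchangeable
protons are co-located with the water envelope by default (the
arginine-rich regions that exchange fastest sit among the interfacial
waters, and the accounting uses only the total exchanged area, not its
position); the center and width are arguments for users who want them
elsewhere. These shapes are simulation fixtures chosen once to be
realistic, not structural claims about any particular peptide.

Default study conditions mirror the reference experiments: titrations of
300 uL of 20 umol/L peptide with 20 additions of 10 uL of 3 mmol/L
vesicles (peptide-to-lipid 1:5 to 1:100) at 0.3 nMRE Gaussian noise;
neutron wavelength 5 Angstrom, X-ray 1.54; five diffraction orders with
Gaussian peak FWHM 0.005 1/Angstrom and Poisson counting noise; contrast
series at `x` = 0, 0.5, 1 with 5% relative amplitude SDs (and a 0.5%-of-
maximum floor) under an arbitrary instrument scale the pipeline must
recover; peptide-per-lipid 1:25 with 114 planted excess waters per
peptide. Every generator records its planted values in a `groundTruth`
audit list, and the recovery tests read truth only from there. All
generators are bit-reproducible under a fixed seed.

What passing recovery tests show - and what they do not: the closed loops
demonstrate that the estimators are consistent and correctly propagate
the modeled noise (counting statistics, Gaussian amplitude errors,
titration scatter). They do not exercise instrument resolution functions
beyond Gaussian peak widths, mosaicity, off-specular scattering,
background structure, baseline drift in CD, or model error in the
Gaussian-component description of a real bilayer. Quantitative
absorption/extinction corrections and absolute helicity constants must
come from the instrument and the literature, respectively.

## Problem sizes

The test suite and the acceptance script run at desk scale on one CPU:
MCMC fits use 20 walkers for 6,000 generations (about 10^5 likelihood
evaluations, a few seconds each; replicate-based checks use shorter
chains), diffraction patterns 2,000-2,500 bins, profiles 512 grid
points, resampling ensembles 100 mocks, and hydration analyses a few
thousand points over a handful of frames.
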