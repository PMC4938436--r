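---
title: "Binary-constrained spectral unmixing: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary-constrained spectral unmixing: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binaryunmix)
```

## The problem

Combinatorially labeled specimens — for instance microbial cells tagged by
rRNA-targeted FISH probes carrying exactly two fluorophores each — encode
object identity in a *pair* of dyes drawn from a repertoire of $n$. With
$n = 16$ fluorophores there are $\binom{16}{2} = 120$ label types, far more
than the number of dyes a bandpass-filter experiment can separate, and more
than standard linear unmixing can resolve reliably once the dyes' emission
spectra overlap and photons are scarce.

Three ideas make the readout work, and this package implements all three.

### 1. Excitation/emission concatenation

A spectral image records an emission spectrum in $m$ channels per pixel.
Acquiring the same field under $p$ different excitation lasers and joining
the stacks end to end gives a concatenated spectrum with one entry per
excitation/emission combination. Emission *shape* is essentially invariant
to excitation, but emission *amplitude* follows the dye's excitation
spectrum, so the concatenated vector carries both signatures. The
concatenated axis always orders excitations ascending by wavelength;
acquisition happens in descending order (long wavelengths first, which
minimizes bleaching of red dyes during the blue exposures), and the layout
object records both orders so files can be ingested as acquired.

Reference spectra are peak-normalized **after** concatenation — one global
unit per dye, the overall brightest excitation/emission channel — not per
excitation block. Normalizing per block would destroy the relative
excitation amplitudes that make the concatenated signature informative.

### 2. Segmentation and per-object averaging

Unmixing is linear in the observation, so for noise-free data the average
of per-pixel solutions equals the solution of the averaged spectrum
(verified to $10^{-9}$ relative tolerance in the test suite). Averaging
first is therefore free of modeling cost and buys two things: a
$\sim$`r format(1024*1024/100, big.mark = ",")`-fold reduction in solver
calls for a 1024×1024 field with ~100 cells, and a $1/\sqrt{N}$ reduction
in spectral noise for an $N$-pixel object before the nonlinear pair
selection happens — which is where the accuracy gain comes from, since pair
selection, unlike the linear solve, does not commute with averaging.

Thresholding uses Otsu's criterion — exhaustive maximization of the
between-class variance $w_0 w_1 (\mu_0 - \mu_1)^2$ over the 256-bin
histogram of the per-pixel sum across a configurable channel subset
(default: all channels). The returned threshold is the upper edge of the
last background bin of the first maximizing split; when the two modes are
separated by an empty gap every cut in the gap is equivalent and the first
one is chosen, which is deterministic and still separates the modes
exactly. Connected components are 8-connected; objects below `min_size`
(default 4 px) are discarded. No watershed splitting is attempted: the
method assumes well-dispersed cells, and objects that touch — especially
axially — violate the one-object-one-pair assumption by construction.

### 3. The binary label constraint

For an object with averaged spectrum $y$, background $b$ and reference
matrix $F = [f_1 \dots f_n]$, every pair $\{i, j\}$ is fitted by

$$\min_{x_i, x_j \ge 0} \; \lVert (y - b) - f_i x_i - f_j x_j \rVert^2,$$

and the pair attaining the smallest sum of squared residuals (SSR) is the
object's label type. This is exhaustive search over all
$\binom{n}{2}$ two-column submodels — maximum-likelihood model selection
under homoscedastic Gaussian noise — and is cheap because each fit has a
closed form (see below). Ties are broken by lexicographic pair order;
with noise they have measure zero. Confidence is reported as the Pearson
correlation between $y$ and the winning model spectrum
$f_i x_i + f_j x_j + b$ (background-inclusive on both sides, so the score
reflects the spectrum actually observed).

Design choices that were genuinely open:

* **Non-negativity inside each pair fit.** The two-component model does not
  force it, but negative dye abundances are unphysical, and the 2-variable
  non-negative solve is exact and cheap. Without the constraint, wrong
  pairs could fit difference spectra and the selection would degrade.
* **Background as a fixed vector, not a fitted amplitude.** $b$ is the
  per-channel mean over a cell-free region of interest and is assumed
  identical for all objects (stray light); fitting a background amplitude
  per object would add a third free parameter to every candidate fit and
  dilute exactly the constraint that gives the method its power.
* **No sum-to-one constraint on abundances.** Abundances are unnormalized
  intensities on the photon scale; a simplex constraint would discard
  brightness information.

## Solvers and numerics

`unmix_unconstrained()` solves ordinary least squares by QR; rank-deficient
references produce a warning and the SVD minimum-norm solution (singular
values below $10^{-12}$ of the largest are treated as zero).
`unmix_nonnegative()` delegates to the Lawson–Hanson active-set
implementation in `pracma::lsqnonneg`. `unmix_with_fallback()` implements
the two-stage policy: the fast unconstrained solve is accepted only if all
abundances are non-negative, otherwise the constrained solve replaces it —
the branch taken is recorded per object.

Each binary pair fit is solved in closed form from the $2 \times 2$ Gram
system: if the unconstrained optimum is feasible it is optimal; otherwise
the optimum lies on a boundary and the better of the two single-component
fits (coefficients clipped at zero) is taken. This is exactly the
active-set enumeration for two variables; agreement with an independent
Lawson–Hanson solve and with a nested grid search is asserted to $10^{-6}$
in the tests, and KKT optimality to $10^{-8}$. Pairs whose Gram matrix has
condition number above $10^8$ (near-parallel spectra) are still fitted but
flagged degenerate. Residuals are computed from the Gram sufficient
statistics and clamped at zero; the numerical floor is $\sim 10^{-15}$
relative to $\lVert y \rVert^2$, well below the $10^{-12}$ tolerance used
for noise-free identifiability checks.

Coordinates are 1-based `(row, col)` with inclusive bounding boxes
throughout, the R convention.

## The simulator

The simulator emulates the full acquisition so the pipeline can be
validated end to end without microscope data.

* **Dye models.** Gaussian excitation and emission spectra,
  parameterized by peak (nm), width (nm, standard deviation) and
  brightness. The default 16-dye palette uses the catalogue peak positions
  of common commercial dyes (7-hydroxycoumarin through AF700, 370–702 nm
  excitation) with widths of 20 nm (excitation) and 15 nm (emission),
  matching the $\approx$35 nm FWHM typical of organic dyes. The shapes are
  synthetic: real spectra are skewed with red tails and vibronic shoulders,
  so real dyes are somewhat *more* distinguishable at close peak spacing
  than these Gaussians — passing tests here exercise the harder geometry.
  Emission at or below the exciting wavelength is zeroed (no anti-Stokes
  emission is modeled).
* **Default layout.** Six excitations (405–633 nm) with 30, 24, 21, 16,
  13, 11 emission channels of 10 nm, 115 concatenated channels in total.
  The per-excitation split is a package choice — real instruments vary —
  and every function accepts arbitrary layouts.
* **Noise and SNR.** Photon counts are independent Poisson draws around
  the expected spectrum. SNR follows the shot-noise convention: a target
  `snr` scales the expected spectrum so its peak channel expects
  $\mathrm{snr}^2$ photons, giving peak-channel
  $\mathrm{SNR} = \mathrm{snr}$. Realized mean/variance and SNR are
  verified against this convention in the tests.
* **Images.** Cells are randomly oriented ellipses (semi-axes 5 × 2.5 px
  by default — rod-like at the default scale; shape does not enter the
  unmixing math) placed without overlap with a 2-px guard ring, with
  per-fluorophore abundances jittered uniformly on (0.7, 1.3) around the
  nominal 1:1 labeling to emulate labeling/pipetting variability, a
  constant stray-light background (default 1 expected photon per channel),
  and a reserved cell-free corner for background estimation. Stacks are
  returned in acquisition (descending-excitation) order. Not modeled:
  photobleaching, detector read noise and gain, PSF blur, chromatic
  aberration, and touching/overlapping cells — so perfect synthetic scores
  bound, rather than predict, real-data performance.

## Experiments

`run_snr_experiment()` isolates the value of the binary constraint from
that of concatenation: four green-excited dyes (AF488, BODIPY-FL, OG514,
AF546), one 488 nm excitation, 16 × 10 nm channels, particles carrying
AF488 + BODIPY-FL at 1:1, 1000 particles per SNR level over the default
grid `c(2, 5, 10, 20, 50)`. Each particle is classified by the
binary-constrained solver and by plain unconstrained unmixing with a
top-2-abundance readout. In the noise-limited regime (SNR $\le 10$) the
constraint is worth tens of percentage points of exact-pair accuracy. One
honest caveat this package's own experiments surface: in a window around
SNR 15–30, the top-2 readout can edge out minimum-SSR pair selection by a
few points in this Gaussian geometry, because AF488's spectrum is nearly a
positive combination of its two flanking dyes and an equal-abundance prior
(implicit in the top-2 rule) then helps; both methods exceed 99.5% by
SNR 50. The default grid reports the full transition rather than hiding
the window.

The restricted-mixture experiment estimates the error rate the way a
wet-lab control would: particles drawn only from the 15 label types
containing one fixed fluorophore are unmixed against all 120 candidates,
and any assignment outside the 15 (an *impossible* label type) is an
error by construction. At SNR 30 with 1000 particles the measured
impossible-type rate is below 1%. The linear-ramp experiment draws 3000
particles from 120 types with proportions ramping linearly from 0.12% to
1.5% and correlates detected against true proportions.

Problem sizes in the bundled tests and in `scripts/acceptance.R` (500–3000
particles, 240-cell images at 420×420, 1000 particles per SNR level) were
chosen so the whole validation runs in a few minutes on one CPU while
keeping Monte-Carlo error well inside the asserted margins.

## Known limitations

* Unweighted least squares is not the maximum-likelihood estimator under
  Poisson noise (bright channels are noisier); the pipeline follows the
  standard unweighted convention throughout.
* The pair search is exhaustive in $\binom{n}{2}$; for the intended
  $n \le 16$ this is 120 closed-form fits per object and negligible, but
  the cost grows quadratically in $n$.
* Per-pixel classification is supported only for the unconstrained/NNLS
  solvers; the binary constraint is designed for segmented objects, and
  applying it per pixel would both cost $\binom{n}{2}$ iterative fits per
  pixel and forgo the averaging that justifies the constraint.
* Reference spectra must be acquired with the same instrument settings and
  acquisition order as the specimen; bleaching correction and
  cross-instrument wavelength harmonization are out of scope.
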