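# binaryunmix

Identify objects labeled with **binary combinations of fluorophores** in
multi-excitation spectral microscope images.

Combinatorial labeling is a standard trick for multiplexed fluorescence
imaging of microbes: tag every population of cells (e.g. rRNA-FISH-labeled
bacteria) with exactly two fluorophores out of a repertoire of *n*, and
*n* dyes distinguish `choose(n, 2)` populations — 120 *label types* from 16
fluorophores. The catch is that the dyes overlap heavily in emission, and
plain linear unmixing of a spectral image cannot reliably tell 16 highly
overlapping dyes apart at realistic photon counts, let alone 120 pairings.

This package implements the spectral image analysis pipeline that makes the
combinatorial strategy work:

1. **Excitation/emission concatenation.** Emission stacks recorded at *p*
   excitation wavelengths over the same field are joined end to end into one
   *m*-channel spectrum per pixel, so both the excitation and the emission
   spectrum of every dye constrain the unmixing.
2. **Per-object averaging.** Particles are segmented from the raw spectral
   image (Otsu threshold on a channel-sum image, 8-connected components) and
   each object is reduced to its mean spectrum — turning ~10⁶ per-pixel
   problems into ~10² per-object problems and shrinking spectral noise by
   `1/sqrt(pixels)`.
3. **Binary-label-constrained unmixing.** For each object with averaged
   spectrum `y`, every candidate pair `{i, j}` is fitted to the two-component
   model

   ```
   y = f_i x_i + f_j x_j + b,     x_i, x_j >= 0
   ```

   where `f_i`, `f_j` are columns of the m x n reference matrix `F` of
   peak-normalized dye spectra and `b` is a constant stray-light background
   estimated from a cell-free region. The pair with the smallest sum of
   squared residuals is the object's label type; the Pearson correlation
   between `y` and the reconstructed model spectrum scores confidence.

The classical solvers are also provided: ordinary least squares `y = F x`
([`unmix_unconstrained()`]), non-negative least squares
([`unmix_nonnegative()`]), and the two-stage policy that accepts the fast
unconstrained solution only when all abundances are non-negative
([`unmix_with_fallback()`]).

A fully parametric simulator (Gaussian excitation/emission dye models, a
16-dye palette named after common commercial dyes, Poisson shot noise with
`SNR = sqrt(peak photon count)`, whole synthetic images of elliptical cells)
supports validation without any microscope data.

## Worked example

```r
library(binaryunmix)

ref <- synth_reference_matrix()        # 16 dyes on the 6-laser default layout
ref
#> Reference matrix: 115 channels x 16 fluorophores
#>   fluorophores: 7HC, PacBl, AF405, PacOr, AF488, BOFl, OG514, AF546, ...

sim <- generate_synthetic_image(ref, enumerate_pairs(16), n_cells = 60,
                                dim = c(220, 220), snr = 30, seed = 11)
image <- concatenate_stacks(sim$stacks, sim$layout)
mask  <- segment_image(image)
mask
#> Segmentation mask 220x220: 60 particle(s), threshold 183.6, min size 4 px

b   <- estimate_background(image, sim$clear_roi, mask = mask)
cls <- classify_image(image, mask, ref, b = b)
head(cls[, c("particle_id", "label_type", "x_i", "x_j", "confidence")], 4)
#>   particle_id  label_type      x_i      x_j confidence
#> 1           1   7HC+OG514 404.7016 560.9023  0.9999606
#> 2           2 PacBl+AF555 448.9460 432.2374  0.9999765
#> 3           3 AF555+AF647 455.6273 391.9699  0.9999693
#> 4           4   7HC+AF647 386.8947 428.1564  0.9999594

score_assignments(cls, sim$truth, match_radius = 8)
#> Assignment score: 60 assigned, 60 matched to ground truth (0 unmatched)
#>   exact-pair accuracy: 100.0%
#>   input-output proportion correlation: 1.000
```

Each row assigns one segmented cell its fluorophore pair (the label type),
the two non-negative abundances on the photon scale, and the Pearson-`r`
confidence of the winning fit. At SNR 30 with averaging over ~40-pixel
cells, all 60 cells in this field are assigned their generating pair.

`run_snr_experiment()` reproduces the head-to-head comparison of the
binary-constrained solver against standard unmixing with a top-2-abundance
readout on a deliberately hard configuration (four green dyes, one 488 nm
excitation, 16 emission channels); `plot()` on its result draws both curves.

## Command line

A thin CLI over the same functions is installed at `inst/cli/binaryunmix`:

```sh
Rscript inst/cli/binaryunmix simulate   --out sim --n-cells 120 --snr 30 --seed 1
Rscript inst/cli/binaryunmix references --layout sim/layout.yaml --out refs.tsv \
    --pure AF488=pure/AF488 --pure BOFl=pure/BOFl
Rscript inst/cli/binaryunmix classify   --layout sim/layout.yaml \
    --refs sim/references.tsv --stacks sim --roi 1,1,16,16 --out results
Rscript inst/cli/binaryunmix snr        --out snr.csv
```

`classify` writes the assignment table, particle table, quantification
report, label mask and a pseudo-colored label-type map (one distinct color
per label type; in restricted-mixture mode, label types known to be absent
are drawn gray).

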