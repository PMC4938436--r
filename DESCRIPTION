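Package: binaryunmix
Title: Binary-Constrained Spectral Unmixing for Combinatorially Labeled Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies objects labeled with binary combinations of
    fluorophores in multi-excitation spectral microscope images. Emission
    stacks acquired at several excitation wavelengths are concatenated into a
    single spectral axis, segmented particles are reduced to averaged object
    spectra, and each object is assigned the pair of reference fluorophores
    whose non-negative two-component least-squares fit minimizes the sum of
    squared residuals, so that n fluorophores distinguish choose(n, 2) label
    types (120 from 16). Includes reference-spectrum derivation from pure
    singly-labeled populations, Otsu segmentation with per-object spectral
    averaging, Pearson-correlation confidence scores, a Poisson shot-noise
    simulator of spectra and whole images, and experiment drivers comparing
    constrained and unconstrained unmixing across signal-to-noise ratios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    pracma,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
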