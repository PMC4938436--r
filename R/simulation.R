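#' Parametric fluorophore model
#'
#' A synthetic fluorophore with Gaussian excitation and emission spectra,
#' used by the simulator to build reference matrices and noisy test data.
#' Peaks are in nm; widths are Gaussian standard deviations in nm. A positive
#' Stokes shift (emission peak above excitation peak) is required.
#'
#' @param name fluorophore label.
#' @param ex_peak,em_peak excitation / emission peak wavelengths (nm), within
#'   350-800 nm.
#' @param ex_width,em_width Gaussian widths (nm).
#' @param brightness relative brightness scale (> 0).
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(name, ex_peak, em_peak, ex_width = 20,
                              em_width = 15, brightness = 1) {
  if (ex_peak < 350 || ex_peak > 800 || em_peak < 350 || em_peak > 800)
    stop("peaks must lie in the 350-800 nm range")
  if (em_peak <= ex_peak)
    stop("emission peak must exceed excitation peak (positive Stokes shift)")
  if (ex_width <= 0 || em_width <= 0 || brightness <= 0)
    stop("widths and brightness must be positive")
  structure(list(name = as.character(name), ex_peak = ex_peak,
                 em_peak = em_peak, ex_width = ex_width,
                 em_width = em_width, brightness = brightness),
            class = "fluorophore_model")
}

#' Default 16-dye synthetic palette
#'
#' Sixteen fluorophore models named after commercial dyes commonly used for
#' combinatorial rRNA-FISH labeling, spanning 370-702 nm excitation peaks.
#' Peak positions are nominal catalogue values; the Gaussian spectral shapes
#' (and therefore every number derived from them) are synthetic.
#'
#' @return List of 16 [fluorophore_model()] objects.
#' @export
default_fluorophores <- function() {
  spec <- list(
    c("7HC",    370, 450), c("PacBl",  401, 455), c("AF405",  401, 421),
    c("PacOr",  400, 551), c("AF488",  495, 519), c("BOFl",   503, 512),
    c("OG514",  511, 530), c("AF546",  556, 573), c("AF555",  555, 565),
    c("TET",    555, 580), c("RRX",    560, 592), c("AF594",  590, 617),
    c("AF633",  632, 647), c("AF647",  650, 668), c("AF680",  679, 702),
    c("AF700",  702, 723))
  lapply(spec, function(s)
    fluorophore_model(s[1], as.numeric(s[2]), as.numeric(s[3])))
}

#' Synthesize a concatenated reference spectrum from a fluorophore model
#'
#' For each excitation block of the layout, the emission channel values are
#' the Gaussian emission curve sampled at the channel centers, scaled by the
#' Gaussian excitation curve evaluated at that block's laser wavelength and
#' by the model brightness. The emission shape is thus identical across
#' blocks while the block amplitudes encode the excitation spectrum.
#' Channels whose center lies at or below the exciting wavelength are zeroed
#' (no anti-Stokes emission). The concatenated vector is peak-normalized.
#'
#' @param model a [fluorophore_model()].
#' @param layout an [acquisition_layout()].
#' @return A peak-normalized [fluorophore_spectrum()].
#' @export
synth_fluorophore_spectrum <- function(model, layout) {
  stopifnot(inherits(model, "fluorophore_model"),
            inherits(layout, "acquisition_layout"))
  centers <- channel_centers(layout)
  vals <- numeric(layout$m)
  for (i in seq_along(layout$excitations)) {
    ex <- layout$excitations[i]
    amp <- model$brightness *
      exp(-((ex - model$ex_peak)^2) / (2 * model$ex_width^2))
    em <- exp(-((centers[[i]] - model$em_peak)^2) / (2 * model$em_width^2))
    em[centers[[i]] <= ex] <- 0
    vals[block_indices(layout, i)] <- amp * em
  }
  if (max(vals) <= 0)
    stop(sprintf("fluorophore '%s' has no signal in any layout channel",
                 model$name))
  normalize_reference(fluorophore_spectrum(model$name, vals))
}

#' Build a reference matrix from fluorophore models
#'
#' @param models list of [fluorophore_model()] objects; default the 16-dye
#'   palette of [default_fluorophores()].
#' @param layout an [acquisition_layout()]; default [default_layout()].
#' @return A [build_reference_matrix()] result.
#' @export
synth_reference_matrix <- function(models = default_fluorophores(),
                                   layout = default_layout()) {
  build_reference_matrix(lapply(models, synth_fluorophore_spectrum,
                                layout = layout), layout)
}

#' Simulate one noisy binary-labeled particle spectrum
#'
#' The expected spectrum is `mu = x_i f_i + x_j f_j + background_level`,
#' rescaled so its peak channel expects `snr^2` photons; each channel is then
#' drawn independently from a Poisson law with that mean. Under Poisson shot
#' noise the peak-channel signal-to-noise ratio is `sqrt(snr^2) = snr`, the
#' standard shot-noise convention.
#'
#' @param F reference matrix (columns = peak-normalized spectra).
#' @param pair integer pair `c(i, j)` of true fluorophore indices.
#' @param abundances positive abundances `c(x_i, x_j)`.
#' @param snr target peak-channel signal-to-noise ratio (> 0); peak expected
#'   photon count is `snr^2`. A warning is raised below 1 expected photon.
#' @param background_level constant background, in the same (pre-scaling)
#'   units as the abundances; default 0.
#' @param noise if `FALSE`, return the expected spectrum exactly (the
#'   infinite-SNR limit).
#' @return List with `y` (the length-m spectrum), `mu` (its expectation),
#'   `background` (the scaled background vector to pass to the unmixers),
#'   `scale`, and `truth` (`pair`, `abundances` on the photon scale).
#' @export
simulate_particle_spectrum <- function(F, pair, abundances, snr,
                                       background_level = 0, noise = TRUE) {
  Fm <- ref_mat(F)
  if (any(abundances <= 0)) stop("true abundances must be positive")
  if (snr <= 0) stop("snr must be positive")
  if (snr^2 < 1) warning("snr^2 < 1: sub-photon peak signal")
  i <- pair[1]; j <- pair[2]
  if (i == j) stop("pair must contain two distinct fluorophores")
  mu0 <- Fm[, i] * abundances[1] + Fm[, j] * abundances[2] + background_level
  scale <- snr^2 / max(mu0)
  mu <- mu0 * scale
  y <- if (noise) stats::rpois(length(mu), mu) else mu
  list(y = as.numeric(y), mu = mu,
       background = rep(background_level * scale, nrow(Fm)),
       scale = scale,
       truth = list(pair = c(i = min(i, j), j = max(i, j)),
                    abundances = abundances * scale))
}

#' Generate a synthetic spectral image of binary-labeled cells
#'
#' Places non-overlapping, randomly oriented elliptical (rod-like) cells in a
#' field, each carrying one of the requested binary label types with
#' per-fluorophore abundances jittered uniformly on `(0.7, 1.3)` around the
#' nominal 1:1 labeling. Pixel values are independent Poisson draws around
#' the expected spectrum (cell signal plus a constant stray-light
#' background); the brightest cell's peak channel expects `snr^2` photons.
#' Stacks are returned in acquisition order (descending excitation
#' wavelength), as they would come off the microscope.
#'
#' @param F reference matrix with its layout (a [build_reference_matrix()] /
#'   [synth_reference_matrix()] result).
#' @param label_types integer matrix of pairs (rows `c(i, j)`), e.g. from
#'   [enumerate_pairs()]; the label types present in the mixture.
#' @param n_cells total number of cells to place.
#' @param proportions mixing proportions over `label_types` rows, summing
#'   to 1; default equal. Cell counts are multinomial.
#' @param dim image size `c(rows, cols)`.
#' @param snr peak-channel signal-to-noise ratio of the brightest cell.
#' @param background_level constant background, expected photons per channel.
#' @param cell_axes ellipse semi-axes in pixels `c(major, minor)`.
#' @param noise if `FALSE`, the expected image is returned (no Poisson draw).
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param max_tries placement attempts per cell before giving up.
#' @param clear_roi `c(row, col, height, width)` rectangle kept free of
#'   cells, for background estimation with [estimate_background()]; default
#'   the top-left 16 x 16 corner. `NULL` to disable.
#' @return List with `stacks` (named per-excitation (channel, row, col)
#'   arrays in acquisition order), `truth` (data frame: `particle_id`, `i`,
#'   `j`, `label_type`, `x_i`, `x_j`, `row`, `col`, `pixel_count`),
#'   `layout`, `background` (length-m vector of expected background photons),
#'   `clear_roi` and `scale`.
#' @export
generate_synthetic_image <- function(F, label_types, n_cells,
                                     proportions = NULL, dim = c(256, 256),
                                     snr = 30, background_level = 1,
                                     cell_axes = c(5, 2.5), noise = TRUE,
                                     seed = NULL, max_tries = 200,
                                     clear_roi = c(1, 1, 16, 16)) {
  stopifnot(inherits(F, "reference_matrix"))
  layout <- F$layout
  Fm <- F$matrix
  if (!is.null(seed)) set.seed(seed)
  label_types <- rbind(label_types)
  nt <- nrow(label_types)
  if (is.null(proportions)) proportions <- rep(1 / nt, nt)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  counts <- as.vector(stats::rmultinom(1, n_cells, proportions))
  type_of_cell <- sample(rep.int(seq_len(nt), counts))

  H <- dim[1]; W <- dim[2]
  occupied <- matrix(FALSE, H, W)
  if (!is.null(clear_roi)) {
    cr0 <- clear_roi
    occupied[cr0[1]:(cr0[1] + cr0[3] - 1L),
             cr0[2]:(cr0[2] + cr0[4] - 1L)] <- TRUE
  }
  a <- cell_axes[1]; b <- cell_axes[2]
  margin <- 2   # >= 1 background pixel between cells keeps 8-connectivity apart
  cells <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cr <- stats::runif(1, a + margin + 1, H - a - margin)
      cc <- stats::runif(1, a + margin + 1, W - a - margin)
      th <- stats::runif(1, 0, pi)
      px <- ellipse_pixels(cr, cc, a, b, th, H, W)
      guard <- ellipse_pixels(cr, cc, a + margin, b + margin, th, H, W)
      if (length(px) >= 4L && !any(occupied[guard])) {
        occupied[guard] <- TRUE
        cells[[k]] <- list(pixels = px, row = cr, col = cc)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could only place %d of %d cells without overlap in a %dx%d field",
                   k - 1L, n_cells, H, W))
  }

  # expected spectra per cell; global photon scale set by the brightest cell
  xs <- matrix(stats::runif(2 * n_cells, 0.7, 1.3), ncol = 2)
  mu_cell <- vapply(seq_len(n_cells), function(k) {
    p <- label_types[type_of_cell[k], ]
    Fm[, p[1]] * xs[k, 1] + Fm[, p[2]] * xs[k, 2]
  }, numeric(nrow(Fm)))
  scale <- snr^2 / max(mu_cell)
  mu_cell <- mu_cell * scale

  m <- nrow(Fm)
  expected <- array(background_level, c(m, H, W))
  for (k in seq_len(n_cells)) {
    for (pxl in cells[[k]]$pixels) {
      r <- ((pxl - 1L) %% H) + 1L
      cl <- ((pxl - 1L) %/% H) + 1L
      expected[, r, cl] <- expected[, r, cl] + mu_cell[, k]
    }
  }
  img <- if (noise)
    array(stats::rpois(length(expected), expected), base::dim(expected))
  else expected

  truth <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
    p <- label_types[type_of_cell[k], ]
    data.frame(particle_id = k, i = min(p), j = max(p),
               label_type = paste(colnames(Fm)[sort(p)], collapse = "+"),
               x_i = xs[k, which.min(p)] * scale,
               x_j = xs[k, which.max(p)] * scale,
               row = cells[[k]]$row, col = cells[[k]]$col,
               pixel_count = length(cells[[k]]$pixels))
  }))

  stacks <- lapply(layout$acquisition_order, function(i)
    img[block_indices(layout, i), , , drop = FALSE])
  names(stacks) <- as.character(layout$excitations[layout$acquisition_order])
  list(stacks = stacks, truth = truth, layout = layout,
       background = rep(background_level, m), clear_roi = clear_roi,
       scale = scale)
}

# linear indices (column-major) of pixels inside a rotated ellipse
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  rr <- max(1L, floor(cr - a)):min(H, ceiling(cr + a))
  cols <- max(1L, floor(cc - a)):min(W, ceiling(cc + a))
  dr <- rep(rr - cr, times = length(cols))
  dc <- rep(cols - cc, each = length(rr))
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- u * u + v * v <= 1
  ridx <- rep(rr, times = length(cols))[inside]
  cidx <- rep(cols, each = length(rr))[inside]
  (cidx - 1L) * H + ridx
}
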