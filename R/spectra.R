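#' Fluorophore reference spectrum on the concatenated channel axis
#'
#' @param name fluorophore label.
#' @param values numeric vector of non-negative intensities, one per
#'   concatenated channel.
#' @param normalized logical; `TRUE` if the peak value is exactly 1.
#' @return An object of class `fluorophore_spectrum`.
#' @export
fluorophore_spectrum <- function(name, values, normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  if (any(values < 0)) stop("spectrum values must be non-negative")
  if (normalized && max(values) != 1)
    stop("a normalized spectrum must have peak value exactly 1")
  structure(list(name = as.character(name), values = values,
                 normalized = isTRUE(normalized)),
            class = "fluorophore_spectrum")
}

#' @export
print.fluorophore_spectrum <- function(x, ...) {
  cat(sprintf("Fluorophore spectrum '%s': %d channels, peak %.4g%s\n",
              x$name, length(x$values), max(x$values),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Peak-normalize a reference spectrum
#'
#' Divides a spectrum by its maximum so the brightest concatenated
#' excitation/emission channel has unit intensity. Normalization is global
#' over the whole concatenated axis, not per excitation block: the overall
#' brightest channel defines the unit.
#'
#' @param spectrum a [fluorophore_spectrum()] or bare numeric vector.
#' @return The peak-normalized spectrum, same type as the input
#'   (`fluorophore_spectrum` in, `fluorophore_spectrum` out).
#' @examples
#' normalize_reference(c(2, 4, 8))
#' @export
normalize_reference <- function(spectrum) {
  if (inherits(spectrum, "fluorophore_spectrum")) {
    v <- spectrum$values
    if (max(v) <= 0) stop("cannot normalize an all-zero spectrum")
    fluorophore_spectrum(spectrum$name, v / max(v), normalized = TRUE)
  } else {
    v <- as.numeric(spectrum)
    if (any(v < 0)) stop("spectrum values must be non-negative")
    if (max(v) <= 0) stop("cannot normalize an all-zero spectrum")
    v / max(v)
  }
}

#' Concatenate per-excitation image stacks into one spectral image
#'
#' Joins the emission stacks recorded at each excitation wavelength end to end
#' along the channel axis, producing a single image whose per-pixel spectrum
#' has `layout$m` points. The output channel axis orders excitations
#' ascending by wavelength (each block's emission channels already ascend in
#' emission wavelength); pixel values are unchanged, only reindexed. Stacks
#' may be supplied in any order when the list is named by excitation
#' wavelength, or unnamed in the layout's acquisition order.
#'
#' @param stacks list of 3-d arrays with dimensions (channel, row, col), one
#'   per excitation. Names, if present, are excitation wavelengths.
#' @param layout an [acquisition_layout()].
#' @return 3-d array of dimension `(layout$m, rows, cols)` of class
#'   `spectral_image`, with the layout attached as attribute `layout`.
#' @export
concatenate_stacks <- function(stacks, layout) {
  stopifnot(inherits(layout, "acquisition_layout"))
  p <- length(layout$excitations)
  if (length(stacks) != p)
    stop(sprintf("expected %d stacks (one per excitation), got %d",
                 p, length(stacks)))
  if (!is.null(names(stacks)) && !all(names(stacks) == "")) {
    key <- match(as.character(layout$excitations), names(stacks))
    if (anyNA(key)) {
      miss <- layout$excitations[is.na(key)]
      stop(sprintf("missing stack for excitation %s nm",
                   paste(miss, collapse = ", ")))
    }
    stacks <- stacks[key]
  } else {
    # unnamed: interpret in acquisition order, reorder to ascending excitation
    stacks <- stacks[order(layout$acquisition_order)]
  }
  dims <- lapply(stacks, dim)
  for (i in seq_len(p)) {
    d <- dims[[i]]
    if (is.null(d) || length(d) != 3L)
      stop(sprintf("excitation %g nm: stack must be a (channel, row, col) array",
                   layout$excitations[i]))
    if (d[1] != layout$channels_per_excitation[i])
      stop(sprintf("excitation %g nm: expected %d channels, got %d",
                   layout$excitations[i], layout$channels_per_excitation[i],
                   d[1]))
    if (any(d[2:3] != dims[[1]][2:3]))
      stop(sprintf("excitation %g nm: image dimensions %dx%d differ from %dx%d",
                   layout$excitations[i], d[2], d[3],
                   dims[[1]][2], dims[[1]][3]))
  }
  out <- array(0, dim = c(layout$m, dims[[1]][2], dims[[1]][3]))
  for (i in seq_len(p)) out[block_indices(layout, i), , ] <- stacks[[i]]
  structure(out, layout = layout, class = "spectral_image")
}

#' Derive a reference spectrum from a pure singly-labeled population image
#'
#' Segments a concatenated spectral image of a pure population, averages the
#' raw pixel spectra over all in-particle pixels, subtracts the background
#' spectrum, clips negative values to zero (spectra are physically
#' non-negative), and peak-normalizes the result.
#'
#' @param pure_image concatenated spectral image (channel, row, col array).
#' @param background length-m background vector, or a scalar, subtracted from
#'   the mean in-particle spectrum; default 0.
#' @param name fluorophore label for the returned spectrum.
#' @param channels channel indices used for threshold/segmentation; default
#'   all channels.
#' @param min_size minimum particle size in pixels.
#' @return A peak-normalized [fluorophore_spectrum()].
#' @export
derive_reference_spectrum <- function(pure_image, background = 0,
                                      name = "reference", channels = NULL,
                                      min_size = 4) {
  thr <- compute_threshold(pure_image, channels = channels)
  mask <- segment_particles(pure_image, thr, min_size = min_size,
                            channels = channels)
  if (max(mask$labels) == 0L)
    stop("no particles found in the pure-population image")
  inpart <- mask$labels > 0L
  m <- dim(pure_image)[1]
  flat <- matrix(pure_image, nrow = m)   # channels x pixels, column-major
  mean_spec <- rowMeans(flat[, as.vector(inpart), drop = FALSE])
  spec <- pmax(mean_spec - rep_len(as.numeric(background), m), 0)
  if (max(spec) <= 0)
    stop("background-subtracted mean spectrum is all zero")
  normalize_reference(fluorophore_spectrum(name, spec))
}

#' Build the m x n reference matrix F
#'
#' Assembles the peak-normalized concatenated reference spectra into the
#' matrix handed to the unmixing solvers: one column per fluorophore, one row
#' per concatenated excitation/emission channel, columns in the given
#' fluorophore order.
#'
#' @param spectra list of [fluorophore_spectrum()] objects with unique names,
#'   all of length `layout$m`.
#' @param layout an [acquisition_layout()].
#' @return An object of class `reference_matrix` with fields `layout`,
#'   `fluorophores` (the normalized input spectra) and `matrix` (m x n, column
#'   names = fluorophore names).
#' @export
build_reference_matrix <- function(spectra, layout) {
  stopifnot(inherits(layout, "acquisition_layout"))
  if (length(spectra) < 2L)
    stop("binary unmixing needs at least 2 reference spectra")
  spectra <- lapply(spectra, function(s) {
    if (!inherits(s, "fluorophore_spectrum"))
      stop("spectra must be fluorophore_spectrum objects")
    if (length(s$values) != layout$m)
      stop(sprintf("spectrum '%s' has %d channels, layout expects %d",
                   s$name, length(s$values), layout$m))
    if (s$normalized) s else normalize_reference(s)
  })
  nm <- vapply(spectra, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop(sprintf("duplicate fluorophore names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  F <- vapply(spectra, function(s) s$values, numeric(layout$m))
  colnames(F) <- nm
  structure(list(layout = layout, fluorophores = spectra, matrix = F),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("Reference matrix: %d channels x %d fluorophores\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  fluorophores:", paste(colnames(x$matrix), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.reference_matrix <- function(x, ...) x$matrix

# accept either a reference_matrix or a plain numeric matrix
ref_mat <- function(F) {
  if (inherits(F, "reference_matrix")) F$matrix
  else if (is.matrix(F)) F
  else stop("F must be a reference_matrix or a numeric matrix")
}

#' Write / read reference spectra as a tab-separated table
#'
#' Plain-text interchange format for reference matrices: one column per
#' fluorophore, one row per concatenated channel, with a header row of
#' fluorophore names.
#'
#' @param ref a [build_reference_matrix()] result (or plain matrix with
#'   column names).
#' @param path file path.
#' @return `write_reference_spectra` returns `path` invisibly;
#'   `read_reference_spectra` returns the m x n numeric matrix (attach a
#'   layout with [build_reference_matrix()] if needed downstream).
#' @export
write_reference_spectra <- function(ref, path) {
  F <- ref_mat(ref)
  utils::write.table(F, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_spectra
#' @export
read_reference_spectra <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  as.matrix(tab)
}
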