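#' Read per-excitation spectral stacks from multipage TIFF files
#'
#' Each excitation's stack is one multipage TIFF whose page count must equal
#' that excitation's channel count in the layout. Integer pages are read
#' bit-exactly. All stacks must share the same image dimensions.
#'
#' @param paths character vector of TIFF paths, named by excitation
#'   wavelength (e.g. `c("633" = "ex633.tif", ...)`); unnamed vectors are
#'   taken in the layout's acquisition order.
#' @param layout an [acquisition_layout()].
#' @return Named list of (channel, row, col) arrays keyed by excitation
#'   wavelength, suitable for [concatenate_stacks()].
#' @export
read_spectral_stacks <- function(paths, layout) {
  stopifnot(inherits(layout, "acquisition_layout"))
  p <- length(layout$excitations)
  if (length(paths) != p)
    stop(sprintf("expected %d stack files, got %d", p, length(paths)))
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- as.character(
      layout$excitations[layout$acquisition_order])
  key <- match(as.character(layout$excitations), names(paths))
  if (anyNA(key))
    stop(sprintf("missing stack file for excitation %s nm",
                 paste(layout$excitations[is.na(key)], collapse = ", ")))
  stacks <- vector("list", p)
  for (i in seq_len(p)) {
    pages <- tiff::readTIFF(paths[[key[i]]], all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != layout$channels_per_excitation[i])
      stop(sprintf("%s: %d pages but layout expects %d channels for %g nm",
                   paths[[key[i]]], length(pages),
                   layout$channels_per_excitation[i], layout$excitations[i]))
    d <- dim(pages[[1]])
    if (length(d) != 2L)
      stop(sprintf("%s: pages must be single-channel (grayscale)",
                   paths[[key[i]]]))
    if (any(!vapply(pages, function(pg) identical(dim(pg), d), logical(1))))
      stop(sprintf("%s: pages have inconsistent dimensions", paths[[key[i]]]))
    arr <- array(0, c(length(pages), d[1], d[2]))
    for (ch in seq_along(pages)) arr[ch, , ] <- pages[[ch]]
    stacks[[i]] <- arr
  }
  names(stacks) <- as.character(layout$excitations)
  stacks
}

#' Write per-excitation stacks as 16-bit multipage TIFF files
#'
#' Inverse of [read_spectral_stacks()]: one file per excitation, one page
#' per channel, written in the layout's acquisition order. Values must be
#' non-negative integers representable in 16 bits; the round trip is
#' bit-exact.
#'
#' @param stacks named list of (channel, row, col) arrays keyed by
#'   excitation (as produced by [generate_synthetic_image()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix><excitation>.tif`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_spectral_stacks <- function(stacks, dir, prefix = "ex") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(stacks)))
    stop("stacks must be named by excitation wavelength")
  paths <- character(0)
  for (ex in names(stacks)) {
    arr <- stacks[[ex]]
    if (any(arr < 0) || any(arr > 65535) || any(arr != round(arr)))
      stop("stack values must be integers in [0, 65535] for 16-bit TIFF")
    pages <- lapply(seq_len(dim(arr)[1]), function(ch) arr[ch, , ] / 65535)
    path <- file.path(dir, paste0(prefix, ex, ".tif"))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    paths[ex] <- path
  }
  invisible(paths)
}

#' Write / read an acquisition layout as YAML
#'
#' @param layout an [acquisition_layout()].
#' @param path file path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns
#'   the reconstructed [acquisition_layout()].
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "acquisition_layout"))
  yaml::write_yaml(list(
    excitations = layout$excitations,
    channels_per_excitation = layout$channels_per_excitation,
    channel_edges = lapply(layout$channel_edges, as.numeric),
    acquisition_order = layout$acquisition_order), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  x <- yaml::read_yaml(path)
  acquisition_layout(x$excitations, x$channels_per_excitation,
                     x$channel_edges, x$acquisition_order)
}

#' Deterministic color palette for binary label types
#'
#' Distinct colors for up to several hundred label types, generated from the
#' label-type index (golden-angle hue steps over three
#' saturation/value rings) so the same type always maps to the same color.
#'
#' @param n number of label types.
#' @return Character vector of `n` distinct hex colors.
#' @export
label_type_palette <- function(n) {
  idx <- seq_len(n) - 1L
  h <- (idx * 0.61803398875) %% 1
  ring <- idx %% 3L
  s <- c(1, 0.55, 0.85)[ring + 1L]
  v <- c(1, 1, 0.6)[ring + 1L]
  cols <- grDevices::hsv(h, s, v)
  if (anyDuplicated(cols))
    stop("palette exhausted: could not generate distinct colors")
  cols
}

#' Render a pseudo-colored label-type map
#'
#' Paints every particle's pixels with the color of its assigned label type
#' on a black background, the standard visualization of a binary-unmixed
#' image. In restricted-mixture mode, assignments outside `allowed_types`
#' (impossible label types) are rendered gray.
#'
#' @param assignments a [classify_image()] result.
#' @param mask the `segmentation_mask` the assignments came from.
#' @param path output PNG path, or `NULL` to return the array only.
#' @param F reference matrix (used to enumerate all label types so colors
#'   are deterministic per type); when `NULL`, the types present are used.
#' @param allowed_types optional integer matrix of pairs known to be
#'   present; others are drawn gray.
#' @return (rows, cols, 3) RGB array in `[0, 1]`, invisibly.
#' @export
write_label_type_map <- function(assignments, mask, path = NULL, F = NULL,
                                 allowed_types = NULL) {
  lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  if (!is.null(F)) {
    pairs <- enumerate_pairs(ncol(ref_mat(F)))
  } else {
    pairs <- unique(cbind(assignments$i, assignments$j))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  pal <- label_type_palette(nrow(pairs))
  type_key <- paste(pairs[, 1], pairs[, 2], sep = "+")
  rgbm <- grDevices::col2rgb(pal) / 255
  gray <- c(0.5, 0.5, 0.5)
  img <- array(0, c(nrow(lab), ncol(lab), 3))
  if (nrow(assignments)) {
    allowed_key <- if (!is.null(allowed_types)) {
      at <- rbind(allowed_types)
      paste(pmin(at[, 1], at[, 2]), pmax(at[, 1], at[, 2]), sep = "+")
    } else NULL
    for (q in seq_len(nrow(assignments))) {
      k <- paste(assignments$i[q], assignments$j[q], sep = "+")
      col <- if (!is.null(allowed_key) && !(k %in% allowed_key)) gray
             else rgbm[, match(k, type_key)]
      if (anyNA(col)) stop(sprintf("no palette color for label type %s", k))
      pix <- which(lab == assignments$particle_id[q])
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pix] <- col[ch]
        img[, , ch] <- plane
      }
    }
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Write the per-label-type quantification report
#'
#' Counts and percentages of each detected label type, the tabular companion
#' of the label-type map. When ground truth is supplied, accuracy and the
#' possible/impossible split of a restricted control mixture are appended as
#' a summary block.
#'
#' @param assignments a [classify_image()] / [classify_particles()] result.
#' @param path output CSV path, or `NULL` to return the table only.
#' @param truth optional ground-truth data frame (see [score_assignments()]).
#' @param allowed_types optional matrix of pairs known to be present.
#' @return Data frame with columns `label_type`, `count`, `percent` (and,
#'   with ground truth, attribute `summary` holding total cells, percent
#'   correct, percent possible and percent impossible), invisibly written to
#'   `path` when given.
#' @export
write_quantification <- function(assignments, path = NULL, truth = NULL,
                                 allowed_types = NULL) {
  tab <- table(assignments$label_type)
  out <- data.frame(label_type = names(tab),
                    count = as.integer(tab),
                    percent = if (nrow(assignments))
                      100 * as.integer(tab) / nrow(assignments) else numeric(0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$label_type), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(truth)) {
    sc <- score_assignments(assignments, truth,
                            allowed_types = allowed_types)
    attr(out, "summary") <- data.frame(
      total_cells = sc$n_assigned,
      percent_correct = sc$percent_correct,
      percent_possible = if (!is.null(sc$percent_possible))
        sc$percent_possible else NA_real_,
      percent_impossible = if (!is.null(sc$percent_impossible))
        sc$percent_impossible else NA_real_)
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    if (!is.null(attr(out, "summary"))) {
      spath <- sub("\\.csv$", "_summary.csv", path)
      utils::write.csv(attr(out, "summary"), spath, row.names = FALSE)
    }
  }
  invisible(out)
}

#' Write the particle table
#'
#' @param particles a `particle_set` from [average_object_spectra()].
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  df <- as.data.frame(particles)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a segmentation mask as 16-bit TIFF
#'
#' @param mask a `segmentation_mask` (or integer label matrix).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  if (max(lab) > 65535) stop("more than 65535 particles; cannot write 16-bit mask")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Run the full classification pipeline from a configuration
#'
#' End-to-end driver: read the layout and reference spectra, read and
#' concatenate the per-excitation stacks, estimate background from the
#' cell-free ROI, threshold and segment, average object spectra, run the
#' binary-constrained unmixing, and write the assignment table, particle
#' table, label-type map, mask and quantification report to the output
#' directory. Given the same configuration and seed-free inputs the written
#' CSVs are byte-identical across runs.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `layout` (path), `reference_spectra` (path to a
#'   [write_reference_spectra()] table), `stacks` (named list or vector of
#'   TIFF paths keyed by excitation), `background_roi` (`c(row, col, height,
#'   width)`), `output_dir`, and optionally `threshold_channels`, `min_size`.
#' @return The `particle_classification` table, invisibly; side effect:
#'   files in `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("layout", "reference_spectra", "stacks", "background_roi",
              "output_dir"))
    if (is.null(config[[f]])) stop(sprintf("config entry '%s' is required", f))
  layout <- read_layout(config$layout)
  Fm <- read_reference_spectra(config$reference_spectra)
  if (nrow(Fm) != layout$m)
    stop("reference spectra and layout disagree on channel count")
  stacks <- read_spectral_stacks(unlist(config$stacks), layout)
  image <- concatenate_stacks(stacks, layout)
  channels <- config$threshold_channels
  min_size <- if (is.null(config$min_size)) 4 else config$min_size
  thr <- compute_threshold(image, channels = channels)
  mask <- segment_particles(image, thr, min_size = min_size,
                            channels = channels)
  message(sprintf("segmented %d particles (threshold %.4g)",
                  max(mask$labels), thr))
  b <- estimate_background(image, as.numeric(config$background_roi),
                           mask = mask)
  particles <- average_object_spectra(image, mask)
  assignments <- classify_particles(particles, Fm, b = b)
  nf <- length(attr(assignments, "failures"))
  if (nf) message(sprintf("%d particle(s) failed to unmix", nf))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$output_dir
  utils::write.csv(as.data.frame(unclass(assignments)),
                   file.path(od, "assignments.csv"), row.names = FALSE)
  write_particle_table(particles, file.path(od, "particles.csv"))
  write_quantification(assignments, file.path(od, "quantification.csv"))
  write_mask(mask, file.path(od, "mask.tif"))
  write_label_type_map(assignments, mask, file.path(od, "label_map.png"),
                       F = Fm)
  invisible(assignments)
}
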