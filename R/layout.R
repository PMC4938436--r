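#' Define a multi-excitation spectral acquisition layout
#'
#' An acquisition layout describes the concatenated channel axis of a
#' multi-excitation spectral data set: which excitation laser lines were used,
#' how many emission channels were recorded for each, and the emission band
#' edges of every channel. The concatenated axis always orders excitations by
#' ascending wavelength, with each excitation's emission channels in ascending
#' emission wavelength; `acquisition_order` records the order in which the
#' stacks were physically acquired (by default descending excitation
#' wavelength, the bleaching-minimizing protocol).
#'
#' All pixel coordinates in this package are 1-based `(row, col)` pairs and
#' bounding boxes are inclusive at both ends.
#'
#' @param excitations numeric vector of excitation wavelengths in nm.
#' @param channels_per_excitation integer vector, one emission channel count
#'   per excitation.
#' @param channel_edges list of numeric vectors, one per excitation; each of
#'   length `channels_per_excitation[i] + 1`, strictly increasing emission band
#'   edges in nm.
#' @param acquisition_order integer permutation of `seq_along(excitations)`
#'   giving the order stacks were acquired in; defaults to descending
#'   excitation wavelength.
#' @return An object of class `acquisition_layout` with fields `excitations`,
#'   `channels_per_excitation`, `channel_edges`, `acquisition_order`, and the
#'   derived total channel count `m`. Excitations are stored in ascending
#'   wavelength order regardless of input order.
#' @examples
#' lay <- acquisition_layout(
#'   excitations = c(488, 405),
#'   channels_per_excitation = c(4, 4),
#'   channel_edges = list(seq(500, 540, 10), seq(420, 460, 10))
#' )
#' lay$m
#' @export
acquisition_layout <- function(excitations, channels_per_excitation,
                               channel_edges,
                               acquisition_order = order(excitations,
                                                         decreasing = TRUE)) {
  excitations <- as.numeric(excitations)
  channels_per_excitation <- as.integer(channels_per_excitation)
  p <- length(excitations)
  if (p < 1L) stop("at least one excitation is required")
  if (length(channels_per_excitation) != p)
    stop("channels_per_excitation must have one entry per excitation")
  if (any(channels_per_excitation < 1L))
    stop("each excitation needs at least one emission channel")
  if (anyDuplicated(excitations))
    stop("excitation wavelengths must be distinct")
  if (!is.list(channel_edges) || length(channel_edges) != p)
    stop("channel_edges must be a list with one numeric vector per excitation")
  if (length(acquisition_order) != p ||
      !setequal(acquisition_order, seq_len(p)))
    stop("acquisition_order must be a permutation of the excitation indices")

  # store in ascending-excitation (concatenated-axis) order
  ord <- order(excitations)
  excitations <- excitations[ord]
  channels_per_excitation <- channels_per_excitation[ord]
  channel_edges <- channel_edges[ord]
  acquisition_order <- match(acquisition_order, ord)

  for (i in seq_len(p)) {
    e <- as.numeric(channel_edges[[i]])
    if (length(e) != channels_per_excitation[i] + 1L)
      stop(sprintf("excitation %g nm: expected %d channel edges, got %d",
                   excitations[i], channels_per_excitation[i] + 1L, length(e)))
    if (any(diff(e) <= 0))
      stop(sprintf("excitation %g nm: channel edges must be strictly increasing",
                   excitations[i]))
    channel_edges[[i]] <- e
  }

  structure(list(
    excitations = excitations,
    channels_per_excitation = channels_per_excitation,
    channel_edges = channel_edges,
    acquisition_order = as.integer(acquisition_order),
    m = sum(channels_per_excitation)
  ), class = "acquisition_layout")
}

#' @export
print.acquisition_layout <- function(x, ...) {
  cat(sprintf("Acquisition layout: %d excitation(s), %d concatenated channels\n",
              length(x$excitations), x$m))
  for (i in seq_along(x$excitations)) {
    e <- x$channel_edges[[i]]
    cat(sprintf("  %g nm: %d channels, %g-%g nm\n", x$excitations[i],
                x$channels_per_excitation[i], min(e), max(e)))
  }
  cat("  acquired in order:",
      paste(x$excitations[x$acquisition_order], collapse = ", "), "nm\n")
  invisible(x)
}

#' Emission channel centers of a layout
#'
#' @param layout an [acquisition_layout()].
#' @return list of numeric vectors of channel center wavelengths (nm), one per
#'   excitation, in concatenated-axis order.
#' @export
channel_centers <- function(layout) {
  stopifnot(inherits(layout, "acquisition_layout"))
  lapply(layout$channel_edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

# index range of excitation block i on the concatenated axis
block_indices <- function(layout, i) {
  ends <- cumsum(layout$channels_per_excitation)
  starts <- c(1L, head(ends, -1L) + 1L)
  seq.int(starts[i], ends[i])
}

#' Default six-excitation synthetic layout (115 channels)
#'
#' A ready-made layout mimicking a six-laser confocal spectral acquisition:
#' excitations at 405, 488, 514, 561, 594 and 633 nm with 30, 24, 21, 16, 13
#' and 11 emission channels of 10 nm starting 10 nm above each laser line,
#' 115 concatenated channels in total. The per-excitation split is a package
#' choice; instruments vary and real layouts should be supplied explicitly.
#'
#' @return An [acquisition_layout()].
#' @export
default_layout <- function() {
  ex <- c(405, 488, 514, 561, 594, 633)
  nch <- c(30L, 24L, 21L, 16L, 13L, 11L)
  edges <- Map(function(e, n) seq(e + 10, by = 10, length.out = n + 1), ex, nch)
  acquisition_layout(ex, nch, edges)
}

#' Single-excitation layout
#'
#' Convenience constructor for a single-laser spectral acquisition, e.g. the
#' 488 nm / 16 x 10 nm configuration used in the bundled signal-to-noise
#' experiments.
#'
#' @param excitation excitation wavelength (nm).
#' @param n_channels number of emission channels.
#' @param bandwidth emission channel width (nm).
#' @param start first band edge (nm); defaults to 10 nm above the laser line.
#' @return An [acquisition_layout()].
#' @export
single_excitation_layout <- function(excitation = 488, n_channels = 16,
                                     bandwidth = 10,
                                     start = excitation + 10) {
  acquisition_layout(excitation, n_channels,
                     list(seq(start, by = bandwidth,
                              length.out = n_channels + 1)))
}
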