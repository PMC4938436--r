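# Per-pixel sum over a channel subset; the grayscale image that is thresholded.
channel_sum <- function(image, channels = NULL) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L)
    stop("image must be a (channel, row, col) array")
  if (is.null(channels)) channels <- seq_len(d[1])
  channels <- as.integer(channels)
  if (length(channels) == 0L || any(channels < 1L) || any(channels > d[1]))
    stop("invalid channel subset for thresholding")
  colSums(image[channels, , , drop = FALSE])
}

#' Histogram-based segmentation threshold
#'
#' Computes a global intensity threshold on the per-pixel sum over a subset of
#' spectral channels, by Otsu's between-class variance maximization on a
#' 256-bin histogram. Segmenting on a sum over many high signal-to-noise
#' channels, rather than a single channel, makes the foreground/background
#' split robust to any one fluorophore being dim.
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param channels channel indices summed before thresholding; default all.
#' @param levels number of histogram bins (default 256).
#' @return Scalar threshold on the channel-sum scale: pixels whose channel sum
#'   exceeds it are foreground. The value returned is the upper edge of the
#'   last background bin of the maximizing split.
#' @export
compute_threshold <- function(image, channels = NULL, levels = 256) {
  s <- channel_sum(image, channels)
  rng <- range(s)
  if (diff(rng) <= 0)
    stop("image is constant over the selected channels; no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- graphics::hist(s, breaks = edges, plot = FALSE)
  cnt <- as.double(h$counts)
  mids <- h$mids
  tot <- sum(cnt)
  w0 <- cumsum(cnt)[-levels]               # background class: bins 1..k
  m0 <- cumsum(cnt * mids)[-levels]
  w1 <- tot - w0
  m1 <- sum(cnt * mids) - m0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, levels - 1L)
  bc[valid] <- w0[valid] * w1[valid] *
    (m0[valid] / w0[valid] - m1[valid] / w1[valid])^2
  edges[which.max(bc) + 1L]
}

#' Segment a spectral image into particles
#'
#' Thresholds the channel-sum image and extracts 8-connected components of
#' the above-threshold pixel set. Components smaller than `min_size` pixels
#' are discarded and the survivors relabeled consecutively (1, 2, ...) in
#' raster order of their first pixel. An empty mask is a valid result.
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param threshold scalar threshold on the channel-sum scale, e.g. from
#'   [compute_threshold()].
#' @param min_size minimum particle size in pixels (default 4).
#' @param channels channel indices summed before thresholding; must match the
#'   set used to compute `threshold`.
#' @return An object of class `segmentation_mask`: `labels` (integer matrix,
#'   0 = background), `threshold_value`, `channels_used`, `min_size`.
#' @export
segment_particles <- function(image, threshold, min_size = 4,
                              channels = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  s <- channel_sum(image, channels)
  fg <- s > threshold
  lab <- label_components8(fg)
  if (max(lab) > 0L && min_size > 1) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    lab <- relabel_raster_order(lab)
  }
  structure(list(labels = lab,
                 threshold_value = threshold,
                 channels_used = if (is.null(channels))
                   seq_len(dim(image)[1]) else as.integer(channels),
                 min_size = min_size),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("Segmentation mask %dx%d: %d particle(s), threshold %.4g, min size %d px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$threshold_value, x$min_size))
  invisible(x)
}

# 8-connected component labeling of a logical matrix via the pixel adjacency
# graph (EBImage's labeling is 4-connected, which would split diagonal
# contacts). Components are numbered in raster (column-major) order of their
# first pixel.
label_components8 <- function(fg) {
  d <- dim(fg)
  lab <- matrix(0L, d[1], d[2])
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  rank <- integer(length(fg))
  rank[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% d[1]) + 1L
  cc <- ((idx - 1L) %/% d[1]) + 1L
  edges <- list()
  # four directed shifts cover all eight undirected neighbours
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    nr <- r + s[1]; ncl <- cc + s[2]
    ok <- nr >= 1L & nr <= d[1] & ncl >= 1L & ncl <= d[2]
    nidx <- (ncl[ok] - 1L) * d[1] + nr[ok]
    hit <- fg[nidx]
    edges[[length(edges) + 1L]] <-
      cbind(rank[idx[ok][hit]], rank[nidx[hit]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  relabel_raster_order(lab)
}

# renumber positive labels by raster order of each component's first pixel
relabel_raster_order <- function(lab) {
  pos <- which(lab > 0L)
  if (length(pos) == 0L) return(lab)
  lab[pos] <- match(lab[pos], unique(lab[pos]))
  lab
}

#' Threshold and segment in one call
#'
#' @inheritParams segment_particles
#' @inheritParams compute_threshold
#' @return A `segmentation_mask`, as [segment_particles()].
#' @export
segment_image <- function(image, channels = NULL, min_size = 4) {
  segment_particles(image, compute_threshold(image, channels),
                    min_size = min_size, channels = channels)
}

#' Average raw pixel spectra over each segmented particle
#'
#' Reduces every particle to a single spectrum: the arithmetic per-channel
#' mean over all of its member pixels in the raw (un-unmixed) spectral image.
#' No pixels are excluded. Averaging before unmixing both shrinks the number
#' of least-squares problems from one per pixel to one per object and reduces
#' spectral noise roughly as 1/sqrt(pixel count).
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param mask a [segment_particles()] result (or bare integer label matrix).
#' @return An object of class `particle_set`: a list of `particle_spectrum`
#'   entries, each with `particle_id`, `spectrum` (length-m mean vector),
#'   `pixel_count`, `centroid` (row, col) and `bbox`
#'   (rmin, rmax, cmin, cmax, inclusive).
#' @export
average_object_spectra <- function(image, mask) {
  lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
  d <- dim(image)
  if (any(dim(lab) != d[2:3]))
    stop("mask shape does not match the image")
  k <- max(lab)
  out <- vector("list", k)
  if (k > 0L) {
    idx <- which(lab > 0L)
    grp <- lab[idx]
    flat <- matrix(image, nrow = d[1])
    sums <- rowsum(t(flat[, idx, drop = FALSE]), grp)   # k x m
    counts <- tabulate(grp, nbins = k)
    r <- ((idx - 1L) %% d[2]) + 1L
    cc <- ((idx - 1L) %/% d[2]) + 1L
    rsum <- rowsum(r, grp); csum <- rowsum(cc, grp)
    for (i in seq_len(k)) {
      ri <- r[grp == i]; ci <- cc[grp == i]
      out[[i]] <- structure(list(
        particle_id = i,
        spectrum = sums[i, ] / counts[i],
        pixel_count = counts[i],
        centroid = c(row = rsum[i] / counts[i], col = csum[i] / counts[i]),
        bbox = c(rmin = min(ri), rmax = max(ri),
                 cmin = min(ci), cmax = max(ci))
      ), class = "particle_spectrum")
    }
  }
  structure(out, class = c("particle_set", "list"))
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("Particle set: %d particle(s)\n", length(x)))
  if (length(x)) {
    px <- vapply(x, function(p) p$pixel_count, numeric(1))
    cat(sprintf("  pixel counts: median %g, range %g-%g\n",
                stats::median(px), min(px), max(px)))
  }
  invisible(x)
}

#' @export
as.data.frame.particle_set <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(particle_id = integer(), pixel_count = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      rmin = integer(), rmax = integer(),
                      cmin = integer(), cmax = integer()))
  do.call(rbind, lapply(x, function(p) data.frame(
    particle_id = p$particle_id, pixel_count = p$pixel_count,
    centroid_row = p$centroid[["row"]], centroid_col = p$centroid[["col"]],
    rmin = p$bbox[["rmin"]], rmax = p$bbox[["rmax"]],
    cmin = p$bbox[["cmin"]], cmax = p$bbox[["cmax"]])))
}

# m x k matrix of averaged particle spectra
particle_matrix <- function(particles) {
  vapply(particles, function(p) p$spectrum,
         numeric(length(particles[[1]]$spectrum)))
}

#' Estimate the background spectrum from a cell-free region
#'
#' Averages the measured spectrum over all pixels of a rectangular region of
#' interest containing no cells. The background is assumed to consist mostly
#' of stray light, constant across the field, and the same vector is
#' subtracted for every object in the image.
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param roi numeric `c(row, col, height, width)`: top-left corner (1-based)
#'   and extent of the rectangle.
#' @param mask optional `segmentation_mask`; if supplied, the ROI is checked
#'   to contain no particle pixels.
#' @return Length-m numeric vector: the per-channel mean over the ROI.
#' @export
estimate_background <- function(image, roi, mask = NULL) {
  d <- dim(image)
  roi <- as.integer(round(roi))
  if (length(roi) != 4L) stop("roi must be c(row, col, height, width)")
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (h < 1L || w < 1L || r0 < 1L || c0 < 1L ||
      r0 + h - 1L > d[2] || c0 + w - 1L > d[3])
    stop("roi out of image bounds")
  if (!is.null(mask)) {
    lab <- if (inherits(mask, "segmentation_mask")) mask$labels else mask
    n_overlap <- sum(lab[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] > 0L)
    if (n_overlap > 0L)
      stop(sprintf("roi overlaps particles in %d pixel(s)", n_overlap))
  }
  sub <- image[, r0:(r0 + h - 1L), c0:(c0 + w - 1L), drop = FALSE]
  rowMeans(matrix(sub, nrow = d[1]))
}
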