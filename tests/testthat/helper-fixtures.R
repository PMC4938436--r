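# Fixtures are built in code; no binary test data.

# two-excitation toy layout: 3 emission channels per excitation
toy_layout <- function(nch = c(3L, 3L)) {
  acquisition_layout(
    excitations = c(405, 488),
    channels_per_excitation = nch,
    channel_edges = list(seq(420, by = 20, length.out = nch[1] + 1),
                         seq(500, by = 20, length.out = nch[2] + 1)))
}

# small well-conditioned reference with hand-written columns
toy_reference <- function() {
  lay <- toy_layout()
  specs <- list(
    fluorophore_spectrum("A", c(1, 0.5, 0.1, 0.2, 0.1, 0)),
    fluorophore_spectrum("B", c(0.1, 1, 0.4, 0.1, 0.3, 0.1)),
    fluorophore_spectrum("C", c(0, 0.2, 1, 0.1, 0.6, 0.3)),
    fluorophore_spectrum("D", c(0.05, 0.1, 0.3, 1, 0.7, 0.2)))
  build_reference_matrix(specs, lay)
}

# noise-free spectral image: cells as rectangles with fixed spectra on a
# constant background; returns image plus the painted footprints
paint_image <- function(m, H, W, cells, background = 0) {
  img <- array(background, c(m, H, W))
  for (cl in cells) {
    for (r in cl$rows) for (cc in cl$cols)
      img[, r, cc] <- img[, r, cc] + cl$spectrum
  }
  structure(img, class = "spectral_image")
}

# independent Otsu oracle: plain double loop over every histogram cut point,
# recomputing both class statistics from scratch at each cut
otsu_bruteforce <- function(x, levels = 256) {
  edges <- seq(min(x), max(x), length.out = levels + 1)
  h <- hist(x, breaks = edges, plot = FALSE)
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(levels - 1)) {
    lo <- seq_len(k); hi <- (k + 1):levels
    w0 <- sum(h$counts[lo]); w1 <- sum(h$counts[hi])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h$counts[lo] * h$mids[lo]) / w0
    m1 <- sum(h$counts[hi] * h$mids[hi]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) { best <- bc; best_t <- edges[k + 1] }
  }
  best_t
}

# independent 2-variable non-negative least squares by nested grid search
nnls2_grid <- function(r, f1, f2, upper = NULL, iters = 4, n_grid = 60) {
  if (is.null(upper))
    upper <- 2 * max(abs(sum(r * f1) / sum(f1^2)),
                     abs(sum(r * f2) / sum(f2^2)), 1e-6)
  lo <- c(0, 0); hi <- c(upper, upper)
  for (it in seq_len(iters)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    ssr <- outer(g1, g2, Vectorize(function(a, b)
      sum((r - a * f1 - b * f2)^2)))
    k <- which(ssr == min(ssr), arr.ind = TRUE)[1, ]
    step1 <- g1[2] - g1[1]; step2 <- g2[2] - g2[1]
    lo <- pmax(c(g1[k[1]] - step1, g2[k[2]] - step2), 0)
    hi <- c(g1[k[1]] + step1, g2[k[2]] + step2)
  }
  x <- c(g1[k[1]], g2[k[2]])
  list(x = x, residual_ss = sum((r - x[1] * f1 - x[2] * f2)^2))
}
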