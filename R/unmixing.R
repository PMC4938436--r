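#' Unconstrained linear spectral unmixing
#'
#' Solves the standard unmixing model `y = F x` for the fluorophore abundance
#' vector `x` by ordinary least squares, minimizing `||y - F x||^2`.
#' Abundances may come out negative; physically impossible negatives are the
#' trigger for the non-negative fallback in [unmix_with_fallback()]. If `F`
#' is rank deficient a warning is raised and the minimum-norm solution is
#' returned.
#'
#' @param y length-m observed spectrum (pixel or particle-averaged).
#' @param F reference matrix: a [build_reference_matrix()] object or a plain
#'   m x n numeric matrix.
#' @return An object of class `unmix_fit` with fields `abundances` (named
#'   length-n vector), `residual_ss`, `method_used` (`"unconstrained"`),
#'   `fitted`, `y` and `rank_deficient`.
#' @export
unmix_unconstrained <- function(y, F) {
  Fm <- ref_mat(F)
  y <- as.numeric(y)
  if (length(y) != nrow(Fm))
    stop(sprintf("spectrum has %d channels, reference matrix has %d rows",
                 length(y), nrow(Fm)))
  qrF <- qr(Fm)
  deficient <- qrF$rank < ncol(Fm)
  if (deficient) {
    warning("reference matrix is rank deficient; returning the minimum-norm solution")
    sv <- svd(Fm)
    pos <- sv$d > max(sv$d) * 1e-12
    x <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    x <- drop(x)
  } else {
    x <- drop(qr.coef(qrF, y))
  }
  names(x) <- colnames(Fm)
  fitted <- drop(Fm %*% x)
  new_unmix_fit(x, y, fitted, "unconstrained", rank_deficient = deficient)
}

#' Non-negative linear spectral unmixing
#'
#' Solves `min ||y - F x||^2` subject to `x >= 0` with the Lawson-Hanson
#' active-set algorithm, reflecting that a fluorophore cannot have negative
#' abundance. When the unconstrained optimum is already feasible the two
#' solvers agree.
#'
#' @inheritParams unmix_unconstrained
#' @return An `unmix_fit` with `method_used = "nonnegative"` and all
#'   abundances `>= 0`.
#' @export
unmix_nonnegative <- function(y, F) {
  Fm <- ref_mat(F)
  y <- as.numeric(y)
  if (length(y) != nrow(Fm))
    stop(sprintf("spectrum has %d channels, reference matrix has %d rows",
                 length(y), nrow(Fm)))
  if (all(y == 0)) {
    x <- numeric(ncol(Fm))
  } else {
    x <- tryCatch(pracma::lsqnonneg(Fm, y)$x,
                  error = function(e)
                    stop("non-negative solver failed to converge: ",
                         conditionMessage(e)))
  }
  names(x) <- colnames(Fm)
  fitted <- drop(Fm %*% x)
  new_unmix_fit(x, y, fitted, "nonnegative")
}

#' Unmix with non-negativity fallback
#'
#' The two-stage solver policy applied to every pixel or object: fast
#' unconstrained least squares first; the result is accepted if all
#' abundances are non-negative and otherwise rejected and recomputed under
#' the non-negativity constraint. `method_used` on the returned fit records
#' which branch produced it.
#'
#' @inheritParams unmix_unconstrained
#' @return An `unmix_fit` from whichever branch was accepted.
#' @export
unmix_with_fallback <- function(y, F) {
  fit <- unmix_unconstrained(y, F)
  if (all(fit$abundances >= 0)) fit else unmix_nonnegative(y, F)
}

new_unmix_fit <- function(abundances, y, fitted, method,
                          rank_deficient = FALSE) {
  structure(list(abundances = abundances,
                 residual_ss = sum((y - fitted)^2),
                 method_used = method,
                 fitted = fitted, y = y,
                 rank_deficient = rank_deficient),
            class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear unmixing fit (%s), %d fluorophores\n",
              x$method_used, length(x$abundances)))
  print(round(x$abundances, digits))
  cat(sprintf("residual sum of squares: %.6g\n", x$residual_ss))
  invisible(x)
}

#' @export
coef.unmix_fit <- function(object, ...) object$abundances

#' @export
fitted.unmix_fit <- function(object, ...) object$fitted

#' @export
residuals.unmix_fit <- function(object, ...) object$y - object$fitted

#' Enumerate all unordered fluorophore pairs
#'
#' Every candidate binary label type: the `choose(n, 2)` unordered pairs
#' `{i, j}` with `i < j`, in deterministic lexicographic order. With the
#' 16-fluorophore repertoire this gives the 120 binary label types.
#'
#' @param n number of fluorophores (>= 2).
#' @return Integer matrix with `choose(n, 2)` rows and columns `i`, `j`
#'   (1-based, `i < j`).
#' @examples
#' nrow(enumerate_pairs(16))  # 120
#' @export
enumerate_pairs <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("need at least 2 fluorophores to enumerate pairs")
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Fit one binary fluorophore pair to a spectrum
#'
#' Solves the two-component model `y = f_i x_i + f_j x_j + b` for a single
#' candidate pair by least squares with non-negative abundances: minimizes
#' `||(y - b) - f_i x_i - f_j x_j||^2` over `x_i >= 0, x_j >= 0`. The
#' 2-variable problem is solved in closed form by checking the unconstrained
#' optimum and, if infeasible, the two single-component boundary solutions.
#' Near-parallel column pairs (2x2 Gram condition number above 1e8) are still
#' fitted but flagged degenerate.
#'
#' @inheritParams unmix_unconstrained
#' @param pair integer pair `c(i, j)` of fluorophore column indices.
#' @param b length-m background vector (or scalar, recycled); default 0.
#' @return List with `x` (the two non-negative abundances), `residual_ss`,
#'   `pair` and `degenerate`.
#' @export
fit_binary_pair <- function(y, F, pair, b = 0) {
  Fm <- ref_mat(F)
  y <- as.numeric(y)
  m <- nrow(Fm)
  if (length(y) != m) stop("spectrum length does not match reference matrix")
  b <- rep_len(as.numeric(b), m)
  i <- pair[1]; j <- pair[2]
  if (i == j) stop("pair must contain two distinct fluorophores")
  r <- y - b
  fi <- Fm[, i]; fj <- Fm[, j]
  fit <- fit_pair_core(r, fi, fj)
  list(x = stats::setNames(fit$x, colnames(Fm)[c(i, j)]),
       residual_ss = fit$residual_ss,
       pair = c(i = min(i, j), j = max(i, j)),
       degenerate = fit$degenerate)
}

# closed-form 2-variable NNLS on r ~ fi*xi + fj*xj
fit_pair_core <- function(r, fi, fj) {
  g11 <- sum(fi * fi); g22 <- sum(fj * fj); g12 <- sum(fi * fj)
  c1 <- sum(fi * r); c2 <- sum(fj * r)
  rtr <- sum(r * r)
  det <- g11 * g22 - g12 * g12
  tr <- g11 + g22
  disc <- sqrt(max(tr * tr - 4 * det, 0))
  lmin <- (tr - disc) / 2
  degenerate <- !is.finite(det) || det <= 0 ||
    lmin <= 0 || (tr + disc) / 2 / lmin > 1e8   # 2x2 Gram condition number
  ssr_at <- function(x1, x2)
    rtr - 2 * (x1 * c1 + x2 * c2) +
      x1 * x1 * g11 + 2 * x1 * x2 * g12 + x2 * x2 * g22
  best <- NULL
  if (det > 0) {
    x1 <- (g22 * c1 - g12 * c2) / det
    x2 <- (g11 * c2 - g12 * c1) / det
    if (x1 >= 0 && x2 >= 0) best <- list(x = c(x1, x2), ssr = ssr_at(x1, x2))
  }
  if (is.null(best)) {
    # constrained optimum lies on a boundary: best single-component fits
    x1 <- if (g11 > 0) max(c1 / g11, 0) else 0
    x2 <- if (g22 > 0) max(c2 / g22, 0) else 0
    cand <- list(c(x1, 0), c(0, x2), c(0, 0))
    ssr <- vapply(cand, function(x) ssr_at(x[1], x[2]), numeric(1))
    k <- which.min(ssr)
    best <- list(x = cand[[k]], ssr = ssr[k])
  }
  list(x = best$x, residual_ss = max(best$ssr, 0), degenerate = degenerate)
}

#' Binary-label-constrained unmixing of one spectrum
#'
#' The combinatorially constrained solver: every one of the `choose(n, 2)`
#' candidate fluorophore pairs is fitted in series with [fit_binary_pair()],
#' and the pair producing the smallest sum of squared residuals is selected
#' as the object's label type (ties broken by lexicographic pair order). The
#' confidence score is the Pearson correlation between the observed spectrum
#' and the reconstructed model spectrum `f_i x_i + f_j x_j + b` of the
#' winning fit.
#'
#' @inheritParams fit_binary_pair
#' @param keep_all if `TRUE`, retain the residual of every candidate pair in
#'   `all_pair_residuals`.
#' @return An object of class `binary_fit`: `pair` (winning `c(i, j)`,
#'   `i < j`), `pair_names`, `abundances` (the two non-negative abundances),
#'   `residual_ss`, `confidence`, `degenerate`, `fitted` (model spectrum
#'   including background), `y`, `b`, and optionally `all_pair_residuals`.
#' @export
binary_constrained_unmix <- function(y, F, b = 0, keep_all = FALSE) {
  Fm <- ref_mat(F)
  n <- ncol(Fm)
  if (n < 2L) stop("binary unmixing needs at least 2 reference spectra")
  y <- as.numeric(y)
  m <- nrow(Fm)
  if (length(y) != m) stop("spectrum length does not match reference matrix")
  b <- rep_len(as.numeric(b), m)
  r <- y - b
  pairs <- enumerate_pairs(n)
  np <- nrow(pairs)
  residuals <- if (keep_all) numeric(np) else NULL
  best_ssr <- Inf; best_k <- NA_integer_; best <- NULL
  for (k in seq_len(np)) {
    fit <- fit_pair_core(r, Fm[, pairs[k, 1]], Fm[, pairs[k, 2]])
    if (keep_all) residuals[k] <- fit$residual_ss
    if (fit$residual_ss < best_ssr) {   # strict '<' keeps lexicographic ties
      best_ssr <- fit$residual_ss; best_k <- k; best <- fit
    }
  }
  pair <- pairs[best_k, ]
  model <- Fm[, pair[1]] * best$x[1] + Fm[, pair[2]] * best$x[2] + b
  structure(list(
    pair = pair,
    pair_names = colnames(Fm)[pair],
    abundances = stats::setNames(best$x, colnames(Fm)[pair]),
    residual_ss = best$residual_ss,
    confidence = confidence_pearson(y, model),
    degenerate = best$degenerate,
    fitted = model, y = y, b = b,
    all_pair_residuals = residuals
  ), class = "binary_fit")
}

#' @export
print.binary_fit <- function(x, digits = 4, ...) {
  nm <- if (!is.null(x$pair_names)) paste(x$pair_names, collapse = " + ")
        else paste(x$pair, collapse = " + ")
  cat(sprintf("Binary-constrained unmixing fit: pair {%d, %d} (%s)\n",
              x$pair[1], x$pair[2], nm))
  cat(sprintf("  abundances: %.*g, %.*g\n", digits, x$abundances[1],
              digits, x$abundances[2]))
  cat(sprintf("  residual SS: %.6g   confidence (Pearson r): %.4f\n",
              x$residual_ss, x$confidence))
  if (isTRUE(x$degenerate))
    cat("  note: near-parallel reference pair (degenerate fit)\n")
  invisible(x)
}

#' @export
coef.binary_fit <- function(object, ...) object$abundances

#' @export
fitted.binary_fit <- function(object, ...) object$fitted

#' @export
residuals.binary_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.binary_fit <- function(x, ...) {
  graphics::plot(x$y, type = "h", xlab = "concatenated channel",
                 ylab = "intensity",
                 main = sprintf("observed vs model (%s)",
                                paste(x$pair_names, collapse = " + ")), ...)
  graphics::lines(x$fitted, col = "red", lwd = 2)
  graphics::legend("topright", legend = c("observed", "best binary fit"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Pearson-correlation confidence of a fit
#'
#' Confidence in an assigned label type: the sample Pearson correlation
#' between the observed spectrum of a particle and the reconstructed model
#' spectrum of its best binary fit. Undefined (returned as `NA`) when either
#' vector has zero variance.
#'
#' @param y observed spectrum.
#' @param model reconstructed spectrum `f_i x_i + f_j x_j + b`.
#' @return Scalar in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
confidence_pearson <- function(y, model) {
  y <- as.numeric(y); model <- as.numeric(model)
  if (length(y) != length(model)) stop("vectors must have equal length")
  if (stats::sd(y) == 0 || stats::sd(model) == 0) return(NA_real_)
  stats::cor(y, model)
}

#' Classify every segmented particle in an image
#'
#' The per-object pipeline step: averages raw pixel spectra over each
#' particle, then assigns each averaged spectrum its best binary label type
#' with [binary_constrained_unmix()]. Per-particle failures are recorded in
#' the `failures` attribute and do not abort the batch.
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param mask a [segment_particles()] result (or label matrix).
#' @param F reference matrix.
#' @param b length-m background vector (or scalar); default 0.
#' @return A data frame of class `particle_classification` with one row per
#'   particle: `particle_id`, `i`, `j`, `label_type` ("A+B"), `x_i`, `x_j`,
#'   `residual_ss`, `confidence`, `pixel_count`, `centroid_row`,
#'   `centroid_col`.
#' @export
classify_image <- function(image, mask, F, b = 0) {
  particles <- average_object_spectra(image, mask)
  classify_particles(particles, F, b = b)
}

#' Classify a set of averaged particle spectra
#'
#' @param particles a `particle_set` from [average_object_spectra()], or an
#'   m x k matrix of spectra (one column per particle).
#' @inheritParams classify_image
#' @return As [classify_image()].
#' @export
classify_particles <- function(particles, F, b = 0) {
  Fm <- ref_mat(F)
  if (is.matrix(particles)) {
    specs <- particles
    ids <- seq_len(ncol(specs))
    px <- rep(NA_integer_, ncol(specs))
    cen <- matrix(NA_real_, ncol(specs), 2)
  } else {
    specs <- if (length(particles)) particle_matrix(particles)
             else matrix(numeric(0), nrow = nrow(Fm))
    ids <- vapply(particles, function(p) p$particle_id, numeric(1))
    px <- vapply(particles, function(p) p$pixel_count, numeric(1))
    cen <- t(vapply(particles, function(p) p$centroid, numeric(2)))
  }
  k <- ncol(specs)
  rows <- vector("list", k)
  failures <- character(0)
  for (q in seq_len(k)) {
    fit <- tryCatch(binary_constrained_unmix(specs[, q], Fm, b = b),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("particle %s: %s", ids[q],
                                      conditionMessage(fit)))
      next
    }
    rows[[q]] <- data.frame(
      particle_id = ids[q],
      i = fit$pair[[1]], j = fit$pair[[2]],
      label_type = paste(fit$pair_names, collapse = "+"),
      x_i = fit$abundances[[1]], x_j = fit$abundances[[2]],
      residual_ss = fit$residual_ss,
      confidence = fit$confidence,
      pixel_count = px[q],
      centroid_row = cen[q, 1], centroid_col = cen[q, 2])
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(particle_id = numeric(), i = integer(), j = integer(),
                      label_type = character(), x_i = numeric(),
                      x_j = numeric(), residual_ss = numeric(),
                      confidence = numeric(), pixel_count = numeric(),
                      centroid_row = numeric(), centroid_col = numeric())
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  class(out) <- c("particle_classification", "data.frame")
  out
}

#' @export
print.particle_classification <- function(x, ...) {
  cat(sprintf("Particle classification: %d particle(s), %d label type(s)\n",
              nrow(x), length(unique(x$label_type))))
  fails <- attr(x, "failures")
  if (length(fails)) cat(sprintf("  %d particle(s) failed\n", length(fails)))
  NextMethod()
}

#' @export
summary.particle_classification <- function(object, ...) {
  tab <- sort(table(object$label_type), decreasing = TRUE)
  out <- list(n_particles = nrow(object),
              n_label_types = length(tab),
              counts = tab,
              mean_confidence = mean(object$confidence, na.rm = TRUE),
              failures = attr(object, "failures"))
  class(out) <- "summary.particle_classification"
  out
}

#' @export
print.summary.particle_classification <- function(x, ...) {
  cat(sprintf("%d particles in %d label types; mean confidence %.3f\n",
              x$n_particles, x$n_label_types, x$mean_confidence))
  print(x$counts)
  if (length(x$failures)) cat(length(x$failures), "failures\n")
  invisible(x)
}

#' @export
plot.particle_classification <- function(x, ...) {
  tab <- sort(table(x$label_type), decreasing = TRUE)
  graphics::barplot(tab, las = 2, cex.names = 0.6,
                    ylab = "particles", main = "label-type counts", ...)
  invisible(x)
}

#' Per-pixel linear unmixing of a spectral image
#'
#' Converts an m-channel spectral image into an n-channel abundance image by
#' solving the unmixing problem at every pixel with the two-stage
#' (unconstrained, then non-negative on rejection) policy, or with a single
#' fixed solver. This is the standard whole-image path; for combinatorially
#' labeled specimens the per-object [classify_image()] is both faster and
#' more accurate.
#'
#' @param image concatenated spectral image, (channel, row, col) array.
#' @param F reference matrix.
#' @param method `"fallback"` (default), `"unconstrained"` or `"nonnegative"`.
#' @return 3-d array of dimension `(n, rows, cols)` of per-pixel abundances,
#'   with attribute `fallback_rate` (fraction of pixels that needed the
#'   constrained solver) when `method = "fallback"`.
#' @export
unmix_pixels <- function(image, F,
                         method = c("fallback", "unconstrained",
                                    "nonnegative")) {
  method <- match.arg(method)
  Fm <- ref_mat(F)
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] != nrow(Fm))
    stop("image channel count does not match the reference matrix")
  flat <- matrix(image, nrow = d[1])
  n <- ncol(Fm)
  # all-pixel OLS in one solve; constrained refits only where needed
  X <- qr.coef(qr(Fm), flat)
  n_fallback <- 0L
  if (method != "unconstrained") {
    bad <- if (method == "nonnegative") seq_len(ncol(flat))
           else which(colSums(X < 0) > 0L)
    n_fallback <- length(bad)
    for (q in bad) X[, q] <- unmix_nonnegative(flat[, q], Fm)$abundances
  }
  out <- array(X, dim = c(n, d[2], d[3]))
  dimnames(out) <- list(colnames(Fm), NULL, NULL)
  if (method == "fallback")
    attr(out, "fallback_rate") <- n_fallback / ncol(flat)
  out
}
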