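test_that("unconstrained unmixing solves ordinary least squares", {
  Fm <- diag(2)
  colnames(Fm) <- c("A", "B")
  fit <- unmix_unconstrained(c(3, 5), Fm)
  expect_equal(unname(coef(fit)), c(3, 5))
  expect_equal(fit$residual_ss, 0)
  expect_equal(fit$method_used, "unconstrained")

  # forward-model recovery: y = F x exactly
  ref <- toy_reference()
  set.seed(31)
  for (rep in 1:15) {
    x_true <- runif(4, 0.1, 5)
    y <- drop(as.matrix(ref) %*% x_true)
    fit <- unmix_unconstrained(y, ref)
    expect_lt(max(abs(coef(fit) - x_true)), 1e-9)
    expect_lt(fit$residual_ss, 1e-18)
  }
})

test_that("rank-deficient references warn and give the minimum-norm solution", {
  Fm <- cbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  expect_warning(fit <- unmix_unconstrained(c(2, 2, 1), Fm), "rank deficient")
  expect_equal(unname(coef(fit)), c(1, 1, 1))   # minimum-norm split
  expect_lt(fit$residual_ss, 1e-18)
})

test_that("non-negative unmixing matches the unconstrained fit when feasible", {
  ref <- toy_reference()
  set.seed(37)
  for (rep in 1:10) {
    x_true <- runif(4, 0.5, 3)
    y <- drop(as.matrix(ref) %*% x_true) + rnorm(6, 0, 1e-3)
    fu <- unmix_unconstrained(y, ref)
    if (all(coef(fu) >= 0)) {
      fn <- unmix_nonnegative(y, ref)
      expect_lt(max(abs(coef(fn) - coef(fu))), 1e-9)
    }
  }
  fit0 <- unmix_nonnegative(rep(0, 6), ref)
  expect_equal(unname(coef(fit0)), rep(0, 4))
  expect_equal(fit0$residual_ss, 0)
})

test_that("non-negative solutions are KKT-optimal and match a grid oracle", {
  # 2-fluorophore toy whose unconstrained solution is infeasible
  f1 <- c(1, 0.8, 0.1); f2 <- c(0.9, 1, 0.15)
  Fm <- cbind(A = f1, B = f2)
  y <- drop(Fm %*% c(1.2, -0.3))
  fu <- unmix_unconstrained(y, Fm)
  expect_lt(min(coef(fu)), 0)
  fn <- unmix_nonnegative(y, Fm)
  expect_true(all(coef(fn) >= 0))
  oracle <- nnls2_grid(y, f1, f2)
  expect_lt(abs(fn$residual_ss - oracle$residual_ss), 1e-6)
  expect_lt(max(abs(unname(coef(fn)) - oracle$x)), 1e-3)
  # KKT: gradient of 0.5||y-Fx||^2 is >= 0 where x = 0, ~ 0 where x > 0
  grad <- drop(-t(Fm) %*% (y - Fm %*% coef(fn)))
  active <- coef(fn) <= 1e-12
  expect_true(all(grad[active] >= -1e-8))
  expect_true(all(abs(grad[!active]) < 1e-8))
})

test_that("fallback policy rejects negative abundances and records its branch", {
  f1 <- c(1, 0.8, 0.1); f2 <- c(0.9, 1, 0.15)
  Fm <- cbind(A = f1, B = f2)
  ok <- unmix_with_fallback(drop(Fm %*% c(1, 2)), Fm)
  expect_equal(ok$method_used, "unconstrained")
  bad <- unmix_with_fallback(drop(Fm %*% c(1.2, -0.3)), Fm)
  expect_equal(bad$method_used, "nonnegative")
  expect_true(all(coef(bad) >= 0))
  # batch of mixed cases: branch decisions match element-wise recomputation
  set.seed(41)
  for (rep in 1:20) {
    y <- drop(Fm %*% runif(2, -0.5, 2)) + rnorm(3, 0, 0.05)
    got <- unmix_with_fallback(y, Fm)
    expected_branch <- if (all(coef(unmix_unconstrained(y, Fm)) >= 0))
      "unconstrained" else "nonnegative"
    expect_equal(got$method_used, expected_branch)
  }
})

test_that("pair enumeration is complete, ordered and duplicate-free", {
  p16 <- enumerate_pairs(16)
  expect_equal(nrow(p16), 120L)
  expect_true(all(p16[, "i"] < p16[, "j"]))
  expect_equal(anyDuplicated(p16), 0L)
  expect_equal(enumerate_pairs(2), cbind(i = 1L, j = 2L))
  # set-equal to a brute-force double loop for n = 7
  p7 <- enumerate_pairs(7)
  brute <- NULL
  for (i in 1:6) for (j in (i + 1):7) brute <- rbind(brute, c(i, j))
  expect_equal(nrow(p7), 21L)
  expect_equal(unname(p7), brute)
  # lexicographic order
  expect_true(all(diff(p7[, 1] * 10 + p7[, 2]) > 0))
  expect_error(enumerate_pairs(1), "at least 2")
})

test_that("binary pair fits recover noise-free abundances with background", {
  ref <- toy_reference()
  Fm <- as.matrix(ref)
  b <- runif(6, 0, 0.5)
  y <- 2 * Fm[, 2] + 3 * Fm[, 4] + b
  fit <- fit_binary_pair(y, ref, c(2, 4), b = b)
  expect_equal(unname(fit$x), c(2, 3), tolerance = 1e-9)
  expect_lt(fit$residual_ss, 1e-12 * sum(y^2))
  expect_false(fit$degenerate)
})

test_that("pair-fit residual equals the orthogonal-projection residual", {
  # f_k lies between f_i and f_j so the projection has positive weights
  centers <- seq(500, 650, 10)
  g <- function(p) exp(-((centers - p)^2) / (2 * 15^2))
  fi <- g(520); fj <- g(560); fk <- g(535)
  Fm <- cbind(I = fi, J = fj, K = fk)
  fit <- fit_binary_pair(fk, Fm, c(1, 2))
  proj <- lm.fit(cbind(fi, fj), fk)   # independent projection oracle
  expect_true(all(proj$coefficients > 0))
  expect_equal(fit$residual_ss, sum(proj$residuals^2), tolerance = 1e-9)
  expect_gt(fit$residual_ss, 0)
})

test_that("near-parallel reference pairs are flagged degenerate", {
  f <- c(1, 0.5, 0.2)
  Fm <- cbind(A = f, B = f * (1 + 1e-9), C = c(0, 0, 1))
  fit <- fit_binary_pair(c(1, 0.5, 0.4), Fm, c(1, 2))
  expect_true(fit$degenerate)
  fit2 <- fit_binary_pair(c(1, 0.5, 0.4), Fm, c(1, 3))
  expect_false(fit2$degenerate)
})

test_that("pair-fit estimates are unbiased within Monte-Carlo error", {
  ref <- toy_reference()
  Fm <- as.matrix(ref)
  truth <- c(1.5, 0.8)
  set.seed(43)
  est <- t(replicate(200, {
    sim <- simulate_particle_spectrum(Fm, c(1, 3), truth, snr = 30)
    fit_binary_pair(sim$y, Fm, c(1, 3), b = sim$background)$x
  }))
  scale_mean <- simulate_particle_spectrum(Fm, c(1, 3), truth, snr = 30,
                                           noise = FALSE)$scale
  for (col in 1:2) {
    se <- sd(est[, col]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, col]) - truth[col] * scale_mean), 3 * se)
  }
})

test_that("binary-constrained unmixing picks the minimum-residual pair", {
  ref <- toy_reference()
  Fm <- as.matrix(ref)
  # noise-free: every pair is recovered exactly
  for (k in seq_len(nrow(enumerate_pairs(4)))) {
    p <- enumerate_pairs(4)[k, ]
    y <- 1.3 * Fm[, p[1]] + 0.9 * Fm[, p[2]]
    fit <- binary_constrained_unmix(y, ref, keep_all = TRUE)
    expect_equal(unname(fit$pair), unname(p))
    expect_lt(fit$residual_ss, 1e-12 * sum(y^2))
    # residual optimality against every candidate pair
    expect_true(all(fit$residual_ss <= fit$all_pair_residuals + 1e-15))
  }
  # noisy spectra: winner identical to an independent brute-force re-fit
  set.seed(47)
  for (rep in 1:25) {
    p <- enumerate_pairs(4)[sample(6, 1), ]
    sim <- simulate_particle_spectrum(Fm, p, runif(2, 0.5, 2), snr = 8)
    fit <- binary_constrained_unmix(sim$y, ref, b = sim$background)
    cand <- t(utils::combn(4, 2))
    ssr <- apply(cand, 1, function(q)
      fit_binary_pair(sim$y, ref, q, b = sim$background)$residual_ss)
    expect_equal(unname(fit$pair), unname(cand[which.min(ssr), ]))
    expect_identical(fit$residual_ss, min(ssr))
  }
})

test_that("pair fits agree with an independent active-set NNLS solver", {
  ref <- synth_reference_matrix()
  Fm <- as.matrix(ref)
  set.seed(53)
  for (rep in 1:20) {
    p <- sort(sample(16, 2))
    sim <- simulate_particle_spectrum(Fm, sample(16, 2), c(1, 1), snr = 5)
    fit <- fit_binary_pair(sim$y, ref, p, b = sim$background)
    ind <- pracma::lsqnonneg(Fm[, p], sim$y - sim$background)
    expect_lt(abs(fit$residual_ss - ind$resid.norm), 1e-8)
    expect_lt(max(abs(unname(fit$x) - ind$x)), 1e-6)
  }
})

test_that("equal-residual ties resolve to the lexicographically first pair", {
  f1 <- c(1, 0, 0); f3 <- c(0, 1, 0)
  Fm <- cbind(A = f1, B = f1, C = f3)   # columns 1 and 2 identical
  y <- f1 * 2
  fit <- binary_constrained_unmix(y, Fm, keep_all = TRUE)
  # pairs {1,2}, {1,3}, {2,3} all reach residual 0; {1,2} is first
  expect_equal(sum(fit$all_pair_residuals < 1e-20), 3L)
  expect_equal(unname(fit$pair), c(1L, 2L))
})

test_that("confidence is the Pearson correlation with standard edge cases", {
  y <- c(1, 4, 2, 7, 3)
  expect_equal(confidence_pearson(y, y), 1)
  expect_equal(confidence_pearson(y, -y + 10), -1)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 4)
  textbook <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(confidence_pearson(a, b), textbook)
  expect_true(is.na(confidence_pearson(y, rep(2, 5))))
  expect_error(confidence_pearson(y, 1:3), "equal length")
})

test_that("whole-image classification assigns every particle its true pair", {
  ref <- synth_reference_matrix()
  sim <- generate_synthetic_image(ref, enumerate_pairs(16)[c(1, 40, 80, 120), ],
                                  n_cells = 20, dim = c(130, 130), snr = 40,
                                  seed = 59)
  img <- concatenate_stacks(sim$stacks, sim$layout)
  mask <- segment_image(img)
  b <- estimate_background(img, sim$clear_roi, mask = mask)
  cls <- classify_image(img, mask, ref, b = b)
  expect_s3_class(cls, "particle_classification")
  expect_equal(nrow(cls), 20L)
  sc <- score_assignments(cls, sim$truth, match_radius = 8)
  expect_equal(sc$n_matched, 20L)
  expect_equal(sc$percent_correct, 100)
  expect_true(all(cls$confidence > 0.99))
  # empty mask gives an empty table
  empty <- classify_image(img, matrix(0L, 130, 130), ref, b = b)
  expect_equal(nrow(empty), 0L)
})

test_that("per-pixel unmixing matches per-spectrum solves and reports fallback", {
  ref <- toy_reference()
  Fm <- as.matrix(ref)
  set.seed(61)
  img <- array(rpois(6 * 6 * 5, 40), c(6, 6, 5))
  ab <- unmix_pixels(img, ref)
  expect_equal(dim(ab), c(4, 6, 5))
  for (q in sample(30, 8)) {
    r <- ((q - 1) %% 6) + 1; cc <- ((q - 1) %/% 6) + 1
    direct <- unmix_with_fallback(img[, r, cc], ref)
    expect_equal(unname(ab[, r, cc]), unname(coef(direct)), tolerance = 1e-9)
  }
  expect_true(attr(ab, "fallback_rate") >= 0 &&
                attr(ab, "fallback_rate") <= 1)
  abn <- unmix_pixels(img, ref, method = "nonnegative")
  expect_true(all(abn >= 0))
})
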