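test_that("synthetic spectra are physical and encode excitation structure", {
  lay <- default_layout()
  for (mdl in default_fluorophores()) {
    s <- synth_fluorophore_spectrum(mdl, lay)
    expect_true(all(s$values >= 0))
    expect_equal(max(s$values), 1)
    expect_length(s$values, 115)
  }
  # a dye peaked exactly on one laser line is dominated by that block
  mdl <- fluorophore_model("X", 488, 530)
  s <- synth_fluorophore_spectrum(mdl, lay)
  blocks <- split(s$values, rep(seq_along(lay$excitations),
                                lay$channels_per_excitation))
  expect_equal(which.max(vapply(blocks, max, numeric(1))),
               which(lay$excitations == 488), ignore_attr = TRUE)
  # no anti-Stokes emission: channels at or below the laser line are zero
  centers <- channel_centers(lay)
  for (i in seq_along(blocks))
    expect_true(all(blocks[[i]][centers[[i]] <= lay$excitations[i]] == 0))
  expect_error(fluorophore_model("bad", 500, 480), "Stokes")
  # no overlap with the layout at all
  uv <- fluorophore_model("uv", 351, 360, ex_width = 2, em_width = 2)
  expect_error(synth_fluorophore_spectrum(uv, lay), "no signal")
})

test_that("emission shape repeats across excitation blocks at scaled amplitude", {
  # two excitations, same emission grid high above both laser lines
  lay <- acquisition_layout(c(405, 488),
                           c(8, 8),
                           list(seq(600, 680, 10), seq(600, 680, 10)))
  mdl <- fluorophore_model("Y", 420, 630, ex_width = 40)
  s <- synth_fluorophore_spectrum(mdl, lay)
  b1 <- s$values[1:8]; b2 <- s$values[9:16]
  # identical shape, different amplitude
  expect_gt(max(b1), max(b2) * 1.1)
  expect_equal(b1 / max(b1), b2 / max(b2), tolerance = 1e-12)
})

test_that("particle simulation follows the Poisson shot-noise model", {
  ref <- toy_reference()
  Fm <- as.matrix(ref)
  nf <- simulate_particle_spectrum(Fm, c(1, 2), c(1, 1), snr = 12,
                                   background_level = 0.05, noise = FALSE)
  expect_equal(max(nf$y), 144)              # peak mean is snr^2
  expect_equal(nf$y, nf$mu)                 # infinite-SNR limit
  # law of large numbers on the peak channel
  set.seed(67)
  peak <- which.max(nf$mu)
  draws <- replicate(10000,
    simulate_particle_spectrum(Fm, c(1, 2), c(1, 1), snr = 12,
                               background_level = 0.05)$y[peak])
  expect_lt(abs(mean(draws) - 144) / 144, 0.01)
  # Poisson property: per-channel variance tracks the mean
  Y <- replicate(2000,
    simulate_particle_spectrum(Fm, c(1, 2), c(1, 1), snr = 12)$y)
  mu <- rowMeans(Y); v <- apply(Y, 1, var)
  bright <- mu > 5
  expect_true(all(abs(v[bright] / mu[bright] - 1) < 0.15))
  # realized peak SNR within 10% of the configured value
  expect_lt(abs(mean(draws) / sd(draws) - 12) / 12, 0.1)
  expect_warning(simulate_particle_spectrum(Fm, c(1, 2), c(1, 1), snr = 0.5),
                 "sub-photon")
})

test_that("image generation respects label types, proportions and geometry", {
  ref <- synth_reference_matrix()
  one <- generate_synthetic_image(ref, rbind(c(3, 11)), n_cells = 10,
                                  dim = c(100, 100), seed = 71)
  expect_equal(nrow(one$truth), 10L)
  expect_true(all(one$truth$i == 3 & one$truth$j == 11))
  expect_true(all(one$truth$pixel_count >= 4))
  expect_equal(length(one$stacks), 6L)
  # stacks come in acquisition (descending excitation) order
  expect_equal(names(one$stacks), c("633", "594", "561", "514", "488", "405"))
  # no cell center falls inside the reserved background ROI
  roi <- one$clear_roi
  expect_false(any(one$truth$row <= roi[1] + roi[3] - 1 &
                     one$truth$col <= roi[2] + roi[4] - 1))
  expect_error(
    generate_synthetic_image(ref, rbind(c(1, 2)), n_cells = 500,
                             dim = c(60, 60), seed = 3),
    "could only place")
  expect_error(
    generate_synthetic_image(ref, rbind(c(1, 2), c(1, 3)), n_cells = 5,
                             proportions = c(0.6, 0.6)),
    "sum to 1")
})

test_that("generated cells carry Poisson noise around the expected image", {
  ref <- toy_reference()
  # identical call with and without noise shares placements under one seed
  clean <- generate_synthetic_image(ref, rbind(c(1, 2)), n_cells = 6,
                                    dim = c(80, 80), snr = 20, seed = 73,
                                    noise = FALSE)
  noisy <- generate_synthetic_image(ref, rbind(c(1, 2)), n_cells = 6,
                                    dim = c(80, 80), snr = 20, seed = 73)
  expect_equal(clean$truth$row, noisy$truth$row)
  # brightest cell's peak channel expects snr^2 photons above background
  mu_all <- max(vapply(clean$stacks, max, numeric(1)))
  expect_equal(mu_all, 400 + 1, tolerance = 1e-9)
  mu <- clean$stacks[["405"]]
  y <- noisy$stacks[["405"]]
  # relative deviation over bright pixels consistent with shot noise
  bright <- mu > 100
  z <- (y[bright] - mu[bright]) / sqrt(mu[bright])
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(sd(z), 0.8); expect_lt(sd(z), 1.2)
})

test_that("the SNR experiment reports both algorithms per level", {
  res <- run_snr_experiment(snr_levels = c(3, 40), n_particles = 150,
                            seed = 79)
  expect_s3_class(res, "snr_experiment")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$pct_correct_constrained >= 0 &
                    res$pct_correct_constrained <= 100))
  # the binary constraint dominates in the noise-limited regime
  expect_gt(res$pct_correct_constrained[1],
            res$pct_correct_unconstrained[1] + 10)
  # both algorithms are reliable at high SNR
  expect_gt(res$pct_correct_constrained[2], 90)
  expect_gt(res$pct_correct_unconstrained[2], 90)
})

test_that("assignment scoring computes accuracy, confusion and rates", {
  # hand-built 4-particle case with one wrong assignment
  truth <- data.frame(particle_id = 1:4, i = c(1, 1, 2, 3),
                      j = c(2, 3, 4, 4))
  asg <- data.frame(particle_id = 1:4, i = c(1, 1, 2, 1),
                    j = c(2, 3, 4, 4))
  sc <- score_assignments(asg, truth)
  expect_equal(sc$percent_correct, 75)
  expect_equal(sc$n_matched, 4L)
  expect_equal(sum(sc$confusion), 4)
  # impossible-type rate against an allowed set
  sc2 <- score_assignments(asg, truth,
                           allowed_types = rbind(c(1, 2), c(1, 3), c(2, 4),
                                                 c(3, 4)))
  expect_equal(sc2$percent_impossible, 25)
  expect_equal(sc2$percent_possible, 75)
  # all correct: 100% possible, correlation 1 on unequal proportions
  truth3 <- data.frame(particle_id = 1:8,
                       i = c(1, 1, 1, 1, 1, 2, 2, 3),
                       j = c(2, 2, 2, 2, 3, 4, 4, 4))
  sc3 <- score_assignments(truth3, truth3,
                           allowed_types = cbind(truth3$i, truth3$j))
  expect_equal(sc3$percent_correct, 100)
  expect_equal(sc3$percent_impossible, 0)
  expect_equal(sc3$proportion_correlation, 1)
})

test_that("input and output proportions correlate on a linear-ramp mixture", {
  ref <- synth_reference_matrix()
  pairs <- enumerate_pairs(16)
  props <- seq(0.12, 1.5, length.out = 120)
  props <- props / sum(props)
  set.seed(83)
  n <- 1200
  type <- sample(120, n, replace = TRUE, prob = props)
  Y <- vapply(seq_len(n), function(k)
    simulate_particle_spectrum(ref, pairs[type[k], ], runif(2, 0.7, 1.3),
                               snr = 20, background_level = 0.02)$y,
    numeric(115))
  b <- simulate_particle_spectrum(ref, c(1, 2), c(1, 1), snr = 20,
                                  background_level = 0.02)$background
  cls <- classify_particles(Y, ref, b = b)
  truth <- data.frame(particle_id = seq_len(n),
                      i = pairs[type, 1], j = pairs[type, 2])
  sc <- score_assignments(cls, truth)
  expect_gt(sc$proportion_correlation, 0.9)
})
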