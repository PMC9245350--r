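test_that("histogram free energy inverts a constructed biased histogram", {
  # sampling under a bias added to the potential gives counts
  # N(s) ∝ e^{-g(s) - B(s)}; -ln N - B must recover g exactly
  grid <- grid_spec(0, 1, 0.1)
  centers <- grid$axes[[1]][-1] - 0.05
  g <- 3 * (centers - 0.4)^2
  B <- 1.5 * sin(2 * centers)
  counts <- round(1e5 * exp(-g - B))
  samples <- tibble::tibble(
    cv = rep(centers, counts),
    bias_value = rep(B, counts),
    replica = 1L
  )
  prof <- histogram_free_energy(samples, grid)
  # rounding to integer counts is the only error source
  expect_equal(prof$delta_G, g - min(g), tolerance = 1e-4)
  expect_true(all(is.na(prof$se)))   # single replica: no error bars, not zero

  # uniform counts, zero bias: flat profile at exactly 0
  flat <- tibble::tibble(cv = rep(centers, 50), bias_value = 0, replica = 1L)
  pf <- histogram_free_energy(flat, grid)
  expect_true(all(pf$delta_G == 0))
})

test_that("histogram free energy equals -ln(density) for unbiased samples", {
  withr::with_seed(4, x <- stats::rnorm(20000, 0.5, 0.12))
  grid <- grid_spec(0, 1, 0.05)
  samples <- tibble::tibble(cv = x, bias_value = 0,
                            replica = rep(1:4, length.out = length(x)))
  prof <- histogram_free_energy(samples, grid)
  counts <- prof$n_samples
  manual <- -log(counts)
  manual <- manual - min(manual[counts > 0])
  expect_equal(prof$delta_G[!prof$empty], manual[counts > 0])
  # empty bins flagged, not interpolated
  expect_true(any(prof$empty))
  expect_true(all(is.na(prof$delta_G[prof$empty])))
  # replica SEs present on well-populated bins
  expect_true(any(!is.na(prof$se)))
})

test_that("2D KDE landscapes: modes, normalisation, metadata", {
  withr::with_seed(10, {
    tight <- matrix(stats::rnorm(400, mean = 0.5, sd = 0.03), ncol = 2)
    k1 <- kde_landscape_2d(tight, bandwidth = 0.05,
                           lims = c(0, 1, 0, 1), n = 41)
    peak <- k1[which.max(k1$density), ]
    expect_lt(abs(peak$s1 - 0.5), 0.05)
    expect_lt(abs(peak$s2 - 0.5), 0.05)

    two <- rbind(matrix(stats::rnorm(300, -1, 0.08), ncol = 2),
                 matrix(stats::rnorm(300, 1, 0.08), ncol = 2))
    k2 <- kde_landscape_2d(two, bandwidth = 0.05,
                           lims = c(-2, 2, -2, 2), n = 81)
    # two local maxima: density high near both cluster centres, low between
    at <- function(x, y) {
      k2$density[which.min((k2$s1 - x)^2 + (k2$s2 - y)^2)]
    }
    expect_gt(at(-1, -1), 10 * at(0, 0))
    expect_gt(at(1, 1), 10 * at(0, 0))

    # density integrates to 1 over a generous domain
    dx <- diff(sort(unique(k2$s1))[1:2]); dy <- diff(sort(unique(k2$s2))[1:2])
    expect_equal(sum(k2$density) * dx * dy, 1, tolerance = 0.01)
    expect_match(attr(k2, "caveat"), "bandwidth")
  })
  expect_error(kde_landscape_2d(matrix(0, 5, 2), bandwidth = 0),
               "bandwidth")
  expect_error(kde_landscape_2d(matrix(0, 1, 2), bandwidth = 0.1),
               "at least 2")
})

test_that("classify_states counts, errors and probability algebra", {
  frames <- tibble::tibble(
    x = c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85, 0.5, 0.45, 0.88, 0.12),
    replica = rep(1:2, 5)
  )
  states <- list(
    state_definition("low", function(df) df$x < 0.3),
    state_definition("high", function(df) df$x > 0.7)
  )
  res <- classify_states(frames, states)
  expect_equal(res$probability[res$state == "low"], 0.4)
  expect_equal(res$probability[res$state == "high"], 0.4)
  expect_equal(res$probability[res$state == "other"], 0.2)
  expect_equal(sum(res$probability), 1)
  expect_true(all(is.finite(res$se)))

  # all frames in one state
  all_low <- classify_states(dplyr::mutate(frames, x = 0.1), states)
  expect_equal(all_low$probability, c(1, 0, 0))

  # overlapping predicates rejected before counting
  overlap <- list(
    state_definition("a", function(df) df$x < 0.5),
    state_definition("b", function(df) df$x < 0.9)
  )
  expect_error(classify_states(frames, overlap), "mutually exclusive")

  # weights shift the occupancy as expected
  w <- ifelse(frames$x < 0.3, 2, 1)
  res_w <- classify_states(frames, states, weights = w)
  expect_equal(res_w$probability[res_w$state == "low"], 8 / 14)
})

test_that("spring weights: trivial cases and the conjugate-Gaussian oracle", {
  springs <- wlc_spring_set(6, 12)
  # no springs, zero bias: weight 1 after normalisation
  w0 <- spring_weight(rep(0, 5), NULL)
  expect_equal(as.numeric(w0), rep(1, 5))

  # B = sum(DG): exact cancellation, weight 1 relative to itself
  L_cancel <- matrix(rep(2, 6), 1)
  dg <- spring_set_free_energy(L_cancel[1, ], springs)
  w1 <- spring_weight(dg, L_cancel, springs)
  expect_equal(as.numeric(w1), 1)

  # overstretched springs get weight zero, flagged not thrown
  L_over <- rbind(rep(2, 6), c(8.5, rep(2, 5)))   # short spring L0 = 4.732
  w2 <- spring_weight(c(0, 0), L_over, springs)
  expect_equal(as.numeric(w2[2]), 0)
  expect_identical(attr(w2, "overstretch_events"), 1L)

  # conjugate-Gaussian check: flat-biased x ~ N(0,1) reweighted by a
  # harmonic "spring" e^{-k x^2 / 2} has mean 0 and variance 1/(1+k)
  withr::with_seed(9, x <- stats::rnorm(1e5))
  k <- 1.7
  w3 <- exp(-0.5 * k * x^2)   # what a quadratic spring penalty would give
  m <- sum(w3 * x) / sum(w3)
  v <- sum(w3 * (x - m)^2) / sum(w3)
  expect_equal(v, 1 / (1 + k), tolerance = 0.01)
})

test_that("reweighted angle statistics reduce correctly and match the oracle", {
  # uniform weights: exactly the unweighted statistics
  frames <- tibble::tibble(phi = c(150, 160, 170, 200),
                           bias_value = 0, replica = c(1, 1, 2, 2))
  st <- reweighted_angle_stats(frames, springs = NULL, L_cols = character(0))
  expect_equal(st$mean_phi, mean(frames$phi))
  expect_equal(st$sd_phi, stats::sd(frames$phi) * sqrt(3 / 4))  # population sd
  expect_equal(st$ess, 4)

  # two frames, weights (1, 0): statistics of frame 1 exactly
  springs1 <- wlc_spring_set(6, 12)
  two <- tibble::tibble(phi = c(123, 300), bias_value = 0,
                        L1 = c(2, 8.5), L2 = 2, L3 = 2,
                        L4 = 3, L5 = 3, L6 = 3)
  expect_warning(st2 <- reweighted_angle_stats(two, springs1, ess_floor = 0.6),
                 "effective sample")
  expect_equal(st2$mean_phi, 123)
  expect_equal(st2$sd_phi, 0)
  expect_identical(st2$overstretch_events, 1L)

  # all frames inadmissible
  allover <- dplyr::mutate(two, L1 = 9)
  expect_error(reweighted_angle_stats(allover, springs1), "no admissible")

  # wrap warning
  wrap <- tibble::tibble(phi = c(5, 355), bias_value = 0)
  expect_warning(reweighted_angle_stats(wrap, NULL, L_cols = character(0)),
                 "wrap")

  # latent-variable oracle: sampled frames vs quadrature-exact moments
  fx <- generate_fixture("spring_frame_table", seed = 41, n = 1e5)
  st3 <- reweighted_angle_stats(fx$frames, fx$springs)
  expect_lt(abs(st3$mean_phi - fx$mean_phi_true) / fx$mean_phi_true, 0.01)
  expect_lt(abs(st3$sd_phi - fx$sd_phi_true) / fx$sd_phi_true, 0.01)
  expect_false(is.na(st3$se_mean))
  expect_lte(st3$ess, st3$n_frames)
})

test_that("spring sweeps isolate failures per row and report monotone trends", {
  fx <- generate_fixture("spring_frame_table", seed = 53, n = 2e4)
  single <- spring_sweep(fx$frames, tibble::tibble(n_short = 6, n_long = 12))
  direct <- reweighted_angle_stats(fx$frames, fx$springs)
  expect_equal(single$mean_phi, direct$mean_phi)
  expect_equal(single$sd_phi, direct$sd_phi)

  cand <- tibble::tibble(n_short = c(0, 6, 8, 10), n_long = 12)
  sw <- spring_sweep(fx$frames, cand)
  # candidate with contour below every observed extension fails alone
  expect_false(sw$admissible[sw$n_short == 0])
  expect_true(all(sw$admissible[sw$n_short > 0]))
  ok <- sw[sw$admissible, ]
  # shorter springs pull the short gap tighter: mean angle moves monotonically
  expect_true(all(diff(ok$mean_phi[order(ok$n_short)]) > 0) ||
                all(diff(ok$mean_phi[order(ok$n_short)]) < 0))
  mono <- attr(sw, "monotone_mean_phi")
  expect_true(all(mono$monotone))
})
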