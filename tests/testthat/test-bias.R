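fresh_bias_1d <- function(sigma = 0.1, height = 1, delta_T = 1,
                          lo = -2, hi = 2, dx = 0.02) {
  gridded_bias(grid_spec(lo, hi, dx), sigma = sigma, height = height,
               delta_T = delta_T)
}

test_that("grid construction enforces spacing rules", {
  expect_error(grid_spec(0, 1, 0.3), "integer multiple")
  expect_error(grid_spec(0, 1, -0.1), "positive")
  g <- grid_spec(c(0, -1), c(1, 1), c(0.05, 0.1))
  expect_identical(g$n_nodes, c(21L, 21L))
  # the delta-x <= sigma/5 rule is enforced where sigma is known
  expect_error(gridded_bias(grid_spec(0, 1, 0.05), sigma = 0.2, height = 1,
                            delta_T = 1), "sigma/5")
  expect_silent(gridded_bias(grid_spec(0, 1, 0.04), sigma = 0.2, height = 1,
                             delta_T = 1))
  expect_error(gridded_bias(grid_spec(0, 1, 0.01), sigma = 0.1, height = 1,
                            delta_T = 0), "delta_T")
})

test_that("well-tempered amplitude follows A exp(-B/delta_T)", {
  b <- fresh_bias_1d(height = 0.7, delta_T = 2)
  expect_equal(well_tempered_amplitude(b, 0.5), 0.7)

  # after manually setting B = delta_T at a node, amplitude there is A/e
  b2 <- b
  node <- which(b2$grid$axes[[1]] == 0.5)
  b2$values[node] <- 2
  expect_equal(well_tempered_amplitude(b2, 0.5), 0.7 * exp(-1))

  # closed-form composition: A = 1, delta_T = 1, two deposits at one point
  b3 <- fresh_bias_1d(height = 1, delta_T = 1)
  b3 <- deposit(b3, 0, warn_edge = FALSE)
  b3 <- deposit(b3, 0, warn_edge = FALSE)
  expect_equal(bias_evaluate(b3, 0), 1 + exp(-1), tolerance = 1e-12)
})

test_that("deposits add truncated Gaussians matching a brute-force oracle", {
  b <- fresh_bias_1d(height = 0.5, delta_T = 1e15)  # effectively untempered
  b <- deposit(b, 0.4, warn_edge = FALSE)
  node <- which(abs(b$grid$axes[[1]] - 0.4) < 1e-12)
  expect_equal(b$values[node], 0.5, tolerance = 1e-15)
  # nodes beyond 5 sigma untouched (10 sigma away certainly)
  far <- which(abs(b$grid$axes[[1]] - 0.4) > 1)
  expect_true(all(b$values[far] == 0))
  expect_identical(b$deposits_made, 1L)

  # three deposits vs brute-force Gaussian sum at every node (1D)
  b1 <- fresh_bias_1d(sigma = 0.3, height = 0.8, delta_T = 1e15, dx = 0.05)
  centers <- c(-0.63, 0.12, 0.97)
  for (s in centers) b1 <- deposit(b1, s, warn_edge = FALSE)
  ax <- b1$grid$axes[[1]]
  oracle <- rowSums(vapply(centers, function(s) {
    g <- 0.8 * exp(-(ax - s)^2 / (2 * 0.3^2))
    g[abs(ax - s) > 5 * 0.3] <- 0
    g
  }, numeric(length(ax))))
  expect_equal(b1$values, oracle, tolerance = 1e-12)

  # 2D deposits vs brute force
  g2 <- grid_spec(c(-1, -1), c(1, 1), c(0.04, 0.04))
  b2 <- gridded_bias(g2, sigma = c(0.2, 0.25), height = 0.6, delta_T = 1e15)
  pts <- rbind(c(-0.3, 0.2), c(0.5, -0.1), c(0.05, 0.66))
  for (i in 1:3) b2 <- deposit(b2, pts[i, ], warn_edge = FALSE)
  axx <- g2$axes[[1]]; axy <- g2$axes[[2]]
  oracle2 <- matrix(0, length(axx), length(axy))
  for (i in 1:3) {
    gx <- exp(-(axx - pts[i, 1])^2 / (2 * 0.2^2))
    gx[abs(axx - pts[i, 1]) > 1] <- 0
    gy <- exp(-(axy - pts[i, 2])^2 / (2 * 0.25^2))
    gy[abs(axy - pts[i, 2]) > 1.25] <- 0
    oracle2 <- oracle2 + 0.6 * outer(gx, gy)
  }
  expect_equal(b2$values, oracle2, tolerance = 1e-12)

  # warns when substantial Gaussian mass falls outside the grid
  expect_warning(deposit(fresh_bias_1d(), -1.95), "mass")
})

test_that("node values are non-negative, non-decreasing, with decaying amplitudes", {
  b <- fresh_bias_1d(sigma = 0.2, height = 1, delta_T = 2, dx = 0.04)
  withr::with_seed(5, {
    amps <- numeric(30)
    for (k in 1:30) {
      before <- b$values
      amps[k] <- well_tempered_amplitude(b, 0.1)
      b <- deposit(b, stats::runif(1, -1, 1), warn_edge = FALSE)
      expect_true(all(b$values >= before))
    }
  })
  expect_true(all(b$values >= 0))

  # strictly decreasing amplitude at a fixed deposit point
  b2 <- fresh_bias_1d(sigma = 0.2, height = 1, delta_T = 2, dx = 0.04)
  amps <- numeric(20)
  for (k in 1:20) {
    amps[k] <- well_tempered_amplitude(b2, 0)
    b2 <- deposit(b2, 0, warn_edge = FALSE)
  }
  expect_true(all(diff(amps) < 0))

  # saturation bound: B(s0) after n deposits < delta_T ln(1 + n A / delta_T) + A,
  # checked against the exact recurrence as well
  n <- 200
  A <- 1; dT <- 2
  b3 <- fresh_bias_1d(sigma = 0.2, height = A, delta_T = dT, dx = 0.04)
  rec <- 0
  for (k in seq_len(n)) {
    b3 <- deposit(b3, 0, warn_edge = FALSE)
    rec <- rec + A * exp(-rec / dT)
  }
  at0 <- bias_evaluate(b3, 0)
  expect_equal(at0, rec, tolerance = 1e-10)
  expect_lt(at0, dT * log(1 + n * A / dT) + A)
})

test_that("interpolation is exact at nodes and matches the textbook oracle", {
  withr::with_seed(21, {
    b <- fresh_bias_1d(sigma = 0.25, height = 1, delta_T = 1e8, dx = 0.05)
    for (k in 1:5) b <- deposit(b, stats::runif(1, -1.5, 1.5), warn_edge = FALSE)
    ax <- b$grid$axes[[1]]
    expect_equal(bias_evaluate(b, ax[17]), b$values[17])

    # 200 random queries vs direct linear interpolation
    q <- stats::runif(200, -2, 2)
    i0 <- pmin(floor((q - (-2)) / 0.05), length(ax) - 2)
    f <- (q - (-2)) / 0.05 - i0
    oracle <- (1 - f) * b$values[i0 + 1] + f * b$values[i0 + 2]
    expect_equal(bias_evaluate(b, matrix(q, ncol = 1)), oracle,
                 tolerance = 1e-12)

    # 2D: query at a cell centre equals the mean of the 4 corner nodes
    g2 <- grid_spec(c(0, 0), c(1, 1), c(0.1, 0.1))
    b2 <- gridded_bias(g2, sigma = 0.5, height = 1, delta_T = 1)
    b2$values <- matrix(stats::rnorm(121)^2, 11, 11)
    expect_equal(bias_evaluate(b2, c(0.35, 0.75)),
                 mean(b2$values[4:5, 8:9]), tolerance = 1e-12)

    # 200 random 2D queries vs the textbook bilinear formula
    qx <- stats::runif(200); qy <- stats::runif(200)
    ix <- pmin(floor(qx / 0.1), 9); iy <- pmin(floor(qy / 0.1), 9)
    fx <- qx / 0.1 - ix; fy <- qy / 0.1 - iy
    oracle2 <- (1 - fx) * (1 - fy) * b2$values[cbind(ix + 1, iy + 1)] +
      fx * (1 - fy) * b2$values[cbind(ix + 2, iy + 1)] +
      (1 - fx) * fy * b2$values[cbind(ix + 1, iy + 2)] +
      fx * fy * b2$values[cbind(ix + 2, iy + 2)]
    expect_equal(bias_evaluate(b2, cbind(qx, qy)), oracle2, tolerance = 1e-12)
  })
})

test_that("grid refinement converges at second order", {
  # smooth bias from a few wide deposits; halving dx changes evaluate() by O(dx^2)
  centers <- c(-0.4, 0.3, 0.8)
  make <- function(dx) {
    b <- fresh_bias_1d(sigma = 0.4, height = 1, delta_T = 1e8, dx = dx)
    for (s in centers) b <- deposit(b, s, warn_edge = FALSE)
    b
  }
  exact <- function(q) {
    rowSums(vapply(centers, function(s) exp(-(q - s)^2 / (2 * 0.4^2)),
                   numeric(length(q))))
  }
  withr::with_seed(8, q <- stats::runif(100, -1.5, 1.5))
  err <- vapply(c(0.08, 0.04, 0.02), function(dx) {
    max(abs(bias_evaluate(make(dx), matrix(q, ncol = 1)) - exact(q)))
  }, numeric(1))
  order1 <- log2(err[1] / err[2]); order2 <- log2(err[2] / err[3])
  expect_gt(order1, 1.8)
  expect_gt(order2, 1.8)
})

test_that("bias forces follow the chain rule through the CV", {
  # flat bias: zero force
  b <- fresh_bias_1d()
  cfg <- random_config(4, seed = 2)
  cv <- cv_com_distance(1:2, 3:4, domain = c(0, 10))
  expect_equal(bias_force(b, cfg, cv), matrix(0, 4, 3))

  # linear 1D bias with slope m on a single-particle coordinate CV
  m <- 0.8
  b1 <- fresh_bias_1d(lo = -2, hi = 2, dx = 0.02)
  b1$values <- m * (b1$grid$axes[[1]] + 2)
  cvx <- cv_coordinate(1, domain = c(-2, 2))
  p <- particle_config(matrix(c(0.3, 0, 0), 1, 3))
  expect_equal(bias_force(b1, p, cvx), matrix(c(-m, 0, 0), 1, 3),
               tolerance = 1e-10)

  # random bias + com_distance: force matches finite differences of B(s(q))
  withr::with_seed(13, {
    b2 <- fresh_bias_1d(sigma = 0.4, height = 1, delta_T = 5, lo = 0, hi = 8,
                        dx = 0.05)
    for (k in 1:6) b2 <- deposit(b2, stats::runif(1, 1, 7), warn_edge = FALSE)
    cfg2 <- random_config(6, seed = 14, sd = 1.5)
    cv2 <- cv_com_distance(1:3, 4:6, domain = c(0, 8))
    f <- bias_force(b2, cfg2, cv2)
    h <- 1e-6
    num <- matrix(0, 6, 3)
    for (i in 1:6) for (d in 1:3) {
      cp <- cfg2; cm <- cfg2
      cp$positions[i, d] <- cp$positions[i, d] + h
      cm$positions[i, d] <- cm$positions[i, d] - h
      num[i, d] <- -(bias_evaluate(b2, cv2$value(cp)) -
                       bias_evaluate(b2, cv2$value(cm))) / (2 * h)
    }
    expect_lt(max(abs(f - num)) / max(abs(num)), 1e-3)
  })

  # dimensionality mismatch is refused
  g2 <- grid_spec(c(0, 0), c(1, 1), c(0.05, 0.05))
  b3 <- gridded_bias(g2, sigma = 0.3, height = 1, delta_T = 1)
  expect_error(bias_force(b3, p, cvx), "dimensionality")

  # no analytic gradient + fallback disabled
  cv_nograd <- collective_variable(1, function(config, topo = NULL) {
    config$positions[1, 1]
  }, domain = c(-2, 2), name = "opaque")
  b4 <- fresh_bias_1d()
  b4$values <- b4$values + seq_along(b4$values) * 0.01
  expect_error(bias_force(b4, p, cv_nograd, allow_fd_gradient = FALSE),
               "no analytic gradient")
})

test_that("implied free energy rescales, flips and min-shifts the bias", {
  b <- fresh_bias_1d(delta_T = 8, lo = 0, hi = 0.04, dx = 0.02)
  expect_warning(ife0 <- implied_free_energy(b), "not yet converged")
  expect_true(all(ife0$delta_G == 0))

  b$values <- c(8, 4, 0)
  ife <- implied_free_energy(b)
  expect_equal(ife$delta_G, c(0, 4.5, 9))
})

test_that("bias files round-trip losslessly and reject corrupt input", {
  withr::with_seed(99, {
    b <- fresh_bias_1d(sigma = 0.3, height = 0.7, delta_T = 4, dx = 0.05)
    for (k in 1:7) b <- deposit(b, stats::runif(1, -1.5, 1.5), warn_edge = FALSE)
    b$cycles_elapsed <- 7L
  })
  path <- withr::local_tempfile(fileext = ".bias")
  write_bias(b, path)
  b2 <- read_bias(path)
  expect_identical(b2$values, b$values)
  expect_identical(b2$deposits_made, b$deposits_made)
  expect_identical(b2$cycles_elapsed, b$cycles_elapsed)
  expect_equal(b2$sigma, b$sigma)
  expect_equal(b2$delta_T, b$delta_T)
  expect_equal(b2$grid$axes, b$grid$axes)

  # 2D round trip
  g2 <- grid_spec(c(0, 0), c(1, 1), c(0.05, 0.05))
  bb <- gridded_bias(g2, sigma = c(0.3, 0.4), height = 1, delta_T = 2)
  bb <- deposit(bb, c(0.4, 0.6), warn_edge = FALSE)
  write_bias(bb, path)
  bb2 <- read_bias(path)
  expect_identical(bb2$values, bb$values)

  # mismatched declared dimensionality
  lines <- readLines(path)
  lines[grep("^# dim:", lines)] <- "# dim: 1"
  writeLines(lines, path)
  expect_error(read_bias(path), "dimensionality")

  # incompatible major version
  write_bias(b, path)
  lines <- readLines(path)
  lines[1] <- "# metadyn-bias-format: 2.0"
  writeLines(lines, path)
  expect_error(read_bias(path), "incompatible")

  # compatible minor version migrates with a note
  lines[1] <- "# metadyn-bias-format: 1.0.1"
  writeLines(lines, path)
  expect_message(b3 <- read_bias(path), "migrated")
  expect_identical(b3$values, b$values)

  # corrupted header
  writeLines(lines[-grep("^# sigma:", lines)], path)
  expect_error(read_bias(path), "missing 'sigma'")
})
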