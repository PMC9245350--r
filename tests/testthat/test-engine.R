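test_that("velocity-Verlet conserves energy without a thermostat", {
  pot <- harmonic_potential(4, matrix(0, 3, 3))
  cfg <- random_config(3, seed = 1, velocities = TRUE)
  smp <- sampler_config(dt = 0.002, thermostat_interval = Inf)
  e0 <- pot$energy(cfg) + 0.5 * sum(cfg$velocities^2)
  out <- md_segment(cfg, pot, 1000, smp)
  e1 <- pot$energy(out) + 0.5 * sum(out$velocities^2)
  expect_equal(e1, e0, tolerance = 1e-4)
  expect_identical(out$step_count, 1000)
})

test_that("a free particle with the thermostat off moves ballistically", {
  pot <- potential_model("free", function(config) 0,
                         function(config) matrix(0, nrow(config$positions), 3))
  cfg <- particle_config(matrix(c(1, 2, 3), 1, 3),
                         velocities = matrix(c(0.5, -1, 2), 1, 3))
  smp <- sampler_config(dt = 0.01, thermostat_interval = Inf)
  out <- md_segment(cfg, pot, 500, smp)
  expect_equal(out$positions[1, ], c(1, 2, 3) + 500 * 0.01 * c(0.5, -1, 2),
               tolerance = 1e-12)
})

test_that("the Andersen-like thermostat equilibrates kinetic energy", {
  pot <- harmonic_potential(2, matrix(0, 8, 3))
  cfg <- random_config(8, seed = 3, velocities = TRUE)
  smp <- sampler_config(dt = 0.01, thermostat_interval = 25,
                        refresh_fraction = 0.5)
  ke <- numeric(400)
  policy <- seed_policy(42, 1)
  res <- metadyn:::run_in_stream(policy, 1, function() {
    for (k in seq_len(400)) {
      cfg <<- md_segment(cfg, pot, 50, smp)
      ke[k] <<- 0.5 * sum(cfg$velocities^2) / 8
    }
  })
  # equipartition: 3/2 kT per particle
  expect_equal(mean(ke[-(1:50)]), 1.5, tolerance = 0.05)
})

test_that("MD raises a named error on integration blow-up", {
  pot <- harmonic_potential(4, matrix(0, 2, 3))
  cfg <- particle_config(matrix(1, 2, 3), velocities = matrix(0, 2, 3))
  smp <- sampler_config(dt = 50, thermostat_interval = Inf)  # wildly unstable
  expect_error(md_segment(cfg, pot, 1000, smp), "blow-up.*step",
               perl = TRUE)
  expect_error(md_segment(particle_config(matrix(0, 2, 3)), pot, 10, smp),
               "requires velocities")
})

test_that("Metropolis MC: free acceptance, Boltzmann variance, hard rejection", {
  free <- potential_model("free", function(config) 0,
                          function(config) matrix(0, nrow(config$positions), 3))
  cfg <- particle_config(matrix(0, 1, 3))
  smp <- sampler_config(mc_move_size = 0.3)
  policy <- seed_policy(7, 1)
  out <- metadyn:::run_in_stream(policy, 1, function() {
    mc_segment(cfg, free, 500, smp)
  })$value
  # zero potential: every move accepted, so the walker random-walks away
  expect_false(any(out$positions == 0))

  # 1D harmonic well: sampled variance = kT / k
  kspring <- 4
  well <- potential_model("well1d",
                          function(config) 0.5 * kspring * sum(config$positions[1, ]^2),
                          function(config) -kspring * config$positions)
  policy <- seed_policy(11, 1)
  xs <- metadyn:::run_in_stream(policy, 1, function() {
    c0 <- particle_config(matrix(0, 1, 3))
    n_samp <- 4000
    out <- numeric(n_samp)
    for (k in seq_len(n_samp)) {
      c0 <- mc_segment(c0, well, 25, smp)
      out[k] <- c0$positions[1, 1]
    }
    out
  })$value
  expect_equal(stats::var(xs[-(1:200)]), 1 / kspring, tolerance = 0.06)

  # an infinite-energy proposal (hard overlap) is always rejected
  hard <- potential_model("hard",
                          function(config) {
                            if (any(abs(config$positions) > 1e-9)) Inf else 0
                          },
                          function(config) matrix(0, nrow(config$positions), 3))
  policy <- seed_policy(5, 1)
  pinned <- metadyn:::run_in_stream(policy, 1, function() {
    mc_segment(particle_config(matrix(0, 1, 3)), hard, 200, smp)
  })$value
  expect_equal(pinned$positions, matrix(0, 1, 3))
})

test_that("MC sampling reproduces the Boltzmann distribution of a 3-well toy", {
  # three discrete-ish basins realised as deep narrow wells along x; the
  # stationary occupancy must match the exact Boltzmann weights
  centers <- c(-1, 0, 1)
  depths <- c(0, 0.7, 1.6)   # energies at the three minima, kT
  kwell <- 30                # inter-well barrier ~3 kT: crossable by moves
  toy <- potential_model(
    "three_state",
    function(config) {
      x <- config$positions[1, 1]
      y2 <- sum(config$positions[1, 2:3]^2)
      min(0.5 * kwell * (x - centers)^2 + depths) + 0.5 * kwell * y2
    },
    function(config) stop("MC only"))
  smp <- sampler_config(mc_move_size = 0.45)
  policy <- seed_policy(123, 1)
  xs <- metadyn:::run_in_stream(policy, 1, function() {
    c0 <- particle_config(matrix(c(-1, 0, 0), 1, 3))
    n_samp <- 6000
    out <- numeric(n_samp)
    for (k in seq_len(n_samp)) {
      c0 <- mc_segment(c0, toy, 20, smp)
      out[k] <- c0$positions[1, 1]
    }
    out
  })$value
  state <- apply(abs(outer(xs, centers, "-")), 1, which.min)
  # exact weights: equal curvature wells, weights e^{-depth}
  w <- exp(-depths); w <- w / sum(w)
  occ <- tabulate(state, 3) / length(state)
  expect_lt(max(abs(occ - w)), 0.03)
})

test_that("metad_run bookkeeping, determinism and walker initialisation", {
  fx <- generate_fixture("double_well_1d")
  smp <- fx$sampler
  run_once <- function(seed) {
    metad_run(fx$potential, fx$cv, fx$grid, n_walkers = 4, n_cycles = 3,
              tau = 10, sigma = 0.15, height = 0.5, delta_T = 8,
              sampler = smp, seed = seed, init_fn = fx$init_fn)
  }
  r <- run_once(31)
  expect_identical(r$bias$deposits_made, 12L)   # n_cycles x n_walkers
  expect_identical(r$bias$cycles_elapsed, 3L)
  expect_identical(nrow(r$trace), 12L)

  # determinism: same seed, bit-identical bias files
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bias(run_once(31)$bias, p1)
  write_bias(run_once(31)$bias, p2)
  expect_identical(readLines(p1), readLines(p2))
  r2 <- run_once(32)
  expect_false(identical(r2$bias$values, r$bias$values))

  # default initialisation spreads walkers over the CV domain quantiles
  expect_error(metad_run(fx$potential, fx$cv, fx$grid, n_walkers = 2,
                         n_cycles = 1, tau = 1, sigma = 0.15, height = 0.5,
                         delta_T = 8, sampler = smp, seed = 1),
               "init_configs or an init_fn")
})

test_that("production runs record the documented number of samples", {
  fx <- generate_fixture("double_well_1d")
  b <- gridded_bias(fx$grid, sigma = 0.15, height = 0.5, delta_T = 8)
  samp <- biased_production_run(b, fx$potential, fx$cv,
                                list(fx$init_fn(-1), fx$init_fn(1)),
                                n_steps = 1030, burn_in = 130, stride = 9,
                                sampler = fx$sampler, seed = 4)
  expect_identical(nrow(samp), 2L * ((1030L - 130L) %/% 9L))
  expect_setequal(unique(samp$replica), 1:2)
  # bias value recorded at the sample's CV point
  expect_equal(samp$bias_value, bias_evaluate(b, matrix(samp$cv, ncol = 1)))
})

test_that("frozen-bias sampling is Boltzmann: KS test against the closed form", {
  # harmonic landscape, zero frozen bias: x ~ N(0, kT/k)
  kspring <- 2
  lsc <- list(dim = 1L, fn = function(s) 0.5 * kspring * s^2,
              grad = function(s) kspring * s, domain = rbind(c(-4, 4)),
              minima = 0, min_value = 0, barrier_height = 0,
              name = "harmonic")
  class(lsc) <- "analytic_landscape"
  pot <- landscape_potential(lsc)
  cv <- cv_coordinate(1, domain = c(-4, 4))
  b <- gridded_bias(grid_spec(-4, 4, 0.02), sigma = 0.15, height = 1,
                    delta_T = 8)
  smp <- sampler_config(dt = 0.005, thermostat_interval = 100)
  # stride chosen >= the position decorrelation time so KS sees ~iid samples
  samp <- biased_production_run(b, pot, cv, list(particle_config(matrix(0, 1, 3))),
                                n_steps = 120000, burn_in = 5000, stride = 250,
                                sampler = smp, seed = 15)
  ks <- stats::ks.test(samp$cv, "pnorm", 0, sqrt(1 / kspring))
  expect_gt(ks$p.value, 0.01)
})

test_that("two replicas from different starts agree (self-consistency)", {
  fx <- generate_fixture("double_well_1d")
  b <- gridded_bias(fx$grid, sigma = 0.15, height = 0.5, delta_T = 8)
  # symmetric well sampled unbiased from the two minima: histograms agree
  samp <- biased_production_run(b, fx$potential, fx$cv,
                                list(fx$init_fn(-1), fx$init_fn(1)),
                                n_steps = 60000, burn_in = 5000, stride = 50,
                                sampler = fx$sampler, seed = 8)
  h <- function(r) {
    x <- abs(samp$cv[samp$replica == r])   # fold: each replica sees one well
    graphics::hist(x, breaks = seq(0, 1.8, 0.1), plot = FALSE)$density
  }
  tv <- 0.5 * sum(abs(h(1) - h(2))) * 0.1
  expect_lt(tv, 0.12)
})

test_that("count_transitions applies hysteresis", {
  s <- c(-1, -0.5, 0.95, 0.2, -0.95, -0.2, 0.91, -1)
  expect_identical(count_transitions(s, -0.9, 0.9), 4L)
  expect_identical(count_transitions(c(-1, 0, -1, 0, -1), -0.9, 0.9), 0L)
  expect_error(count_transitions(s, 1, -1), "lower < upper")
})
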