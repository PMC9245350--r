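# Shared helpers: small random systems and geometry utilities used across
# test files. Everything is generated in code under explicit seeds.

random_config <- function(n, seed, sd = 1, velocities = FALSE) {
  withr::with_seed(seed, {
    particle_config(matrix(stats::rnorm(n * 3L, sd = sd), n, 3L),
                    velocities = if (velocities) {
                      matrix(stats::rnorm(n * 3L), n, 3L)
                    })
  })
}

# a valid random chain configuration near the straight state
perturbed_chain <- function(model, seed, sd = 0.1) {
  cfg <- straight_chain_config(model)
  withr::with_seed(seed, {
    cfg$positions <- cfg$positions +
      matrix(stats::rnorm(model$n_beads * 3L, sd = sd), model$n_beads, 3L)
  })
  cfg
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  outer(a, a) * (1 - c_) + diag(3) * c_ +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s_
}

rotate_config <- function(config, R, shift = c(0, 0, 0)) {
  config$positions <- sweep(config$positions %*% t(R), 2, shift, "+")
  config
}

# a small two-strand duplex-like topology used by validation tests
toy_duplex_topology <- function(n_per_strand = 30L) {
  n <- 2L * n_per_strand
  topology(
    n,
    strands = list(seq_len(n_per_strand), n_per_strand + seq_len(n_per_strand)),
    groups = list(end_a = c(1:3, (n - 2):n),
                  end_b = c((n_per_strand - 2):n_per_strand,
                            n_per_strand + 1:3))
  )
}

expect_tibble_empty <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_identical(nrow(x), 0L)
}
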