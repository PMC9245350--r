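#' Deterministic test systems with known answers
#'
#' Builds one of the benchmark systems used throughout the package, each
#' shipped with its analytic reference so estimators can be checked against
#' a known answer. Everything is generated in code — no downloads, no stored
#' binaries — and is deterministic given `seed`.
#'
#' Kinds:
#' \describe{
#'   \item{`double_well_1d`}{1D quartic double well (default barrier 8
#'     k_B*T) as a point-walker system: landscape, potential, CV, grid and
#'     the sampler/MetaD parameters used by the convergence benchmarks.}
#'   \item{`bistable_2d`}{2D two-minima-plus-saddle landscape in the
#'     diagonal-distance plane of a four-way junction; symmetric
#'     (`tilt = 0`) or tilted; includes state definitions and
#'     quadrature-exact state probabilities.}
#'   \item{`kinkable_chain`}{compressible bead-spring duplex with capped
#'     bending (smooth-bent vs kinked bistability) plus its end-to-end CV
#'     and MetaD parameters.}
#'   \item{`four_group_angle_frame`}{a 14-bead configuration whose
#'     [bend_angle_phi()] equals a prescribed angle exactly (inverse
#'     construction), with the frame definition.}
#'   \item{`spring_frame_table`}{synthetic reweighting frames from a 1D
#'     latent variable with closed-form (quadrature-exact) reweighted
#'     moments; used to validate the WLC-spring reweighting end to end.}
#' }
#'
#' @param kind fixture name (see Details).
#' @param seed integer seed for any sampling the fixture performs.
#' @param ... kind-specific overrides (documented per kind in the source).
#' @return a named list; always contains `kind` and the objects named above.
#' @export
generate_fixture <- function(kind, seed = 20260101, ...) {
  kinds <- c("double_well_1d", "bistable_2d", "kinkable_chain",
             "four_group_angle_frame", "spring_frame_table")
  if (!kind %in% kinds) {
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  switch(kind,
         double_well_1d = fixture_double_well_1d(seed = seed, ...),
         bistable_2d = fixture_bistable_2d(seed = seed, ...),
         kinkable_chain = fixture_kinkable_chain(seed = seed, ...),
         four_group_angle_frame = fixture_angle_frame(seed = seed, ...),
         spring_frame_table = fixture_spring_frames(seed = seed, ...))
}

# Study conditions for the 1D double-well benchmark. The sampler must be in
# a regime where the unbiased walker is trapped (barrier 8 k_BT >> k_BT) yet
# diffuses freely on the tempered landscape; dt and the thermostat interval
# were fixed once from the unbiased/biased crossing-rate requirement and are
# not tuned per run.
fixture_double_well_1d <- function(seed = 20260101, barrier = 8, tilt = 0) {
  landscape <- double_well_1d(barrier = barrier, tilt = tilt)
  list(
    kind = "double_well_1d",
    seed = seed,
    landscape = landscape,
    potential = landscape_potential(landscape),
    cv = cv_coordinate(1L, domain = c(-1.7, 1.7)),
    grid = grid_spec(-1.7, 1.7, 0.02),
    sampler = sampler_config(dt = 0.005, thermostat_interval = 100,
                             refresh_fraction = 1),
    metad = list(n_walkers = 4L, n_cycles = 2000L, tau = 25L,
                 sigma = 0.15, height = 0.5, delta_T = 8),
    init_fn = function(s) particle_config(matrix(c(s[1], 0, 0), 1L, 3L)),
    analytic = function(s) analytic_reference(landscape, s)
  )
}

fixture_bistable_2d <- function(seed = 20260101, barrier = 6, k_conf = 8,
                                tilt = 0) {
  landscape <- bistable_2d(barrier = barrier, k_conf = k_conf, tilt = tilt)
  # exact state probabilities by 2D quadrature of the Boltzmann weight
  boltz <- function(u_sign) {
    fu <- function(u) {
      vapply(u, function(ui) {
        stats::integrate(function(v) {
          exp(-(barrier * (ui^2 - 1)^2 + 0.5 * k_conf * v^2 + tilt * ui))
        }, -4, 4)$value
      }, numeric(1))
    }
    if (u_sign < 0) stats::integrate(fu, -4, 0)$value
    else stats::integrate(fu, 0, 4)$value
  }
  zA <- boltz(-1); zB <- boltz(1)
  states <- list(
    state_definition("A", function(df) (df$cv1 - df$cv2) / sqrt(2) < 0),
    state_definition("B", function(df) (df$cv1 - df$cv2) / sqrt(2) >= 0)
  )
  list(
    kind = "bistable_2d",
    seed = seed,
    landscape = landscape,
    potential = landscape_potential(landscape),
    cv = cv_coordinate(2L, domain = landscape$domain),
    grid = grid_spec(c(-2, -2), c(2, 2), c(0.04, 0.04)),
    sampler = sampler_config(dt = 0.005, thermostat_interval = 100,
                             refresh_fraction = 1),
    metad = list(n_walkers = 4L, n_cycles = 2000L, tau = 25L,
                 sigma = c(0.2, 0.2), height = 0.5, delta_T = 8),
    init_fn = function(s) particle_config(matrix(c(s[1], s[2], 0), 1L, 3L)),
    states = states,
    state_probabilities = c(A = zA / (zA + zB), B = zB / (zA + zB)),
    analytic = function(s) analytic_reference(landscape, s)
  )
}

# The fixture stiffens the generic chain defaults (kappa 40 -> 56,
# e_kink 10 -> 14, same kink threshold angle sqrt(2 e_kink / kappa)): beyond
# the cap the junction potential is flat, so a junction that touches the cap
# lingers there, and the cap must sit high enough that the uncompressed
# chain essentially never reaches it within the study budget (expected
# touches ~ 14 junctions x run time x attempt rate x e^-e_kink << 1). The
# smooth-bend/kink crossover stays near 3/4 compression.
fixture_kinkable_chain <- function(seed = 20260101, n_beads = 16, kappa = 56,
                                   e_kink = 14) {
  model <- kinkable_chain(n_beads = n_beads, kappa = kappa, e_kink = e_kink)
  n <- model$n_beads
  ends <- list(head = 1:3, tail = (n - 2):n)
  topo <- topology(n, strands = list(seq_len(n)),
                   bonds = cbind(seq_len(n - 1), seq_len(n - 1) + 1L),
                   junction_triplets = cbind(seq_len(n - 2), seq_len(n - 2) + 1L,
                                             seq_len(n - 2) + 2L),
                   groups = ends)
  # end-to-end (three-bead end groups) distance; straight chain sits near
  # (n - 3) * b. The smooth-bend/kink bistability lives around 0.55-0.8 of
  # the straight extension; the domain stops at half extension so the bias
  # maps the two-state region instead of chasing ever-deeper crumpled states.
  straight_x <- (n - 3) * model$b
  cv <- cv_com_distance("head", "tail", domain = c(0.5 * straight_x,
                                                   1.05 * straight_x))
  # walls confine the end-to-end distance to the mapped window; outside the
  # grid the bias is flat, so an unconfined walker deposits at the edge
  bare <- kinkable_chain_potential(model)
  confined <- with_cv_wall(bare, cv, lo = 0.52 * straight_x,
                           hi = 1.03 * straight_x, k = 30, topo = topo)
  list(
    kind = "kinkable_chain",
    seed = seed,
    model = model,
    potential = confined,
    potential_unconfined = bare,
    topology = topo,
    cv = cv,
    grid = grid_spec(0.5 * straight_x, 1.05 * straight_x,
                     0.055 * straight_x / 11),
    sampler = sampler_config(dt = 0.005, thermostat_interval = 100,
                             refresh_fraction = 0.5),
    metad = list(n_walkers = 2L, n_cycles = 1600L, tau = 25L,
                 sigma = 0.03 * straight_x, height = 0.5, delta_T = 10),
    init_config = straight_chain_config(model),
    straight_extension = straight_x
  )
}

fixture_angle_frame <- function(seed = 20260101, phi = 250) {
  stopifnot(phi > 0, phi < 360)
  # groups of two beads; arms in the xz-plane, v_ortho along +y.
  # v_top fixed along +z; v_bottom at angle phi180 from v_top, rotated about
  # y so that the triple-product indicator reproduces the requested branch.
  phi180 <- if (phi <= 180) phi else 360 - phi
  th <- phi180 * pi / 180
  sgn <- if (phi > 180) 1 else -1   # indicator > 0 lifts to 360 - phi180
  v_top <- c(0, 0, 1)
  v_bottom <- c(sgn * sin(th), 0, cos(th))
  mk_pair <- function(base, v) {
    near <- rbind(base + c(0, 0.1, 0), base - c(0, 0.1, 0))
    far <- rbind(base + v + c(0, 0.1, 0), base + v - c(0, 0.1, 0))
    list(near = near, far = far)
  }
  top <- mk_pair(c(0, 0, 0.5), v_top)
  bottom <- mk_pair(c(0, 0, -0.5), v_bottom)
  ortho_from <- rbind(c(2, -0.5, 0), c(2.2, -0.5, 0))
  ortho_to <- rbind(c(2, 0.5, 0), c(2.2, 0.5, 0))
  pos <- rbind(top$near, top$far, bottom$near, bottom$far,
               ortho_from, ortho_to)
  frame <- angle_frame(near_top = 1:2, far_top = 3:4,
                       near_bottom = 5:6, far_bottom = 7:8,
                       ortho_from = 9:10, ortho_to = 11:12)
  list(
    kind = "four_group_angle_frame",
    seed = seed,
    config = particle_config(pos),
    frame = frame,
    phi_true = phi
  )
}

# Latent-variable reweighting toy: z ~ density p_b(z) ∝ exp(-U(z) + B(z)),
# phi = phi0 + a*z (degrees), spring extensions L_i(z) = c_i + d_i*z (nm).
# Reweighted moments of phi are 1D integrals computed by quadrature to
# machine precision — the closed-form oracle the sampled table must match.
fixture_spring_frames <- function(seed = 20260101, n = 1e5, n_replicas = 4,
                                  n_short = 6, n_long = 12,
                                  phi0 = 180, a = 30) {
  springs <- wlc_spring_set(n_short, n_long)
  u_fn <- function(z) 0.5 * z^2
  b_fn <- function(z) 1.5 * exp(-(z - 0.5)^2)   # a frozen, smooth "bias"
  # spring extensions: short set stretches with +z, long set with -z; kept
  # strictly inside the contour lengths over the sampled z range
  L_short0 <- 0.55 * springs$springs$L0[1]
  L_long0 <- 0.55 * springs$springs$L0[4]
  dL_s <- 0.08 * springs$springs$L0[1]
  dL_l <- -0.05 * springs$springs$L0[4]
  L_fn <- function(z) {
    cbind(L_short0 + dL_s * z, L_short0 + dL_s * z, L_short0 + dL_s * z,
          L_long0 + dL_l * z, L_long0 + dL_l * z, L_long0 + dL_l * z)
  }
  zlim <- c(-3.5, 3.5)
  dg_springs <- function(z) spring_set_free_energy(L_fn(z), springs)
  # biased sampling density (the bias adds to the potential) and the
  # spring-constrained target density the weights must recover
  dens_b <- function(z) exp(-u_fn(z) - b_fn(z))
  dens_w <- function(z) exp(-u_fn(z) - dg_springs(z))
  quad <- function(f) stats::integrate(function(z) vapply(z, f, numeric(1)),
                                       zlim[1], zlim[2],
                                       rel.tol = 1e-10)$value
  z_w <- quad(function(z) dens_w(z))
  m1 <- quad(function(z) z * dens_w(z)) / z_w
  m2 <- quad(function(z) z^2 * dens_w(z)) / z_w
  mean_phi_true <- phi0 + a * m1
  sd_phi_true <- a * sqrt(m2 - m1^2)
  # inverse-CDF sampling of the biased density on a fine grid
  zg <- seq(zlim[1], zlim[2], length.out = 20001L)
  pg <- dens_b(zg)
  cdf <- cumsum(pg); cdf <- cdf / cdf[length(cdf)]
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed, kind = "Mersenne-Twister")
  u <- stats::runif(n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  z <- stats::approx(cdf, zg, xout = u, ties = "ordered", rule = 2)$y
  Lmat <- L_fn(z)
  colnames(Lmat) <- paste0("L", 1:6)
  frames <- tibble::tibble(
    replica = rep(seq_len(n_replicas), length.out = n),
    z = z,
    phi = phi0 + a * z,
    bias_value = b_fn(z)
  )
  frames <- dplyr::bind_cols(frames, tibble::as_tibble(Lmat))
  list(
    kind = "spring_frame_table",
    seed = seed,
    frames = frames,
    springs = springs,
    mean_phi_true = mean_phi_true,
    sd_phi_true = sd_phi_true,
    latent = list(u_fn = u_fn, b_fn = b_fn, L_fn = L_fn, zlim = zlim,
                  phi0 = phi0, a = a)
  )
}
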