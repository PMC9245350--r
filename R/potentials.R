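#' Potential model contract
#'
#' A potential model is a list with a `name`, an `energy(config)` function
#' returning a scalar in k_B*T, and a `forces(config)` function returning the
#' negative energy gradient as an n-by-3 matrix. All shipped models satisfy
#' the finite-difference consistency check (see
#' [check_forces_finite_difference()]).
#'
#' @param name descriptive name.
#' @param energy function(config) -> scalar.
#' @param forces function(config) -> n x 3 matrix.
#' @param ... extra fields stored on the object.
#' @return an object of class `potential_model`.
#' @export
potential_model <- function(name, energy, forces, ...) {
  structure(list(name = name, energy = energy, forces = forces, ...),
            class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Isotropic harmonic potential (testing workhorse)
#'
#' U = sum_i k/2 |r_i - c_i|^2, in k_B*T.
#'
#' @param k spring constant (k_B*T per length^2).
#' @param centers n x 3 matrix of rest positions.
#' @return a [potential_model()].
#' @export
harmonic_potential <- function(k, centers) {
  centers <- as.matrix(centers)
  potential_model(
    name = "harmonic",
    energy = function(config) {
      d <- config$positions - centers
      0.5 * k * sum(d * d)
    },
    forces = function(config) -k * (config$positions - centers),
    k = k, centers = centers
  )
}

#' Finite-difference force check
#'
#' Verifies that `forces` is the negative gradient of `energy` by central
#' differences on the supplied configuration. Used by the test suite as the
#' contract oracle for every shipped potential.
#'
#' @param potential a [potential_model()].
#' @param config a [particle_config()].
#' @param h finite-difference step.
#' @return maximum relative error over components (scalar).
#' @export
check_forces_finite_difference <- function(potential, config, h = 1e-5) {
  f <- potential$forces(config)
  num <- matrix(0, nrow(config$positions), 3L)
  for (i in seq_len(nrow(config$positions))) {
    for (d in 1:3) {
      cp <- config; cm <- config
      cp$positions[i, d] <- cp$positions[i, d] + h
      cm$positions[i, d] <- cm$positions[i, d] - h
      num[i, d] <- -(potential$energy(cp) - potential$energy(cm)) / (2 * h)
    }
  }
  scale <- max(abs(f), abs(num), 1)
  max(abs(f - num)) / scale
}

# ---- Analytic benchmark landscapes -----------------------------------------

#' One-dimensional quartic double well
#'
#' Free-energy surface Delta G(s) = barrier * (s^2 - 1)^2 (+ tilt * s),
#' minima near s = -1 and s = +1, barrier top at s = 0 with height `barrier`
#' k_B*T for the untilted well. The closed-form minima and barrier are stored
#' on the object and verified against numeric minimisation at construction.
#'
#' @param barrier barrier height in k_B*T.
#' @param tilt linear tilt in k_B*T per unit s (0 for the symmetric well).
#' @param domain length-2 numeric, declared CV domain.
#' @return an object of class `analytic_landscape`.
#' @export
double_well_1d <- function(barrier = 8, tilt = 0, domain = c(-1.7, 1.7)) {
  fn <- function(s) barrier * (s^2 - 1)^2 + tilt * s
  gr <- function(s) 4 * barrier * s * (s^2 - 1) + tilt
  # stationary points: minima of the untilted well at exactly +-1, polished
  # by Newton iteration under tilt (gradient zero to machine precision)
  hess <- function(s) 4 * barrier * (3 * s^2 - 1)
  minima <- vapply(c(-1, 1), function(g) {
    s <- stats::optimize(fn, interval = g + c(-0.5, 0.5), tol = 1e-10)$minimum
    for (k in 1:4) s <- s - gr(s) / hess(s)
    s
  }, numeric(1))
  vals <- fn(minima)
  structure(
    list(dim = 1L, fn = fn, grad = gr, domain = rbind(domain),
         minima = minima, min_value = min(vals),
         barrier_height = fn(0) - min(vals),
         name = sprintf("double_well_1d(barrier=%g, tilt=%g)", barrier, tilt)),
    class = "analytic_landscape"
  )
}

#' Two-dimensional bistable landscape with a saddle
#'
#' A double well along the antidiagonal u = (x1 - x2)/sqrt(2) plus a harmonic
#' confinement along the diagonal v = (x1 + x2)/sqrt(2):
#' Delta G = barrier * (u^2 - 1)^2 + k_conf/2 * (v - v0)^2 + tilt * u.
#' The two minima sit at (v0/sqrt2 -+ 1/sqrt2, v0/sqrt2 +- 1/sqrt2) — one with
#' x1 small / x2 large and one mirrored — separated by a saddle on the
#' diagonal, the geometry of the two coaxially stacked conformers of a
#' four-way junction in its diagonal-distance plane.
#'
#' @param barrier saddle height in k_B*T (untilted).
#' @param k_conf confinement stiffness along the diagonal.
#' @param v0 centre of the diagonal confinement.
#' @param tilt linear tilt along u; 0 gives the mirror-symmetric variant.
#' @param domain 2 x 2 matrix of per-dimension (min, max).
#' @return an object of class `analytic_landscape`.
#' @export
bistable_2d <- function(barrier = 6, k_conf = 8, v0 = 0, tilt = 0,
                        domain = rbind(c(-2, 2), c(-2, 2))) {
  fn <- function(s) {
    u <- (s[1] - s[2]) / sqrt(2)
    v <- (s[1] + s[2]) / sqrt(2)
    barrier * (u^2 - 1)^2 + 0.5 * k_conf * (v - v0)^2 + tilt * u
  }
  gr <- function(s) {
    u <- (s[1] - s[2]) / sqrt(2)
    v <- (s[1] + s[2]) / sqrt(2)
    du <- 4 * barrier * u * (u^2 - 1) + tilt
    dv <- k_conf * (v - v0)
    c(du / sqrt(2) + dv / sqrt(2), -du / sqrt(2) + dv / sqrt(2))
  }
  # untilted minima at u = ±1, v = v0, refined numerically under tilt
  to_xy <- function(u, v) c((v + u) / sqrt(2), (v - u) / sqrt(2))
  minima_xy <- rbind(to_xy(-1, v0), to_xy(1, v0))
  refined <- t(apply(minima_xy, 1, function(p) {
    stats::optim(p, fn, gr, method = "BFGS")$par
  }))
  vals <- apply(refined, 1, fn)
  structure(
    list(dim = 2L, fn = fn, grad = gr, domain = domain,
         minima = refined, min_value = min(vals),
         saddle = to_xy(0, v0),
         barrier_height = fn(to_xy(0, v0)) - min(vals),
         name = sprintf("bistable_2d(barrier=%g, tilt=%g)", barrier, tilt)),
    class = "analytic_landscape"
  )
}

#' @export
print.analytic_landscape <- function(x, ...) {
  cat("<analytic_landscape> ", x$name, " (", x$dim, "D)\n", sep = "")
  invisible(x)
}

#' Closed-form reference free energy of an analytic landscape
#'
#' Evaluates the landscape's free-energy surface at CV point(s) `s`,
#' min-shifted so the global minimum is exactly 0 k_B*T.
#'
#' @param landscape an `analytic_landscape`.
#' @param s numeric vector (1D: any length; 2D: length 2) or a matrix with
#'   one row per point.
#' @return numeric vector of Delta G values in k_B*T.
#' @export
analytic_reference <- function(landscape, s) {
  pts <- if (is.matrix(s)) s else if (landscape$dim == 1L) {
    matrix(s, ncol = 1L)
  } else {
    matrix(s, ncol = landscape$dim, byrow = TRUE)
  }
  lo <- landscape$domain[, 1]; hi <- landscape$domain[, 2]
  for (d in seq_len(landscape$dim)) {
    if (any(pts[, d] < lo[d] - 1e-12 | pts[, d] > hi[d] + 1e-12)) {
      stop("CV point outside the declared landscape domain", call. = FALSE)
    }
  }
  apply(pts, 1, landscape$fn) - landscape$min_value
}

#' Treat an analytic landscape as the potential of a point walker
#'
#' Maps a landscape Delta G(s) onto a single-particle potential whose first
#' `dim` coordinates are the collective variables; the remaining coordinates
#' are harmonically restrained to 0 so the walker stays on the CV manifold.
#'
#' @param landscape an `analytic_landscape`.
#' @param k_rest restraint stiffness on unused coordinates.
#' @return a [potential_model()].
#' @export
landscape_potential <- function(landscape, k_rest = 50) {
  d <- landscape$dim
  potential_model(
    name = paste0("landscape:", landscape$name),
    energy = function(config) {
      p <- config$positions[1, ]
      e <- landscape$fn(p[seq_len(d)])
      if (d < 3) e <- e + 0.5 * k_rest * sum(p[(d + 1):3]^2)
      e
    },
    forces = function(config) {
      p <- config$positions[1, ]
      f <- numeric(3)
      f[seq_len(d)] <- -landscape$grad(p[seq_len(d)])
      if (d < 3) f[(d + 1):3] <- -k_rest * p[(d + 1):3]
      matrix(f, 1L, 3L)
    },
    landscape = landscape
  )
}

# ---- Kinkable bead-spring chain --------------------------------------------

#' Kinkable bead-spring chain model
#'
#' A discrete worm-like chain whose bending energy at each interior junction
#' is capped: junction i contributes min(kappa/2 * theta_i^2, e_kink), where
#' theta_i is the angle between successive bond vectors. The cap models a
#' local break in coaxial stacking — beyond a critical bend the junction
#' "kinks" at constant energy cost instead of resisting further curvature,
#' which is what makes a compressed duplex buckle at a point rather than
#' bend smoothly. The per-junction stacking energy is defined as
#' min(kappa/2 theta^2, e_kink) - e_kink <= 0, reaching 0 exactly when the
#' junction is fully kinked. Terminal beads carry no bending term.
#'
#' Defaults give a chain whose compression-induced buckling barrier is of
#' order 10 k_B*T, producing a two-state (smooth-bent vs kinked) structure.
#'
#' @param n_beads number of beads.
#' @param b bond rest length (reduced units).
#' @param k_bond bond stiffness, k_B*T per length^2.
#' @param kappa bending stiffness, k_B*T per rad^2.
#' @param e_kink kink cap, k_B*T; `Inf` recovers the pure discrete WLC.
#' @return an object of class `kinkable_chain`.
#' @export
kinkable_chain <- function(n_beads = 16, b = 1, k_bond = 100,
                           kappa = 40, e_kink = 10) {
  stopifnot(n_beads >= 3, b > 0, k_bond > 0, kappa > 0, e_kink > 0)
  structure(
    list(n_beads = as.integer(n_beads), b = b, k_bond = k_bond,
         kappa = kappa, e_kink = e_kink),
    class = "kinkable_chain"
  )
}

#' @export
print.kinkable_chain <- function(x, ...) {
  cat(sprintf("<kinkable_chain> %d beads, b=%g, k_bond=%g, kappa=%g, e_kink=%g\n",
              x$n_beads, x$b, x$k_bond, x$kappa, x$e_kink))
  invisible(x)
}

# bend angles at interior beads; returns list(theta, cos_theta, u = bond vecs)
chain_geometry <- function(positions, model) {
  u <- diff(positions)                      # bond vectors, (n-1) x 3
  len <- sqrt(rowSums(u * u))
  nb <- nrow(u)
  dot <- rowSums(u[-nb, , drop = FALSE] * u[-1, , drop = FALSE])
  ct <- pmin(1, pmax(-1, dot / (len[-nb] * len[-1])))
  list(u = u, len = len, cos_theta = ct, theta = acos(ct))
}

#' Energy and forces of the kinkable chain
#'
#' Bond terms k_bond/2 (|u_i| - b)^2 plus capped bending terms
#' min(kappa/2 theta_i^2, e_kink). The energy is continuous in theta; at a
#' saturated junction the bending force vanishes (the cap is flat). Forces
#' are returned analytically and validated against central differences in
#' the test suite.
#'
#' @param config a [particle_config()] with `n_beads` rows.
#' @param model a [kinkable_chain()].
#' @return list with `energy` (scalar, k_B*T) and `forces` (n x 3 matrix).
#' @export
kinkable_chain_energy_forces <- function(config, model) {
  x <- config$positions
  if (nrow(x) != model$n_beads) {
    stop("configuration has ", nrow(x), " beads; model declares ",
         model$n_beads, call. = FALSE)
  }
  n <- nrow(x)
  nb <- n - 1L
  u <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
  len <- sqrt(.rowSums(u * u, nb, 3L))
  nj <- nb - 1L
  dot <- .rowSums(u[-nb, , drop = FALSE] * u[-1, , drop = FALSE], nj, 3L)
  ct <- pmin(1, pmax(-1, dot / (len[-nb] * len[-1])))
  theta <- acos(ct)
  # bonds
  stretch <- len - model$b
  e_bond <- 0.5 * model$k_bond * sum(stretch^2)
  f <- matrix(0, n, 3L)
  fb <- (model$k_bond * stretch / len) * u   # dE/d(head) per bond
  f[seq_len(nb), ] <- fb
  f[seq_len(nb) + 1L, ] <- f[seq_len(nb) + 1L, ] - fb
  # capped bending at interior beads 2..n-1 (junction j uses bonds j, j+1)
  e_bend_raw <- 0.5 * model$kappa * theta^2
  capped <- e_bend_raw >= model$e_kink
  e_bend <- sum(pmin(e_bend_raw, model$e_kink))
  # dE/dtheta = kappa*theta (0 when capped or at theta -> 0), chained through
  # dtheta/dx for all junctions at once
  s <- sin(theta)
  active <- !capped & theta > 1e-8
  if (any(active)) {
    coef <- numeric(nj)
    coef[active] <- -model$kappa * theta[active] / s[active]   # dE/dcos
    a <- u[seq_len(nj), , drop = FALSE]
    bm <- u[seq_len(nj) + 1L, , drop = FALSE]
    la <- len[seq_len(nj)]; lb <- len[seq_len(nj) + 1L]
    dcos_da <- bm / (la * lb) - (ct / la^2) * a
    dcos_db <- a / (la * lb) - (ct / lb^2) * bm
    dEda <- coef * dcos_da
    dEdb <- coef * dcos_db
    j <- seq_len(nj)
    f[j, ] <- f[j, ] + dEda
    f[j + 1L, ] <- f[j + 1L, ] - dEda + dEdb
    f[j + 2L, ] <- f[j + 2L, ] - dEdb
  }
  list(energy = e_bond + e_bend, forces = f)
}

#' Kinkable chain as a potential model
#'
#' @param model a [kinkable_chain()].
#' @return a [potential_model()].
#' @export
kinkable_chain_potential <- function(model) {
  potential_model(
    name = sprintf("kinkable_chain(n=%d)", model$n_beads),
    energy = function(config) kinkable_chain_energy_forces(config, model)$energy,
    forces = function(config) kinkable_chain_energy_forces(config, model)$forces,
    model = model
  )
}

#' Per-junction stacking energies of a chain configuration
#'
#' min(kappa/2 theta^2, e_kink) - e_kink for each interior junction; always
#' <= 0, equal to 0 exactly when the junction is fully kinked.
#'
#' @param config a [particle_config()].
#' @param model a [kinkable_chain()].
#' @return numeric vector, one value per interior junction.
#' @export
junction_stacking_energies <- function(config, model) {
  if (nrow(config$positions) != model$n_beads) {
    stop("configuration has ", nrow(config$positions), " beads; model declares ",
         model$n_beads, call. = FALSE)
  }
  geo <- chain_geometry(config$positions, model)
  pmin(0.5 * model$kappa * geo$theta^2, model$e_kink) - model$e_kink
}

#' k-th weakest stacking interaction
#'
#' Returns the k-th least-negative per-junction stacking energy — the order
#' parameter that distinguishes a smoothly bent chain from a kinked one. It
#' equals 0 if and only if at least k junctions are fully kinked; for a DNA
#' duplex the analogous quantity (fourth weakest stack over nonterminal
#' nucleotides) rises to 0 only when the duplex is buckled.
#'
#' @param config a [particle_config()].
#' @param model a [kinkable_chain()].
#' @param k rank (1 = weakest, i.e. least negative).
#' @return scalar stacking energy in k_B*T (<= 0).
#' @export
kth_weakest_stack <- function(config, model, k) {
  e <- junction_stacking_energies(config, model)
  k <- as.integer(k)
  if (k < 1L || k > length(e)) {
    stop("k must be between 1 and the number of interior junctions (",
         length(e), ")", call. = FALSE)
  }
  sort(e, decreasing = TRUE)[k]
}

#' Straight reference configuration of a chain
#'
#' Beads along the x-axis at the bond rest length; the model's ground state
#' (zero energy, zero forces).
#'
#' @param model a [kinkable_chain()].
#' @param velocities logical; draw zero velocities if TRUE.
#' @return a [particle_config()].
#' @export
straight_chain_config <- function(model, velocities = FALSE) {
  pos <- cbind((seq_len(model$n_beads) - 1) * model$b, 0, 0)
  particle_config(pos,
                  velocities = if (velocities) matrix(0, model$n_beads, 3L))
}

#' Add harmonic restraining walls on a collective variable
#'
#' Wraps a potential with half-harmonic walls k/2 (s - lo)^2 below `lo` and
#' k/2 (s - hi)^2 above `hi` on a 1D CV. Walls keep walkers inside the
#' gridded bias window: outside the grid the bias exerts no force, so an
#' unconfined walker can wander off the mapped region and deposit all its
#' Gaussians at the clamped edge. Standard practice when the CV range of
#' interest is a sub-window of what the system can reach.
#'
#' @param base a [potential_model()].
#' @param cv a 1D [collective_variable()] with an analytic gradient.
#' @param lo,hi wall positions (CV units).
#' @param k wall stiffness, k_B*T per CV unit^2.
#' @param topo optional topology forwarded to the CV.
#' @return a [potential_model()].
#' @export
with_cv_wall <- function(base, cv, lo, hi, k = 20, topo = NULL) {
  stopifnot(cv$dim == 1L, !is.null(cv$gradient), lo < hi)
  excess <- function(s) if (s < lo) s - lo else if (s > hi) s - hi else 0
  potential_model(
    name = paste0(base$name, " + cv_wall[", signif(lo, 4), ",",
                  signif(hi, 4), "]"),
    energy = function(config) {
      e <- excess(cv$value(config, topo))
      base$energy(config) + 0.5 * k * e^2
    },
    forces = function(config) {
      f <- base$forces(config)
      e <- excess(cv$value(config, topo))
      if (e != 0) f <- f - (k * e) * cv$gradient(config, topo)[[1]]
      f
    },
    base = base, wall = list(lo = lo, hi = hi, k = k)
  )
}

# ---- Worm-like-chain entropic spring ---------------------------------------

#' Worm-like-chain stretching free energy of an ssDNA segment
#'
#' Free-energy cost (k_B*T) of holding a worm-like chain of contour length
#' L0 = n_nts * 0.676 nm at end-to-end extension L, using the integrated
#' Marko-Siggia interpolation
#' Delta G(L) = (L0/Lp) * (L^2/(2 L0^2) + 1/(4(1 - L/L0)) - L/(4 L0) - 1/4),
#' normalised so Delta G(0) = 0. The persistence length default is the ssDNA
#' value of 2 nm and the per-nucleotide contour 0.676 nm/nt. Note `n_nts` is
#' the spring's nucleotide parameter, which is 1 greater than the number of
#' nucleotides in the physical chain (zero inserted nucleotides still leave
#' one nucleotide of separation between the attachment points); use
#' [wlc_spring_set()] to apply that convention automatically.
#'
#' @param L extension in nm (0 <= L < L0); vectorised.
#' @param n_nts nucleotide parameter of the spring (integer >= 1).
#' @param Lp persistence length in nm.
#' @param contour_per_nt contour length per nucleotide, nm/nt.
#' @return Delta G in k_B*T; same length as `L`.
#' @export
wlc_free_energy <- function(L, n_nts, Lp = 2, contour_per_nt = 0.676) {
  L0 <- n_nts * contour_per_nt
  if (L0 <= 0) stop("contour length must be positive", call. = FALSE)
  if (any(L < 0)) stop("extension must be non-negative", call. = FALSE)
  if (any(L >= L0)) {
    stop("extension exceeds contour length (L >= L0 = ", signif(L0, 6), " nm)",
         call. = FALSE)
  }
  x <- L / L0
  (L0 / Lp) * (x^2 / 2 + 1 / (4 * (1 - x)) - x / 4 - 1 / 4)
}

#' Six-spring worm-like-chain description of a compliant joint
#'
#' The experimental compliant joint is bent by two sets of three ssDNA
#' springs bridging a short and a long gap. Each spring is characterised by
#' its physical nucleotide count; the stored WLC parameter `n_nts` is one
#' greater (see [wlc_free_energy()]).
#'
#' @param n_short physical nucleotide count of each short-gap spring.
#' @param n_long physical nucleotide count of each long-gap spring.
#' @param n_each number of springs per set (3 for the joint).
#' @param Lp persistence length in nm.
#' @param contour_per_nt contour length per nucleotide, nm/nt.
#' @return an object of class `wlc_spring_set`; tibble-like `springs` field
#'   with one row per spring (`spring`, `set`, `n_nts`, `L0`).
#' @export
wlc_spring_set <- function(n_short, n_long, n_each = 3, Lp = 2,
                           contour_per_nt = 0.676) {
  stopifnot(n_short >= 0, n_long >= 0, n_each >= 1)
  n_nts <- c(rep(n_short + 1L, n_each), rep(n_long + 1L, n_each))
  springs <- tibble::tibble(
    spring = seq_along(n_nts),
    set = rep(c("short", "long"), each = n_each),
    n_nts = as.integer(n_nts),
    L0 = n_nts * contour_per_nt
  )
  structure(list(springs = springs, Lp = Lp,
                 contour_per_nt = contour_per_nt),
            class = "wlc_spring_set")
}

#' @export
print.wlc_spring_set <- function(x, ...) {
  cat("<wlc_spring_set> Lp =", x$Lp, "nm,", x$contour_per_nt, "nm/nt\n")
  print(x$springs)
  invisible(x)
}

#' Total spring free energy of a frame
#'
#' Sum of the per-spring WLC free energies at the measured attachment
#' separations. Returns `Inf` when any spring is at or beyond its contour
#' length (the WLC's own divergent limit).
#'
#' @param L numeric vector of separations (nm), one per spring, or a matrix
#'   with one row per frame.
#' @param springs a [wlc_spring_set()].
#' @return total Delta G in k_B*T (vector over frames).
#' @export
spring_set_free_energy <- function(L, springs) {
  Lm <- if (is.matrix(L)) L else matrix(L, nrow = 1L)
  if (ncol(Lm) != nrow(springs$springs)) {
    stop("expected one separation per spring (", nrow(springs$springs), ")",
         call. = FALSE)
  }
  out <- numeric(nrow(Lm))
  for (j in seq_len(ncol(Lm))) {
    L0 <- springs$springs$L0[j]
    ok <- Lm[, j] < L0 & Lm[, j] >= 0
    out[!ok] <- Inf
    out[ok] <- out[ok] + wlc_free_energy(Lm[ok, j], springs$springs$n_nts[j],
                                         Lp = springs$Lp,
                                         contour_per_nt = springs$contour_per_nt)
  }
  if (is.matrix(L)) out else out[1]
}
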