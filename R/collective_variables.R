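#' Collective variable contract
#'
#' A collective variable (CV) maps a particle configuration to 1 or 2
#' scalars onto which the free energy is projected and the metadynamics bias
#' applied. Shipped CVs are invariant under global translation and rotation
#' (the signed bending angle is rotation-invariant but reflection-sensitive,
#' by construction). A CV carries:
#' \itemize{
#'   \item `dim`: 1 or 2;
#'   \item `value(config, topology)`: the CV point;
#'   \item `gradient(config, topology)`: optional analytic gradient — a list
#'     of n-by-3 matrices, one per CV component. When absent, bias forces
#'     fall back to finite differences of the CV (or are refused if the
#'     fallback is disabled);
#'   \item `domain`: dim-by-2 matrix of declared (min, max) per component.
#'     Excursions outside the domain are clamped for bias lookup and logged.
#' }
#'
#' @param dim dimensionality (1 or 2).
#' @param value function(config, topology) -> numeric of length `dim`.
#' @param domain dim x 2 matrix of bounds.
#' @param gradient optional function(config, topology) -> list of matrices.
#' @param name descriptive name.
#' @param ... extra fields.
#' @return an object of class `collective_variable`.
#' @export
collective_variable <- function(dim, value, domain, gradient = NULL,
                                name = "cv", ...) {
  dim <- as.integer(dim)
  stopifnot(dim %in% c(1L, 2L))
  domain <- matrix(as.numeric(domain), nrow = dim)
  if (any(domain[, 2] <= domain[, 1])) {
    stop("CV domain must have max > min in every component", call. = FALSE)
  }
  structure(list(dim = dim, value = value, gradient = gradient,
                 domain = domain, name = name, ...),
            class = "collective_variable")
}

#' @export
print.collective_variable <- function(x, ...) {
  cat("<collective_variable> ", x$name, " (", x$dim, "D, ",
      if (is.null(x$gradient)) "numeric gradient" else "analytic gradient",
      ")\n", sep = "")
  invisible(x)
}

# resolve a group reference (name or index vector) against a topology
resolve_group_ref <- function(g, topo) {
  if (is.character(g)) {
    if (is.null(topo) || is.null(topo$groups[[g]])) {
      stop("group '", g, "' not found in topology", call. = FALSE)
    }
    topo$groups[[g]]
  } else as.integer(g)
}

# gradient of a group-centroid distance wrt positions; returns n x 3 matrix
com_distance_gradient <- function(config, group_a, group_b) {
  ca <- center_of_mass(config, group_a, "group_a")
  cb <- center_of_mass(config, group_b, "group_b")
  d <- ca - cb
  r <- sqrt(sum(d * d))
  g <- matrix(0, n_particles(config), 3L)
  if (r < 1e-12) {
    warning("coincident group centroids: distance gradient reported as zero",
            call. = FALSE)
    return(g)
  }
  unit <- d / r
  g[group_a, ] <- g[group_a, ] + rep(unit / length(group_a), each = length(group_a))
  g[group_b, ] <- g[group_b, ] - rep(unit / length(group_b), each = length(group_b))
  g
}

#' Centre-of-mass distance between two bead groups
#'
#' The workhorse CV for duplex buckling: the distance between virtual
#' particles at the centres of mass of the bead groups at either end of a
#' duplex. Biasing a many-bead group distance induces bending rather than
#' tearing individual base pairs. Overlapping groups are permitted (with a
#' design warning from [check_cv_design()]); the gradient is well defined
#' unless the centroids coincide, in which case it is reported as zero with
#' a warning.
#'
#' @param group_a,group_b group names (resolved in the topology) or integer
#'   index vectors.
#' @param domain length-2 numeric (min, max) of the declared CV domain.
#' @return a 1D [collective_variable()].
#' @export
cv_com_distance <- function(group_a, group_b, domain) {
  resolve <- function(g, topo, what) {
    if (is.character(g)) {
      if (is.null(topo) || is.null(topo$groups[[g]])) {
        stop("group '", g, "' not found in topology (", what, ")", call. = FALSE)
      }
      topo$groups[[g]]
    } else as.integer(g)
  }
  collective_variable(
    dim = 1L,
    value = function(config, topo = NULL) {
      a <- resolve(group_a, topo, "group_a"); b <- resolve(group_b, topo, "group_b")
      ca <- center_of_mass(config, a, "group_a")
      cb <- center_of_mass(config, b, "group_b")
      sqrt(sum((ca - cb)^2))
    },
    gradient = function(config, topo = NULL) {
      a <- resolve(group_a, topo, "group_a"); b <- resolve(group_b, topo, "group_b")
      list(com_distance_gradient(config, a, b))
    },
    domain = domain,
    name = "com_distance",
    groups = list(group_a = group_a, group_b = group_b)
  )
}

#' The two diagonal distances across a four-way junction
#'
#' 2D CV (x1, x2): distances between the centroids of the two group pairs
#' spanning the junction diagonals, in declaration order. The two stacked
#' isomers sit at (small, large) and (large, small); the open intermediate
#' has both distances large, so the transition state is cleanly separated
#' from both minima in the (x1, x2) plane.
#'
#' @param pair_1,pair_2 each a list of two groups (names or index vectors).
#' @param domain 2 x 2 matrix of bounds (rows: components).
#' @return a 2D [collective_variable()].
#' @export
cv_diagonal_distances <- function(pair_1, pair_2, domain) {
  d1 <- cv_com_distance(pair_1[[1]], pair_1[[2]],
                        domain = domain[1, ])
  d2 <- cv_com_distance(pair_2[[1]], pair_2[[2]],
                        domain = domain[2, ])
  collective_variable(
    dim = 2L,
    value = function(config, topo = NULL) {
      c(d1$value(config, topo), d2$value(config, topo))
    },
    gradient = function(config, topo = NULL) {
      c(d1$gradient(config, topo), d2$gradient(config, topo))
    },
    domain = domain,
    name = "diagonal_distances",
    components = list(d1, d2)
  )
}

#' Sum of the two diagonal distances (1D junction CV)
#'
#' x1 + x2 with a closed-form gradient (sum of the two distance gradients);
#' the 1D order parameter used when a single-coordinate bias suffices to
#' drive isomerisation.
#'
#' @inheritParams cv_diagonal_distances
#' @param domain length-2 numeric bounds for the sum.
#' @return a 1D [collective_variable()].
#' @export
cv_sum_distance <- function(pair_1, pair_2, domain) {
  d1 <- cv_com_distance(pair_1[[1]], pair_1[[2]], domain = c(0, 1e6))
  d2 <- cv_com_distance(pair_2[[1]], pair_2[[2]], domain = c(0, 1e6))
  collective_variable(
    dim = 1L,
    value = function(config, topo = NULL) {
      d1$value(config, topo) + d2$value(config, topo)
    },
    gradient = function(config, topo = NULL) {
      list(d1$gradient(config, topo)[[1]] + d2$gradient(config, topo)[[1]])
    },
    domain = domain,
    name = "sum_distance"
  )
}

#' Coordinate projection CV for point-walker systems
#'
#' Exposes the first `dim` Cartesian coordinates of particle 1 as the CV —
#' the natural CV when the "system" is a walker moving directly on an
#' analytic landscape. Not translation-invariant, by design.
#'
#' @param dim 1 or 2.
#' @param domain dim x 2 bounds.
#' @return a [collective_variable()].
#' @export
cv_coordinate <- function(dim, domain) {
  dim <- as.integer(dim)
  collective_variable(
    dim = dim,
    value = function(config, topo = NULL) config$positions[1, seq_len(dim)],
    gradient = function(config, topo = NULL) {
      lapply(seq_len(dim), function(d) {
        g <- matrix(0, n_particles(config), 3L)
        g[1, d] <- 1
        g
      })
    },
    domain = domain,
    name = "coordinate"
  )
}

# ---- Signed bending angle ---------------------------------------------------

#' Reference frame for the signed bending angle
#'
#' Four reference groups (near/far on the top and bottom arms of the bent
#' element) define the arm direction vectors; a fifth/sixth group pair
#' defines the orthogonal reference used to lift the angle from (0, 180) to
#' (0, 360) degrees. All six groups must be pairwise disjoint.
#'
#' @param near_top,far_top,near_bottom,far_bottom integer index vectors.
#' @param ortho_from,ortho_to index vectors; v_ortho runs from the centroid
#'   of `ortho_from` to the centroid of `ortho_to`.
#' @return an object of class `angle_frame`.
#' @export
angle_frame <- function(near_top, far_top, near_bottom, far_bottom,
                        ortho_from, ortho_to) {
  groups <- list(near_top = as.integer(near_top), far_top = as.integer(far_top),
                 near_bottom = as.integer(near_bottom),
                 far_bottom = as.integer(far_bottom),
                 ortho_from = as.integer(ortho_from),
                 ortho_to = as.integer(ortho_to))
  all_idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_idx)) {
    stop("angle_frame groups must be pairwise disjoint", call. = FALSE)
  }
  structure(groups, class = "angle_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed bending angle phi on (0, 360) degrees
#'
#' Computes the arm vectors v_top = com(far_top) - com(near_top) and
#' v_bottom = com(far_bottom) - com(near_bottom); their unsigned angle
#' phi^(0,180) = acos of the normalised dot product; and lifts it to
#' (0, 360) using the orthogonal reference: with
#' indicator = (v_top x v_bottom) . v_ortho_hat, phi = phi^(0,180) when the
#' indicator is negative (phi < 180 side) and 360 - phi^(0,180) otherwise.
#' The handedness of this convention is arbitrary but self-consistent:
#' mirror-reflecting a configuration maps phi to 360 - phi.
#'
#' @param config a [particle_config()].
#' @param frame an [angle_frame()].
#' @return angle in degrees, in (0, 360).
#' @export
bend_angle_phi <- function(config, frame) {
  com <- function(g, nm) center_of_mass(config, frame[[g]], nm)
  v_top <- com("far_top", "far_top") - com("near_top", "near_top")
  v_bottom <- com("far_bottom", "far_bottom") - com("near_bottom", "near_bottom")
  v_ortho <- com("ortho_to", "ortho_to") - com("ortho_from", "ortho_from")
  lt <- sqrt(sum(v_top^2)); lb <- sqrt(sum(v_bottom^2))
  lo <- sqrt(sum(v_ortho^2))
  if (lt < 1e-12 || lb < 1e-12 || lo < 1e-12) {
    stop("degenerate geometry: zero-length direction vector in angle frame",
         call. = FALSE)
  }
  ct <- sum(v_top * v_bottom) / (lt * lb)
  phi180 <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  indicator <- sum(cross3(v_top, v_bottom) * (v_ortho / lo))
  if (indicator > 0) 360 - phi180 else phi180
}

#' Bending angle as a (analysis) collective variable
#'
#' @param frame an [angle_frame()].
#' @param domain length-2 numeric bounds in degrees.
#' @return a 1D [collective_variable()] without analytic gradient.
#' @export
cv_bend_angle <- function(frame, domain = c(0, 360)) {
  collective_variable(
    dim = 1L,
    value = function(config, topo = NULL) bend_angle_phi(config, frame),
    gradient = NULL,
    domain = domain,
    name = "bend_angle_phi",
    frame = frame
  )
}

#' Stacking order parameter as an analysis CV
#'
#' Thin wrapper over [kth_weakest_stack()] for use on the second axis of
#' kinked-vs-bent landscapes; not intended for biasing.
#'
#' @param model a [kinkable_chain()].
#' @param k rank of the weakest stack.
#' @param domain bounds in k_B*T.
#' @return a 1D [collective_variable()] without analytic gradient.
#' @export
cv_stack <- function(model, k = 1L, domain = c(-model$e_kink, 0)) {
  collective_variable(
    dim = 1L,
    value = function(config, topo = NULL) kth_weakest_stack(config, model, k),
    gradient = NULL,
    domain = domain,
    name = sprintf("stack_cv(k=%d)", k),
    model = model, k = as.integer(k)
  )
}

#' Heuristic design checks for a collective variable
#'
#' Advisory warnings encoding the design criteria for MetaD CVs: the CV must
#' couple to the deformation mode of interest, not to bond rupture. A
#' distance CV between two single beads concentrates the bias force on one
#' interaction and invites rupture/disassembly; a 2D CV whose components
#' share beads produces degenerate bias forces. Warnings never block a run.
#'
#' @param cv a [collective_variable()].
#' @param topo optional [topology()] used to resolve group names.
#' @return tibble with columns `warning`, `detail`; zero rows when clean.
#' @export
check_cv_design <- function(cv, topo = NULL) {
  out <- list()
  add <- function(warning, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(warning = warning, detail = detail)
  }
  resolve <- function(g) {
    if (is.character(g)) {
      if (!is.null(topo) && !is.null(topo$groups[[g]])) topo$groups[[g]] else NULL
    } else as.integer(g)
  }
  check_pair <- function(groups, label) {
    a <- resolve(groups$group_a); b <- resolve(groups$group_b)
    if (!is.null(a) && !is.null(b)) {
      if (length(a) == 1L && length(b) == 1L) {
        add("single_bead_distance",
            paste0(label, ": distance between two single beads concentrates ",
                   "bias force on one interaction; bias buildup can rupture ",
                   "it instead of deforming the structure — use multi-bead ",
                   "groups spanning several strands"))
      }
      if (length(intersect(a, b)) > 0L) {
        add("overlapping_groups",
            paste0(label, ": the two groups overlap; the distance gradient ",
                   "is still defined but degenerate when centroids coincide"))
      }
    }
  }
  if (identical(cv$name, "com_distance")) check_pair(cv$groups, "com_distance")
  if (identical(cv$name, "diagonal_distances")) {
    comps <- cv$components
    check_pair(comps[[1]]$groups, "component 1")
    check_pair(comps[[2]]$groups, "component 2")
    g1 <- c(resolve(comps[[1]]$groups$group_a), resolve(comps[[1]]$groups$group_b))
    g2 <- c(resolve(comps[[2]]$groups$group_a), resolve(comps[[2]]$groups$group_b))
    if (!is.null(g1) && !is.null(g2) && length(intersect(g1, g2)) > 0L) {
      add("shared_group_across_components",
          "the two CV components share beads; bias forces along the two axes are coupled")
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(warning = character(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Numeric CV gradient by central differences
#'
#' Fallback used by [bias_force()] for CVs without analytic gradients; also
#' the oracle against which analytic CV gradients are validated.
#'
#' @param cv a [collective_variable()].
#' @param config a [particle_config()].
#' @param topo optional topology.
#' @param h step size.
#' @return list of n x 3 matrices, one per CV component.
#' @export
cv_gradient_fd <- function(cv, config, topo = NULL, h = 1e-6) {
  n <- n_particles(config)
  grads <- lapply(seq_len(cv$dim), function(d) matrix(0, n, 3L))
  for (i in seq_len(n)) {
    for (d in 1:3) {
      cp <- config; cm <- config
      cp$positions[i, d] <- cp$positions[i, d] + h
      cm$positions[i, d] <- cm$positions[i, d] - h
      vp <- cv$value(cp, topo); vm <- cv$value(cm, topo)
      for (k in seq_len(cv$dim)) grads[[k]][i, d] <- (vp[k] - vm[k]) / (2 * h)
    }
  }
  grads
}
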