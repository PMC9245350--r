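#' Particle configuration
#'
#' Container for the Cartesian state of a coarse-grained system: one
#' position (and optionally one velocity) 3-vector per particle, plus the
#' number of MD/MC steps elapsed. Velocities are absent for Monte Carlo
#' sampling. Lengths are in nm for real structures and reduced units for the
#' toy systems; energies throughout the package are in units of k_B*T, so
#' beta = 1 internally.
#'
#' @param positions numeric matrix, one row per particle, three columns.
#' @param velocities optional numeric matrix of the same shape.
#' @param step_count integer, MD/MC steps elapsed.
#' @return an object of class `particle_config`.
#' @export
particle_config <- function(positions, velocities = NULL, step_count = 0L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) {
    stop("positions must have three columns (x, y, z)", call. = FALSE)
  }
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions))) {
    stop("positions must be finite", call. = FALSE)
  }
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    storage.mode(velocities) <- "double"
    if (!identical(dim(velocities), dim(positions))) {
      stop("velocities must have the same shape as positions", call. = FALSE)
    }
  }
  structure(
    list(positions = positions, velocities = velocities,
         step_count = as.integer(step_count)),
    class = "particle_config"
  )
}

#' @export
print.particle_config <- function(x, ...) {
  cat("<particle_config> ", nrow(x$positions), " particles, ",
      if (is.null(x$velocities)) "no velocities" else "with velocities",
      ", step ", x$step_count, "\n", sep = "")
  invisible(x)
}

n_particles <- function(config) nrow(config$positions)

#' Topology of a bead system
#'
#' Declares how many particles the system has, how they are organised into
#' strands (listed 3'->5'), which pairs are bonded, which consecutive
#' triplets carry stacking/bending terms, and any named bead groups used to
#' define collective variables (e.g. the six nucleotides at each duplex end).
#' Particle indices are 1-based, the native R convention; file readers
#' convert from the 0-based oxDNA convention at the I/O boundary.
#'
#' @param n_particles integer particle count.
#' @param strands list of integer vectors partitioning `1:n_particles`.
#' @param bonds two-column integer matrix of bonded pairs (may be NULL).
#' @param junction_triplets three-column integer matrix of consecutive
#'   triplets carrying bending terms (may be NULL).
#' @param groups named list of integer vectors; bead groups for CVs.
#' @param base_annotations optional character vector of base letters.
#' @return an object of class `topology`.
#' @export
topology <- function(n_particles, strands = list(seq_len(n_particles)),
                     bonds = NULL, junction_triplets = NULL,
                     groups = list(), base_annotations = NULL) {
  structure(
    list(n_particles = as.integer(n_particles),
         strands = lapply(strands, as.integer),
         bonds = bonds, junction_triplets = junction_triplets,
         groups = lapply(groups, as.integer),
         base_annotations = base_annotations),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n_particles, " particles, ", length(x$strands),
      " strand(s), ", length(x$groups), " named group(s)\n", sep = "")
  invisible(x)
}

#' Validate a topology against its declared particle count
#'
#' Checks every structural invariant and reports each violation as one row of
#' a findings tibble rather than throwing: indices in range, groups non-empty
#' and duplicate-free, strands partitioning the particle set. An empty tibble
#' means the topology is consistent. The input is never modified.
#'
#' @param topo a [topology()].
#' @param n_particles_declared particle count to validate against; defaults
#'   to the topology's own field.
#' @return tibble with columns `check`, `detail`; zero rows when valid.
#' @export
validate_topology <- function(topo, n_particles_declared = topo$n_particles) {
  n <- as.integer(n_particles_declared)
  findings <- list()
  add <- function(check, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(check = check,
                                                         detail = detail)
  }
  in_range <- function(idx) all(idx >= 1L & idx <= n)

  for (nm in names(topo$groups)) {
    g <- topo$groups[[nm]]
    if (length(g) == 0L) add("group_empty", paste0("group '", nm, "' is empty"))
    if (length(g) > 0L && !in_range(g)) {
      add("index_range", paste0("group '", nm, "' references indices outside 1..", n))
    }
    if (anyDuplicated(g)) {
      add("group_duplicates", paste0("group '", nm, "' has duplicate indices"))
    }
  }
  if (!is.null(topo$bonds) && nrow(topo$bonds) > 0L &&
      !in_range(as.integer(topo$bonds))) {
    add("index_range", paste0("bond list references indices outside 1..", n))
  }
  if (!is.null(topo$junction_triplets) && nrow(topo$junction_triplets) > 0L &&
      !in_range(as.integer(topo$junction_triplets))) {
    add("index_range", paste0("junction list references indices outside 1..", n))
  }
  strand_idx <- unlist(topo$strands, use.names = FALSE)
  if (length(strand_idx) > 0L && !in_range(strand_idx)) {
    add("index_range", paste0("strands reference indices outside 1..", n))
  }
  if (anyDuplicated(strand_idx) ||
      !setequal(strand_idx, seq_len(n))) {
    add("strand_partition",
        paste0("strands must partition 1..", n, " exactly; got ",
               length(unique(strand_idx)), " distinct indices"))
  }
  if (length(findings) == 0L) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

#' Centre of mass of a bead group
#'
#' Unweighted mean position of the group members (equal-mass convention for
#' coarse-grained nucleotide beads).
#'
#' @param config a [particle_config()].
#' @param group integer vector of particle indices (1-based).
#' @param group_name label used in error messages.
#' @return numeric length-3 vector.
#' @export
center_of_mass <- function(config, group, group_name = "group") {
  group <- as.integer(group)
  if (length(group) == 0L) {
    stop("centre of mass of empty ", group_name, call. = FALSE)
  }
  n <- n_particles(config)
  if (any(group < 1L | group > n)) {
    stop(group_name, " references particle indices outside 1..", n,
         call. = FALSE)
  }
  if (length(group) == 1L) return(config$positions[group, ])
  colMeans(config$positions[group, , drop = FALSE])
}

#' Reproducible per-walker random streams
#'
#' Multi-walker runs interleave stochastic segments of several replicas; to
#' keep each walker's trajectory reproducible and independent of the others,
#' each walker owns a saved Mersenne-Twister state seeded from
#' `master_seed` and its walker index. `with_stream()` swaps a walker's
#' state in, evaluates an expression, and captures the advanced state back.
#'
#' @param master_seed integer master seed.
#' @param n_streams number of walker streams.
#' @return an object of class `seed_policy`.
#' @export
seed_policy <- function(master_seed, n_streams = 1L) {
  master_seed <- as.integer(master_seed)
  states <- vector("list", n_streams)
  old <- get0(".Random.seed", envir = globalenv())
  for (i in seq_len(n_streams)) {
    # offset keeps derived seeds clear of each other and below 2^31
    set.seed((master_seed %% 1000003L) * 2011L + i, kind = "Mersenne-Twister")
    states[[i]] <- get(".Random.seed", envir = globalenv())
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(master_seed = master_seed, states = states),
            class = "seed_policy")
}

# Internal: run fn() under stream i and return list(value, policy)
run_in_stream <- function(policy, i, fn) {
  assign(".Random.seed", policy$states[[i]], envir = globalenv())
  value <- fn()
  policy$states[[i]] <- get(".Random.seed", envir = globalenv())
  list(value = value, policy = policy)
}
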