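#' Free-energy profile from biased configuration histograms
#'
#' The preferred route to a free-energy landscape: sample configurations
#' under the frozen, converged bias, histogram the CV, and undo the bias at
#' each bin: Delta G(s) = -ln N(s) - B(s) in k_B*T (the immaterial constant
#' is absorbed by min-shifting to 0). Per-bin standard errors are the
#' standard error of the per-replica Delta G estimates, so at least two
#' replicas are needed for error bars (with one replica they are reported as
#' NA, not zero). Empty bins are flagged, never interpolated.
#'
#' @param samples tibble of production samples, e.g. from
#'   [biased_production_run()]: CV column(s) (`cv`, or `cv1` and `cv2`),
#'   `bias_value`, and a replica label column.
#' @param grid a [grid_spec()] defining the histogram bins (bin centres at
#'   node midpoints; the spacing is the bin width).
#' @param cv_cols names of the CV columns (length 1 or 2).
#' @param bias_col name of the bias-value column.
#' @param replica_col name of the replica label column.
#' @return tibble of class `free_energy_profile`: bin-centre coordinates
#'   (`s` or `s1`,`s2`), `delta_G` (min-shifted, k_B*T), `se`, `n_samples`,
#'   `empty` flag.
#' @export
histogram_free_energy <- function(samples, grid,
                                  cv_cols = intersect(c("cv", "cv1", "cv2"),
                                                      names(samples)),
                                  bias_col = "bias_value",
                                  replica_col = "replica") {
  stopifnot(inherits(grid, "grid_spec"))
  dim <- grid$dim
  if (length(cv_cols) != dim) {
    stop("need ", dim, " CV column(s) to match the grid", call. = FALSE)
  }
  has_reps <- replica_col %in% names(samples) &&
    length(unique(samples[[replica_col]])) >= 2L
  if (!has_reps && !(replica_col %in% names(samples))) {
    samples[[replica_col]] <- 1L
  }

  bin_index <- function(x, d) {
    idx <- floor((x - grid$min[d]) / grid$spacing[d]) + 1L
    n_bins <- grid$n_nodes[d] - 1L
    idx[idx < 1L | idx > n_bins] <- NA_integer_
    idx
  }
  centers <- lapply(seq_len(dim), function(d) {
    grid$axes[[d]][-1] - grid$spacing[d] / 2
  })
  n_bins <- vapply(centers, length, integer(1))

  # per-replica Delta G estimates on the flattened bin index
  reps <- unique(samples[[replica_col]])
  flat <- function(df) {
    i1 <- bin_index(df[[cv_cols[1]]], 1L)
    if (dim == 1L) i1 else i1 + (bin_index(df[[cv_cols[2]]], 2L) - 1L) * n_bins[1]
  }
  total_bins <- prod(n_bins)
  # mean bias per bin (bias is a smooth function of s; average over samples)
  all_idx <- flat(samples)
  keep <- !is.na(all_idx)
  bias_by_bin <- rep(NA_real_, total_bins)
  tb <- tapply(samples[[bias_col]][keep], all_idx[keep], mean)
  bias_by_bin[as.integer(names(tb))] <- tb
  counts <- tabulate(all_idx[keep], nbins = total_bins)

  dg_of <- function(cnt, biasv) {
    dg <- -log(cnt) - biasv
    dg - min(dg[cnt > 0L], na.rm = TRUE)
  }
  delta_G <- rep(NA_real_, total_bins)
  nz <- counts > 0L
  delta_G[nz] <- dg_of(counts, bias_by_bin)[nz]

  se <- rep(NA_real_, total_bins)
  if (has_reps) {
    per_rep <- matrix(NA_real_, total_bins, length(reps))
    for (k in seq_along(reps)) {
      df <- samples[samples[[replica_col]] == reps[k], ]
      idx <- flat(df); idx <- idx[!is.na(idx)]
      cnt <- tabulate(idx, nbins = total_bins)
      ok <- cnt > 0L
      dg <- rep(NA_real_, total_bins)
      dg[ok] <- (-log(cnt) - bias_by_bin)[ok]
      dg <- dg - min(dg, na.rm = TRUE)
      per_rep[, k] <- dg
    }
    n_ok <- rowSums(!is.na(per_rep))
    sd_rep <- apply(per_rep, 1L, stats::sd, na.rm = TRUE)
    se[n_ok >= 2L] <- (sd_rep / sqrt(n_ok))[n_ok >= 2L]
  }

  out <- if (dim == 1L) {
    tibble::tibble(s = centers[[1]])
  } else {
    tidyr::expand_grid(s2 = centers[[2]], s1 = centers[[1]]) |>
      dplyr::select("s1", "s2")
  }
  out$delta_G <- delta_G
  out$se <- se
  out$n_samples <- counts
  out$empty <- counts == 0L
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' Two-dimensional kernel density landscape
#'
#' Gaussian kernel density estimate of 2D samples on a declared grid, plus
#' -ln(density) as a free-energy-like surface. `bandwidth` is the Gaussian
#' kernel standard deviation in CV units. A KDE landscape indicates
#' bistability and basin locations; absolute values near sharp features
#' depend strongly on the bandwidth and should not be overinterpreted —
#' this caveat is recorded in the result's metadata.
#'
#' @param samples tibble or matrix of 2D points (first two columns used).
#' @param bandwidth Gaussian kernel sd (one value or per-dimension pair).
#' @param lims grid limits c(xmin, xmax, ymin, ymax); defaults to the data
#'   range padded by 3 bandwidths.
#' @param n number of grid points per axis.
#' @return tibble with `s1`, `s2`, `density`, `neg_log_density`; attributes
#'   `bandwidth` and `caveat`.
#' @export
kde_landscape_2d <- function(samples, bandwidth = 0.05, lims = NULL, n = 80L) {
  m <- as.matrix(samples)[, 1:2, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 samples for a KDE", call. = FALSE)
  if (any(bandwidth <= 0)) stop("bandwidth must be positive", call. = FALSE)
  bw <- rep(bandwidth, length.out = 2L)
  if (is.null(lims)) {
    lims <- c(range(m[, 1]) + c(-3, 3) * bw[1],
              range(m[, 2]) + c(-3, 3) * bw[2])
  }
  # MASS::kde2d's h is 4x the Gaussian kernel sd
  k <- MASS::kde2d(m[, 1], m[, 2], h = 4 * bw, n = n, lims = lims)
  out <- tidyr::expand_grid(s1 = k$x, s2 = k$y) |>
    dplyr::arrange(.data$s2, .data$s1) |>
    dplyr::mutate(density = as.numeric(k$z),
                  neg_log_density = -log(pmax(.data$density, 1e-300)))
  attr(out, "bandwidth") <- bw
  attr(out, "caveat") <- paste(
    "KDE landscapes indicate bistability and basin locations;",
    "free-energy values near sharp features depend strongly on the",
    "bandwidth and should not be overinterpreted.")
  out
}

#' State definition for conformer classification
#'
#' A named predicate over per-frame observables. For four-way-junction
#' isomer analysis the conventions are: a hydrogen bond counts as intact
#' when its internal energy is below -1 k_B*T, and a coaxial stack as formed
#' when its internal energy is below -5 k_B*T; the two stacked isomers are
#' told apart by which stack pair is formed, and the open intermediate has
#' all bonds intact but no stacks.
#'
#' @param name state label.
#' @param predicate function(frames_tibble) -> logical vector.
#' @return an object of class `state_definition`.
#' @export
state_definition <- function(name, predicate) {
  stopifnot(is.character(name), is.function(predicate))
  structure(list(name = name, predicate = predicate),
            class = "state_definition")
}

#' Default energy thresholds for bond/stack formation (k_B*T)
#' @export
BOND_INTACT_THRESHOLD <- -1
#' @rdname BOND_INTACT_THRESHOLD
#' @export
STACK_FORMED_THRESHOLD <- -5

#' Classify trajectory frames into states
#'
#' Evaluates each state's predicate on the frame table and returns the
#' (optionally weighted) occupancy probability of each state plus "other"
#' for frames matching no state. Sibling predicates must be mutually
#' exclusive on the data — overlap is a validation error before any
#' counting. Standard errors are across replicas when a replica column is
#' present (between-replica SE of the final statistic).
#'
#' @param frames tibble of per-frame observables.
#' @param states list of [state_definition()]s.
#' @param weights optional per-frame weights (e.g. from [spring_weight()]).
#' @param replica_col replica label column name (optional).
#' @return tibble: `state`, `probability`, `se`.
#' @export
classify_states <- function(frames, states, weights = NULL,
                            replica_col = "replica") {
  stopifnot(length(states) >= 1L)
  member <- vapply(states, function(st) st$predicate(frames),
                   logical(nrow(frames)))
  member <- matrix(member, nrow = nrow(frames))
  if (any(rowSums(member) > 1L)) {
    stop("state predicates overlap on ", sum(rowSums(member) > 1L),
         " frame(s); definitions must be mutually exclusive", call. = FALSE)
  }
  other <- rowSums(member) == 0L
  member <- cbind(member, other)
  state_names <- c(vapply(states, function(st) st$name, character(1)), "other")
  w <- if (is.null(weights)) rep(1, nrow(frames)) else as.numeric(weights)
  if (length(w) != nrow(frames)) {
    stop("weights must have one value per frame", call. = FALSE)
  }
  prob <- colSums(member * w) / sum(w)

  se <- rep(NA_real_, length(prob))
  if (replica_col %in% names(frames)) {
    reps <- unique(frames[[replica_col]])
    if (length(reps) >= 2L) {
      per_rep <- vapply(reps, function(r) {
        sel <- frames[[replica_col]] == r
        colSums(member[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
      }, numeric(length(prob)))
      se <- apply(per_rep, 1L, stats::sd) / sqrt(length(reps))
    }
  }
  tibble::tibble(state = state_names, probability = as.numeric(prob), se = se)
}

#' Statistical weight of a frame under metadynamics + WLC springs
#'
#' The total weight used to compute spring-constrained averages from a
#' frozen-bias ensemble: w = exp(+B(x) - sum_i Delta G_WLC(L_i)) in k_B*T
#' units. The +B factor undoes the metadynamics bias the frame was sampled
#' under; the spring sum applies the Boltzmann penalty of the six ssDNA
#' entropic springs at their measured attachment separations. Frames with
#' any spring at or beyond its contour length get weight 0 (the WLC's own
#' divergent limit), counted as overstretch events rather than errors.
#' Normalisation is immaterial; consumers normalise.
#'
#' @param bias_values numeric vector, bias at each frame's CV value (k_B*T).
#' @param L matrix of spring extensions, one row per frame, one column per
#'   spring (nm).
#' @param springs a [wlc_spring_set()].
#' @return numeric vector of non-negative weights; attribute
#'   `overstretch_events` counts zero-weight frames.
#' @export
spring_weight <- function(bias_values, L, springs = NULL) {
  Lm <- if (is.null(L)) {
    matrix(numeric(0), nrow = length(bias_values), ncol = 0L)
  } else if (is.matrix(L)) L else matrix(L, ncol = 1L)
  if (nrow(Lm) != length(bias_values)) {
    stop("need one row of spring extensions per frame", call. = FALSE)
  }
  dg <- if (is.null(springs) || ncol(Lm) == 0L) {
    numeric(length(bias_values))
  } else {
    spring_set_free_energy(Lm, springs)
  }
  over <- !is.finite(dg)
  # subtract the max exponent for numerical stability; normalisation is free
  expo <- bias_values - dg
  expo[over] <- -Inf
  if (all(over)) {
    w <- rep(0, length(bias_values))
  } else {
    w <- exp(expo - max(expo[!over]))
  }
  attr(w, "overstretch_events") <- sum(over)
  w
}

#' Kish effective sample size of a weight vector
#'
#' (sum w)^2 / sum(w^2); equals n for uniform weights and collapses toward 1
#' as the weights degenerate.
#'
#' @param w numeric weights.
#' @return scalar effective sample size.
#' @export
kish_ess <- function(w) {
  if (sum(w) == 0) return(0)
  sum(w)^2 / sum(w^2)
}

#' Reweighted bending-angle statistics
#'
#' Weighted mean and standard deviation of the bending angle phi under the
#' metadynamics-unbiasing + WLC-spring weights, with standard errors across
#' replica groups (simulations started from different initial conditions)
#' and the Kish effective sample size. Angles are treated linearly: observed
#' joint-angle distributions sit far from the 0/360 wrap, matching how
#' micrograph angle data are analysed; a warning fires if samples span both
#' ends of the circle.
#'
#' @param frames tibble with the angle, bias and spring-extension columns.
#' @param springs a [wlc_spring_set()] (NULL for bias-only reweighting).
#' @param phi_col angle column name (degrees).
#' @param bias_col bias-value column name (k_B*T).
#' @param L_cols spring-extension column names, one per spring (nm).
#' @param replica_col replica label column (optional, for standard errors).
#' @param ess_floor warn when the Kish effective sample size falls below
#'   this fraction of the frame count.
#' @return one-row tibble of class `angle_stats`: `mean_phi`, `sd_phi`,
#'   `se_mean`, `se_sd`, `ess`, `n_frames`, `overstretch_events`.
#' @export
reweighted_angle_stats <- function(frames, springs = NULL,
                                   phi_col = "phi", bias_col = "bias_value",
                                   L_cols = grep("^L[0-9]+$", names(frames),
                                                 value = TRUE),
                                   replica_col = "replica",
                                   ess_floor = 0.01) {
  phi <- frames[[phi_col]]
  if (any(phi > 340) && any(phi < 20)) {
    warning("angle samples span both (0,20) and (340,360) degrees; linear ",
            "statistics are unreliable near the wrap", call. = FALSE)
  }
  Lm <- if (length(L_cols) > 0L) {
    as.matrix(frames[, L_cols, drop = FALSE])
  } else NULL
  w <- spring_weight(frames[[bias_col]], Lm, springs)
  over <- attr(w, "overstretch_events")
  if (sum(w) == 0) {
    stop("no admissible frames: all weights are zero (every frame ",
         "overstretches at least one spring)", call. = FALSE)
  }
  wstats <- function(phi, w) {
    m <- sum(w * phi) / sum(w)
    v <- sum(w * (phi - m)^2) / sum(w)
    c(mean = m, sd = sqrt(v))
  }
  st <- wstats(phi, w)
  ess <- kish_ess(w)
  if (ess < ess_floor * length(w)) {
    warning(sprintf(paste0("Kish effective sample size %.1f is below %.0f%% of ",
                           "the %d frames; reweighted statistics are degenerate"),
                    ess, 100 * ess_floor, length(w)), call. = FALSE)
  }
  se_mean <- NA_real_; se_sd <- NA_real_
  if (replica_col %in% names(frames)) {
    reps <- unique(frames[[replica_col]])
    if (length(reps) >= 2L) {
      per <- vapply(reps, function(r) {
        sel <- frames[[replica_col]] == r
        if (sum(w[sel]) == 0) return(c(mean = NA_real_, sd = NA_real_))
        wstats(phi[sel], w[sel])
      }, numeric(2))
      n_ok <- sum(!is.na(per[1, ]))
      if (n_ok >= 2L) {
        se_mean <- stats::sd(per[1, ], na.rm = TRUE) / sqrt(n_ok)
        se_sd <- stats::sd(per[2, ], na.rm = TRUE) / sqrt(n_ok)
      }
    }
  }
  out <- tibble::tibble(mean_phi = st[["mean"]], sd_phi = st[["sd"]],
                        se_mean = se_mean, se_sd = se_sd,
                        ess = ess, n_frames = length(w),
                        overstretch_events = over)
  class(out) <- c("angle_stats", class(out))
  out
}

#' Sweep candidate spring designs over one frame set
#'
#' The inverse-design workflow: one converged frozen-bias ensemble, many
#' candidate (N_short, N_long) ssDNA spring pairs; each candidate is
#' reweighted from the same frames, giving the predicted angle distribution
#' per design, plus a monotonicity diagnostic of the mean angle against the
#' short-spring length. Candidates whose springs are shorter than every
#' observed extension produce an `admissible = FALSE` row instead of
#' propagating the "no admissible frames" error.
#'
#' @param frames as [reweighted_angle_stats()].
#' @param candidates tibble or data.frame with columns `n_short`, `n_long`
#'   (physical nucleotide counts).
#' @param n_each springs per set.
#' @param ... forwarded to [reweighted_angle_stats()] / [wlc_spring_set()].
#' @inheritParams reweighted_angle_stats
#' @return tibble: one row per candidate with the angle statistics, plus
#'   `admissible`; attribute `monotone_mean_phi` reports whether the mean
#'   angle is monotone in `n_short` at fixed `n_long`.
#' @export
spring_sweep <- function(frames, candidates, n_each = 3,
                         phi_col = "phi", bias_col = "bias_value",
                         L_cols = grep("^L[0-9]+$", names(frames), value = TRUE),
                         replica_col = "replica", ...) {
  candidates <- tibble::as_tibble(candidates)
  stopifnot(all(c("n_short", "n_long") %in% names(candidates)))
  rows <- purrr::pmap(candidates, function(n_short, n_long, ...) {
    springs <- wlc_spring_set(n_short, n_long, n_each = n_each)
    res <- tryCatch(
      suppressWarnings(
        reweighted_angle_stats(frames, springs, phi_col = phi_col,
                               bias_col = bias_col, L_cols = L_cols,
                               replica_col = replica_col)
      ),
      error = function(e) {
        if (grepl("no admissible frames", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(res)) {
      res <- tibble::tibble(mean_phi = NA_real_, sd_phi = NA_real_,
                            se_mean = NA_real_, se_sd = NA_real_,
                            ess = 0, n_frames = nrow(frames),
                            overstretch_events = nrow(frames))
      res$admissible <- FALSE
    } else {
      res$admissible <- TRUE
    }
    dplyr::bind_cols(tibble::tibble(n_short = n_short, n_long = n_long), res)
  })
  out <- dplyr::bind_rows(rows)
  mono <- out |>
    dplyr::filter(.data$admissible) |>
    dplyr::group_by(.data$n_long) |>
    dplyr::summarise(monotone = all(diff(.data$mean_phi[order(.data$n_short)]) >= 0) ||
                       all(diff(.data$mean_phi[order(.data$n_short)]) <= 0),
                     .groups = "drop")
  attr(out, "monotone_mean_phi") <- mono
  out
}
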