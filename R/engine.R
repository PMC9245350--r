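#' Sampler settings
#'
#' Shared settings for the Langevin-MD and Metropolis-MC samplers. MD uses
#' velocity-Verlet integration with an Andersen-like thermostat: time
#' evolution is Newtonian, but every `thermostat_interval` steps a fraction
#' `refresh_fraction` of particles has its velocities redrawn from the
#' Maxwell-Boltzmann distribution at the simulation temperature. All
#' energies are in k_B*T (beta = 1) and particle masses are 1, so
#' Maxwell-Boltzmann velocity components have unit-variance scaled by
#' sqrt(kT). The default thermostat interval of 1000 steps matches typical
#' coarse-grained practice; the toy fixtures use shorter intervals to reach
#' the diffusive regime quickly.
#'
#' @param dt MD time step (reduced units).
#' @param thermostat_interval steps between velocity refreshes (>= 1);
#'   `Inf` disables the thermostat (pure NVE).
#' @param refresh_fraction fraction of particles redrawn per refresh, (0, 1].
#' @param mc_move_size maximum single-particle displacement per MC move.
#' @param kT thermal energy (defaults to 1; energies are in k_B*T).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(dt = 0.002, thermostat_interval = 1000,
                           refresh_fraction = 1, mc_move_size = 0.1, kT = 1) {
  stopifnot(dt > 0, thermostat_interval >= 1,
            refresh_fraction > 0, refresh_fraction <= 1,
            mc_move_size > 0, kT > 0)
  structure(list(dt = dt, thermostat_interval = thermostat_interval,
                 refresh_fraction = refresh_fraction,
                 mc_move_size = mc_move_size, kT = kT),
            class = "sampler_config")
}

total_force <- function(config, potential, bias, cv, topo) {
  f <- potential$forces(config)
  if (!is.null(bias)) f <- f + bias_force(bias, config, cv, topo)
  f
}

draw_mb_velocities <- function(n, kT) {
  matrix(stats::rnorm(n * 3L, sd = sqrt(kT)), n, 3L)
}

#' Advance a configuration by Langevin MD under potential + bias
#'
#' Velocity-Verlet integration of U + B_t for `n_steps`, with periodic
#' partial velocity refresh (Andersen-like thermostat). The bias is held
#' fixed during the segment; metadynamics updates it between segments.
#' Uses the current R random stream; callers manage per-walker streams.
#'
#' @param config a [particle_config()] with velocities.
#' @param potential a [potential_model()].
#' @param n_steps number of steps.
#' @param sampler a [sampler_config()].
#' @param bias optional frozen [gridded_bias()] to add to the potential.
#' @param cv the [collective_variable()] the bias acts on (required with bias).
#' @param topo optional topology.
#' @return the advanced [particle_config()].
#' @export
md_segment <- function(config, potential, n_steps, sampler,
                       bias = NULL, cv = NULL, topo = NULL) {
  if (is.null(config$velocities)) {
    stop("md_segment requires velocities; use mc_segment for velocity-free ",
         "configurations", call. = FALSE)
  }
  x <- config$positions
  v <- config$velocities
  dt <- sampler$dt
  n <- nrow(x)
  cfg <- config
  f <- total_force(cfg, potential, bias, cv, topo)
  step0 <- config$step_count
  for (step in seq_len(n_steps)) {
    v_half <- v + 0.5 * dt * f
    x <- x + dt * v_half
    cfg$positions <- x
    f <- total_force(cfg, potential, bias, cv, topo)
    if (!all(is.finite(f)) || !all(is.finite(x))) {
      stop("integration blow-up (non-finite positions or forces) at step ",
           step0 + step, call. = FALSE)
    }
    v <- v_half + 0.5 * dt * f
    if (is.finite(sampler$thermostat_interval) &&
        (step0 + step) %% sampler$thermostat_interval == 0) {
      k <- max(1L, round(sampler$refresh_fraction * n))
      idx <- if (k == n) seq_len(n) else sample.int(n, k)
      v[idx, ] <- draw_mb_velocities(k, sampler$kT)
    }
  }
  cfg$positions <- x
  cfg$velocities <- v
  cfg$step_count <- step0 + n_steps
  cfg
}

#' Advance a configuration by Metropolis Monte Carlo under potential + bias
#'
#' Single-particle random displacement moves accepted with probability
#' min(1, exp(-delta U / kT)), where U includes the interpolated bias. One
#' "step" is one attempted move.
#'
#' @inheritParams md_segment
#' @return the advanced [particle_config()] (velocities untouched).
#' @export
mc_segment <- function(config, potential, n_steps, sampler,
                       bias = NULL, cv = NULL, topo = NULL) {
  cfg <- config
  n <- nrow(cfg$positions)
  e_total <- function(c0) {
    e <- potential$energy(c0)
    if (!is.null(bias)) e <- e + bias_eval_point(bias, cv$value(c0, topo))
    e
  }
  e_cur <- e_total(cfg)
  for (step in seq_len(n_steps)) {
    i <- if (n == 1L) 1L else sample.int(n, 1L)
    trial <- cfg
    trial$positions[i, ] <- trial$positions[i, ] +
      stats::runif(3L, -sampler$mc_move_size, sampler$mc_move_size)
    e_new <- e_total(trial)
    if (is.nan(e_new) || (is.infinite(e_new) && e_new < 0)) {
      stop("non-finite energy at step ", cfg$step_count + step, call. = FALSE)
    }
    if (e_new <= e_cur ||
        stats::runif(1L) < exp(-(e_new - e_cur) / sampler$kT)) {
      cfg <- trial
      e_cur <- e_new
    }
  }
  cfg$step_count <- config$step_count + n_steps
  cfg
}

#' Multi-walker well-tempered metadynamics run
#'
#' The orchestration loop: `n_walkers` replicas evolve under the unbiased
#' potential plus one shared, time-dependent bias. Each MetaD cycle advances
#' every walker `tau` steps under the current bias, then deposits one
#' tempered Gaussian per walker at its instantaneous CV value. Deposits
#' within a cycle are applied sequentially in walker order, each seeing the
#' bias left by the preceding walkers (the alternative — evaluating all N
#' amplitudes against the pre-cycle bias — differs only at order
#' A^2/delta_T). Sharing the bias gives an N-fold speed-up in convergence,
#' and at early times walkers repel each other into different regions.
#'
#' Walkers are initialised by default at evenly spaced quantiles of the CV
#' domain (each walker starting from a different location in CV space), or
#' from `init_configs`. Each walker owns an independent, reproducible random
#' stream derived from `seed`, so runs are bit-reproducible and independent
#' of scheduling.
#'
#' @param potential a [potential_model()].
#' @param cv a [collective_variable()] (1D or 2D) with matching grid.
#' @param grid a [grid_spec()].
#' @param n_walkers number of replicas sharing the bias.
#' @param n_cycles number of MetaD cycles.
#' @param tau steps per cycle per walker.
#' @param sigma,height,delta_T bias hyperparameters (see [gridded_bias()]).
#' @param sampler a [sampler_config()].
#' @param seed master seed.
#' @param sampler_kind "md" or "mc".
#' @param init_configs optional list of `n_walkers` starting
#'   [particle_config()]s; otherwise `init_fn(s)` must build a configuration
#'   at CV value s.
#' @param init_fn function(s) -> particle_config, used for default
#'   initialisation across the CV domain.
#' @param topo optional topology forwarded to the CV.
#' @param trace_stride record each walker's CV every `trace_stride` cycles.
#' @param trace_fn optional function(config) -> named numeric vector of
#'   extra per-walker observables recorded alongside the CV trace.
#' @param average_from fraction of cycles (0 disables) after which bias
#'   snapshots are accumulated into a time-averaged bias shape. A deposited
#'   bias fluctuates around its converged profile by one Gaussian height;
#'   averaging late-run snapshots (every 10 cycles, offset-aligned by their
#'   spatial mean so the uniform growth of B cancels) removes most of that
#'   deposition noise from the free-energy estimate. The averaged shape is
#'   returned as `bias_avg` and used by [implied_free_energy()] when present.
#' @return object of class `metad_result`: `bias` (final [gridded_bias()]),
#'   `bias_avg` (time-averaged copy, when requested), `trace`
#'   (tibble: cycle, walker, step, cv or cv1/cv2, bias_value) and
#'   `clamp_events` (count of CV excursions clamped to the grid).
#' @export
metad_run <- function(potential, cv, grid, n_walkers, n_cycles, tau,
                      sigma, height, delta_T, sampler, seed,
                      sampler_kind = c("md", "mc"),
                      init_configs = NULL, init_fn = NULL, topo = NULL,
                      trace_stride = 1L, average_from = 0.5,
                      trace_fn = NULL) {
  sampler_kind <- match.arg(sampler_kind)
  stopifnot(n_walkers >= 1, n_cycles >= 1, tau >= 1)
  bias <- gridded_bias(grid, sigma = sigma, height = height, delta_T = delta_T)
  policy <- seed_policy(seed, n_streams = n_walkers)

  if (is.null(init_configs)) {
    if (is.null(init_fn)) {
      stop("supply init_configs or an init_fn placing a walker at a CV value",
           call. = FALSE)
    }
    # evenly spaced quantiles of the CV domain (diagonal in 2D)
    q <- (seq_len(n_walkers) - 0.5) / n_walkers
    init_configs <- lapply(q, function(p) {
      s <- grid$min + p * (grid$max - grid$min)
      init_fn(s)
    })
  }
  if (length(init_configs) != n_walkers) {
    stop("need one initial configuration per walker", call. = FALSE)
  }
  configs <- init_configs
  if (sampler_kind == "md") {
    for (w in seq_len(n_walkers)) {
      if (is.null(configs[[w]]$velocities)) {
        res <- run_in_stream(policy, w, function() {
          draw_mb_velocities(n_particles(configs[[w]]), sampler$kT)
        })
        configs[[w]]$velocities <- res$value
        policy <- res$policy
      }
    }
  }

  clamp_events <- 0L
  trace <- vector("list", n_cycles)
  advance <- if (sampler_kind == "md") md_segment else mc_segment
  avg_start <- if (average_from > 0) ceiling(average_from * n_cycles) else Inf
  avg_sum <- NULL
  avg_n <- 0L
  for (cyc in seq_len(n_cycles)) {
    s_now <- matrix(NA_real_, n_walkers, cv$dim)
    for (w in seq_len(n_walkers)) {
      res <- run_in_stream(policy, w, function() {
        advance(configs[[w]], potential, tau, sampler,
                bias = bias, cv = cv, topo = topo)
      })
      configs[[w]] <- res$value
      policy <- res$policy
      s_now[w, ] <- cv$value(configs[[w]], topo)
    }
    # deposition: serialized synchronization point, fixed walker order
    for (w in seq_len(n_walkers)) {
      s_w <- s_now[w, ]
      if (any(s_w < grid$min | s_w > grid$max)) clamp_events <- clamp_events + 1L
      bias <- deposit(bias, s_w, warn_edge = FALSE)
    }
    if (cyc >= avg_start && (cyc - avg_start) %% 10L == 0L) {
      shape <- bias$values - mean(bias$values)
      avg_sum <- if (is.null(avg_sum)) shape else avg_sum + shape
      avg_n <- avg_n + 1L
    }
    if (cyc %% trace_stride == 0L) {
      trace[[cyc]] <- tibble::tibble(
        cycle = cyc,
        walker = seq_len(n_walkers),
        step = vapply(configs, function(c0) as.numeric(c0$step_count), numeric(1)),
        bias_value = bias_evaluate(bias, s_now)
      )
      if (cv$dim == 1L) {
        trace[[cyc]]$cv <- s_now[, 1]
      } else {
        trace[[cyc]]$cv1 <- s_now[, 1]
        trace[[cyc]]$cv2 <- s_now[, 2]
      }
      if (!is.null(trace_fn)) {
        proto <- trace_fn(configs[[1]])
        extras <- matrix(NA_real_, n_walkers, length(proto),
                         dimnames = list(NULL, names(proto)))
        for (w in seq_len(n_walkers)) extras[w, ] <- trace_fn(configs[[w]])
        trace[[cyc]] <- dplyr::bind_cols(trace[[cyc]],
                                         tibble::as_tibble(extras))
      }
    }
  }
  bias$cycles_elapsed <- as.integer(n_cycles)
  bias_avg <- NULL
  if (avg_n > 0L) {
    bias_avg <- bias
    # restore the final run's offset so the averaged object is still a
    # valid non-negative bias; only the shape is averaged
    shape <- avg_sum / avg_n
    bias_avg$values <- shape - min(shape)
  }
  out <- list(bias = bias, bias_avg = bias_avg,
              trace = dplyr::bind_rows(trace),
              clamp_events = clamp_events,
              configs = configs)
  class(out) <- "metad_result"
  out
}

#' Free energy implied by a metadynamics result
#'
#' Applies [implied_free_energy()] to the time-averaged bias shape when the
#' run accumulated one, otherwise to the final bias.
#'
#' @param result a `metad_result`.
#' @return tibble as [implied_free_energy()].
#' @export
implied_free_energy_result <- function(result) {
  implied_free_energy(if (!is.null(result$bias_avg)) result$bias_avg else result$bias)
}

#' @export
print.metad_result <- function(x, ...) {
  cat("<metad_result> ", x$bias$deposits_made, " deposits over ",
      x$bias$cycles_elapsed, " cycles; ", x$clamp_events,
      " CV clamp event(s)\n", sep = "")
  print(x$bias)
  invisible(x)
}

#' Production sampling under a frozen bias
#'
#' Runs one or more replicas under the unbiased potential plus a frozen
#' (non-depositing) bias, discards `burn_in` steps for decorrelation, then
#' records the CV and the bias value at the sample point every `stride`
#' steps — exactly the table [histogram_free_energy()] needs to undo the
#' bias. Exactly `floor((n_steps - burn_in)/stride)` samples per replica.
#'
#' @param bias a converged [gridded_bias()] (left untouched).
#' @param potential a [potential_model()].
#' @param cv the biased [collective_variable()].
#' @param init_configs list of starting configurations, one per replica.
#' @param n_steps total steps per replica (including burn-in).
#' @param burn_in steps discarded before sampling.
#' @param stride steps between samples.
#' @param sampler a [sampler_config()].
#' @param seed master seed (one stream per replica).
#' @param sampler_kind "md" or "mc".
#' @param topo optional topology.
#' @param extra_cols optional function(config) -> named numeric vector of
#'   additional per-frame observables (e.g. angles, spring extensions).
#' @return tibble: replica, step, cv (or cv1, cv2), bias_value, extras.
#' @export
biased_production_run <- function(bias, potential, cv, init_configs,
                                  n_steps, burn_in, stride, sampler, seed,
                                  sampler_kind = c("md", "mc"), topo = NULL,
                                  extra_cols = NULL) {
  sampler_kind <- match.arg(sampler_kind)
  stopifnot(burn_in >= 0, stride >= 1, n_steps > burn_in)
  n_rep <- length(init_configs)
  policy <- seed_policy(seed, n_streams = n_rep)
  advance <- if (sampler_kind == "md") md_segment else mc_segment
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- init_configs[[r]]
    if (sampler_kind == "md" && is.null(cfg$velocities)) {
      res <- run_in_stream(policy, r, function() {
        draw_mb_velocities(n_particles(cfg), sampler$kT)
      })
      cfg$velocities <- res$value
      policy <- res$policy
    }
    res <- run_in_stream(policy, r, function() {
      advance(cfg, potential, burn_in, sampler, bias = bias, cv = cv,
              topo = topo)
    })
    cfg <- res$value
    policy <- res$policy
    n_samples <- (n_steps - burn_in) %/% stride
    svals <- matrix(NA_real_, n_samples, cv$dim)
    steps <- integer(n_samples)
    extras <- NULL
    for (k in seq_len(n_samples)) {
      res <- run_in_stream(policy, r, function() {
        advance(cfg, potential, stride, sampler, bias = bias, cv = cv,
                topo = topo)
      })
      cfg <- res$value
      policy <- res$policy
      svals[k, ] <- cv$value(cfg, topo)
      steps[k] <- cfg$step_count
      if (!is.null(extra_cols)) {
        e <- extra_cols(cfg)
        if (is.null(extras)) {
          extras <- matrix(NA_real_, n_samples, length(e),
                           dimnames = list(NULL, names(e)))
        }
        extras[k, ] <- e
      }
    }
    tb <- tibble::tibble(replica = r, step = steps,
                         bias_value = bias_evaluate(bias, svals))
    if (cv$dim == 1L) tb$cv <- svals[, 1] else {
      tb$cv1 <- svals[, 1]; tb$cv2 <- svals[, 2]
    }
    if (!is.null(extras)) tb <- dplyr::bind_cols(tb, tibble::as_tibble(extras))
    rows[[r]] <- tb
  }
  dplyr::bind_rows(rows)
}

#' Count committed transitions of a 1D CV between two basins
#'
#' A transition is counted each time the trajectory, having last been at or
#' beyond one threshold, reaches the opposite one — hysteresis that ignores
#' recrossings of the barrier top. Used to quantify the ergodicity rescue of
#' metadynamics (an unbiased trajectory stays in one basin; a tempered run
#' crosses repeatedly).
#'
#' @param s numeric vector of CV samples (one walker/replica).
#' @param lower,upper basin thresholds (lower < upper).
#' @return integer transition count.
#' @export
count_transitions <- function(s, lower, upper) {
  stopifnot(lower < upper)
  state <- 0L  # -1 in lower basin, +1 in upper basin, 0 unassigned
  n <- 0L
  for (x in s) {
    if (x <= lower) {
      if (state == 1L) n <- n + 1L
      state <- -1L
    } else if (x >= upper) {
      if (state == -1L) n <- n + 1L
      state <- 1L
    }
  }
  n
}
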