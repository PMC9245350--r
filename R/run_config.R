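#' Read a declarative run configuration
#'
#' A single YAML file declares the whole run: the system (a built-in fixture
#' kind or external oxDNA files), the CV, the grid, the MetaD
#' hyperparameters, sampler settings, seed and output paths. All defaults
#' are filled in and returned, so the effective configuration can be logged
#' verbatim and every run is self-documenting.
#'
#' @param path YAML file path.
#' @return a named list of class `run_config` with defaults applied.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- list(
    system = list(kind = "double_well_1d"),
    metad = list(n_walkers = 4L, n_cycles = 2000L, tau = 25L,
                 sigma = 0.15, height = 0.5, delta_T = 8),
    sampler = list(dt = 0.005, thermostat_interval = 100,
                   refresh_fraction = 1, mc_move_size = 0.1, kT = 1),
    sampler_kind = "md",
    seed = 20260101L,
    production = list(n_steps = 200000L, burn_in = 10000L, stride = 100L),
    output = list(bias = "bias.dat", trace = "trace.tsv", log = "run.log")
  )
  cfg <- utils::modifyList(defaults, raw)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Cross-checks the configuration against the chosen system: the fixture
#' kind exists, grid bounds cover the CV domain, the grid spacing respects
#' the delta-x <= sigma/5 rule in every biased dimension, and sampler and
#' MetaD scalars are in range. Findings are returned, not thrown, so the
#' command-line `validate` subcommand can report all of them at once.
#'
#' @param cfg a `run_config`.
#' @return tibble with columns `check`, `detail`; zero rows when valid.
#' @export
validate_run_config <- function(cfg) {
  findings <- list()
  add <- function(check, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(check = check,
                                                         detail = detail)
  }
  kinds <- c("double_well_1d", "bistable_2d", "kinkable_chain")
  if (!cfg$system$kind %in% kinds) {
    add("system_kind", paste0("unknown system kind '", cfg$system$kind,
                              "'; available: ", paste(kinds, collapse = ", ")))
  } else {
    fx <- generate_fixture(cfg$system$kind, seed = cfg$seed)
    grid <- tryCatch(resolve_grid(cfg, fx), error = function(e) e)
    if (inherits(grid, "error")) {
      add("grid", conditionMessage(grid))
    } else {
      sigma <- rep(cfg$metad$sigma, length.out = grid$dim)
      bad <- grid$spacing > sigma / 5 + 1e-12
      if (any(bad)) {
        add("grid_spacing",
            paste0("grid spacing must be at most one fifth of the MetaD ",
                   "sigma; dimension ", paste(which(bad), collapse = ", "),
                   " has spacing ", paste(grid$spacing[bad], collapse = ", "),
                   " > sigma/5 = ", paste(signif(sigma[bad] / 5, 4),
                                          collapse = ", ")))
      }
      dom <- fx$cv$domain
      if (any(grid$min > dom[, 1] + 1e-9) || any(grid$max < dom[, 2] - 1e-9)) {
        add("grid_domain", "grid does not cover the declared CV domain")
      }
    }
  }
  with(cfg$metad, {
    if (delta_T <= 0) add("delta_T", "delta_T must be positive")
    if (height <= 0) add("height", "height increment A must be positive")
    if (tau < 1) add("tau", "tau must be at least 1")
    if (n_walkers < 1) add("n_walkers", "need at least one walker")
  })
  if (cfg$sampler$dt <= 0) add("dt", "time step must be positive")
  if (length(findings) == 0L) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

resolve_grid <- function(cfg, fx) {
  if (!is.null(cfg$grid)) {
    grid_spec(cfg$grid$min, cfg$grid$max, cfg$grid$spacing)
  } else {
    fx$grid
  }
}

#' Command-line dispatcher
#'
#' Subcommands: `run` (metadynamics), `produce` (frozen-bias production
#' sampling), `fe` (free-energy profile from a production table), `reweight`
#' (WLC-spring reweighting, optionally a design sweep), `fixtures` (write a
#' test system), `validate` (configuration checks). Every run writes a log
#' with the effective parameters, seed, clamp/overstretch event counts and
#' package version. Invalid input exits non-zero with the findings listed.
#' Installed as a script under `inst/cli/metad.R`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metad.R <subcommand> [options]",
    "subcommands:",
    "  run      --config <yaml> [--bias-out <file>] [--trace-out <file>]",
    "  produce  --config <yaml> --bias-in <file> --samples-out <file>",
    "  fe       --config <yaml> --samples <tsv> --out <tsv>",
    "  reweight --samples <tsv> --n-short <int> --n-long <int> --out <tsv>",
    "           [--sweep '<n_short:n_long,...>']",
    "  fixtures --kind <name> --out-dir <dir> [--seed <int>]",
    "  validate --config <yaml>",
    sep = "\n")
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  rest <- args[-1]
  if (length(rest) > 0 && rest[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else default
  }
  code <- tryCatch({
    switch(
      sub,
      validate = cli_validate(opt("config")),
      run = cli_run(opt("config"), opt("bias-out"), opt("trace-out")),
      produce = cli_produce(opt("config"), opt("bias-in"), opt("samples-out")),
      fe = cli_fe(opt("config"), opt("samples"), opt("out")),
      reweight = cli_reweight(opt("samples"), opt("n-short"), opt("n-long"),
                              opt("out"), opt("sweep")),
      fixtures = cli_fixtures(opt("kind"), opt("out-dir"),
                              opt("seed", "20260101")),
      {
        cat("unknown subcommand '", sub, "'\n", usage, "\n", sep = "")
        2L
      })
  }, error = function(e) {
    cat("error: ", conditionMessage(e), "\n", sep = "")
    1L
  })
  invisible(as.integer(code))
}

cli_log <- function(path, cfg, extra = list()) {
  lines <- c(
    paste0("metadyn ", as.character(utils::packageVersion("metadyn"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "effective configuration:",
    strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]],
    vapply(names(extra), function(k) paste0(k, ": ", extra[[k]]), character(1))
  )
  writeLines(lines, path)
}

cli_validate <- function(config_path) {
  if (is.null(config_path)) stop("validate requires --config", call. = FALSE)
  cfg <- read_run_config(config_path)
  findings <- validate_run_config(cfg)
  if (nrow(findings) == 0L) {
    cat("configuration OK\n")
    0L
  } else {
    for (i in seq_len(nrow(findings))) {
      cat(findings$check[i], ": ", findings$detail[i], "\n", sep = "")
    }
    1L
  }
}

cli_system <- function(cfg) {
  fx <- generate_fixture(cfg$system$kind, seed = cfg$seed)
  smp <- do.call(sampler_config, cfg$sampler)
  list(fx = fx, sampler = smp, grid = resolve_grid(cfg, fx))
}

cli_run <- function(config_path, bias_out, trace_out) {
  if (is.null(config_path)) stop("run requires --config", call. = FALSE)
  cfg <- read_run_config(config_path)
  findings <- validate_run_config(cfg)
  if (nrow(findings) > 0L) {
    for (i in seq_len(nrow(findings))) {
      cat(findings$check[i], ": ", findings$detail[i], "\n", sep = "")
    }
    return(1L)
  }
  sys <- cli_system(cfg)
  fx <- sys$fx
  res <- metad_run(fx$potential, fx$cv, sys$grid,
                   n_walkers = cfg$metad$n_walkers,
                   n_cycles = cfg$metad$n_cycles, tau = cfg$metad$tau,
                   sigma = cfg$metad$sigma, height = cfg$metad$height,
                   delta_T = cfg$metad$delta_T, sampler = sys$sampler,
                   seed = cfg$seed, sampler_kind = cfg$sampler_kind,
                   init_fn = fx$init_fn,
                   init_configs = if (!is.null(fx$init_config)) {
                     rep(list(fx$init_config), cfg$metad$n_walkers)
                   },
                   topo = fx$topology)
  bias_out <- bias_out %||% cfg$output$bias
  write_bias(if (!is.null(res$bias_avg)) res$bias_avg else res$bias, bias_out)
  trace_out <- trace_out %||% cfg$output$trace
  utils::write.table(res$trace, trace_out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cli_log(cfg$output$log, cfg,
          list(deposits_made = res$bias$deposits_made,
               clamp_events = res$clamp_events,
               bias_file = bias_out, trace_file = trace_out))
  cat("bias written to ", bias_out, " (", res$bias$deposits_made,
      " deposits, ", res$clamp_events, " clamp events)\n", sep = "")
  0L
}

cli_produce <- function(config_path, bias_in, samples_out) {
  if (is.null(config_path) || is.null(bias_in) || is.null(samples_out)) {
    stop("produce requires --config, --bias-in and --samples-out", call. = FALSE)
  }
  cfg <- read_run_config(config_path)
  sys <- cli_system(cfg)
  fx <- sys$fx
  bias <- read_bias(bias_in)
  n_rep <- max(2L, cfg$metad$n_walkers)
  init <- if (!is.null(fx$init_config)) {
    rep(list(fx$init_config), n_rep)
  } else {
    q <- (seq_len(n_rep) - 0.5) / n_rep
    lapply(q, function(p) fx$init_fn(sys$grid$min + p * (sys$grid$max - sys$grid$min)))
  }
  samples <- biased_production_run(bias, fx$potential, fx$cv, init,
                                   n_steps = cfg$production$n_steps,
                                   burn_in = cfg$production$burn_in,
                                   stride = cfg$production$stride,
                                   sampler = sys$sampler, seed = cfg$seed + 1L,
                                   sampler_kind = cfg$sampler_kind,
                                   topo = fx$topology)
  utils::write.table(samples, samples_out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cli_log(cfg$output$log, cfg, list(samples_file = samples_out,
                                    n_samples = nrow(samples)))
  cat(nrow(samples), "samples written to", samples_out, "\n")
  0L
}

cli_fe <- function(config_path, samples_path, out_path) {
  if (is.null(config_path) || is.null(samples_path) || is.null(out_path)) {
    stop("fe requires --config, --samples and --out", call. = FALSE)
  }
  cfg <- read_run_config(config_path)
  sys <- cli_system(cfg)
  samples <- tibble::as_tibble(utils::read.delim(samples_path))
  prof <- histogram_free_energy(samples, sys$grid)
  utils::write.table(prof, out_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cat("free-energy profile written to", out_path, "\n")
  0L
}

cli_reweight <- function(samples_path, n_short, n_long, out_path, sweep) {
  if (is.null(samples_path) || is.null(out_path)) {
    stop("reweight requires --samples and --out", call. = FALSE)
  }
  frames <- tibble::as_tibble(utils::read.delim(samples_path))
  if (!is.null(sweep)) {
    pairs <- strsplit(strsplit(sweep, ",")[[1]], ":")
    cand <- tibble::tibble(
      n_short = as.integer(vapply(pairs, `[`, character(1), 1)),
      n_long = as.integer(vapply(pairs, `[`, character(1), 2)))
    out <- spring_sweep(frames, cand)
  } else {
    if (is.null(n_short) || is.null(n_long)) {
      stop("reweight requires --n-short and --n-long (or --sweep)",
           call. = FALSE)
    }
    springs <- wlc_spring_set(as.integer(n_short), as.integer(n_long))
    out <- reweighted_angle_stats(frames, springs)
  }
  utils::write.table(out, out_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cat("reweighted statistics written to", out_path, "\n")
  0L
}

cli_fixtures <- function(kind, out_dir, seed) {
  if (is.null(kind) || is.null(out_dir)) {
    stop("fixtures requires --kind and --out-dir", call. = FALSE)
  }
  fx <- generate_fixture(kind, seed = as.integer(seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fx$frames)) {
    utils::write.table(fx$frames, file.path(out_dir, "frames.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(fx$topology)) {
    write_oxdna_topology(fx$topology, file.path(out_dir, "system.top"))
  }
  if (!is.null(fx$init_config)) {
    write_oxdna_configuration(fx$init_config, file.path(out_dir, "system.dat"))
  }
  meta <- fx[vapply(fx, function(v) is.numeric(v) && length(v) <= 6,
                    logical(1))]
  yaml::write_yaml(meta, file.path(out_dir, "fixture.yaml"))
  cat("fixture '", kind, "' written to ", out_dir, "\n", sep = "")
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
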