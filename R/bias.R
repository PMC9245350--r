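#' Grid specification for the bias
#'
#' Per-dimension (min, max, spacing) for the 1D or 2D grid on which the
#' history-dependent bias is tabulated. Gridding keeps the cost of bias
#' evaluation independent of the number of deposited Gaussians. The spacing
#' must divide the extent into an integer number of cells, and — enforced at
#' [gridded_bias()] construction, where the Gaussian width is known — must
#' be at most one fifth of the MetaD sigma in that dimension, so that
#' interpolation error is negligible against the deposited features.
#'
#' @param min,max numeric vectors (length 1 or 2) of per-dimension bounds.
#' @param spacing numeric vector of per-dimension node spacings (delta x).
#' @return an object of class `grid_spec` with node coordinate vectors.
#' @export
grid_spec <- function(min, max, spacing) {
  dim <- length(min)
  stopifnot(dim %in% c(1L, 2L), length(max) == dim, length(spacing) == dim)
  if (any(spacing <= 0)) stop("grid spacing must be positive", call. = FALSE)
  n_cells <- (max - min) / spacing
  if (any(abs(n_cells - round(n_cells)) > 1e-8) || any(round(n_cells) < 1)) {
    stop("(max - min) must be an integer multiple (>= 1) of the spacing",
         call. = FALSE)
  }
  n_nodes <- as.integer(round(n_cells)) + 1L
  axes <- lapply(seq_len(dim), function(d) {
    min[d] + spacing[d] * (seq_len(n_nodes[d]) - 1L)
  })
  structure(list(dim = as.integer(dim), min = as.numeric(min),
                 max = as.numeric(max), spacing = as.numeric(spacing),
                 n_nodes = n_nodes, axes = axes),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$dim, "D, ",
      paste(sprintf("[%g, %g] by %g (%d nodes)", x$min, x$max, x$spacing,
                    x$n_nodes), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Well-tempered gridded bias
#'
#' The central artifact of a metadynamics run: the time-dependent bias
#' B_t(s) tabulated on a grid, together with its hyperparameters — the
#' per-dimension Gaussian width `sigma`, the initial height increment
#' `height` (A, in k_B*T), and the tempering temperature `delta_T`
#' (in units of the simulation temperature; since energies are in k_B*T,
#' this is also k_B*delta_T in energy units). B starts identically zero and
#' only ever grows; with tempering, successive deposits at an already-biased
#' point shrink exponentially, which is what makes B converge to
#' -delta_T/(T+delta_T) times the free energy rather than oscillate.
#'
#' @param grid a [grid_spec()].
#' @param sigma per-dimension Gaussian width (same length as grid dim).
#' @param height initial Gaussian height increment A, k_B*T (> 0).
#' @param delta_T tempering temperature in units of T (> 0). delta_T -> 0 is
#'   the unbiased limit (represented by not depositing, not by this object);
#'   delta_T -> Inf approaches untempered, constant-height deposition.
#' @return an object of class `gridded_bias`.
#' @export
gridded_bias <- function(grid, sigma, height, delta_T) {
  stopifnot(inherits(grid, "grid_spec"))
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L && grid$dim == 2L) sigma <- rep(sigma, 2L)
  stopifnot(length(sigma) == grid$dim)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (height <= 0) stop("height increment A must be positive", call. = FALSE)
  if (delta_T <= 0) {
    stop("delta_T must be positive; the unbiased limit is represented by ",
         "disabling deposition, not delta_T = 0", call. = FALSE)
  }
  bad <- grid$spacing > sigma / 5 + 1e-12
  if (any(bad)) {
    stop("grid spacing must be at most sigma/5 in every biased dimension ",
         "(dimension ", paste(which(bad), collapse = ", "), " violates the rule)",
         call. = FALSE)
  }
  values <- if (grid$dim == 1L) {
    numeric(grid$n_nodes[1])
  } else {
    matrix(0, grid$n_nodes[1], grid$n_nodes[2])
  }
  structure(list(grid = grid, values = values, sigma = sigma,
                 height = height, delta_T = delta_T,
                 deposits_made = 0L, cycles_elapsed = 0L),
            class = "gridded_bias")
}

#' @export
print.gridded_bias <- function(x, ...) {
  cat("<gridded_bias> ", x$grid$dim, "D, sigma = ",
      paste(x$sigma, collapse = ", "), ", A = ", x$height,
      " kT, delta_T = ", x$delta_T, " T; ", x$deposits_made,
      " deposits over ", x$cycles_elapsed, " cycles; max B = ",
      signif(max(x$values), 4), " kT\n", sep = "")
  invisible(x)
}

clamp_point <- function(bias, s) {
  pmin(pmax(s, bias$grid$min), bias$grid$max)
}

#' Interpolated bias value
#'
#' Linear (1D) or bilinear (2D) interpolation of the tabulated bias; exact
#' at grid nodes. Query points are clamped into the grid domain.
#'
#' @param bias a [gridded_bias()].
#' @param s CV point (numeric of length dim) or a matrix with one row per point.
#' @return numeric vector of bias values, k_B*T.
#' @export
bias_evaluate <- function(bias, s) {
  g <- bias$grid
  pts <- if (is.matrix(s)) s else matrix(s, ncol = g$dim, byrow = g$dim > 1L)
  if (g$dim == 1L && !is.matrix(s)) pts <- matrix(s, ncol = 1L)
  n <- nrow(pts)
  out <- numeric(n)
  if (g$dim == 1L) {
    x <- pmin(pmax(pts[, 1], g$min[1]), g$max[1])
    u <- (x - g$min[1]) / g$spacing[1]
    i0 <- pmin(floor(u), g$n_nodes[1] - 2)
    f <- u - i0
    out <- (1 - f) * bias$values[i0 + 1] + f * bias$values[i0 + 2]
  } else {
    x <- pmin(pmax(pts[, 1], g$min[1]), g$max[1])
    y <- pmin(pmax(pts[, 2], g$min[2]), g$max[2])
    ux <- (x - g$min[1]) / g$spacing[1]
    uy <- (y - g$min[2]) / g$spacing[2]
    i0 <- pmin(floor(ux), g$n_nodes[1] - 2)
    j0 <- pmin(floor(uy), g$n_nodes[2] - 2)
    fx <- ux - i0; fy <- uy - j0
    v00 <- bias$values[cbind(i0 + 1, j0 + 1)]
    v10 <- bias$values[cbind(i0 + 2, j0 + 1)]
    v01 <- bias$values[cbind(i0 + 1, j0 + 2)]
    v11 <- bias$values[cbind(i0 + 2, j0 + 2)]
    out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
  }
  out
}

#' Current well-tempered deposit amplitude at a CV point
#'
#' w_t = A * exp(-B_t(s) / delta_T), with B_t and delta_T both in k_B*T
#' units (beta = 1). Equal to A on a fresh bias; strictly decreasing in the
#' accumulated bias, which is the tempering mechanism. The bias is read by
#' interpolation at `s`, the same value the walker feels, not the nearest
#' node.
#'
#' @param bias a [gridded_bias()].
#' @param s CV point (clamped into the grid domain).
#' @return scalar amplitude in (0, A].
#' @export
well_tempered_amplitude <- function(bias, s) {
  bias$height * exp(-bias_eval_point(bias, clamp_point(bias, s)) / bias$delta_T)
}

#' Deposit one tempered Gaussian
#'
#' Adds w_t * exp(-sum_d (s_d - s_t,d)^2 / (2 sigma_d^2)) to every node
#' within the 5-sigma truncation window around the deposit centre `s_t`
#' (beyond it the Gaussian is below e^-12.5 and nodes are untouched).
#' Deposits near an edge lose the mass that falls outside the grid — the
#' domain should generously cover the reachable CV range; a warning fires
#' when more than about 1% of the Gaussian's mass lies outside.
#'
#' @param bias a [gridded_bias()].
#' @param s_t CV point of the deposit (clamped into the domain).
#' @param warn_edge logical; warn on substantial mass loss outside the grid.
#' @return the updated `gridded_bias` (deposits_made incremented).
#' @export
deposit <- function(bias, s_t, warn_edge = TRUE) {
  g <- bias$grid
  s_t <- clamp_point(bias, s_t)
  w <- well_tempered_amplitude(bias, s_t)
  trunc_r <- 5 * bias$sigma
  if (warn_edge &&
      any(s_t - g$min < 2.33 * bias$sigma | g$max - s_t < 2.33 * bias$sigma)) {
    warning("deposit centre within 2.33 sigma of the grid edge: >1% of its ",
            "mass falls outside the grid and is lost", call. = FALSE)
  }
  if (g$dim == 1L) {
    ax <- g$axes[[1]]
    idx <- which(abs(ax - s_t[1]) <= trunc_r[1])
    bias$values[idx] <- bias$values[idx] +
      w * exp(-(ax[idx] - s_t[1])^2 / (2 * bias$sigma[1]^2))
  } else {
    ax <- g$axes[[1]]; ay <- g$axes[[2]]
    ix <- which(abs(ax - s_t[1]) <= trunc_r[1])
    iy <- which(abs(ay - s_t[2]) <= trunc_r[2])
    gx <- exp(-(ax[ix] - s_t[1])^2 / (2 * bias$sigma[1]^2))
    gy <- exp(-(ay[iy] - s_t[2])^2 / (2 * bias$sigma[2]^2))
    bias$values[ix, iy] <- bias$values[ix, iy] + w * outer(gx, gy)
  }
  bias$deposits_made <- bias$deposits_made + 1L
  bias
}

#' Bias force on the particles
#'
#' F = -(dB/ds) (ds/dq): the bias derivative along each CV component comes
#' from central differences of the interpolated bias at one grid spacing,
#' chained through the CV gradient (analytic where the CV provides one,
#' otherwise central finite differences of the CV itself).
#'
#' @param bias a [gridded_bias()].
#' @param config a [particle_config()].
#' @param cv a [collective_variable()] of matching dimensionality.
#' @param topo optional topology forwarded to the CV.
#' @param allow_fd_gradient permit the finite-difference CV fallback.
#' @return n x 3 matrix of forces, k_B*T per length unit.
#' @export
bias_force <- function(bias, config, cv, topo = NULL,
                       allow_fd_gradient = TRUE) {
  if (cv$dim != bias$grid$dim) {
    stop("CV dimensionality (", cv$dim, ") does not match the bias grid (",
         bias$grid$dim, ")", call. = FALSE)
  }
  s <- cv$value(config, topo)
  dBds <- bias_gradient_s(bias, s)
  if (all(dBds == 0)) return(matrix(0, n_particles(config), 3L))
  # fast paths for the two CVs used in inner sampling loops
  if (identical(cv$name, "coordinate")) {
    f <- matrix(0, n_particles(config), 3L)
    f[1, seq_len(cv$dim)] <- -dBds
    return(f)
  }
  if (identical(cv$name, "com_distance")) {
    ga <- resolve_group_ref(cv$groups$group_a, topo)
    gb <- resolve_group_ref(cv$groups$group_b, topo)
    na <- length(ga); nb <- length(gb)
    ca <- .colMeans(config$positions[ga, , drop = FALSE], na, 3L)
    cb <- .colMeans(config$positions[gb, , drop = FALSE], nb, 3L)
    d <- ca - cb
    r <- sqrt(sum(d * d))
    f <- matrix(0, n_particles(config), 3L)
    if (r > 1e-12) {
      pull <- dBds[1] * d / r
      f[ga, ] <- matrix(-pull / na, na, 3L, byrow = TRUE)
      f[gb, ] <- f[gb, ] + matrix(pull / nb, nb, 3L, byrow = TRUE)
    }
    return(f)
  }
  grads <- if (!is.null(cv$gradient)) {
    cv$gradient(config, topo)
  } else if (allow_fd_gradient) {
    cv_gradient_fd(cv, config, topo)
  } else {
    stop("CV '", cv$name, "' has no analytic gradient and the ",
         "finite-difference fallback is disabled", call. = FALSE)
  }
  f <- matrix(0, n_particles(config), 3L)
  for (d in seq_len(cv$dim)) f <- f - dBds[d] * grads[[d]]
  f
}

# fast scalar interpolation, no input massaging (s already a numeric point)
bias_eval_point <- function(bias, s) {
  g <- bias$grid
  if (g$dim == 1L) {
    x <- s[1]
    if (x < g$min[1]) x <- g$min[1] else if (x > g$max[1]) x <- g$max[1]
    u <- (x - g$min[1]) / g$spacing[1]
    i0 <- floor(u)
    if (i0 > g$n_nodes[1] - 2) i0 <- g$n_nodes[1] - 2
    f <- u - i0
    (1 - f) * bias$values[i0 + 1] + f * bias$values[i0 + 2]
  } else {
    x <- s[1]; y <- s[2]
    if (x < g$min[1]) x <- g$min[1] else if (x > g$max[1]) x <- g$max[1]
    if (y < g$min[2]) y <- g$min[2] else if (y > g$max[2]) y <- g$max[2]
    ux <- (x - g$min[1]) / g$spacing[1]
    uy <- (y - g$min[2]) / g$spacing[2]
    i0 <- floor(ux); j0 <- floor(uy)
    if (i0 > g$n_nodes[1] - 2) i0 <- g$n_nodes[1] - 2
    if (j0 > g$n_nodes[2] - 2) j0 <- g$n_nodes[2] - 2
    fx <- ux - i0; fy <- uy - j0
    v <- bias$values
    (1 - fx) * (1 - fy) * v[i0 + 1, j0 + 1] + fx * (1 - fy) * v[i0 + 2, j0 + 1] +
      (1 - fx) * fy * v[i0 + 1, j0 + 2] + fx * fy * v[i0 + 2, j0 + 2]
  }
}

# dB/ds at point s by central differences of the interpolated bias.
# Grid fields are pulled into locals once; the interpolation is inlined for
# the 2 (1D) or 4 (2D) probe points of the stencil.
bias_gradient_s <- function(bias, s) {
  g <- bias$grid
  v <- bias$values
  gmin <- g$min; gmax <- g$max; dx <- g$spacing; nn <- g$n_nodes
  if (g$dim == 1L) {
    x <- s[1]
    if (x < gmin) x <- gmin else if (x > gmax) x <- gmax
    ev <- function(p) {
      u <- (p - gmin) / dx
      i0 <- floor(u); if (i0 > nn - 2) i0 <- nn - 2
      f <- u - i0
      (1 - f) * v[i0 + 1] + f * v[i0 + 2]
    }
    xp <- min(x + dx, gmax); xm <- max(x - dx, gmin)
    if (xp == xm) return(0)
    (ev(xp) - ev(xm)) / (xp - xm)
  } else {
    x <- s[1]; y <- s[2]
    if (x < gmin[1]) x <- gmin[1] else if (x > gmax[1]) x <- gmax[1]
    if (y < gmin[2]) y <- gmin[2] else if (y > gmax[2]) y <- gmax[2]
    ev <- function(px, py) {
      ux <- (px - gmin[1]) / dx[1]; uy <- (py - gmin[2]) / dx[2]
      i0 <- floor(ux); if (i0 > nn[1] - 2) i0 <- nn[1] - 2
      j0 <- floor(uy); if (j0 > nn[2] - 2) j0 <- nn[2] - 2
      fx <- ux - i0; fy <- uy - j0
      (1 - fx) * (1 - fy) * v[i0 + 1, j0 + 1] + fx * (1 - fy) * v[i0 + 2, j0 + 1] +
        (1 - fx) * fy * v[i0 + 1, j0 + 2] + fx * fy * v[i0 + 2, j0 + 2]
    }
    out <- numeric(2L)
    xp <- min(x + dx[1], gmax[1]); xm <- max(x - dx[1], gmin[1])
    if (xp > xm) out[1] <- (ev(xp, y) - ev(xm, y)) / (xp - xm)
    yp <- min(y + dx[2], gmax[2]); ym <- max(y - dx[2], gmin[2])
    if (yp > ym) out[2] <- (ev(x, yp) - ev(x, ym)) / (yp - ym)
    out
  }
}

#' Free energy implied by the converged bias
#'
#' At long times the well-tempered bias converges to
#' -delta_T/(T + delta_T) times the free energy projected on the CV, so
#' Delta G_implied(s) = -(T + delta_T)/delta_T * B(s), min-shifted to 0.
#' T + delta_T is the effective temperature felt along the CV.
#'
#' @param bias a [gridded_bias()].
#' @return tibble with node coordinates (`s` or `s1`,`s2`) and `delta_G`
#'   (k_B*T, minimum exactly 0).
#' @export
implied_free_energy <- function(bias) {
  if (all(bias$values == 0)) {
    warning("bias is identically zero ('bias not yet converged'): implied ",
            "free energy is all zero", call. = FALSE)
  }
  scale <- (1 + bias$delta_T) / bias$delta_T
  dg <- -scale * bias$values
  dg <- dg - min(dg)
  g <- bias$grid
  out <- if (g$dim == 1L) {
    tibble::tibble(s = g$axes[[1]], delta_G = as.numeric(dg))
  } else {
    tidyr::expand_grid(s2 = g$axes[[2]], s1 = g$axes[[1]]) |>
      dplyr::select("s1", "s2") |>
      dplyr::mutate(delta_G = as.numeric(dg))
  }
  out$se <- NA_real_
  out$n_samples <- NA_integer_
  out$empty <- FALSE
  class(out) <- c("free_energy_profile", class(out))
  out
}

# ---- Persistence ------------------------------------------------------------

BIAS_FORMAT_VERSION <- "1.0"

#' Write a bias grid to a self-describing text file
#'
#' Versioned, diff-able, language-neutral layout: a `# key: value` header
#' (format version, dimensionality, axes, sigma, A, delta_T, counters)
#' followed by node values in row-major order, one per line, at full double
#' precision.
#'
#' @param bias a [gridded_bias()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bias <- function(bias, path) {
  g <- bias$grid
  hdr <- c(
    paste0("# metadyn-bias-format: ", BIAS_FORMAT_VERSION),
    paste0("# dim: ", g$dim),
    paste0("# min: ", paste(format(g$min, digits = 17), collapse = " ")),
    paste0("# max: ", paste(format(g$max, digits = 17), collapse = " ")),
    paste0("# spacing: ", paste(format(g$spacing, digits = 17), collapse = " ")),
    paste0("# sigma: ", paste(format(bias$sigma, digits = 17), collapse = " ")),
    paste0("# height: ", format(bias$height, digits = 17)),
    paste0("# delta_T: ", format(bias$delta_T, digits = 17)),
    paste0("# deposits_made: ", bias$deposits_made),
    paste0("# cycles_elapsed: ", bias$cycles_elapsed)
  )
  vals <- if (g$dim == 1L) bias$values else as.numeric(t(bias$values))
  writeLines(c(hdr, format(vals, digits = 17, trim = TRUE, scientific = TRUE)),
             path)
  invisible(path)
}

#' Read a bias grid written by [write_bias()]
#'
#' @param path input file path.
#' @return a [gridded_bias()], bit-identical to the one written.
#' @export
read_bias <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  get_field <- function(key, required = TRUE) {
    pat <- paste0("^# ", key, ": ")
    hit <- grep(pat, hdr_lines, value = TRUE)
    if (length(hit) != 1L) {
      if (required) stop("corrupted bias file header: missing '", key, "' (",
                         path, ")", call. = FALSE)
      return(NULL)
    }
    sub(pat, "", hit)
  }
  ver <- get_field("metadyn-bias-format")
  if (!identical(ver, BIAS_FORMAT_VERSION)) {
    major <- function(v) strsplit(v, ".", fixed = TRUE)[[1]][1]
    if (is.na(ver) || !identical(major(ver), major(BIAS_FORMAT_VERSION))) {
      stop("bias file format version ", ver, " is incompatible with ",
           BIAS_FORMAT_VERSION, call. = FALSE)
    }
    message("bias file written by format version ", ver,
            "; migrated to ", BIAS_FORMAT_VERSION)
  }
  dim <- as.integer(get_field("dim"))
  num <- function(key) as.numeric(strsplit(get_field(key), " +")[[1]])
  g <- grid_spec(num("min"), num("max"), num("spacing"))
  if (g$dim != dim) {
    stop("bias file declares dimensionality ", dim,
         " but its axes describe a ", g$dim, "D grid", call. = FALSE)
  }
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  if (length(vals) != prod(g$n_nodes)) {
    stop("bias file has ", length(vals), " node values; grid requires ",
         prod(g$n_nodes), call. = FALSE)
  }
  bias <- gridded_bias(g, sigma = num("sigma"),
                       height = as.numeric(get_field("height")),
                       delta_T = as.numeric(get_field("delta_T")))
  bias$values <- if (dim == 1L) vals else {
    t(matrix(vals, g$n_nodes[2], g$n_nodes[1]))
  }
  bias$deposits_made <- as.integer(get_field("deposits_made"))
  bias$cycles_elapsed <- as.integer(get_field("cycles_elapsed"))
  bias
}
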