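#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metadynamics result into its CV trace
#'
#' @param x a `metad_result` from [metad_run()].
#' @param ... unused.
#' @return the per-cycle walker trace tibble.
#' @export
tidy.metad_result <- function(x, ...) x$trace

#' One-row summary of a metadynamics run
#'
#' @param x a `metad_result`.
#' @param ... unused.
#' @return tibble: walkers, cycles, deposits, max bias, clamp events.
#' @export
glance.metad_result <- function(x, ...) {
  tibble::tibble(
    n_walkers = length(x$configs),
    n_cycles = x$bias$cycles_elapsed,
    deposits_made = x$bias$deposits_made,
    max_bias = max(x$bias$values),
    clamp_events = x$clamp_events
  )
}

#' Tidy a gridded bias into a node table
#'
#' @param x a [gridded_bias()].
#' @param ... unused.
#' @return tibble with node coordinates and `bias` (k_B*T).
#' @export
tidy.gridded_bias <- function(x, ...) {
  g <- x$grid
  if (g$dim == 1L) {
    tibble::tibble(s = g$axes[[1]], bias = as.numeric(x$values))
  } else {
    tidyr::expand_grid(s2 = g$axes[[2]], s1 = g$axes[[1]]) |>
      dplyr::select("s1", "s2") |>
      dplyr::mutate(bias = as.numeric(x$values))
  }
}

#' @export
glance.gridded_bias <- function(x, ...) {
  tibble::tibble(dim = x$grid$dim, n_nodes = prod(x$grid$n_nodes),
                 sigma = paste(x$sigma, collapse = ","),
                 height = x$height, delta_T = x$delta_T,
                 deposits_made = x$deposits_made,
                 cycles_elapsed = x$cycles_elapsed,
                 max_bias = max(x$values))
}

#' Plot a free-energy profile
#'
#' 1D: Delta G against the CV with replica standard-error ribbon where
#' available; 2D: filled contours of Delta G.
#'
#' @param object a `free_energy_profile` from [histogram_free_energy()] or
#'   [implied_free_energy()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$empty)
  if ("s" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$delta_G))
    if (any(!is.na(df$se))) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$delta_G - .data$se,
                     ymax = .data$delta_G + .data$se),
        alpha = 0.25)
    }
    p + ggplot2::geom_line() +
      ggplot2::labs(x = "collective variable",
                    y = expression(Delta * G ~ "(" * k[B] * T * ")"))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2,
                                     z = .data$delta_G)) +
      ggplot2::geom_contour_filled(bins = 12) +
      ggplot2::labs(x = "CV 1", y = "CV 2",
                    fill = expression(Delta * G ~ "(" * k[B] * T * ")"))
  }
}

#' Plot a gridded bias
#'
#' @param object a [gridded_bias()].
#' @param ... unused.
#' @return a ggplot of the tabulated bias.
#' @export
autoplot.gridded_bias <- function(object, ...) {
  df <- tidy(object)
  if ("s" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$bias)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "collective variable",
                    y = expression(B[t] ~ "(" * k[B] * T * ")"))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2,
                                     fill = .data$bias)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "CV 1", y = "CV 2",
                    fill = expression(B[t] ~ "(" * k[B] * T * ")"))
  }
}

#' Plot a 2D KDE landscape
#'
#' @param object output of [kde_landscape_2d()].
#' @param what "neg_log_density" (free-energy-like) or "density".
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_kde_landscape <- function(object, what = c("neg_log_density", "density"),
                               ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s1, y = .data$s2,
                                       fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = if (what == "density") 1 else -1) +
    ggplot2::labs(x = "CV 1", y = "CV 2", fill = what,
                  caption = attr(object, "caveat"))
}
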