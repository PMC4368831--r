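#' Plot a planar landscape
#'
#' Raster rendering of a 2-D landscape slice or projection (quasi-potential
#' or finite-volume \eqn{-\ln \hat P}).
#'
#' @param object a planar \code{landscape_grid}.
#' @param ... unused.
#' @param trim upper quantile at which to clip S for display contrast.
#' @return a ggplot object.
#' @export
autoplot.landscape_grid <- function(object, ..., trim = 0.98) {
  free <- which(lengths(object$axes) > 1L)
  if (length(free) != 2L)
    stop("autoplot draws planar landscapes; use landscape_slice() or min_project() first")
  df <- tidy.landscape_grid(object)
  nm <- names(object$axes)[free]
  cap <- quantile(df$S, trim, na.rm = TRUE)
  df$S <- pmin(df$S, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                   fill = .data$S)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "S")
}

#' Plot a trajectory
#'
#' Time courses of the three module variables.
#'
#' @param object a \code{cc_trajectory} from \code{\link{cc_integrate}}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cc_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("x", "y", "z"),
                            names_to = "variable", values_to = "concentration")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$concentration,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration")
}

#' Plot a minimized transition path
#'
#' @param object a \code{curve_path}.
#' @param vars which two coordinates to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.curve_path <- function(object, vars = c("x", "y"), ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[vars[1]]], y = .data[[vars[2]]])) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = df[c(1, nrow(df)), ], size = 2)
}

#' Plot the pseudo-landscape tangential potential
#'
#' Tangential potential T(s) against arc length, annotated with the local
#' driving-force strength.
#'
#' @param object a \code{pseudo_landscape}.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pseudo_landscape <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$arclength)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$tangential)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$speed), linetype = "dashed",
                       colour = "red") +
    ggplot2::labs(x = "arc length from P2", y = "T(s) (solid), |b| (dashed)")
}

#' @importFrom rlang .data
NULL
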