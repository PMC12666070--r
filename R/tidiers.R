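#' Tidy a registration result
#'
#' One row per pose parameter: the three z-y-x Euler angles (degrees) and
#' the three translation components, in the frame the solver ran in.
#'
#' @param x a `registration_result`.
#' @param ... unused.
#' @return a tibble with `term` and `estimate` columns.
#' @export
tidy.registration_result <- function(x, ...) {
  ang <- euler_zyx(x$transform$rotation)
  tibble::tibble(
    term = c("yaw_deg", "pitch_deg", "roll_deg", "tx", "ty", "tz"),
    estimate = c(ang, x$transform$translation))
}

#' @rdname tidy.registration_result
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations,
                 final_residual = x$final_residual,
                 converged = x$converged,
                 n_correspondences = if (is.null(x$correspondences)) NA_integer_
                                     else length(x$correspondences),
                 flag = x$flag)
}

#' @export
tidy.benchmark_run <- function(x, ...) x$summary

#' @export
glance.benchmark_run <- function(x, ...) {
  tibble::tibble(n_pairs = length(unique(x$metrics$pair_id)),
                 n_methods = length(unique(x$metrics$method)),
                 n_failures = length(x$failures))
}

#' Plot a benchmark pair
#'
#' Orthographic projection of the complete source cloud and the partial,
#' perturbed target, with the TRE landmarks overlaid.
#'
#' @param object a `pair_record`.
#' @param axes which two coordinate axes to project onto.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pair_record <- function(object, axes = c(1, 2), ...) {
  ax <- axes[1:2]
  lab <- c("x", "y", "z")
  df <- dplyr::bind_rows(
    tibble::tibble(u = object$source$points[, ax[1]],
                   v = object$source$points[, ax[2]], cloud = "source (complete)"),
    tibble::tibble(u = object$target$points[, ax[1]],
                   v = object$target$points[, ax[2]], cloud = "target (partial)"))
  lm <- tibble::tibble(u = object$landmarks_source[, ax[1]],
                       v = object$landmarks_source[, ax[2]])
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$v, colour = .data$cloud)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_point(data = lm, colour = "black", shape = 4, size = 2,
                        inherit.aes = FALSE,
                        mapping = ggplot2::aes(.data$u, .data$v)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[ax[1]], y = lab[ax[2]], colour = NULL,
                  title = sprintf("pair seed %d (crop %g%%)", object$seed,
                                  100 * object$provenance$crop_ratio)) +
    ggplot2::theme_minimal()
}

#' Plot benchmark metrics across partiality levels
#'
#' @param object a `benchmark_run`.
#' @param metric which metric to plot (`"tre"`, `"mae_r"` or `"mae_t"`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.benchmark_run <- function(object, metric = c("tre", "mae_r", "mae_t"), ...) {
  metric <- match.arg(metric)
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  ylab <- c(tre = "TRE (mm)", mae_r = "MAE(R) (deg)", mae_t = "MAE(t) (mm)")[metric]
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$crop_ratio, .data[[mcol]],
                                   colour = .data$method, group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                          ymax = .data[[mcol]] + .data[[scol]])) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%g%%", 100 * x)) +
    ggplot2::labs(x = "partiality (crop ratio)", y = ylab, colour = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
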