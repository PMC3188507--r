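#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a membrane or cytosol trajectory into long format
#'
#' @param x A `bcr_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `theta`, `K`, `R`.
#' @method tidy bcr_trajectory
#' @export
tidy.bcr_trajectory <- function(x, ...) {
  nt <- length(x$times); ns <- length(x$theta)
  tibble::tibble(
    time = rep(x$times, times = ns),
    theta = rep(x$theta, each = nt),
    K = as.vector(x$K),
    R = as.vector(x$R)
  )
}

#' One-row summary of a trajectory
#'
#' @param x A `bcr_trajectory`.
#' @param ... Unused.
#' @return A tibble with activation outcome, activation time, final kinase
#'   extrema and the run configuration scalars.
#' @method glance bcr_trajectory
#' @export
glance.bcr_trajectory <- function(x, ...) {
  K_end <- x$K[nrow(x$K), ]
  tibble::tibble(
    activated = !is.na(x$activation_time),
    activation_time = x$activation_time,
    threshold = x$threshold,
    K_min_final = min(K_end),
    K_max_final = max(K_end),
    alpha = x$params$alpha,
    b = x$b,
    F = x$dist$F,
    i = x$dist$i
  )
}

#' Tidy a steady-state set
#'
#' @param x A `steady_state_set`.
#' @param ... Unused.
#' @return The underlying tibble (columns `K`, `R`, `stable`).
#' @method tidy steady_state_set
#' @export
tidy.steady_state_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a bistability range
#'
#' @param x A `bistability_range`.
#' @param ... Unused.
#' @return A one-row tibble with `b_min`, `b_max`, `receptor_level`, `empty`.
#' @method tidy bistability_range
#' @export
tidy.bistability_range <- function(x, ...) {
  tibble::tibble(b_min = x$b_min, b_max = x$b_max,
                 receptor_level = x$receptor_level, empty = x$empty)
}

#' Plot kinase snapshots of a trajectory
#'
#' Kinase activity against polar angle at a selection of saved times, the
#' standard way to visualize the traveling activation front.
#'
#' @param object A `bcr_trajectory`.
#' @param times Times to draw (nearest saved frames); defaults to eight
#'   frames spanning the run.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcr_trajectory
#' @export
autoplot.bcr_trajectory <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- object$times[unique(pmax(1, round(seq(1, length(object$times),
                                                   length.out = 8))))]
  idx <- vapply(times, function(t) which.min(abs(object$times - t)),
                integer(1))
  df <- tidy.bcr_trajectory(object)
  df <- df[df$time %in% object$times[idx], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$K,
                                   colour = factor(round(.data$time, 2)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "polar angle (rad)", y = "active kinase K",
                  colour = "time") +
    ggplot2::ylim(0, 1)
}

#' Plot a critical-fraction sweep
#'
#' `F_crit` against the surface fraction `1/i` on log-log axes, one line per
#' `(model_tier, alpha, r_n)` configuration.
#'
#' @param object A `sweep_table` with `F_crit` rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_table
#' @export
autoplot.sweep_table <- function(object, ...) {
  df <- object[!is.na(object$F_crit), ]
  df$config <- interaction(df$model_tier, df$alpha, df$r_n, drop = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 / .data$i, y = .data$F_crit,
                                   colour = .data$config)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster surface fraction 1/i",
                  y = "critical aggregated fraction F_crit",
                  colour = "tier.alpha.r_n")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
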