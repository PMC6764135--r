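#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the restricted log-likelihood trace of a REML fit
#'
#' @param object a `reml_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.reml_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$logL_trace) - 1,
                       logL = object$logL_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$logL)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "restricted log-likelihood",
                  title = sprintf("REML convergence (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a mating grid, highlighting a plan
#'
#' Scatter of expected progeny breeding value against expected total
#' genetic value over all candidate matings; pairs selected in `plan` (if
#' given) are highlighted. The vertical spread at a given `u_hat` is the
#' dominance (mate-specific) component that allocation on total genetic
#' value exploits.
#'
#' @param object a `mating_grid`
#' @param plan optional `mating_plan`
#' @param max_points subsample cap for very large grids
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mating_grid <- function(object, plan = NULL, max_points = 20000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  pl <- ggplot2::ggplot(df, ggplot2::aes(.data$u_hat, .data$g_hat)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4, colour = "grey40") +
    ggplot2::labs(x = "expected progeny breeding value (u)",
                  y = "expected progeny total genetic value (g)") +
    ggplot2::theme_minimal()
  if (!is.null(plan)) {
    sel <- tibble::as_tibble(plan)[, c("u_hat", "g_hat")]
    pl <- pl + ggplot2::geom_point(data = sel, colour = "firebrick",
                                   size = 0.6)
  }
  pl
}

#' Plot expected gains of competing mating plans
#'
#' Bar chart of `Delta_U` and `Delta_G` (genetic-SD units) for plans
#' optimised on breeding value versus total genetic value.
#'
#' @param object a `run_report`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.run_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$gains[, c("plan", "delta_U_sd", "delta_G_sd")],
                            cols = c("delta_U_sd", "delta_G_sd"),
                            names_to = "measure", values_to = "gain")
  df$measure <- ifelse(df$measure == "delta_U_sd", "Delta U", "Delta G")
  ggplot2::ggplot(df, ggplot2::aes(.data$plan, .data$gain, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "allocation objective", y = "expected gain (genetic SD)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
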