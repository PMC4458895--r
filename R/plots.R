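# ggplot2 autoplot methods for the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs theme_minimal scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a two-state denaturation fit
#'
#' @param object A `two_state_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.two_state_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$denaturant_M)) +
    geom_point(aes(y = .data$signal)) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    labs(x = "[urea] (M)", y = "signal",
         title = sprintf("m = %.2f kcal mol⁻¹ M⁻¹, D50 = %.2f M, ΔG = %.2f kcal/mol",
                         object$m, object$d50, object$dG)) +
    theme_minimal()
}

#' Plot a chevron fit
#'
#' @param object A `chevron_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.chevron_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$denaturant_M)) +
    geom_point(aes(y = .data$kobs_s)) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    scale_y_log10() +
    labs(x = "[urea] (M)", y = expression(k[obs] ~ (s^-1)),
         title = sprintf("%s model", object$model)) +
    theme_minimal()
}

#' Plot a distance histogram with its Gaussian fit
#'
#' @param object A `distance_histogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  grid <- tibble(
    r = seq(min(object$bins$mid), max(object$bins$mid), length.out = 200)
  )
  grid$fit <- object$gauss_amplitude *
    exp(-(grid$r - object$gauss_mean)^2 / (2 * object$gauss_sd^2))
  ggplot(object$bins, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$bin_width, fill = "grey70", colour = "grey40") +
    geom_line(data = grid, aes(x = .data$r, y = .data$fit), colour = "firebrick") +
    labs(x = "distance (nm)", y = "count",
         title = sprintf("mean = %.1f nm (n = %d)", object$gauss_mean, object$n_pairs)) +
    theme_minimal()
}

#' Plot a force-extension trace with detected events
#'
#' @param object An `fx_trace` (or data frame with `extension_nm`,
#'   `force_pN`).
#' @param events Optional event table from [detect_events()] /
#'   [afm_analyze_trace()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fx_trace <- function(object, events = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$extension_nm, y = .data$force_pN)) +
    geom_line(colour = "grey40") +
    labs(x = "extension (nm)", y = "force (pN)") +
    theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + geom_point(data = as_tibble(events),
                        aes(colour = .data$is_detachment), size = 2)
  }
  p
}

#' Plot a pair-distance distribution
#'
#' @param object A `pair_distribution`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pair_distribution <- function(object, ...) {
  ggplot(tibble(r = object$r, p = object$p), aes(x = .data$r, y = .data$p)) +
    geom_line() +
    labs(x = "r (nm)", y = "P(r)",
         title = sprintf("Dmax = %.1f nm", object$Dmax)) +
    theme_minimal()
}

#' Plot a model scattering profile
#'
#' @param object A `scattering_profile`.
#' @param log_log Plot on log-log axes (default) or log-linear.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.scattering_profile <- function(object, log_log = TRUE, ...) {
  p <- ggplot(tibble(s = object$s, I = object$I), aes(x = .data$s, y = .data$I)) +
    geom_line() +
    scale_y_log10() +
    labs(x = expression(s ~ (nm^-1)), y = "I(s)") +
    theme_minimal()
  if (log_log) p <- p + ggplot2::scale_x_log10()
  p
}
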