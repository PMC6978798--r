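#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   facet_grid labs theme_minimal scale_x_log10
#' @export
ggplot2::autoplot

#' Plot a trace set
#'
#' Simulated sets are drawn as the three potentials per site; recorded sets
#' as trials (thin) with sites in facets.
#'
#' @param object a `trace_set`.
#' @param measures which potentials to show for simulated sets.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trace_set <- function(object, measures = c("V_m", "V_my", "V_mym"), ...) {
  df <- as_tibble(object)
  if ("V_m" %in% names(df)) {
    long <- tidyr::pivot_longer(df, cols = dplyr::any_of(measures),
                                names_to = "potential", values_to = "mV")
    ggplot(long, aes(x = .data$time, y = .data$mV, colour = .data$potential)) +
      geom_line() + facet_wrap(~site) +
      labs(x = "time (ms)", y = "potential (mV)") + theme_minimal()
  } else if ("trial" %in% names(df)) {
    ggplot(df, aes(x = .data$time, y = .data$v,
                   group = interaction(.data$trial, .data$level),
                   colour = factor(.data$level))) +
      geom_line(alpha = 0.3) + facet_wrap(~site) +
      labs(x = "time (ms)", y = "V (mV)", colour = "pA") + theme_minimal()
  } else {
    yvar <- intersect(c("v", "f"), names(df))[1]
    ggplot(df, aes(x = .data$time, y = .data[[yvar]],
                   colour = if ("level" %in% names(df)) factor(.data$level) else .data$site)) +
      geom_line() + facet_wrap(~site) +
      labs(x = "time (ms)", y = yvar, colour = NULL) + theme_minimal()
  }
}

#' Plot a latency profile
#'
#' Onset latency, peak amplitude and maximal rate of rise against path
#' distance, coloured by domain; per-internode latency maxima are marked.
#'
#' @param object a `latency_profile` from [spatial_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.latency_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("latency_ms", "peak_mV", "max_dvdt_V_s"),
                            names_to = "feature", values_to = "value")
  marks <- as_tibble(object)[object$is_internode_max, ]
  marks <- tibble(x_path = marks$x_path, value = marks$latency_ms,
                  feature = "latency_ms", kind = marks$kind)
  ggplot(df, aes(x = .data$x_path, y = .data$value, colour = .data$kind)) +
    geom_point(size = 0.8) +
    geom_point(data = marks, shape = 1, size = 2, colour = "black") +
    facet_wrap(~feature, scales = "free_y", ncol = 1) +
    labs(x = "path distance (um)", y = NULL) + theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' @param sweep output of [sensitivity_sweep()].
#' @param log_x log-scale the parameter axis (default TRUE).
#' @return A ggplot of CV against the swept value; points flagged for
#'   regenerative spiking are drawn open.
#' @export
plot_sweep <- function(sweep, log_x = TRUE) {
  p <- ggplot(sweep, aes(x = .data$value, y = .data$cv_m_s)) +
    geom_line() + geom_point(aes(shape = .data$regenerative), size = 2) +
    labs(x = unique(sweep$parameter), y = "conduction velocity (m/s)") +
    theme_minimal()
  if (log_x) p <- p + scale_x_log10()
  p
}

#' Plot a fit overlay
#'
#' Target traces with the best model solution superimposed.
#'
#' @param object a `fit_result`.
#' @param ... unused.
#' @return A ggplot faceted by site and injection level.
#' @export
autoplot.fit_result <- function(object, ...) {
  target <- object$problem$target
  model <- forward_model(object$problem, object$best$params)
  df <- dplyr::bind_rows(dplyr::mutate(target, which = "target"),
                         dplyr::mutate(model, which = "model"))
  ggplot(df, aes(x = .data$time, y = .data$v, colour = .data$which)) +
    geom_line(linewidth = 0.4) +
    facet_grid(site ~ level, scales = "free_y") +
    labs(x = "time (ms)", y = "V (mV)") + theme_minimal()
}
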