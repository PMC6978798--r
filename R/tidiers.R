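#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fit result
#'
#' One row per fitted parameter of the best solution, with its bounds.
#'
#' @param x a `fit_result` from [optimize_fit()].
#' @param ... unused.
#' @return A tibble: `parameter`, `estimate`, `low`, `high`, `transform`.
#' @export
tidy.fit_result <- function(x, ...) {
  b <- x$problem$bounds[x$problem$bounds$fit, ]
  tibble(parameter = b$parameter,
         estimate = vapply(b$parameter, function(nm) x$best$params[[nm]], numeric(1)),
         low = b$low, high = b$high, transform = b$transform)
}

#' @rdname tidy.fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble(circuit = x$problem$circuit, mse = x$best$error,
         exit = x$exit, generations = x$generations,
         n_traces = nrow(x$best$per_trace %||% tibble()),
         seed = x$seed)
}

#' @export
tidy.circuit_comparison <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.circuit_comparison <- function(x, ...) {
  tibble(best_mode = x$mode[1], best_error = x$error[1],
         n_modes = nrow(x))
}
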