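#' @keywords internal
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_lgl map2 pmap imap
#' @importFrom Rcpp sourceCpp
#' @useDynLib axoncable, .registration = TRUE
"_PACKAGE"

# unit conversions used across the solver; geometry is carried in um,
# electrical state in (mV, ms, nA, uS, nF)
UM_PER_CM <- 1e4
NM_PER_CM <- 1e7

check_positive <- function(..., .call = rlang::caller_env()) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("`%s` must be a positive finite number", nms[i]),
            call = .call)
    }
  }
  invisible(TRUE)
}

# lateral (membrane) area of a cylinder, cm^2; d and L in um
cyl_area_cm2 <- function(d_um, L_um) pi * (d_um / UM_PER_CM) * (L_um / UM_PER_CM)

`%||%` <- function(a, b) if (is.null(a)) b else a
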