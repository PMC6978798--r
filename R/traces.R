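#' Trace sets
#'
#' A `trace_set` is a tidy tibble of time series with a `time` column (ms),
#' a `site` label, and one or more measure columns: simulations carry the
#' three potentials `V_m`, `V_my`, `V_mym` (mV); recorded trial sets carry
#' `v` (mV) and a `trial` index; fluorescence sets carry `f` (arbitrary
#' units). Site geometry and protocol metadata travel in attributes and
#' survive the CSV round trip via a JSON sidecar.
#'
#' @param df the tidy data.
#' @param sites tibble describing the sites (label, section, path distance).
#' @param meta free-form list (sampling period, protocol, ground truth...).
#' @return A `trace_set`.
#' @export
new_trace_set <- function(df, sites = NULL, meta = list()) {
  out <- as_tibble(df)
  attr(out, "sites") <- if (!is.null(sites)) as_tibble(sites) else NULL
  attr(out, "meta") <- meta
  class(out) <- c("trace_set", class(out))
  out
}

#' @export
print.trace_set <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<trace_set> %d samples x %d site(s)%s\n",
              length(unique(x$time)), length(unique(x$site)),
              if (!is.null(x$trial)) sprintf(" x %d trial(s)", length(unique(x$trial))) else ""))
  NextMethod()
}

trace_sites <- function(ts) attr(ts, "sites")
trace_meta <- function(ts) attr(ts, "meta")

#' Write / read a trace set (CSV + JSON sidecar)
#'
#' @param ts a `trace_set`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @export
write_traces <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  side <- list(meta = attr(ts, "meta"))
  if (!is.null(attr(ts, "sites"))) {
    side$sites <- as.data.frame(attr(ts, "sites"))
  }
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidefile <- paste0(path, ".meta.json")
  sites <- NULL; meta <- list()
  if (file.exists(sidefile)) {
    side <- jsonlite::read_json(sidefile, simplifyVector = TRUE)
    meta <- side$meta %||% list()
    if (!is.null(side$sites)) sites <- as_tibble(side$sites)
  }
  new_trace_set(df, sites = sites, meta = meta)
}

# wide matrix (time x site) of one measure, plus the time vector
trace_matrix <- function(ts, measure = "V_m", site_order = NULL) {
  sites <- site_order %||% unique(ts$site)
  tt <- sort(unique(ts$time))
  m <- vapply(sites, function(s) {
    sub <- ts[ts$site == s, ]
    sub[[measure]][order(sub$time)]
  }, numeric(length(tt)))
  list(time = tt, m = matrix(m, ncol = length(sites),
                             dimnames = list(NULL, sites)))
}
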