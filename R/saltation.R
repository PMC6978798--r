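#' Onset latency of a deflection
#'
#' Time of the first crossing of a fraction (default one half) of the
#' peak deflection above baseline, linearly interpolated between samples.
#' The statistic is invariant to affine amplitude scaling of the trace.
#'
#' @param time sample times, ms.
#' @param v trace, mV (or any unit).
#' @param fraction fraction of the peak (default 0.5).
#' @param baseline baseline level; default the mean over `baseline_window`.
#' @param baseline_window time window (ms, length 2) used for the default
#'   baseline; default the first sample only.
#' @return Latency in ms.
#' @export
onset_latency <- function(time, v, fraction = 0.5, baseline = NULL,
                          baseline_window = NULL) {
  if (is.null(baseline)) {
    baseline <- if (is.null(baseline_window)) v[1] else
      mean(v[time >= baseline_window[1] & time <= baseline_window[2]])
  }
  dv <- v - baseline
  pk <- max(dv)
  if (pk <= 0) abort("no positive-going deflection above baseline")
  thr <- fraction * pk
  idx <- which(dv >= thr)[1]
  if (is.na(idx)) abort("threshold never crossed")
  if (idx == 1) return(time[1])
  # linear interpolation between the bracketing samples
  t0 <- time[idx - 1]; t1 <- time[idx]
  y0 <- dv[idx - 1]; y1 <- dv[idx]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Spatial profile of latency, amplitude and rate of rise
#'
#' Summarises a multi-site trace set (e.g. an [ap_clamp()] output) into a
#' per-position profile: onset latency (time to half-maximum), peak
#' amplitude above baseline, and maximum dV/dt. Per-internode latency
#' maxima are flagged; their interior position is the temporal-saltation
#' signature of the double cable.
#'
#' @param traces a `trace_set` with `V_m`; sites must carry path distances.
#' @param measure which potential to profile (default `"V_m"`).
#' @param fraction latency fraction (default 0.5).
#' @param min_peak_mV positions with peaks below this are dropped.
#' @param kinds domains kept in the profile; the default restricts to the
#'   axonal path so that position is monotone along one anatomical branch
#'   (dendritic sites share path distances with the axon and would corrupt
#'   a spatial profile).
#' @return A `latency_profile` tibble: `site`, `x_path`, `kind`,
#'   `latency_ms`, `peak_mV`, `max_dvdt_V_s`, `internode`,
#'   `is_internode_max`.
#' @export
spatial_profile <- function(traces, measure = "V_m", fraction = 0.5,
                            min_peak_mV = 0.5,
                            kinds = c("ais", "axon", "node", "paranode",
                                      "internode", "unmyelinated_end")) {
  st <- trace_sites(traces)
  if (is.null(st) || anyNA(st$x_path)) abort("traces lack site path distances")
  st <- st[st$kind %in% kinds, , drop = FALSE]
  if (nrow(st) < 3) abort("need >= 3 positions for a spatial profile")
  tm <- trace_matrix(traces, measure, site_order = st$site)
  dt <- tm$time[2] - tm$time[1]
  prof <- purrr::map_dfr(seq_len(nrow(st)), function(j) {
    v <- tm$m[, j]
    base <- v[1]
    pk <- max(v - base)
    lat <- if (pk >= min_peak_mV)
      onset_latency(tm$time, v, fraction, baseline = base) else NA_real_
    tibble(site = st$site[j], x_path = st$x_path[j], kind = st$kind[j],
           latency_ms = lat, peak_mV = pk,
           max_dvdt_V_s = max(central_deriv(v, dt)))
  })
  prof <- prof[order(prof$x_path), ]
  # tag internode membership and per-internode latency maxima
  prof$internode <- NA_integer_
  ino <- prof$kind == "internode"
  if (any(ino)) {
    brk <- cumsum(c(TRUE, diff(which(ino)) > 1))
    prof$internode[ino] <- brk
  }
  prof$is_internode_max <- FALSE
  for (g in unique(stats::na.omit(prof$internode))) {
    rows <- which(prof$internode == g & !is.na(prof$latency_ms))
    if (length(rows)) {
      prof$is_internode_max[rows[which.max(prof$latency_ms[rows])]] <- TRUE
    }
  }
  structure(prof, class = c("latency_profile", class(prof)))
}

#' Nodal latency advancement
#'
#' Temporal saltation statistic: the mean onset latency of the internodal
#' axolemma at `offset_um` on either side of a node, minus the latency at
#' the node itself. Positive values mean the node depolarises before its
#' internodal surround.
#'
#' @param profile a [spatial_profile()] result.
#' @param node_pos node path distance, um.
#' @param offset_um flank offset (default 5).
#' @return Advancement in ms.
#' @export
saltation_advancement <- function(profile, node_pos, offset_um = 5) {
  lat_at <- function(x) {
    ok <- !is.na(profile$latency_ms)
    if (!any(ok)) abort("profile has no defined latencies")
    xs <- profile$x_path[ok]
    if (x < min(xs) - offset_um || x > max(xs) + offset_um) {
      abort(sprintf("position %.1f um not covered by the profile", x))
    }
    stats::approx(xs, profile$latency_ms[ok], xout = x, rule = 2)$y
  }
  mean(c(lat_at(node_pos - offset_um), lat_at(node_pos + offset_um))) -
    lat_at(node_pos)
}

#' VSD calibration description
#'
#' @param k_mm axo-somatic steady-state attenuation length, mm
#'   (default 1.18).
#' @param V_step_soma_mV somatic amplitude of the calibration step, mV.
#' @param dF_cal fluorescence deflection of the calibration step at the
#'   imaged site.
#' @param x_mm path distance of the imaged site from the soma, mm.
#' @return A `vsd_calibration` list.
#' @export
vsd_calibration <- function(k_mm = 1.18, V_step_soma_mV, dF_cal, x_mm) {
  if (k_mm <= 0) abort("`k_mm` must be positive")
  if (dF_cal == 0) abort("`dF_cal` must be non-zero")
  structure(list(k_mm = k_mm, V_step_soma_mV = V_step_soma_mV,
                 dF_cal = dF_cal, x_mm = x_mm), class = "vsd_calibration")
}

#' Calibrate a fluorescence trace to membrane voltage
#'
#' The local amplitude of a somatically applied steady-state step is the
#' somatic amplitude attenuated by `exp(-x/k)`; dividing the fluorescence
#' by the calibration deflection and multiplying by that local voltage
#' yields millivolts, independent of the (unknown) optical gain. The
#' baseline maps to the resting potential.
#'
#' @param F_trace fluorescence values (baseline-subtracted or raw).
#' @param cal a [vsd_calibration()] sharing gain with the trace.
#' @param v_rest resting potential added back to the scaled deflection, mV.
#' @param baseline fluorescence baseline subtracted before scaling
#'   (default the first sample).
#' @return Voltage trace, mV.
#' @export
calibrate_vsd <- function(F_trace, cal, v_rest = -75, baseline = F_trace[1]) {
  v_local <- cal$V_step_soma_mV * exp(-cal$x_mm / cal$k_mm)
  (F_trace - baseline) * v_local / cal$dF_cal + v_rest
}

#' Action-potential features of a single trace
#'
#' @param time sample times, ms (>= 10 kHz sampling recommended for the
#'   rate-of-rise estimate).
#' @param v trace, mV.
#' @param baseline_window optional window for the baseline (ms, length 2).
#' @return Tibble: `peak_mV` (above baseline), `max_dvdt_V_s`, `onset_ms`.
#' @export
ap_features <- function(time, v, baseline_window = NULL) {
  base <- if (is.null(baseline_window)) v[1] else
    mean(v[time >= baseline_window[1] & time <= baseline_window[2]])
  if (max(v) - min(v) < .Machine$double.eps^0.5) {
    abort("constant trace: no deflection to characterise")
  }
  dt <- time[2] - time[1]
  tibble(peak_mV = max(v) - base,
         max_dvdt_V_s = max(central_deriv(v, dt)),
         onset_ms = onset_latency(time, v, 0.5, baseline = base))
}
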