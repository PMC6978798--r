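#' Voltage-gated channel models
#'
#' Channels follow Hodgkin-Huxley-style kinetics: each gate has forward and
#' backward rate functions drawn from three parametric families, an integer
#' power, and a shared Q10 temperature factor. The shipped defaults are
#' generic kinetics with field-typical voltage dependence; rate parameters
#' are fully config-exposed (including via a YAML schema) and are not a
#' reproduction of any published allosteric scheme.
#'
#' Rate families (`V` in mV, rates in 1/ms):
#' * `explinear`: `A (V - Vh) / (1 - exp(-(V - Vh)/k))`
#' * `exponential`: `A exp((V - Vh)/k)`
#' * `sigmoid`: `A / (1 + exp(-(V - Vh)/k))`
#'
#' @param name channel name.
#' @param gates list of gates; each `list(power =, alpha = rate_spec(...),
#'   beta = rate_spec(...))`.
#' @param erev reversal potential, mV.
#' @param q10 temperature coefficient (default 2.3).
#' @param T_ref temperature the rates are specified at, Celsius.
#' @return A `channel_model`.
#' @export
channel_model <- function(name, gates, erev, q10 = 2.3, T_ref = 23) {
  structure(list(name = name, gates = gates, erev = erev,
                 q10 = q10, T_ref = T_ref), class = "channel_model")
}

#' @rdname channel_model
#' @param form one of `"explinear"`, `"exponential"`, `"sigmoid"`.
#' @param A,Vh,k rate parameters (see family definitions).
#' @export
rate_spec <- function(form, A, Vh, k) {
  form_id <- match(form, c("explinear", "exponential", "sigmoid"))
  if (is.na(form_id)) abort(sprintf("unknown rate form: %s", form))
  list(form = form_id, A = A, Vh = Vh, k = k)
}

#' Default channel models
#'
#' Generic fast Na (m^3 h), delayed-rectifier K (n^4), slow
#' non-inactivating K (Kv7-like, m) and hyperpolarization-activated cation
#' (HCN, one gate) models. Reversals default to E_Na = +55 mV and
#' E_K = -85 mV; the HCN reversal is -45 mV.
#'
#' @return Named list of [channel_model()]s: `Nav`, `Kv1`, `Kv7`, `HCN`.
#' @export
default_channel_models <- function() {
  list(
    Nav = channel_model("Nav", erev = 55, gates = list(
      list(power = 3,
           alpha = rate_spec("explinear", 0.182, -38, 6),
           beta = rate_spec("explinear", -0.124, -38, -6)),
      list(power = 1,
           alpha = rate_spec("explinear", -0.015, -66, -6),
           beta = rate_spec("explinear", 0.015, -66, 6)))),
    Kv1 = channel_model("Kv1", erev = -85, gates = list(
      list(power = 4,
           alpha = rate_spec("explinear", 0.05, -45, 10),
           beta = rate_spec("exponential", 0.625, -55, -80)))),
    Kv7 = channel_model("Kv7", erev = -85, gates = list(
      list(power = 1,
           alpha = rate_spec("exponential", 0.0033, -30, 40),
           beta = rate_spec("exponential", 0.0033, -30, -20)))),
    HCN = channel_model("HCN", erev = -45, gates = list(
      list(power = 1,
           alpha = rate_spec("exponential", 0.001, -90, -10),
           beta = rate_spec("exponential", 0.001, -90, 10))))
  )
}

#' Read channel models from a declarative YAML file
#'
#' The schema mirrors [channel_model()]: a top-level map of channel names to
#' `{erev, q10, T_ref, gates: [{power, alpha: {form, A, Vh, k}, beta: ...}]}`.
#'
#' @param path YAML file.
#' @return Named list of [channel_model()]s.
#' @export
read_channel_models <- function(path) {
  doc <- yaml::read_yaml(path)
  purrr::imap(doc, function(ch, nm) {
    gates <- lapply(ch$gates, function(g) {
      list(power = g$power,
           alpha = rate_spec(g$alpha$form, g$alpha$A, g$alpha$Vh, g$alpha$k),
           beta = rate_spec(g$beta$form, g$beta$A, g$beta$Vh, g$beta$k))
    })
    channel_model(nm, gates, erev = ch$erev, q10 = ch$q10 %||% 2.3,
                  T_ref = ch$T_ref %||% 23)
  })
}

#' Per-domain peak conductance densities
#'
#' Densities in pS/um^2 per anatomical domain. The dendritic Na density is
#' a linear distance-dependent gradient from `dend_na` down to
#' `dend_na_distal` at the most distal dendritic point.
#'
#' @param ... per-domain overrides, e.g. `node = c(Nav = 45000, ...)`.
#' @return A tibble `domain`, `channel`, `density` (`channel_density_table`).
#' @export
channel_density_table <- function(...) {
  base <- list(
    ais = c(Nav = 40000, Kv1 = 1000, Kv7 = 200),
    soma = c(Nav = 650, Kv1 = 100, Kv7 = 20),
    dendrite = c(Nav = 600, Kv1 = 22, Kv7 = 30),
    dendrite_distal = c(Nav = 40),
    internode = c(HCN = 1, Nav = 2, Kv1 = 2, Kv7 = 0.1),
    paranode = c(HCN = 1, Nav = 2, Kv1 = 2, Kv7 = 0.1),
    node = c(Nav = 45000, Kv1 = 1000, Kv7 = 100),
    unmyelinated_end = c(Nav = 525, Kv1 = 380, Kv7 = 1))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  tbl <- purrr::imap_dfr(base, function(v, dom) {
    tibble(domain = dom, channel = names(v), density = unname(v))
  })
  if (any(tbl$density < 0)) abort("channel densities must be non-negative")
  structure(tbl, class = c("channel_density_table", class(tbl)))
}

#' Insert active conductances into a compartment graph
#'
#' Channels live on the axolemma only (core to periaxonal layer under
#' myelin, core to ground elsewhere); the myelin radial elements stay
#' passive. Requesting a `myelin` domain is rejected.
#'
#' @param graph a `compartment_graph`.
#' @param densities a [channel_density_table()].
#' @param models named list of [channel_model()]s covering every channel
#'   name in `densities`.
#' @param temperature_C simulation temperature for the Q10 scaling.
#' @return The graph with a channel table attached; [simulate_ap()] and
#'   [simulate_passive()] share one solver code path, so zero densities
#'   reproduce the passive simulation exactly.
#' @export
build_active_model <- function(graph, densities = channel_density_table(),
                               models = default_channel_models(),
                               temperature_C = 35) {
  densities <- as_tibble(densities)
  if (any(densities$domain == "myelin")) {
    abort("channels cannot be assigned to the myelin radial element")
  }
  if (any(densities$density < 0)) abort("channel densities must be non-negative")
  comps <- graph$comps
  dist_grad <- densities$domain == "dendrite_distal"
  grad <- densities[dist_grad, ]
  densities <- densities[!dist_grad, ]

  core <- integer(); peri <- integer(); gmax <- numeric(); erev <- numeric()
  gates <- list()
  dend <- comps$kind == "dendrite"
  x_max <- if (any(dend)) max(comps$x_path[dend]) else 1
  x_min <- if (any(dend)) min(comps$x_path[dend]) else 0
  for (r in seq_len(nrow(densities))) {
    dom <- densities$domain[r]; chn <- densities$channel[r]
    dens <- densities$density[r]
    rows <- which(comps$kind == dom)
    if (!length(rows) || dens <= 0) next
    mod <- models[[chn]]
    if (is.null(mod)) abort(sprintf("no channel model named %s", chn))
    dvec <- rep(dens, length(rows))
    if (dom == "dendrite" && chn %in% grad$channel && x_max > x_min) {
      d_distal <- grad$density[grad$channel == chn]
      frac <- (comps$x_path[rows] - x_min) / (x_max - x_min)
      dvec <- dens + (d_distal - dens) * frac
    }
    area_um2 <- pi * comps$diam_um[rows] * comps$L_um[rows]
    for (q in seq_along(rows)) {
      k <- rows[q]
      core <- c(core, k - 1L)
      peri <- c(peri, if (is.na(comps$peri[k])) -1L else
        graph$n_core + comps$peri[k] - 1L)
      gmax <- c(gmax, dvec[q] * area_um2[q] * 1e-6)  # pS/um2 * um2 -> uS
      erev <- c(erev, mod$erev)
      sc <- mod$q10^((temperature_C - mod$T_ref) / 10)
      ci <- length(gmax) - 1L
      for (g in mod$gates) {
        gates[[length(gates) + 1]] <- c(ci, g$power,
                                        g$alpha$form, g$alpha$A, g$alpha$Vh, g$alpha$k,
                                        g$beta$form, g$beta$A, g$beta$Vh, g$beta$k,
                                        sc)
      }
    }
  }
  graph$channels <- if (length(gmax)) {
    list(core = as.integer(core), peri = as.integer(peri),
         gmax = gmax, erev = erev, gates = do.call(rbind, gates))
  } else NULL
  graph$temperature_C <- temperature_C
  graph
}

#' Simulate action potentials in the active model
#'
#' @param graph a `compartment_graph` with channels attached
#'   ([build_active_model()]).
#' @param protocol a [stimulus_protocol()] (typically a somatic step).
#' @param cfg a [solver_config()]; active models usually need `dt <= 0.005`.
#' @param record recording sites; `NULL` records every compartment.
#' @return A `trace_set`; attribute `ap` holds flags: `spiked` (any somatic
#'   or nodal 0 mV crossing), `regenerative` (a non-stimulated compartment
#'   crossing 0 mV more than once).
#' @export
simulate_ap <- function(graph, protocol, cfg = solver_config(dt = 0.005, t_stop = 10),
                        record = NULL) {
  rec <- record %||% tibble(section_id = graph$comps$section_id,
                            pos = graph$comps$pos,
                            site = sprintf("c%04d", seq_len(nrow(graph$comps))))
  run <- run_simulation(graph, protocol, cfg, channels = graph$channels,
                        record = rec, record_all = TRUE)
  ts <- traj_to_traces(run, graph)
  core_traj <- run$traj[, seq_len(run$sys$n_core), drop = FALSE]
  peri_full <- matrix(0, nrow(core_traj), run$sys$n_core)
  if (run$sys$n_peri > 0) {
    has <- !is.na(run$sys$comps$peri)
    peri_full[, has] <- run$traj[, run$sys$n_core + run$sys$comps$peri[has]]
  }
  vm <- core_traj - peri_full
  crossings <- apply(vm, 2, function(v) sum(diff(v > 0) == 1))
  watch <- run$sys$comps$kind %in% c("soma", "node")
  stim_sec <- if (!is.null(protocol)) protocol$stimuli$section_id else integer()
  nonstim <- !(run$sys$comps$section_id %in% stim_sec)
  attr(ts, "ap") <- list(
    spiked = any(crossings[watch] >= 1),
    regenerative = any(crossings[nonstim] > 1),
    crossings = crossings)
  ts
}

# derivative by central differences, V/s when v in mV and dt in ms
central_deriv <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# first prominent local maximum of a series (fraction of global max)
first_peak_time <- function(t, y, frac = 0.25) {
  thr <- frac * max(y)
  n <- length(y)
  locmax <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  locmax <- locmax[y[locmax] >= thr]
  if (!length(locmax)) return(NA_real_)
  t[locmax[1]]
}

#' Conduction velocity between recording sites
#'
#' Onset times are defined as in axonal electrophysiology: for model traces
#' the first peak of the third voltage derivative; for recorded traces the
#' first time dV/dt exceeds 3x the standard deviation of the pre-stimulus
#' dV/dt noise (thresholds typically land at 60-120 V/s). With more than
#' two sites the velocity is the inverse slope of onset time against path
#' distance.
#'
#' @param traces a `trace_set` with a `V_m` (or `v`) column.
#' @param sites character vector of site labels (>= 2), ordered downstream.
#' @param positions path distances (um) of `sites`; taken from the trace
#'   attributes when omitted.
#' @param mode `"model_d3v"` or `"recorded_threshold"`.
#' @param pre_stim_ms pre-stimulus window used for the noise SD.
#' @return A tibble: `cv_m_s`, plus per-site onsets in `onsets` (list col).
#' @export
conduction_velocity <- function(traces, sites, positions = NULL,
                                mode = c("model_d3v", "recorded_threshold"),
                                pre_stim_ms = 1) {
  mode <- match.arg(mode)
  measure <- if ("V_m" %in% names(traces)) "V_m" else "v"
  if (is.null(positions)) {
    st <- trace_sites(traces)
    positions <- st$x_path[match(sites, st$site)]
  }
  if (length(sites) < 2 || anyNA(positions)) {
    abort("need >= 2 sites with known path distances")
  }
  tm <- trace_matrix(traces, measure, site_order = sites)
  dt <- tm$time[2] - tm$time[1]
  onset <- vapply(seq_along(sites), function(j) {
    v <- tm$m[, j]
    if (mode == "model_d3v") {
      d3 <- central_deriv(central_deriv(central_deriv(v, dt), dt), dt)
      first_peak_time(tm$time, d3)
    } else {
      dv <- central_deriv(v, dt)
      pre <- dv[tm$time < pre_stim_ms]
      thr <- 3 * stats::sd(pre)
      # sustained crossing (3 consecutive samples) so isolated noise
      # excursions beyond 3 SD do not fire the detector
      above <- dv > thr
      run3 <- above & c(above[-1], FALSE) & c(above[-(1:2)], FALSE, FALSE)
      hit <- which(run3)
      if (!length(hit)) NA_real_ else tm$time[hit[1]]
    }
  }, numeric(1))
  if (anyNA(onset)) abort("no onset detected at one or more sites")
  if (length(sites) == 2 && diff(onset) == 0) {
    abort("identical onset times: conduction velocity undefined")
  }
  slope <- if (length(sites) == 2) diff(onset) / diff(positions) else
    stats::coef(stats::lm(onset ~ positions))[2]
  cv <- 1e-3 / slope  # um/ms -> m/s
  tibble(cv_m_s = unname(cv),
         flagged = unname(cv) < 0,
         onsets = list(tibble(site = sites, x_path = positions, onset = onset)))
}

#' Sweep a biophysical parameter and measure conduction velocity
#'
#' Re-parameterises the active model point by point and reports CV and
#' spiking flags. Ultrastructural sweep axes map onto cable parameters
#' through the closed-form algebra: `delta_pa`/`delta_pn` move the
#' periaxonal/paranodal axial resistances at fixed fluid resistivity,
#' and `n_my` moves `R_my` and `C_my` together at fixed single-membrane
#' properties.
#'
#' @param graph active `compartment_graph` (see [build_active_model()]).
#' @param parameter one of `"nodal_gNa"`, `"internodal_gNa"`, `"R_my"`,
#'   `"C_my"`, `"delta_pa"`, `"delta_pn"`, `"n_my"`.
#' @param grid numeric values: multiplicative factors for the conductance
#'   and `R_my`/`C_my` axes; nm for the width axes; lamellae for `n_my`.
#' @param protocol stimulation protocol (suprathreshold somatic step).
#' @param cfg solver configuration.
#' @param cv_sites two or more node site labels for the CV measurement;
#'   `NULL` picks the second and second-to-last node automatically.
#' @param densities base density table.
#' @param bounds optional parameter bounds; out-of-bound points are skipped
#'   with a warning.
#' @param R_pa_fluid,R_pn_fluid fluid resistivities (ohm cm) used by the
#'   width axes.
#' @return Tibble: `parameter`, `value`, `cv_m_s`, `spiked`, `regenerative`.
#' @export
sensitivity_sweep <- function(graph, parameter, grid, protocol,
                              cfg = solver_config(dt = 0.005, t_stop = 10),
                              cv_sites = NULL,
                              densities = channel_density_table(),
                              bounds = NULL,
                              R_pa_fluid = 53.7, R_pn_fluid = 550) {
  par0 <- graph$ref_params
  d_axon <- mean(graph$comps$diam_um[graph$comps$kind == "internode"])
  rows <- purrr::map_dfr(grid, function(val) {
    p <- par0; dens <- densities; g <- graph
    if (parameter == "nodal_gNa") {
      nd <- dens$domain == "node" & dens$channel == "Nav"
      dens$density[nd] <- dens$density[nd] * val
      g <- build_active_model(g, dens, temperature_C = graph$temperature_C %||% 35)
    } else if (parameter == "internodal_gNa") {
      nd <- dens$domain %in% c("internode", "paranode") & dens$channel == "Nav"
      dens$density[nd] <- dens$density[nd] * val
      g <- build_active_model(g, dens, temperature_C = graph$temperature_C %||% 35)
    } else if (parameter == "R_my") {
      p$R_my <- p$R_my * val
    } else if (parameter == "C_my") {
      p$C_my <- p$C_my * val
    } else if (parameter == "delta_pa") {
      # the paranodal gap is contiguous with the periaxonal space: widening
      # or tightening moves both axial resistances at fixed fluid
      # resistivities (the seal stays a seal through its higher resistivity)
      p$r_pa <- periaxonal_resistivity_inverse(R_pa_fluid, d_axon, val)
      p$r_pn <- periaxonal_resistivity_inverse(R_pn_fluid, d_axon, val)
    } else if (parameter == "delta_pn") {
      p$r_pn <- periaxonal_resistivity_inverse(R_pn_fluid, d_axon, val)
    } else if (parameter == "n_my") {
      mm <- membrane_props_from_sheath(par0$R_my, par0$C_my,
                                       n_my = graph$base_n_my %||% 12)
      sh <- sheath_from_lamellae(mm$R_mm, mm$C_mm, val)
      p$R_my <- sh$R_my; p$C_my <- sh$C_my
    } else abort(sprintf("unknown sweep parameter: %s", parameter))

    if (!is.null(bounds) && !params_in_bounds(p, bounds)) {
      warn(sprintf("%s = %g puts parameters out of bounds; skipped", parameter, val))
      return(NULL)
    }
    g$ref_params <- p
    ts <- simulate_ap(g, protocol, cfg)
    flags <- attr(ts, "ap")
    cv <- tryCatch({
      st <- trace_sites(ts)
      nsites <- cv_sites %||% default_cv_sites(g, st)
      conduction_velocity(ts, nsites)$cv_m_s
    }, error = function(e) NA_real_)
    tibble(parameter = parameter, value = val, cv_m_s = cv,
           spiked = flags$spiked, regenerative = flags$regenerative)
  })
  rows
}

# second and second-to-last node recording sites along the axon
default_cv_sites <- function(graph, site_tbl) {
  nodes <- site_tbl[site_tbl$kind == "node", ]
  nodes <- nodes[order(nodes$x_path), ]
  if (nrow(nodes) < 2) abort("need at least two nodes for a CV measurement")
  picks <- if (nrow(nodes) >= 4) c(2, nrow(nodes) - 1) else c(1, nrow(nodes))
  nodes$site[picks]
}
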