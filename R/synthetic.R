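#' Synthetic study configuration
#'
#' Defaults emulate the study conditions for thick-tufted L5 pyramidal
#' axons: 1-6 internodes that lengthen with distance, 2.3 um paranodes, a
#' g-ratio of 0.698, 10.5 lamellae per um of core diameter, a periaxonal
#' width averaging 12.3 nm (range 8.5-17.1), dual-electrode current-clamp
#' protocols of +/-300 to +/-600 pA, 2 ms pulses sampled at 50 kHz with a
#' 10 kHz low-pass acquisition filter, Gaussian recording noise and
#' occasional artifact trials.
#'
#' @param seed RNG seed; all generators are reproducible given the seed.
#' @param n_internodes number of internodes (1-6).
#' @param axon_diam_um internodal axon core diameter, um.
#' @param g_ratio inner/outer fiber diameter ratio.
#' @param lamellae_per_um lamellae per um of core diameter.
#' @param delta_pa_nm,delta_pa_sd_nm,delta_pa_range_nm periaxonal width
#'   distribution (truncated normal), nm.
#' @param noise_sd_mV recording noise SD.
#' @param n_trials trials per injection level (study range 30-180).
#' @param levels_pA injection levels.
#' @param pulse_onset_ms,pulse_ms pulse timing.
#' @param sampling_khz acquisition rate.
#' @param t_stop_ms trace duration.
#' @param artifact_prob probability of an artifact trial.
#' @param internode_scale length multipliers applied to the first
#'   internodes (the proximal internodes are short).
#' @param R_i,R_m,C_m axoplasmic/axolemmal ground-truth passive values.
#' @param R_mm_kohm,C_mm_uF single myelin membrane properties used to build
#'   the true sheath values from the lamella count.
#' @param R_pa_ohm,R_pn_ohm periaxonal/paranodal fluid resistivities.
#' @param node_len_um,paranode_len_um nodal and paranodal lengths.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_internodes = 6, axon_diam_um = 1.1,
                         g_ratio = 0.698, lamellae_per_um = 10.5,
                         delta_pa_nm = 12.3, delta_pa_sd_nm = 2.7,
                         delta_pa_range_nm = c(8.5, 17.1),
                         noise_sd_mV = 0.1, n_trials = 100,
                         levels_pA = c(-600, -500, -400, -300, 300, 400, 500, 600),
                         pulse_onset_ms = 5, pulse_ms = 2,
                         sampling_khz = 50, t_stop_ms = 50,
                         artifact_prob = 0.05,
                         internode_scale = c(0.5, 0.5, rep(1, 10)),
                         R_i = 100, R_m = 15, C_m = 1,
                         R_mm_kohm = 8.56, C_mm_uF = 1.0,
                         R_pa_ohm = 53.7, R_pn_ohm = 550,
                         node_len_um = 1, paranode_len_um = 2.3) {
  cfg <- as.list(environment())
  stopifnot(n_internodes >= 1, axon_diam_um > 0, g_ratio > 0, g_ratio < 1)
  structure(cfg, class = "synth_config")
}

#' Ground-truth cable parameters implied by a synthetic configuration
#'
#' Sheath values follow the series-compaction algebra from the lamella
#' count; periaxonal/paranodal axial resistances follow the annular
#' geometry at the configured fluid resistivities and widths.
#'
#' @param cfg a [synth_config()].
#' @param n_my lamella count (default from the diameter law).
#' @return A [cable_params()].
#' @export
true_cable_params <- function(cfg, n_my = round(cfg$lamellae_per_um * cfg$axon_diam_um)) {
  sh <- sheath_from_lamellae(cfg$R_mm_kohm, cfg$C_mm_uF, n_my)
  cable_params(
    R_i = cfg$R_i, R_m = cfg$R_m, C_m = cfg$C_m,
    R_my = sh$R_my, C_my = sh$C_my,
    r_pa = periaxonal_resistivity_inverse(cfg$R_pa_ohm, cfg$axon_diam_um,
                                          cfg$delta_pa_nm),
    r_pn = periaxonal_resistivity_inverse(cfg$R_pn_ohm, cfg$axon_diam_um,
                                          DELTA_PN_NM))
}

#' Generate a stylised L5-like morphology
#'
#' Soma, two equivalent-cylinder dendrites, an AIS, and an alternating
#' paranode/internode/node chain ending in an unmyelinated cut end.
#' Internode lengths scale linearly with core diameter (100 um per um of
#' diameter) with the first internodes shortened, so lengths increase with
#' distance from the soma. Per-internode myelin geometry (lamella count,
#' outer diameter, periaxonal width) follows the configured laws.
#'
#' @param cfg a [synth_config()].
#' @return List: `morph` (a [morphology()]), `geometry` (per-internode
#'   tibble: `internode`, `section_id`, `L_um`, `d_um`, `D_um`, `n_my`,
#'   `delta_pa_nm`), `params` (ground-truth [cable_params()]).
#' @export
make_l5_morphology <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  d <- cfg$axon_diam_um
  rows <- list(
    section_row(1, "soma", NA, 20, 20),
    section_row(2, "dendrite", 1, 700, 4),    # apical equivalent cylinder
    section_row(3, "dendrite", 1, 300, 2.5),  # basal equivalent cylinder
    section_row(4, "ais", 1, 45, data.frame(pos = c(0, 1), diam = c(1.8, d))))
  id <- 5L; parent <- 4L
  geom <- list()
  for (i in seq_len(cfg$n_internodes)) {
    L <- 100 * d * cfg$internode_scale[min(i, length(cfg$internode_scale))]
    rows[[length(rows) + 1]] <- section_row(id, "paranode", parent,
                                            cfg$paranode_len_um, d)
    parent <- id; id <- id + 1L
    rows[[length(rows) + 1]] <- section_row(id, "internode", parent, L, d)
    geom[[i]] <- tibble(internode = i, section_id = id, L_um = L, d_um = d,
                        D_um = d / cfg$g_ratio,
                        n_my = round(cfg$lamellae_per_um * d),
                        delta_pa_nm = cfg$delta_pa_nm)
    parent <- id; id <- id + 1L
    rows[[length(rows) + 1]] <- section_row(id, "paranode", parent,
                                            cfg$paranode_len_um, d)
    parent <- id; id <- id + 1L
    rows[[length(rows) + 1]] <- section_row(id, "node", parent,
                                            cfg$node_len_um, d)
    parent <- id; id <- id + 1L
  }
  rows[[length(rows) + 1]] <- section_row(id, "unmyelinated_end", parent, 30, d)
  morph <- morphology(dplyr::bind_rows(rows),
                      metadata = list(generator = "make_l5_morphology",
                                      seed = cfg$seed))
  list(morph = morph, geometry = dplyr::bind_rows(geom),
       params = true_cable_params(cfg))
}

# 4-pole low-pass emulating the acquisition (Bessel-type) filter
lowpass4 <- function(v, fc_khz, dt_ms) {
  # one-pole cascade applied four times (phase detail is irrelevant at the
  # tested tolerances; -3 dB point adjusted for the cascade)
  fc <- fc_khz / sqrt(2^(1 / 4) - 1)  # per-pole cutoff for a 4-pole cascade
  a <- exp(-2 * pi * fc * dt_ms)
  for (k in 1:4) v <- stats::filter(v, filter = a, method = "recursive",
                                    init = v[1] / (1 - a)) * (1 - a)
  as.numeric(v)
}

#' Generate a noisy dual-electrode recording set
#'
#' Forward-simulates the passive double cable for every injection level
#' (one unit-current simulation scaled per level; the passive system is
#' linear), then builds trials: Gaussian recording noise, a 10 kHz low-pass
#' acquisition step, per-trial baseline jitter, and artifact trials at the
#' configured probability (a >= 0.5 ms square excursion of 10x the noise
#' SD, for the rejection rule to catch). Ground truth is recorded in the
#' metadata for recovery scoring.
#'
#' @param morph a [morphology()] (typically `make_l5_morphology()$morph`).
#' @param true_params ground-truth [cable_params()].
#' @param cfg a [synth_config()].
#' @param sites recording sites; default soma (injecting) and the axon cut
#'   end (recording-only).
#' @return A raw `trace_set`: `time`, `site`, `level`, `trial`, `v`, with
#'   `meta$ground_truth`, `meta$protocol` and `meta$artifact_trials`.
#' @export
make_recording_set <- function(morph, true_params, cfg = synth_config(),
                               sites = NULL) {
  set.seed(cfg$seed + 1)
  dt <- 1 / cfg$sampling_khz
  scfg <- solver_config(dt = dt, t_stop = cfg$t_stop_ms, tau_min = 1)
  graph <- discretize(morph, true_params, scfg)
  if (is.null(sites)) {
    end_sec <- morph$id[morph$kind == "unmyelinated_end"]
    end_sec <- end_sec[length(end_sec)]
    sites <- tibble(section_id = c(1L, end_sec), pos = c(0.5, 0.5),
                    site = c("soma", "axon_end"),
                    role = c("injecting_recording", "recording_only"))
  }
  prot <- stimulus_protocol(tibble(
    section_id = sites$section_id[1], pos = sites$pos[1],
    kind = "current_step", amplitude_nA = 1,
    onset_ms = cfg$pulse_onset_ms, duration_ms = cfg$pulse_ms,
    waveform = list(NULL)), sampling_khz = cfg$sampling_khz)
  run <- run_simulation(graph, prot, scfg, record = sites, record_all = FALSE,
                        params = true_params)
  unit <- sweep(run$traj, 2, run$traj[1, ])
  nt <- length(run$time)

  artifacts <- list()
  out <- purrr::map_dfr(cfg$levels_pA, function(lv) {
    amp <- lv / 1000
    purrr::map_dfr(seq_len(nrow(sites)), function(j) {
      clean <- amp * unit[, j]
      purrr::map_dfr(seq_len(cfg$n_trials), function(tr) {
        # the acquisition filter shapes the recorded noise; the simulated
        # signal is already band-limited by the solver, so trials with zero
        # noise reduce to the clean simulation
        v <- clean + lowpass4(stats::rnorm(nt, 0, cfg$noise_sd_mV), 10, dt)
        v <- v + stats::rnorm(1, 0, 0.5 * cfg$noise_sd_mV)  # baseline jitter
        if (stats::runif(1) < cfg$artifact_prob) {
          t0 <- stats::runif(1, 0, cfg$t_stop_ms - 3)
          dur <- stats::runif(1, 0.5, 2)
          v[run$time >= t0 & run$time < t0 + dur] <-
            v[run$time >= t0 & run$time < t0 + dur] + 10 * cfg$noise_sd_mV
          artifacts[[length(artifacts) + 1]] <<-
            list(site = sites$site[j], level = lv, trial = tr)
        }
        tibble(time = run$time, site = sites$site[j], level = lv,
               trial = tr, v = v)
      })
    })
  })
  new_trace_set(out, sites = site_table(graph, sites),
                meta = list(ground_truth = unclass(true_params),
                            protocol = list(onset_ms = cfg$pulse_onset_ms,
                                            duration_ms = cfg$pulse_ms,
                                            levels_pA = cfg$levels_pA,
                                            sampling_khz = cfg$sampling_khz),
                            noise_sd_mV = cfg$noise_sd_mV,
                            artifact_trials = artifacts,
                            seed = cfg$seed))
}

#' Synthetic action-potential command waveform
#'
#' Difference-of-exponentials spike used as the AP-clamp command.
#'
#' @param t_onset onset, ms.
#' @param amp_mV peak amplitude above rest.
#' @param rest_mV resting potential.
#' @param tau_rise_ms,tau_fall_ms kinetics.
#' @param t_stop_ms,dt_ms waveform extent and sampling.
#' @return Tibble `time`, `v`.
#' @export
ap_waveform <- function(t_onset = 1, amp_mV = 100, rest_mV = -75,
                        tau_rise_ms = 0.1, tau_fall_ms = 0.45,
                        t_stop_ms = 10, dt_ms = 0.01) {
  tt <- seq(0, t_stop_ms, by = dt_ms)
  s <- pmax(tt - t_onset, 0)
  shape <- exp(-s / tau_fall_ms) - exp(-s / tau_rise_ms)
  shape[tt <= t_onset] <- 0
  shape <- shape / max(shape)
  tibble(time = tt, v = rest_mV + amp_mV * shape)
}

#' Generate VSD-like fluorescence with a calibration step
#'
#' Fluorescence is a gain- and offset-transformed copy of the membrane
#' potential with shot-like noise; the gain is unknown to the analyst. A
#' paired calibration segment encodes a hyperpolarizing somatic step of
#' known amplitude, attenuated along the axon as `exp(-x/k)`.
#'
#' @param sim a `trace_set` with `V_m` and site path distances (um).
#' @param cfg a [synth_config()].
#' @param k_mm attenuation length (default 1.18).
#' @param V_step_soma_mV calibration step amplitude at the soma, mV.
#' @param gain_range per-site uniform gain range (fluorescence units/mV).
#' @param noise_sd fluorescence noise SD (same units as F).
#' @param v_rest resting potential, mV.
#' @return List: `fluor` (trace_set with `f`), `cal` (tibble per site:
#'   `site`, `x_mm`, `dF_cal`, `V_step_soma_mV`, `gain`), `k_mm`.
#' @export
make_vsd_traces <- function(sim, cfg = synth_config(), k_mm = 1.18,
                            V_step_soma_mV = -20, gain_range = c(0.5, 2),
                            noise_sd = 0.02, v_rest = -75) {
  set.seed(cfg$seed + 2)
  st <- trace_sites(sim)
  gains <- stats::runif(nrow(st), gain_range[1], gain_range[2])
  offsets <- stats::runif(nrow(st), 5, 10)
  cal <- tibble(site = st$site, x_mm = st$x_path / 1000,
                V_step_soma_mV = V_step_soma_mV,
                gain = gains,
                dF_cal = gains * V_step_soma_mV * exp(-(st$x_path / 1000) / k_mm))
  fluor <- purrr::map_dfr(seq_len(nrow(st)), function(j) {
    sub <- sim[sim$site == st$site[j], ]
    f <- gains[j] * (sub$V_m - v_rest) + offsets[j] +
      stats::rnorm(nrow(sub), 0, noise_sd)
    tibble(time = sub$time, site = st$site[j], f = f)
  })
  list(fluor = new_trace_set(fluor, sites = st,
                             meta = list(seed = cfg$seed, k_mm = k_mm)),
       cal = cal, k_mm = k_mm)
}

#' Sample EM-like ultrastructure measurements
#'
#' Draws periaxonal widths from a truncated normal matching the configured
#' mean and range, diameters from a truncated normal over the physiological
#' range, outer diameters from the g-ratio law with multiplicative scatter,
#' and lamella counts from the linear diameter law with unit-SD rounding
#' noise.
#'
#' @param cfg a [synth_config()].
#' @param n number of sampled internodes (default 195).
#' @return Tibble: `delta_pa_nm`, `d_um`, `D_um`, `n_my`.
#' @export
make_em_samples <- function(cfg = synth_config(), n = 195) {
  set.seed(cfg$seed + 3)
  rtrunc <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2 * n, mean, sd)
      out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
  }
  dpa <- rtrunc(n, cfg$delta_pa_nm, cfg$delta_pa_sd_nm,
                cfg$delta_pa_range_nm[1], cfg$delta_pa_range_nm[2])
  d <- rtrunc(n, cfg$axon_diam_um, 0.25, 0.5, 2)
  D <- d / cfg$g_ratio * exp(stats::rnorm(n, 0, 0.03))
  n_my <- pmax(1, round(cfg$lamellae_per_um * d + stats::rnorm(n, 0, 1)))
  tibble(delta_pa_nm = dpa, d_um = d, D_um = D, n_my = n_my)
}
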