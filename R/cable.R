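#' Solver configuration
#'
#' @param dt time step, ms.
#' @param method `"backward_euler"` (default) or `"crank_nicolson"`.
#' @param d_lambda spatial resolution as a fraction of the AC length
#'   constant (default 0.1).
#' @param tau_min smallest membrane time constant expected in the data, ms;
#'   sets the frequency `f_m = 1/(2 pi tau_min)` at which the length
#'   constant is evaluated.
#' @param t_stop simulation end, ms.
#' @param v_rest uniform resting potential, mV.
#' @param record tibble of recording sites with columns `section_id`, `pos`
#'   (arc fraction) and optional `site` label; `NULL` records the soma.
#' @return A `solver_config` list.
#' @export
solver_config <- function(dt = 0.01, method = c("backward_euler", "crank_nicolson"),
                          d_lambda = 0.1, tau_min = 1, t_stop = 20,
                          v_rest = -75, record = NULL) {
  method <- match.arg(method)
  if (dt <= 0) abort("`dt` must be positive")
  if (d_lambda <= 0 || d_lambda > 1) abort("`d_lambda` must be in (0, 1]")
  structure(list(dt = dt, method = method, d_lambda = d_lambda,
                 tau_min = tau_min, t_stop = t_stop, v_rest = v_rest,
                 record = record), class = "solver_config")
}

# AC length constant at frequency f (Hz), um; d um, R_i ohm cm, C_m uF/cm2
lambda_f_um <- function(d_um, f_hz, R_i, C_m) {
  1e5 * sqrt(d_um / (4 * pi * f_hz * R_i * C_m))
}

#' Discretize a morphology into a compartment graph
#'
#' Splits every section into the smallest odd number of compartments whose
#' length does not exceed `d_lambda` times the AC length constant at
#' `f_m = 1/(2 pi tau_min)` (the d-lambda rule). Myelinated compartments
#' (paranode, internode) receive a periaxonal unknown in addition to the
#' axon-core unknown; the periaxonal layer is hard-grounded at the outer
#' boundary of each myelinated chain (the nodal edges of the paranodes).
#'
#' Only geometry is frozen here; electrical elements are built by
#' [assemble_system()] from a parameter set, so the same graph can be
#' re-parameterised cheaply during fitting.
#'
#' @param morph a [morphology()].
#' @param params reference [cable_params()] used for the length constant.
#' @param cfg a [solver_config()].
#' @return A `compartment_graph` object.
#' @export
discretize <- function(morph, params, cfg = solver_config()) {
  f_m <- 1000 / (2 * pi * cfg$tau_min)  # Hz, tau_min in ms
  pd <- path_distances(morph)

  comp_rows <- list(); edge_rows <- list()
  first_comp <- integer(); last_comp <- integer()
  n <- 0L
  for (i in seq_len(nrow(morph))) {
    L <- morph$length_um[i]
    prof <- morph$diam[[i]]
    dbar <- mean_diam(prof)
    if (any(prof$diam <= 0)) abort(sprintf("zero diameter in section %d", morph$id[i]))
    lam <- lambda_f_um(dbar, f_m, params$R_i, params$C_m)
    nseg <- ceiling(L / (cfg$d_lambda * lam))
    nseg <- max(1L, as.integer(nseg))
    if (nseg %% 2 == 0) nseg <- nseg + 1L
    centers <- (seq_len(nseg) - 0.5) / nseg
    dd <- diam_at(prof, centers)
    x0 <- pd$x_start[pd$id == morph$id[i]]
    comp_rows[[i]] <- tibble(
      comp = n + seq_len(nseg), section_id = morph$id[i],
      kind = morph$kind[i], pos = centers,
      x_path = x0 + centers * L,
      L_um = L / nseg, diam_um = dd,
      myelinated = morph$myelinated[i])
    if (nseg > 1) {
      edge_rows[[length(edge_rows) + 1]] <- tibble(
        i = n + seq_len(nseg - 1), j = n + 1 + seq_len(nseg - 1))
    }
    first_comp[as.character(morph$id[i])] <- n + 1L
    last_comp[as.character(morph$id[i])] <- n + nseg
    n <- n + nseg
  }
  comps <- dplyr::bind_rows(comp_rows)
  # inter-section edges: child's first compartment to parent's last
  for (r in seq_len(nrow(morph))) {
    p <- morph$parent_id[r]
    if (!is.na(p)) {
      ei <- last_comp[[as.character(p)]]
      ej <- first_comp[[as.character(morph$id[r])]]
      edge_rows[[length(edge_rows) + 1]] <- tibble(i = ei, j = ej)
    }
  }
  edges <- dplyr::bind_rows(edge_rows)

  # geometric factors: axial resistance = R_i * factor (factor in cm^-1)
  half_axial <- function(k) 4 * (comps$L_um[k] / 2 / UM_PER_CM) /
    (pi * (comps$diam_um[k] / UM_PER_CM)^2)
  edges$axial_factor <- half_axial(edges$i) + half_axial(edges$j)
  edges$R_fixed_ohm <- NA_real_

  # periaxonal layer: chains of myelinated compartments
  comps$peri <- NA_integer_
  comps$peri[comps$myelinated] <- seq_len(sum(comps$myelinated))
  # per-length factor split by domain: paranodal halves count toward r_pn
  half_len_cm <- comps$L_um / 2 / UM_PER_CM
  is_pn <- comps$kind == "paranode"
  pe <- edges[comps$myelinated[edges$i] & comps$myelinated[edges$j], c("i", "j")]
  if (nrow(pe)) {
    pe$f_pa <- ifelse(is_pn[pe$i], 0, half_len_cm[pe$i]) +
      ifelse(is_pn[pe$j], 0, half_len_cm[pe$j])
    pe$f_pn <- ifelse(is_pn[pe$i], half_len_cm[pe$i], 0) +
      ifelse(is_pn[pe$j], half_len_cm[pe$j], 0)
  } else pe <- tibble(i = integer(), j = integer(), f_pa = numeric(), f_pn = numeric())

  # grounded ends: myelinated compartments with a core neighbour that is
  # unmyelinated, or with a free end (tree boundary)
  ground <- purrr::map_dfr(which(comps$myelinated), function(k) {
    nbs <- unique(c(edges$j[edges$i == k], edges$i[edges$j == k]))
    n_mye <- sum(comps$myelinated[nbs])
    n_open <- 2 - length(nbs) + (length(nbs) - n_mye)  # unmyelinated or free ends
    if (n_open <= 0) return(NULL)
    tibble(p = comps$peri[k],
           f_pa = if (is_pn[k]) 0 else half_len_cm[k],
           f_pn = if (is_pn[k]) half_len_cm[k] else 0,
           n_ends = n_open)
  })

  structure(list(comps = comps, edges = edges,
                 peri_edges = pe, peri_ground = ground,
                 n_core = nrow(comps), n_peri = sum(comps$myelinated),
                 circuit = "DC", ref_params = params, cfg = cfg,
                 Rm_override = rep(NA_real_, nrow(comps)),
                 Cm_override = rep(NA_real_, nrow(comps)),
                 channels = NULL),
            class = "compartment_graph")
}

#' @export
print.compartment_graph <- function(x, ...) {
  cat(sprintf("<compartment_graph> %s circuit: %d core + %d periaxonal compartments\n",
              x$circuit, x$n_core, x$n_peri))
  invisible(x)
}

#' Collapse the double cable to a single cable
#'
#' Removes the periaxonal layer: in myelinated compartments the axolemma and
#' myelin elements combine in series (resistances add; capacitances add
#' reciprocally) and a single core axial path remains.
#'
#' @param graph a `compartment_graph`.
#' @param circuit one of `"SC"`, `"SC_expected"` (myelin tied to 20x R_m,
#'   0.05x C_m), `"SC_rmn"` (separate nodal membrane resistance `R_mN`),
#'   `"SC_rmi"` (separate internodal axolemma resistance `R_mI`),
#'   `"SC_per_internode"` (per-internode `R_my_per`, `C_my_per`) or
#'   `"bare"` (myelin removed entirely: the unmyelinated control).
#' @return The graph flagged to assemble as the requested single cable.
#' @export
to_single_cable <- function(graph, circuit = "SC") {
  stopifnot(circuit %in% c("SC", "SC_expected", "SC_rmn", "SC_rmi",
                           "SC_per_internode", "bare"))
  graph$circuit <- circuit
  graph
}

# series membrane combination (resistances kOhm cm2, capacitances uF/cm2)
series_membrane <- function(R_m, C_m, R_my, C_my) {
  list(R = R_m + R_my, C = (C_m * C_my) / (C_m + C_my))
}

#' Assemble the electrical system for a parameter set
#'
#' Builds the dense mass matrix `M`, conductance matrix `A` and constant
#' source `b0` of the system `M x' = A x + b` on the fixed grid of a
#' [discretize()]d graph. The state is `x = c(V_core, V_peri)` in mV;
#' transaxonal/transmyelin/transfiber potentials are derived views.
#'
#' @param graph a `compartment_graph`.
#' @param params a [cable_params()].
#' @param circuit override of the graph's circuit mode (e.g. `"DC"`,
#'   `"DC_no_rpn"`, `"SC"`, ...).
#' @param ground_paranodes clamp the periaxonal layer to 0 mV at myelinated
#'   chain ends (default TRUE).
#' @return List with `M`, `A`, `b0`, `x0`, `n`, `comps`, `peri_index`.
#' @export
assemble_system <- function(graph, params = graph$ref_params,
                            circuit = graph$circuit,
                            ground_paranodes = TRUE) {
  comps <- graph$comps
  dc <- circuit %in% c("DC", "DC_no_rpn")
  n_core <- graph$n_core
  n_peri <- if (dc) graph$n_peri else 0L
  n <- n_core + n_peri
  peri_row <- function(p) n_core + p

  area <- cyl_area_cm2(comps$diam_um, comps$L_um)
  R_m_eff <- rep(params$R_m, n_core)
  C_m_eff <- rep(params$C_m, n_core)
  if (circuit == "SC_rmn") R_m_eff[comps$kind == "node"] <- params$R_mN %||% params$R_m
  if (circuit == "SC_rmi") R_m_eff[comps$myelinated] <- params$R_mI %||% params$R_m

  R_my_eff <- rep(params$R_my, n_core)
  C_my_eff <- rep(params$C_my, n_core)
  if (circuit == "SC_expected") {
    R_my_eff <- 20 * R_m_eff
    C_my_eff <- 0.05 * C_m_eff
  }
  if (circuit == "SC_per_internode") {
    idx <- internode_index(comps)
    has <- comps$myelinated & !is.na(idx)
    R_my_eff[has] <- (params$R_my_per %||% rep(params$R_my, max(idx, na.rm = TRUE)))[idx[has]]
    C_my_eff[has] <- (params$C_my_per %||% rep(params$C_my, max(idx, na.rm = TRUE)))[idx[has]]
  }

  if (dc || circuit == "bare") {
    Rm <- R_m_eff; Cm <- C_m_eff
  } else {
    ser <- series_membrane(R_m_eff, C_m_eff, R_my_eff, C_my_eff)
    Rm <- ifelse(comps$myelinated, ser$R, R_m_eff)
    Cm <- ifelse(comps$myelinated, ser$C, C_m_eff)
  }
  Rm <- ifelse(is.na(graph$Rm_override), Rm, graph$Rm_override)
  ov <- !is.na(graph$Cm_override)
  Cm[ov] <- graph$Cm_override[ov]
  # pipette wall capacitance may be tied to the fitted C_pip parameter
  if (length(graph$cpip_slot)) Cm[graph$cpip_slot] <- params$C_pip

  G_m <- area * 1e3 / Rm                 # uS (Rm in kOhm cm2)
  C_mem <- Cm * area * 1e3               # nF
  G_my <- area * 1e3 / params$R_my       # uS, myelin radial, per axolemma area
  C_my_nF <- params$C_my * area * 1e3

  M <- matrix(0, n, n); A <- matrix(0, n, n); b0 <- numeric(n)
  E_L <- graph$cfg$v_rest

  diag(M)[seq_len(n_core)] <- C_mem
  diag(A)[seq_len(n_core)] <- -G_m
  b0[seq_len(n_core)] <- G_m * E_L

  # core axial
  gax <- ifelse(is.na(graph$edges$R_fixed_ohm),
                1e6 / (params$R_i * graph$edges$axial_factor),
                1e6 / graph$edges$R_fixed_ohm)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]; g <- gax[k]
    A[i, i] <- A[i, i] - g; A[j, j] <- A[j, j] - g
    A[i, j] <- A[i, j] + g; A[j, i] <- A[j, i] + g
  }

  if (dc) {
    r_pn_eff <- if (circuit == "DC_no_rpn") params$r_pa else params$r_pn
    mye <- which(graph$comps$myelinated)
    for (k in mye) {
      p <- peri_row(comps$peri[k])
      # move axolemma elements to couple core <-> periaxonal
      M[k, p] <- -C_mem[k]; M[p, k] <- -C_mem[k]
      M[p, p] <- C_mem[k] + C_my_nF[k]
      A[k, p] <- A[k, p] + G_m[k]; A[p, k] <- A[p, k] + G_m[k]
      A[p, p] <- A[p, p] - G_m[k] - G_my[k]
      b0[p] <- -G_m[k] * E_L
    }
    if (nrow(graph$peri_edges)) {
      gpa <- 1e6 / (params$r_pa * graph$peri_edges$f_pa +
                      r_pn_eff * graph$peri_edges$f_pn)
      for (k in seq_len(nrow(graph$peri_edges))) {
        i <- peri_row(comps$peri[graph$peri_edges$i[k]])
        j <- peri_row(comps$peri[graph$peri_edges$j[k]])
        g <- gpa[k]
        A[i, i] <- A[i, i] - g; A[j, j] <- A[j, j] - g
        A[i, j] <- A[i, j] + g; A[j, i] <- A[j, i] + g
      }
    }
    if (ground_paranodes && nrow(graph$peri_ground)) {
      ggd <- graph$peri_ground$n_ends * 1e6 /
        (params$r_pa * graph$peri_ground$f_pa + r_pn_eff * graph$peri_ground$f_pn)
      for (k in seq_len(nrow(graph$peri_ground))) {
        i <- peri_row(graph$peri_ground$p[k])
        A[i, i] <- A[i, i] - ggd[k]
      }
    }
  }

  x0 <- c(rep(E_L, n_core), rep(0, n_peri))
  list(M = M, A = A, b0 = b0, x0 = x0, n = n, n_core = n_core,
       n_peri = n_peri, comps = comps, dc = dc)
}

# per-compartment internode ordinal (1-based, counted along increasing path
# distance); NA for non-internode compartments
internode_index <- function(comps) {
  idx <- rep(NA_integer_, nrow(comps))
  sec <- comps |>
    dplyr::filter(.data$kind == "internode") |>
    dplyr::group_by(.data$section_id) |>
    dplyr::summarise(x = min(.data$x_path)) |>
    dplyr::arrange(.data$x)
  for (r in seq_len(nrow(sec))) {
    idx[comps$section_id == sec$section_id[r]] <- r
  }
  idx
}

#' Nearest compartment to a position on a section
#'
#' @param graph a `compartment_graph`.
#' @param section_id section id.
#' @param pos arc fraction in \[0, 1\].
#' @return Compartment index.
#' @export
comp_index <- function(graph, section_id, pos = 0.5) {
  rows <- which(graph$comps$section_id == section_id)
  if (!length(rows)) abort(sprintf("no compartments for section %d", section_id))
  rows[which.min(abs(graph$comps$pos[rows] - pos))]
}

#' Stimulation protocol
#'
#' @param stimuli tibble with columns `section_id`, `pos`, `kind`
#'   (`"current_step"` or `"voltage_clamp_waveform"`), `amplitude_nA`,
#'   `onset_ms`, `duration_ms`, and for clamp stimuli a `waveform` list
#'   column holding a data frame with `time`, `v`.
#' @param sampling_khz nominal acquisition rate, kHz (metadata).
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(stimuli, sampling_khz = 50) {
  structure(list(stimuli = as_tibble(stimuli), sampling_khz = sampling_khz),
            class = "stimulus_protocol")
}

#' Convenience: one somatic current step
#' @param amplitude_nA step amplitude, nA.
#' @param onset_ms,duration_ms pulse timing, ms.
#' @param section_id stimulated section (default 1, the soma).
#' @param pos arc fraction.
#' @rdname stimulus_protocol
#' @export
current_step <- function(amplitude_nA, onset_ms = 5, duration_ms = 2,
                         section_id = 1L, pos = 0.5) {
  stimulus_protocol(tibble(section_id = section_id, pos = pos,
                           kind = "current_step", amplitude_nA = amplitude_nA,
                           onset_ms = onset_ms, duration_ms = duration_ms,
                           waveform = list(NULL)))
}

# build injection/clamp schedules for the C++ kernel
build_schedules <- function(graph, protocol, cfg, nstep) {
  tmid <- (seq_len(nstep) - 0.5) * cfg$dt
  tend <- seq_len(nstep) * cfg$dt
  inj_idx <- integer(); inj <- matrix(0, nstep, 0)
  clamp_idx <- integer(); clamp <- matrix(0, nstep, 0)
  if (!is.null(protocol)) {
    for (k in seq_len(nrow(protocol$stimuli))) {
      st <- protocol$stimuli[k, ]
      ci <- comp_index(graph, st$section_id, st$pos)
      if (st$kind == "current_step") {
        col <- as.numeric(tmid >= st$onset_ms & tmid < st$onset_ms + st$duration_ms) *
          st$amplitude_nA
        inj_idx <- c(inj_idx, ci); inj <- cbind(inj, col)
      } else if (st$kind == "voltage_clamp_waveform") {
        wf <- st$waveform[[1]]
        col <- stats::approx(wf$time, wf$v, xout = tend, rule = 2)$y
        clamp_idx <- c(clamp_idx, ci); clamp <- cbind(clamp, col)
      } else abort(sprintf("unknown stimulus kind: %s", st$kind))
    }
  }
  list(inj_idx = inj_idx, inj = inj, clamp_idx = clamp_idx, clamp = clamp)
}

default_record <- function(graph) {
  soma <- graph$comps$section_id[graph$comps$kind == "soma"][1]
  tibble(section_id = soma, pos = 0.5, site = "soma")
}

site_table <- function(graph, record) {
  record <- as_tibble(record)
  if (!"site" %in% names(record)) record$site <- NA_character_
  record$comp <- purrr::map2_int(record$section_id, record$pos,
                                 function(s, p) comp_index(graph, s, p))
  info <- graph$comps[record$comp, ]
  record$site <- ifelse(is.na(record$site),
                        sprintf("%s_%d@%.2f", info$kind, info$section_id, info$pos),
                        record$site)
  record$x_path <- info$x_path
  record$kind <- info$kind
  record
}

# shared driver for passive / clamped / active simulations
run_simulation <- function(graph, protocol, cfg, channels = NULL,
                           record = NULL, record_all = FALSE,
                           params = graph$ref_params, circuit = graph$circuit,
                           ground_paranodes = TRUE, keep_states = FALSE) {
  graph$cfg <- cfg  # resting potential and d-lambda bookkeeping follow cfg
  sys <- assemble_system(graph, params, circuit, ground_paranodes)
  nstep <- ceiling(cfg$t_stop / cfg$dt)
  sch <- build_schedules(graph, protocol, cfg, nstep)
  rec <- site_table(graph, record %||% cfg$record %||% default_record(graph))
  method <- if (cfg$method == "crank_nicolson") 1L else 0L
  ch <- channels %||% list()
  if (length(ch) && !sys$dc) {
    # single-layer circuits: axolemma channels face ground directly
    ch$peri <- rep(-1L, length(ch$peri))
  }
  res <- cpp_integrate(sys$M, sys$A, sys$b0, sys$x0, cfg$dt, nstep, method,
                       as.integer(rec$comp) - 1L,
                       as.integer(sch$inj_idx) - 1L, sch$inj,
                       as.integer(sch$clamp_idx) - 1L, sch$clamp,
                       ch, record_all || keep_states)
  time <- seq(0, by = cfg$dt, length.out = nstep + 1)
  out <- list(traj = res$traj, time = time, sys = sys, sites = rec,
              schedules = sch, record_all = record_all || keep_states)
  out
}

# turn a full-state trajectory into a tidy three-potential trace tibble
traj_to_traces <- function(run, graph) {
  comps <- run$sys$comps
  n_core <- run$sys$n_core
  rows <- purrr::map_dfr(seq_len(nrow(run$sites)), function(r) {
    comp <- run$sites$comp[r]
    vc <- run$traj[, comp]
    vp <- if (run$sys$dc && !is.na(comps$peri[comp]))
      run$traj[, n_core + comps$peri[comp]] else rep(0, length(vc))
    tibble(time = run$time, site = run$sites$site[r],
           x_path = run$sites$x_path[r], kind = run$sites$kind[r],
           V_m = vc - vp, V_my = vp, V_mym = vc)
  })
  new_trace_set(rows, sites = run$sites,
                meta = list(dt = run$time[2] - run$time[1]))
}

#' Simulate the passive circuit
#'
#' Integrates the passive double-cable (or degenerate single-cable) system
#' under a stimulation protocol using implicit time stepping, and returns
#' the transaxonal (`V_m`), transmyelin (`V_my`) and transfiber (`V_mym`)
#' potentials at the requested sites.
#'
#' @param graph a `compartment_graph`.
#' @param protocol a [stimulus_protocol()].
#' @param cfg a [solver_config()].
#' @param params optional [cable_params()] overriding the graph's reference.
#' @param record recording sites (see [solver_config()]); default soma.
#' @param ground_paranodes see [assemble_system()].
#' @return A `trace_set` tibble (long): `time`, `site`, `x_path`, `kind`,
#'   `V_m`, `V_my`, `V_mym`.
#' @export
simulate_passive <- function(graph, protocol, cfg = graph$cfg,
                             params = graph$ref_params, record = NULL,
                             ground_paranodes = TRUE) {
  run <- run_simulation(graph, protocol, cfg, record = record,
                        record_all = TRUE, params = params,
                        ground_paranodes = ground_paranodes)
  traj_to_traces(run, graph)
}

#' Clamp a node to an action-potential waveform
#'
#' Drives the core potential of a nodal compartment with a voltage command
#' (row substitution, i.e. an exact Dirichlet clamp) and propagates the
#' response passively, as in AP-clamp experiments on optimized cells.
#'
#' @param graph a `compartment_graph`.
#' @param node_section_id section id of a node of Ranvier.
#' @param waveform data frame with `time` (ms) and `v` (mV).
#' @param cfg a [solver_config()].
#' @param params optional parameter override.
#' @return A `trace_set` with all compartments recorded (suitable for
#'   [spatial_profile()]).
#' @export
ap_clamp <- function(graph, node_section_id, waveform, cfg = graph$cfg,
                     params = graph$ref_params) {
  kind <- graph$comps$kind[match(node_section_id, graph$comps$section_id)]
  if (!identical(kind, "node")) {
    abort(sprintf("section %d is a %s; AP clamp sites must be nodes",
                  node_section_id, kind %||% "missing section"))
  }
  prot <- stimulus_protocol(tibble(
    section_id = node_section_id, pos = 0.5, kind = "voltage_clamp_waveform",
    amplitude_nA = NA_real_, onset_ms = 0, duration_ms = cfg$t_stop,
    waveform = list(waveform)))
  rec <- tibble(section_id = graph$comps$section_id, pos = graph$comps$pos,
                site = sprintf("c%04d", seq_len(nrow(graph$comps))))
  run <- run_simulation(graph, prot, cfg, record = rec, record_all = TRUE,
                        params = params)
  traj_to_traces(run, graph)
}

#' Derive the three potentials from a state matrix
#'
#' Given core and periaxonal potentials, returns the transaxonal,
#' transmyelin and transfiber potentials. `V_mym = V_m + V_my` holds
#' identically; `V_my = 0` in unmyelinated compartments.
#'
#' @param V_core numeric vector/matrix of core potentials, mV.
#' @param V_peri matching periaxonal potentials (0 where unmyelinated).
#' @return A list with `V_m`, `V_my`, `V_mym`.
#' @export
three_potentials <- function(V_core, V_peri = 0) {
  list(V_m = V_core - V_peri, V_my = V_peri, V_mym = V_core)
}

#' Pipette model
#'
#' A patch pipette modelled as a tapering cable of `n_sections` cylinders.
#' The wall behaves as a leaky dielectric with fixed specific resistance and
#' a capacitance that is either fitted (`C_pip` of the parameter set) or
#' taken from the geometric estimate of [pipette_cpip_geometric()]. The
#' axial resistance profile follows the taper and is scaled so the total
#' equals the bridge balance.
#'
#' @param n_sections number of cylinders (default 200).
#' @param section_len_um cylinder length, um.
#' @param tip_diam_um,back_diam_um tip and back diameters, um.
#' @param wall_R_Gohm_cm2 wall specific resistance, GOhm cm^2 (default 50).
#' @param bridge_MOhm bridge-balance series resistance, MOhm.
#' @param use_fit_cpip take wall capacitance from the `C_pip` parameter
#'   (default) rather than the geometric estimate.
#' @return A `pipette_model` list.
#' @export
pipette_model <- function(n_sections = 200, section_len_um = 10,
                          tip_diam_um = 1, back_diam_um = 530,
                          wall_R_Gohm_cm2 = 50, bridge_MOhm = 15,
                          use_fit_cpip = TRUE) {
  if (bridge_MOhm < 0) abort("bridge balance must be non-negative")
  structure(list(n_sections = n_sections, section_len_um = section_len_um,
                 tip_diam_um = tip_diam_um, back_diam_um = back_diam_um,
                 wall_R_Gohm_cm2 = wall_R_Gohm_cm2, bridge_MOhm = bridge_MOhm,
                 use_fit_cpip = use_fit_cpip),
            class = "pipette_model")
}

#' Geometric pipette wall capacitance
#'
#' Capacitance of a tapering glass wall treated as a conical capacitor with
#' front-end angle `alpha`; at `alpha = 90` degrees this reduces to the
#' coaxial form `2 pi L K e0 / ln(r_outer/r_inner)`. Divided by the outer
#' lateral cone surface, it yields a specific capacitance per cm^2.
#'
#' @param L_cm modelled tip length, cm.
#' @param r_inner_cm,r_outer_cm front-end inner and outer radii, cm.
#' @param R_inner_cm,R_outer_cm back-end inner and outer radii, cm.
#' @param K_pip wall dielectric constant (default 4.7).
#' @param alpha_deg front-end angle, degrees.
#' @return List with `C_uF` (total) and `C_uF_cm2` (per outer wall area).
#' @export
pipette_cpip_geometric <- function(L_cm = 0.2, r_inner_cm = 0.5e-4,
                                   r_outer_cm = 1e-4, R_inner_cm = 265e-4,
                                   R_outer_cm = 290e-4, K_pip = 4.7,
                                   alpha_deg = 90) {
  eps0 <- 8.85e-8  # uF / cm
  a <- alpha_deg * pi / 180
  cot <- if (abs(alpha_deg - 90) < 1e-12) 0 else cos(a) / sin(a)
  C <- 2 * pi * L_cm * K_pip * eps0 /
    (sin(a) * log((2 * r_outer_cm + L_cm * cot) / (2 * r_inner_cm + L_cm * cot)))
  A <- pi * (R_outer_cm + r_outer_cm) *
    sqrt((R_outer_cm - r_outer_cm)^2 + L_cm^2)
  list(C_uF = C, C_uF_cm2 = C / A)
}

#' Attach a pipette to the graph
#'
#' Appends the pipette cable to a somatic/dendritic/AIS/nodal compartment.
#' The pipette interior couples axially to the cell; its wall couples
#' radially to ground.
#'
#' @param graph a `compartment_graph`.
#' @param section_id,pos attachment site.
#' @param pip a [pipette_model()].
#' @return The augmented graph; the pipette becomes a pseudo-section whose
#'   id is recorded in `graph$pipette_section`, with the far (back) end last.
#' @export
attach_pipette <- function(graph, section_id, pos = 0.5, pip = pipette_model()) {
  at <- comp_index(graph, section_id, pos)
  kind <- graph$comps$kind[at]
  if (!kind %in% c("soma", "dendrite", "ais", "node")) {
    abort(sprintf("pipettes attach to soma/dendrite/AIS/node, not %s", kind))
  }
  n0 <- graph$n_core
  ns <- pip$n_sections
  sec_id <- max(graph$comps$section_id) + 1L
  dd <- pip$tip_diam_um +
    (pip$back_diam_um - pip$tip_diam_um) * ((seq_len(ns) - 0.5) / ns)
  newc <- tibble(comp = n0 + seq_len(ns), section_id = sec_id,
                 kind = "pipette", pos = (seq_len(ns) - 0.5) / ns,
                 x_path = NA_real_, L_um = pip$section_len_um, diam_um = dd,
                 myelinated = FALSE, peri = NA_integer_)
  # tapered axial profile scaled to the bridge balance
  raw <- 4 * (pip$section_len_um / UM_PER_CM) / (pi * (dd / UM_PER_CM)^2)
  edge_raw <- c(raw[1] / 2, (raw[-ns] + raw[-1]) / 2)  # cell->tip, then chain
  scale <- if (sum(edge_raw) > 0) (pip$bridge_MOhm * 1e6) / sum(edge_raw) else 0
  # per-edge resistance floored at 1 kOhm (total <= 0.2 MOhm, negligible
  # against bridge balances of MOhm scale) to keep the system well
  # conditioned when the bridge balance is zero
  newe <- tibble(i = c(at, n0 + seq_len(ns - 1)),
                 j = n0 + seq_len(ns),
                 axial_factor = NA_real_,
                 R_fixed_ohm = pmax(edge_raw * scale, 1e3))
  graph$comps <- dplyr::bind_rows(graph$comps, newc)
  graph$edges <- dplyr::bind_rows(graph$edges, newe)
  graph$n_core <- n0 + ns
  graph$Rm_override <- c(graph$Rm_override, rep(pip$wall_R_Gohm_cm2 * 1e6, ns))
  cpip_val <- pipette_cpip_geometric()$C_uF_cm2
  graph$Cm_override <- c(graph$Cm_override, rep(cpip_val, ns))
  if (pip$use_fit_cpip) {
    graph$cpip_slot <- c(graph$cpip_slot, n0 + seq_len(ns))
  }
  graph$pipette_section <- sec_id
  graph
}
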