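# shared fixtures, memoised so expensive simulations are built once per run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# minimal soma + short myelinated axon, coarse grid: used by solver tests
tiny_axon_morph <- function() {
  morphology(dplyr::bind_rows(
    section_row(1, "soma", NA, 20, 15),
    section_row(2, "ais", 1, 20, 1.2),
    section_row(3, "paranode", 2, 2.3, 1.1),
    section_row(4, "internode", 3, 40, 1.1),
    section_row(5, "paranode", 4, 2.3, 1.1),
    section_row(6, "node", 5, 1, 1.1)))
}

# bare unbranched axon trunk for annotation tests
bare_axon_morph <- function(L = 100, d = 1) {
  morphology(section_row(1, "axon", NA, L, d))
}

# a 4-internode synthetic cell with AP-clamp latency profiles for the
# double-cable and the collapsed single-cable circuit
salt_setup <- function() fixture("salt_setup", function() {
  cfg <- synth_config(seed = 3, n_internodes = 4)
  gen <- make_l5_morphology(cfg)
  scfg <- solver_config(dt = 0.005, t_stop = 6)
  graph <- discretize(gen$morph, gen$params, scfg)
  nodes <- gen$morph$id[gen$morph$kind == "node"]
  wf <- ap_waveform(t_onset = 1, t_stop_ms = 6, dt_ms = 0.005)
  prof_dc <- spatial_profile(ap_clamp(graph, nodes[1], wf, scfg))
  prof_sc <- spatial_profile(ap_clamp(to_single_cable(graph), nodes[1], wf, scfg))
  node_x <- prof_dc$x_path[prof_dc$kind == "node"]
  list(cfg = cfg, gen = gen, graph = graph, scfg = scfg, nodes = nodes,
       node_x = sort(node_x), prof_dc = prof_dc, prof_sc = prof_sc)
})

# a 5-internode active model with a propagated AP
active_setup <- function() fixture("active_setup", function() {
  cfg <- synth_config(seed = 4, n_internodes = 5)
  gen <- make_l5_morphology(cfg)
  scfg <- solver_config(dt = 0.0025, t_stop = 8)
  graph <- discretize(gen$morph, gen$params, scfg)
  active <- build_active_model(graph)
  prot <- current_step(2, onset_ms = 1, duration_ms = 1)
  traces <- simulate_ap(active, prot, scfg)
  st <- attr(traces, "sites")
  nodes <- st[st$kind == "node", ]
  nodes <- nodes[order(nodes$x_path), ]
  list(cfg = cfg, gen = gen, scfg = scfg, graph = graph, active = active,
       prot = prot, traces = traces, nodes = nodes)
})

# Crank-Nicolson solution of a small two-layer system vs the dense
# matrix-exponential solution with piecewise-constant input, plus the
# backward-Euler Kirchhoff residual; returns worst-case deviations
expm_oracle_check <- function(dt = 1e-3, t_stop = 3) {
  m <- tiny_axon_morph()
  p <- cable_params()
  cfg <- solver_config(dt = dt, method = "crank_nicolson", t_stop = t_stop,
                       d_lambda = 0.35)
  g <- discretize(m, p, cfg)
  sys <- assemble_system(g, p)
  B <- solve(sys$M, sys$A)
  stim <- comp_index(g, 1, 0.5)
  onset <- 0.5; dur <- 1; amp <- -0.3
  E <- function(t) as.matrix(Matrix::expm(Matrix::Matrix(B * t)))
  b1 <- sys$b0; b1[stim] <- b1[stim] + amp
  xs1 <- solve(sys$A, -b1)
  xs0 <- solve(sys$A, -sys$b0)
  exact_at <- function(tt) {
    if (tt <= onset) return(sys$x0)
    if (tt <= onset + dur) {
      return(as.numeric(xs1 + E(tt - onset) %*% (sys$x0 - xs1)))
    }
    xend <- as.numeric(xs1 + E(dur) %*% (sys$x0 - xs1))
    as.numeric(xs0 + E(tt - onset - dur) %*% (xend - xs0))
  }
  prot <- current_step(amp, onset, dur)
  rec <- tibble::tibble(section_id = c(1, 4, 6), pos = 0.5)
  ts <- simulate_passive(g, prot, cfg, record = rec)
  tm <- axoncable:::trace_matrix(ts, "V_mym")
  comps <- vapply(c(1, 4, 6), function(s) comp_index(g, s, 0.5), integer(1))
  max_err_mV <- max(vapply(c(1, 1.5, 2, 3), function(tq) {
    xe <- exact_at(tq)
    row <- which.min(abs(tm$time - tq))
    max(abs(tm$m[row, ] - xe[comps]))
  }, numeric(1)))

  # Kirchhoff residual of a backward-Euler run with full state recorded
  cfg_be <- solver_config(dt = 0.01, method = "backward_euler", t_stop = 2,
                          d_lambda = 0.35)
  run <- axoncable:::run_simulation(g, prot, cfg_be, record_all = TRUE)
  X <- run$traj
  nstep <- nrow(X) - 1
  inj <- matrix(0, nstep, 1)
  tmid <- (seq_len(nstep) - 0.5) * cfg_be$dt
  inj[tmid >= onset & tmid < onset + dur, 1] <- amp
  sysb <- run$sys
  # scale by the largest branch (axial/membrane) current over the run
  imax <- 0; worst <- 0
  steps <- seq(10, nstep, by = 7)
  for (s in steps) {
    b <- sysb$b0
    b[stim] <- b[stim] + inj[s, 1]
    rhs <- sysb$A %*% X[s + 1, ] + b
    res <- sysb$M %*% (X[s + 1, ] - X[s, ]) / cfg_be$dt - rhs
    imax <- max(imax, max(abs(rhs)), abs(inj[s, 1]))
    worst <- max(worst, max(abs(res)))
  }
  rel <- worst / imax
  list(max_err_mV = max_err_mV, charge_residual = rel, n = sys$n)
}

# a small recovery problem shared by fitting tests (2 internodes, short
# traces, modest trial count)
recovery_setup <- function() fixture("recovery_setup", function() {
  cfg <- synth_config(seed = 7, n_internodes = 2, n_trials = 30,
                      t_stop_ms = 25)
  gen <- make_l5_morphology(cfg)
  raw <- make_recording_set(gen$morph, gen$params, cfg)
  avg <- preprocess_trials(raw, pulse_onset_ms = cfg$pulse_onset_ms)
  scfg <- solver_config(dt = 1 / cfg$sampling_khz, t_stop = cfg$t_stop_ms)
  graph <- discretize(gen$morph, cable_params(), scfg)
  sites <- tibble::tibble(site = c("soma", "axon_end"),
                          section_id = c(1L, max(gen$morph$id)), pos = 0.5,
                          role = c("injecting_recording", "recording_only"))
  sub <- avg[avg$site == "soma" & avg$level == 300, ]
  nf <- noise_floor(sub$time, sub$v, cfg$pulse_onset_ms)
  problem <- fit_problem(graph, avg, sites,
                         tibble::tibble(onset_ms = cfg$pulse_onset_ms,
                                        duration_ms = cfg$pulse_ms),
                         circuit = "DC", noise_floor_mV2 = nf)
  list(cfg = cfg, gen = gen, raw = raw, avg = avg, graph = graph,
       sites = sites, noise_floor = nf, problem = problem)
})
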