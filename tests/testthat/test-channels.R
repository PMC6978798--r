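test_that("zero channel densities reproduce the passive solver exactly", {
  g <- discretize(tiny_axon_morph(), cable_params(),
                  solver_config(dt = 0.02, t_stop = 4))
  zeros <- channel_density_table(
    ais = c(Nav = 0), soma = c(Nav = 0), dendrite = c(Nav = 0),
    dendrite_distal = c(Nav = 0), internode = c(Nav = 0),
    paranode = c(Nav = 0), node = c(Nav = 0), unmyelinated_end = c(Nav = 0))
  ga <- build_active_model(g, zeros)
  expect_null(ga$channels)
  cfg <- solver_config(dt = 0.02, t_stop = 4)
  prot <- current_step(-0.2, 0.5, 1)
  active <- simulate_ap(ga, prot, cfg)
  passive <- simulate_passive(g, prot, cfg,
                              record = tibble::tibble(
                                section_id = g$comps$section_id,
                                pos = g$comps$pos,
                                site = sprintf("c%04d", seq_len(nrow(g$comps)))))
  expect_identical(active$V_m, passive$V_m)
})

test_that("density table encodes the nodal/internodal contrast and validates", {
  tbl <- channel_density_table()
  nav_node <- tbl$density[tbl$domain == "node" & tbl$channel == "Nav"]
  nav_ino <- tbl$density[tbl$domain == "internode" & tbl$channel == "Nav"]
  expect_equal(nav_node / nav_ino, 22500)
  expect_error(channel_density_table(node = c(Nav = -5)), "non-negative")

  g <- discretize(tiny_axon_morph(), cable_params(), solver_config())
  expect_error(build_active_model(g, tibble::tibble(
    domain = "myelin", channel = "Kv1", density = 10)), "myelin")
})

test_that("suprathreshold stimulation spikes and gating stays in bounds", {
  s <- active_setup()
  flags <- attr(s$traces, "ap")
  expect_true(flags$spiked)
  st <- attr(s$traces, "sites")
  soma <- s$traces[s$traces$site == st$site[st$kind == "soma"][1], ]
  expect_gt(max(soma$V_m), 0)

  # subthreshold stimulus: no AP flag, no error
  sub <- simulate_ap(s$active, current_step(0.1, 1, 1), s$scfg)
  expect_false(attr(sub, "ap")$spiked)

  # gate states (returned by the kernel) remain probabilities
  run <- axoncable:::run_simulation(s$active, s$prot, s$scfg,
                                    channels = s$active$channels,
                                    record_all = TRUE)
  expect_true(all(is.finite(run$traj)))
  gf <- axoncable:::cpp_integrate(
    run$sys$M, run$sys$A, run$sys$b0, run$sys$x0, s$scfg$dt, 400, 0L,
    integer(0), as.integer(run$schedules$inj_idx) - 1L, run$schedules$inj[1:400, , drop = FALSE],
    integer(0), matrix(0, 400, 0), s$active$channels, TRUE)$gates_final
  expect_true(all(gf >= 0 & gf <= 1))
})

test_that("node APs exceed internodal APs in amplitude and rate of rise", {
  s <- active_setup()
  prof <- spatial_profile(s$traces, min_peak_mV = 5)
  nodes <- prof[prof$kind == "node", ]
  for (i in unique(stats::na.omit(prof$internode))) {
    ino <- prof[!is.na(prof$internode) & prof$internode == i, ]
    adj <- nodes[abs(nodes$x_path - mean(ino$x_path)) < 150, ]
    expect_gt(min(adj$peak_mV), max(ino$peak_mV))
    expect_gt(min(adj$max_dvdt_V_s), max(ino$max_dvdt_V_s))
  }
})

test_that("conduction velocity extraction matches constructed waves", {
  # synthetic travelling wave: 200 um apart, onsets 0.2 ms apart -> 1 m/s
  tt <- seq(0, 5, by = 0.01)
  wave <- function(t0) 100 / (1 + exp(-(tt - t0) / 0.1)) - 75
  ts <- new_trace_set(
    dplyr::bind_rows(
      tibble::tibble(time = tt, site = "a", V_m = wave(1.0)),
      tibble::tibble(time = tt, site = "b", V_m = wave(1.2))),
    sites = tibble::tibble(site = c("a", "b"), x_path = c(100, 300),
                           kind = "node", comp = 1:2))
  cv <- conduction_velocity(ts, c("a", "b"))
  expect_equal(cv$cv_m_s, 1, tolerance = 0.02)
  expect_false(cv$flagged)

  # identical traces: undefined velocity
  ts2 <- new_trace_set(
    dplyr::bind_rows(
      tibble::tibble(time = tt, site = "a", V_m = wave(1.0)),
      tibble::tibble(time = tt, site = "b", V_m = wave(1.0))),
    sites = tibble::tibble(site = c("a", "b"), x_path = c(100, 300),
                           kind = "node", comp = 1:2))
  expect_error(conduction_velocity(ts2, c("a", "b")), "undefined")

  # third-derivative onset of a logistic: d3V/dt3 peaks where the fourth
  # derivative vanishes, at m -/+ ln(5 - 2 sqrt(6)) * k around the midpoint
  k <- 0.15; m <- 3
  v <- 100 / (1 + exp(-(tt - m) / k)) - 75
  d3 <- axoncable:::central_deriv(
    axoncable:::central_deriv(axoncable:::central_deriv(v, 0.01), 0.01), 0.01)
  t_first <- axoncable:::first_peak_time(tt, d3)
  expect_equal(t_first, m + k * log(5 - 2 * sqrt(6)), tolerance = 1e-2)
})

test_that("recorded-mode onsets use the noise-referenced dV/dt threshold", {
  # noisy travelling waves at 50 kHz with a known 1 m/s velocity: the
  # 3 SD dV/dt threshold lands in the tens-of-V/s range and recovers it
  set.seed(21)
  tt <- seq(0, 6, by = 0.02)
  wave <- function(t0) 100 / (1 + exp(-(tt - t0) / 0.1)) - 75 +
    stats::rnorm(length(tt), 0, 0.3)
  ts <- new_trace_set(
    dplyr::bind_rows(
      tibble::tibble(time = tt, site = "a", V_m = wave(2.0)),
      tibble::tibble(time = tt, site = "b", V_m = wave(2.2))),
    sites = tibble::tibble(site = c("a", "b"), x_path = c(100, 300),
                           kind = "node", comp = 1:2))
  cv <- conduction_velocity(ts, c("a", "b"), mode = "recorded_threshold",
                            pre_stim_ms = 1.5)
  expect_equal(cv$cv_m_s, 1, tolerance = 0.15)
})

test_that("sustained drive produces repetitive firing that the flags report", {
  s <- active_setup()
  cfg <- solver_config(dt = 0.0025, t_stop = 30)
  ts <- simulate_ap(s$active, current_step(1.5, 1, 28), cfg)
  flags <- attr(ts, "ap")
  expect_true(flags$spiked)
  expect_true(flags$regenerative)  # non-stimulated nodes cross 0 mV repeatedly
})
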