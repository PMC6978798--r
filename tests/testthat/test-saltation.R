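test_that("onset latency interpolates the fractional crossing", {
  tt <- seq(0, 5, by = 0.01)
  # unit step at t = 1
  v <- ifelse(tt >= 1, 1, 0)
  expect_equal(onset_latency(tt, v), 1, tolerance = 0.011)
  # linear ramp 0 -> 1 over [0, 2]: half-max at exactly 1
  ramp <- pmin(pmax(tt / 2, 0), 1)
  expect_equal(onset_latency(tt, ramp), 1, tolerance = 1e-9)
  # logistic midpoint = half-max crossing
  v3 <- 1 / (1 + exp(-(tt - 3) / 0.2))
  expect_equal(onset_latency(tt, v3, baseline = 0), 3, tolerance = 1e-3)
  # invariance under affine amplitude scaling
  expect_equal(onset_latency(tt, 40 * v3 - 75, baseline = -75),
               onset_latency(tt, v3, baseline = 0), tolerance = 1e-9)
  expect_error(onset_latency(tt, rep(0, length(tt))), "deflection")
})

test_that("spatial profiles flag interior latency maxima under AP clamp", {
  s <- salt_setup()
  prof <- s$prof_dc
  # latency is defined at positions with real deflections, ordered by path
  expect_true(all(diff(prof$x_path) > 0))
  clamp_x <- prof$x_path[prof$kind == "node"][1]
  distal <- prof[prof$x_path > clamp_x, ]
  # per-internode maxima sit in the interior, not at the internode edges
  for (i in unique(stats::na.omit(distal$internode))) {
    rows <- which(!is.na(distal$internode) & distal$internode == i)
    if (length(rows) < 3) next
    peak_at <- which.max(distal$latency_ms[rows])
    expect_gt(peak_at, 1)
    expect_lt(peak_at, length(rows))
  }
  # each node is earlier than the preceding mid-internode
  nodes <- distal[distal$kind == "node", ]
  for (r in seq_len(nrow(nodes))) {
    before <- distal[distal$kind == "internode" &
                       distal$x_path < nodes$x_path[r] &
                       distal$x_path > nodes$x_path[r] - 130, ]
    if (!nrow(before)) next
    expect_lt(nodes$latency_ms[r], max(before$latency_ms))
  }
})

test_that("a uniformly translating wave gives a linear latency profile", {
  tt <- seq(0, 5, by = 0.01)
  xs <- seq(0, 400, by = 100)
  df <- purrr::map_dfr(seq_along(xs), function(j) {
    tibble::tibble(time = tt, site = sprintf("s%d", j),
                   V_m = 50 / (1 + exp(-(tt - 1 - xs[j] / 400) / 0.1)) - 75)
  })
  ts <- new_trace_set(df, sites = tibble::tibble(
    site = sprintf("s%d", seq_along(xs)), x_path = xs, kind = "node",
    comp = seq_along(xs)))
  prof <- spatial_profile(ts)
  fitl <- stats::lm(latency_ms ~ x_path, data = prof)
  expect_gt(summary(fitl)$r.squared, 0.999)
  expect_lt(diff(range(prof$peak_mV)), 0.01)
})

test_that("saltation advancement is positive at nodes in the double cable only", {
  s <- salt_setup()
  clamp_x <- min(s$node_x)
  test_nodes <- s$node_x[s$node_x > clamp_x]
  adv_dc <- vapply(test_nodes, function(x)
    saltation_advancement(s$prof_dc, x), numeric(1))
  adv_sc <- vapply(test_nodes, function(x)
    saltation_advancement(s$prof_sc, x), numeric(1))
  expect_true(all(adv_dc > 0.02))      # tens of microseconds or more
  expect_true(all(abs(adv_sc) < 0.01)) # within solver tolerance
  # constructed checks: flat profile -> 0; a 0.2 ms node dip -> 0.2 ms
  prof <- tibble::tibble(x_path = c(95, 100, 105),
                         latency_ms = c(1.2, 1.2, 1.2))
  expect_equal(saltation_advancement(prof, 100), 0)
  prof$latency_ms <- c(1.2, 1.0, 1.2)
  expect_equal(saltation_advancement(prof, 100), 0.2)
  expect_error(saltation_advancement(prof, 500), "not covered")
})

test_that("VSD calibration recovers voltage independent of optical gain", {
  cal <- vsd_calibration(k_mm = 1.18, V_step_soma_mV = -20, dF_cal = -7.5,
                         x_mm = 1.18)
  # at one attenuation length the local step is exactly V_soma / e
  expect_equal(-20 * exp(-1), cal$V_step_soma_mV * exp(-cal$x_mm / cal$k_mm))
  tt <- seq(0, 10, by = 0.1)
  v_true <- -75 + 30 * exp(-((tt - 5)^2) / 2)
  gain <- 1.7; offset <- 11
  x <- 0.4
  dF_cal <- gain * (-20) * exp(-x / 1.18)
  F_tr <- gain * (v_true + 75) + offset
  cal2 <- vsd_calibration(V_step_soma_mV = -20, dF_cal = dF_cal, x_mm = x)
  v_rec <- calibrate_vsd(F_tr, cal2, baseline = offset)
  expect_equal(v_rec, v_true, tolerance = 1e-12)
  # doubling the gain on both the trace and the calibration changes nothing
  cal3 <- vsd_calibration(V_step_soma_mV = -20, dF_cal = 2 * dF_cal, x_mm = x)
  expect_equal(calibrate_vsd(2 * gain * (v_true + 75) + offset, cal3,
                             baseline = offset), v_true, tolerance = 1e-12)
  # x = 0 and dF = dF_cal returns the somatic step itself
  cal0 <- vsd_calibration(V_step_soma_mV = -20, dF_cal = -5, x_mm = 0)
  expect_equal(calibrate_vsd(c(0, -5), cal0), c(-75, -95))
  expect_error(vsd_calibration(V_step_soma_mV = -20, dF_cal = 0, x_mm = 1),
               "non-zero")
})

test_that("AP features scale as expected and reject flat traces", {
  tt <- seq(0, 5, by = 0.01)
  v <- -75 + 100 * exp(-((tt - 2)^2) / (2 * 0.04))
  f1 <- ap_features(tt, v)
  f2 <- ap_features(tt, -75 + 2 * (v + 75))
  expect_equal(f2$peak_mV, 2 * f1$peak_mV)
  expect_equal(f2$max_dvdt_V_s, 2 * f1$max_dvdt_V_s, tolerance = 1e-9)
  expect_equal(f2$onset_ms, f1$onset_ms, tolerance = 1e-9)
  expect_error(ap_features(tt, rep(-75, length(tt))), "constant")
})

test_that("calibration commutes with feature extraction up to the scale factor", {
  tt <- seq(0, 5, by = 0.01)
  v_true <- -75 + 60 * exp(-((tt - 2)^2) / (2 * 0.04))
  gain <- 0.8
  F_tr <- gain * (v_true + 75) + 3
  x <- 0.25
  cal <- vsd_calibration(V_step_soma_mV = -20,
                         dF_cal = gain * (-20) * exp(-x / 1.18), x_mm = x)
  f_cal <- ap_features(tt, calibrate_vsd(F_tr, cal))
  f_true <- ap_features(tt, v_true)
  expect_equal(f_cal$peak_mV, f_true$peak_mV, tolerance = 1e-9)
  expect_equal(f_cal$onset_ms, f_true$onset_ms, tolerance = 1e-9)
})
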