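make_trial_set <- function(base, n_trials, noise_sd = 0, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    tibble::tibble(time = base$time, site = "soma", level = 300, trial = tr,
                   v = base$v + stats::rnorm(length(base$v), 0, noise_sd))
  })
}

test_that("trial preprocessing baselines, rejects artifacts and averages", {
  tt <- seq(0, 20, by = 0.02)
  clean <- tibble::tibble(time = tt, v = ifelse(tt > 5 & tt < 12,
                                                -3 * exp(-(tt - 5) / 4), 0))
  # identical trials with a constant 5 mV offset average to zero baseline
  raw <- make_trial_set(clean, 4)
  raw$v <- raw$v + 5
  avg <- preprocess_trials(new_trace_set(raw), pulse_onset_ms = 5)
  expect_lt(abs(mean(avg$v[avg$time < 3.5])), 1e-12)
  expect_equal(nrow(avg), length(tt))

  # one trial with a 0.5 ms artifact of 10 SD covering ~6% of samples:
  # rejected; a 0.05 ms excursion (below the filter criterion) is retained
  noisy <- make_trial_set(clean, 10, noise_sd = 0.1, seed = 3)
  long_artifact <- noisy$trial == 7 & noisy$time > 14 & noisy$time < 14 + 1.25
  expect_gt(mean(long_artifact[noisy$trial == 7]), 0.05)
  noisy$v[long_artifact] <- noisy$v[long_artifact] + 1.0
  avg2 <- preprocess_trials(new_trace_set(noisy), pulse_onset_ms = 5)
  kept <- attr(avg2, "meta")$kept_trials
  expect_equal(kept[["soma 300"]], 9L)

  short <- make_trial_set(clean, 10, noise_sd = 0.1, seed = 4)
  blip <- rep(FALSE, length(tt))
  starts <- seq(120, 1000, by = 30)  # many 0.04 ms blips: > 5% of samples
  for (s0 in starts) blip[s0 + 0:1] <- TRUE
  expect_gt(mean(blip), 0.05)
  short$v[short$trial == 2][blip] <- short$v[short$trial == 2][blip] + 1.0
  avg3 <- preprocess_trials(new_trace_set(short), pulse_onset_ms = 5)
  expect_equal(attr(avg3, "meta")$kept_trials[["soma 300"]], 10L)

  # all trials carrying the same huge artifact cannot all be rejected
  # (the band tracks them); a single surviving configuration must error
  # only when every trial fails the rule
  expect_error(preprocess_trials(new_trace_set(make_trial_set(clean, 1)),
                                 pulse_onset_ms = 5), ">= 2 trials")
})

test_that("fit windows respect the electrode role", {
  tt <- seq(0, 25, by = 0.02)
  w1 <- fit_window(tt, 10, 2, "injecting_recording")
  expect_equal(w1$t_start, 12.5)
  expect_equal(w1$t_end, 25)
  w2 <- fit_window(tt, 10, 2, "recording_only")
  expect_equal(w2$t_start, 12)
  expect_error(fit_window(tt, 24, 2, "recording_only"), "empty")
})

test_that("the combined objective is a weighted mean of windowed MSEs", {
  tt <- seq(0, 10, by = 0.1)
  target <- dplyr::bind_rows(
    tibble::tibble(time = tt, site = "a", level = 300, v = 0),
    tibble::tibble(time = tt, site = "b", level = 300, v = 0))
  model <- target
  windows <- tibble::tibble(site = c("a", "b"), t_start = 2, t_end = 10)
  expect_equal(objective_mse(model, target, windows)$combined, 0)
  # constant 1 mV offset in the window -> 1 mV^2
  model$v[model$site == "a"] <- 1
  o <- objective_mse(model, target, windows)
  expect_equal(o$per_trace$mse[o$per_trace$site == "a"], 1)
  expect_equal(o$combined, 0.5)
  # traces with MSE 1 and 3 at equal weights -> 2
  model$v[model$site == "b"] <- sqrt(3)
  expect_equal(objective_mse(model, target, windows)$combined, 2)
})

test_that("the noise floor is the pre-stimulus variance", {
  set.seed(8)
  tt <- seq(0, 20, by = 0.02)
  v <- stats::rnorm(length(tt), 0, 0.1)
  expect_equal(noise_floor(tt, v, 5), 0.01, tolerance = 0.15)
  expect_equal(noise_floor(tt, rep(2, length(tt)), 5), 0)
  ramp <- tt
  expect_gt(noise_floor(tt, ramp, 5), 1)  # drift is flagged as variance
  expect_error(noise_floor(tt[1:5], v[1:5], 5), "10 samples")
})

test_that("a budget of one generation returns the evaluated initial sample", {
  rs <- recovery_setup()
  fit <- optimize_fit(rs$problem, budget = list(pop = 1, generations = 1),
                      seed = 2)
  expect_equal(fit$exit, "max_iter")
  expect_equal(nrow(fit$solutions), 1)
  expect_true(is.finite(fit$best$error))
})

test_that("solutions always respect the box bounds", {
  rs <- recovery_setup()
  fit <- optimize_fit(rs$problem,
                      budget = list(pop = 12, generations = 4,
                                    refine_passes = 1, nm_evals = 50), seed = 3)
  b <- rs$problem$bounds[rs$problem$bounds$fit, ]
  for (nm in b$parameter) {
    vals <- c(fit$solutions[[nm]], fit$best$params[[nm]])
    expect_true(all(vals >= b$low[b$parameter == nm] * (1 - 1e-9)))
    expect_true(all(vals <= b$high[b$parameter == nm] * (1 + 1e-9)))
  }
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
})

test_that("a parameter the data cannot see stays dispersed across solutions", {
  # soma + dendrite only: no myelin anywhere, so r_pa and r_pn cannot move
  # the objective; their final-population spread must span the bounds
  m <- morphology(dplyr::bind_rows(
    section_row(1, "soma", NA, 20, 15),
    section_row(2, "dendrite", 1, 300, 2)))
  cfg <- synth_config(seed = 11, n_trials = 10, t_stop_ms = 20,
                      artifact_prob = 0)
  truth <- cable_params()
  raw <- make_recording_set(m, truth, cfg,
                            sites = tibble::tibble(section_id = 1L, pos = 0.5,
                                                   site = "soma",
                                                   role = "injecting_recording"))
  avg <- preprocess_trials(raw, pulse_onset_ms = 5)
  graph <- discretize(m, truth, solver_config(dt = 0.02, t_stop = 20))
  pr <- fit_problem(graph, avg,
                    tibble::tibble(site = "soma", section_id = 1L, pos = 0.5,
                                   role = "injecting_recording"),
                    tibble::tibble(onset_ms = 5, duration_ms = 2),
                    circuit = "DC")
  fit <- optimize_fit(pr, budget = list(pop = 24, generations = 10,
                                        refine_passes = 0), seed = 6)
  b <- pr$bounds[pr$bounds$fit, ]
  spread_z <- function(nm) {
    lo <- log(b$low[b$parameter == nm]); hi <- log(b$high[b$parameter == nm])
    diff(range(log(fit$solutions[[nm]]))) / (hi - lo)
  }
  expect_gt(spread_z("r_pa"), 0.5)
  expect_gt(spread_z("r_pn"), 0.5)
  # while an identified parameter has collapsed
  expect_lt(spread_z("C_m"), 0.5)
})

test_that("the normalised log transform scales with its bounds", {
  rs <- recovery_setup()
  pr1 <- rs$problem
  # shifting a parameter's box by a decade maps the same normalised
  # coordinate to a parameter exactly one decade larger
  pr2 <- pr1
  sel <- pr2$bounds$parameter == "R_i"
  pr2$bounds$low[sel] <- pr2$bounds$low[sel] * 10
  pr2$bounds$high[sel] <- pr2$bounds$high[sel] * 10
  z <- rep(0.37, sum(pr1$bounds$fit))
  p1 <- axoncable:::z_to_params(z, pr1)
  p2 <- axoncable:::z_to_params(z, pr2)
  expect_equal(p2$R_i / p1$R_i, 10, tolerance = 1e-12)
  expect_equal(p2$R_m, p1$R_m, tolerance = 1e-12)
  # and the seeded search itself is reproducible
  f1 <- optimize_fit(pr1, budget = list(pop = 6, generations = 1), seed = 9)
  f2 <- optimize_fit(pr1, budget = list(pop = 6, generations = 1), seed = 9)
  expect_identical(f1$solutions$error, f2$solutions$error)
})

test_that("morphology perturbation is seeded, scaled and clipped", {
  gen <- make_l5_morphology(synth_config(seed = 5, n_internodes = 3))
  m0 <- gen$morph
  expect_identical(perturb_morphology(m0, rd_nm = 0, seed = 1)$diam, m0$diam)
  p1 <- perturb_morphology(m0, rd_nm = 300, seed = 4)
  p2 <- perturb_morphology(m0, rd_nm = 300, seed = 4)
  expect_identical(p1$diam, p2$diam)
  ino <- which(m0$kind == "internode")
  deltas <- unlist(purrr::map(ino, function(i) p1$diam[[i]]$diam - m0$diam[[i]]$diam))
  expect_gt(stats::sd(deltas), 0.15)   # ~0.3 um scale
  expect_lt(stats::sd(deltas), 0.6)
  # non-internodal sections untouched
  other <- which(m0$kind != "internode")
  expect_identical(p1$diam[other], m0$diam[other])
  expect_warning(perturb_morphology(m0, rd_nm = 5000, seed = 2), "clipped")
})
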