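#' Preprocess raw trial sets
#'
#' Per site and injection level: every trial is baselined by subtracting its
#' mean voltage over the first 70% of the delay preceding the pulse; trials
#' are rejected when more than 5% of their samples fall outside the
#' pointwise across-trial mean +/- 2 SD band, counting only excursions that
#' last at least `min_excursion_ms` (shorter deviations are within the
#' bandwidth of the acquisition filter and treated as false positives);
#' surviving trials are averaged.
#'
#' @param raw a `trace_set` with columns `time`, `site`, `level`, `trial`,
#'   `v`.
#' @param pulse_onset_ms pulse onset (delay), ms.
#' @param outlier_frac rejection fraction (default 0.05).
#' @param n_sd band half-width in SD units (default 2).
#' @param min_excursion_ms minimum excursion duration (default 0.1).
#' @return A `trace_set` of averaged traces (`time`, `site`, `level`, `v`)
#'   with per-group trial counts in `meta$kept_trials`.
#' @export
preprocess_trials <- function(raw, pulse_onset_ms, outlier_frac = 0.05,
                              n_sd = 2, min_excursion_ms = 0.1) {
  stopifnot(all(c("time", "site", "level", "trial", "v") %in% names(raw)))
  tt <- sort(unique(raw$time))
  dt <- tt[2] - tt[1]
  base_win <- tt < 0.7 * pulse_onset_ms
  min_run <- max(1L, round(min_excursion_ms / dt))
  kept <- list()
  out <- purrr::map_dfr(
    split(as_tibble(raw), list(raw$site, raw$level), drop = TRUE),
    function(g) {
      trials <- sort(unique(g$trial))
      if (length(trials) < 2) abort("need >= 2 trials per injection level")
      m <- vapply(trials, function(tr) {
        v <- g$v[g$trial == tr][order(g$time[g$trial == tr])]
        v - mean(v[base_win])
      }, numeric(length(tt)))
      mu <- rowMeans(m)
      sdv <- apply(m, 1, stats::sd)
      bad_trial <- vapply(seq_along(trials), function(j) {
        outside <- abs(m[, j] - mu) > n_sd * sdv
        r <- rle(outside)
        qualifying <- r$values & r$lengths >= min_run
        sum(r$lengths[qualifying]) / length(tt) > outlier_frac
      }, logical(1))
      if (all(bad_trial)) {
        abort(sprintf("all trials rejected at site %s, level %s pA",
                      g$site[1], g$level[1]))
      }
      kept[[paste(g$site[1], g$level[1])]] <<- sum(!bad_trial)
      tibble(time = tt, site = g$site[1], level = g$level[1],
             v = rowMeans(m[, !bad_trial, drop = FALSE]))
    })
  new_trace_set(out, sites = trace_sites(raw),
                meta = c(trace_meta(raw), list(kept_trials = kept)))
}

#' Fit window for an electrode role
#'
#' Recordings from injecting/recording electrodes are fitted from 0.5 ms
#' after the end of the current injection (skipping lingering pipette
#' discharge artifacts); recording-only electrodes from the pulse end.
#'
#' @param time sample times, ms.
#' @param pulse_onset_ms,pulse_duration_ms pulse timing.
#' @param electrode_role `"injecting_recording"` or `"recording_only"`.
#' @return Tibble `t_start`, `t_end`.
#' @export
fit_window <- function(time, pulse_onset_ms, pulse_duration_ms,
                       electrode_role = c("injecting_recording", "recording_only")) {
  electrode_role <- match.arg(electrode_role)
  pulse_end <- pulse_onset_ms + pulse_duration_ms
  t_start <- pulse_end + if (electrode_role == "injecting_recording") 0.5 else 0
  t_end <- max(time)
  if (t_start >= t_end) abort("fit window is empty: pulse ends at or after the trace end")
  tibble(t_start = t_start, t_end = t_end)
}

#' Combined mean-squared error over fit windows
#'
#' @param model,target matching tibbles with `time`, `site`, `level`, `v`.
#' @param windows tibble with `site`, `t_start`, `t_end`.
#' @param weights optional per-trace weights (named by `site.level`);
#'   default equal.
#' @return List: `combined` (mV^2) and per-trace tibble `per_trace`.
#' @export
objective_mse <- function(model, target, windows, weights = NULL) {
  key <- function(d) paste(d$site, d$level, sep = ".")
  groups <- unique(key(target))
  per <- purrr::map_dfr(groups, function(k) {
    tg <- target[key(target) == k, ]
    md <- model[key(model) == k, ]
    if (nrow(md) != nrow(tg)) abort(sprintf("model/target sampling mismatch for %s", k))
    w <- windows[windows$site == tg$site[1], ]
    sel <- tg$time >= w$t_start & tg$time <= w$t_end
    if (!any(sel)) abort(sprintf("empty fit window for %s", k))
    tibble(trace = k, site = tg$site[1], level = tg$level[1],
           mse = mean((md$v[sel] - tg$v[sel])^2))
  })
  wts <- if (is.null(weights)) rep(1, nrow(per)) else weights[per$trace]
  list(combined = sum(per$mse * wts) / sum(wts), per_trace = per)
}

#' Noise floor of a trace
#'
#' Signal variance over the delay preceding the current injection.
#'
#' @param time,v the trace.
#' @param delay_ms pre-stimulus window end, ms.
#' @return Variance, mV^2.
#' @export
noise_floor <- function(time, v, delay_ms) {
  seg <- v[time < delay_ms]
  if (length(seg) < 10) abort("pre-stimulus delay too short for a noise estimate (< 10 samples)")
  stats::var(seg)
}

#' Define a passive fitting problem
#'
#' @param graph a [discretize()]d `compartment_graph` of the cell.
#' @param target averaged, baselined target traces: tibble `time`, `site`,
#'   `level` (pA), `v` (mV, deviation from rest).
#' @param sites tibble `site`, `section_id`, `pos`, `role`
#'   (`injecting_recording` / `recording_only`).
#' @param injection tibble `onset_ms`, `duration_ms` (shared across levels);
#'   levels are taken from the target.
#' @param circuit `"DC"`, `"DC_no_rpn"`, `"SC"`, `"SC_expected"`,
#'   `"SC_rmn"`, `"SC_rmi"` or `"SC_per_internode"`.
#' @param bounds parameter bounds ([default_bounds()]); rows with
#'   `fit = FALSE` stay at `base` values.
#' @param base baseline [cable_params()] supplying non-fitted parameters.
#' @param noise_floor_mV2 experimental noise variance used for the
#'   refinement exit rule.
#' @return A `fit_problem`.
#' @export
fit_problem <- function(graph, target, sites, injection,
                        circuit = "DC", bounds = default_bounds(),
                        base = cable_params(), noise_floor_mV2 = 1e-4) {
  target <- as_tibble(target)
  missing_sites <- setdiff(unique(target$site), sites$site)
  if (length(missing_sites)) {
    abort(paste0("target sites without a model site: ",
                 paste(missing_sites, collapse = ", ")))
  }
  tt <- sort(unique(target$time))
  windows <- purrr::map_dfr(seq_len(nrow(sites)), function(r) {
    w <- fit_window(tt, injection$onset_ms, injection$duration_ms, sites$role[r])
    tibble(site = sites$site[r], t_start = w$t_start, t_end = w$t_end)
  })
  # which bounds rows actually matter for this circuit
  fit_tbl <- bounds
  drop <- character()
  if (circuit %in% c("SC", "SC_rmn", "SC_rmi", "SC_per_internode")) drop <- c("r_pa", "r_pn")
  if (circuit == "SC_expected") drop <- c("r_pa", "r_pn", "R_my", "C_my")
  if (circuit == "DC_no_rpn") drop <- "r_pn"
  if (is.null(graph$pipette_section)) drop <- c(drop, "C_pip")
  fit_tbl$fit[fit_tbl$parameter %in% drop] <- FALSE
  if (circuit == "SC_rmn" && !"R_mN" %in% fit_tbl$parameter) {
    fit_tbl <- dplyr::bind_rows(fit_tbl, tibble(
      parameter = "R_mN", low = fit_tbl$low[fit_tbl$parameter == "R_m"],
      high = fit_tbl$high[fit_tbl$parameter == "R_m"],
      transform = "log", fit = TRUE))
  }
  if (circuit == "SC_rmi" && !"R_mI" %in% fit_tbl$parameter) {
    fit_tbl <- dplyr::bind_rows(fit_tbl, tibble(
      parameter = "R_mI", low = fit_tbl$low[fit_tbl$parameter == "R_m"],
      high = fit_tbl$high[fit_tbl$parameter == "R_m"],
      transform = "log", fit = TRUE))
  }
  problem <- structure(
    list(graph = graph, target = target, sites = as_tibble(sites),
         injection = injection, circuit = circuit, bounds = fit_tbl,
         base = base, windows = windows,
         noise_floor_mV2 = noise_floor_mV2,
         levels = sort(unique(target$level)),
         time = tt),
    class = "fit_problem")
  problem$cache <- prepare_forward(problem)
  problem
}

# precomputed pieces that do not depend on the candidate parameters:
# stimulus schedule, recording compartments, and the target as a
# [time x site x level] array with per-site window masks
prepare_forward <- function(problem) {
  cfg <- problem$graph$cfg
  cfg$dt <- problem$time[2] - problem$time[1]
  cfg$t_stop <- max(problem$time)
  nstep <- ceiling(cfg$t_stop / cfg$dt)
  graph <- problem$graph
  graph$cfg <- cfg
  inj_site <- problem$sites[problem$sites$role == "injecting_recording", ][1, ]
  prot <- stimulus_protocol(tibble(
    section_id = inj_site$section_id, pos = inj_site$pos,
    kind = "current_step", amplitude_nA = 1,
    onset_ms = problem$injection$onset_ms,
    duration_ms = problem$injection$duration_ms, waveform = list(NULL)))
  sch <- build_schedules(graph, prot, cfg, nstep)
  rec <- site_table(graph, problem$sites)
  ns <- nrow(rec); nl <- length(problem$levels); ntm <- length(problem$time)
  tgt <- array(NA_real_, c(ntm, ns, nl))
  win <- matrix(FALSE, ntm, ns)
  for (s in seq_len(ns)) {
    w <- problem$windows[problem$windows$site == rec$site[s], ]
    win[, s] <- problem$time >= w$t_start & problem$time <= w$t_end
    for (l in seq_len(nl)) {
      sub <- problem$target[problem$target$site == rec$site[s] &
                              problem$target$level == problem$levels[l], ]
      tgt[, s, l] <- sub$v[order(sub$time)]
    }
  }
  list(cfg = cfg, graph = graph, sch = sch, rec = rec, nstep = nstep,
       target_arr = tgt, win = win)
}

# unit-current response at the recording sites (deviation from rest),
# as a [time x site] matrix
forward_unit <- function(problem, params) {
  cc <- problem$cache
  sys <- assemble_system(cc$graph, params, problem$circuit)
  res <- cpp_integrate(sys$M, sys$A, sys$b0, sys$x0, cc$cfg$dt, cc$nstep, 0L,
                       as.integer(cc$rec$comp) - 1L,
                       as.integer(cc$sch$inj_idx) - 1L, cc$sch$inj,
                       integer(0) - 1L, matrix(0, cc$nstep, 0),
                       list(), FALSE)
  sweep(res$traj, 2, res$traj[1, ])
}

fast_objective <- function(problem, params) {
  cc <- problem$cache
  unit <- forward_unit(problem, params)
  ns <- ncol(unit); nl <- length(problem$levels)
  mse <- matrix(NA_real_, ns, nl)
  for (s in seq_len(ns)) {
    w <- cc$win[, s]
    us <- unit[w, s]
    for (l in seq_len(nl)) {
      amp <- problem$levels[l] / 1000
      mse[s, l] <- mean((amp * us - cc$target_arr[w, s, l])^2)
    }
  }
  list(combined = mean(mse),
       per_trace = tibble(site = rep(cc$rec$site, nl),
                          level = rep(problem$levels, each = ns),
                          mse = as.numeric(mse)))
}

# params list from a point in normalised log space
z_to_params <- function(z, problem) {
  p <- unclass(problem$base)
  b <- problem$bounds[problem$bounds$fit, ]
  vals <- exp(log(b$low) + z * (log(b$high) - log(b$low)))
  for (i in seq_along(b$parameter)) p[[b$parameter[i]]] <- vals[i]
  class(p) <- "cable_params"
  p
}

# forward model: passive unit-current response scaled per level (the
# passive circuit is linear, so one simulation serves all levels)
forward_model <- function(problem, params) {
  unit <- forward_unit(problem, params)
  purrr::map_dfr(problem$levels, function(lv) {
    amp <- lv / 1000  # pA -> nA
    purrr::map_dfr(seq_len(nrow(problem$sites)), function(j) {
      tibble(time = problem$time, site = problem$cache$rec$site[j], level = lv,
             v = amp * unit[, j])
    })
  })
}

#' Evaluate the objective at a fixed parameter set
#'
#' Runs the forward model once (no optimisation); used e.g. to score the
#' expected single cable at another circuit's solution.
#'
#' @param problem a [fit_problem()].
#' @param params a [cable_params()].
#' @return List: `combined` (mV^2), `per_trace`.
#' @export
evaluate_params <- function(problem, params) {
  fast_objective(problem, params)
}

eval_candidate <- function(z, problem) {
  params <- z_to_params(z, problem)
  o <- tryCatch(fast_objective(problem, params), error = function(e) NULL)
  if (is.null(o)) return(list(error = Inf, per_trace = NULL))
  list(error = o$combined, per_trace = o$per_trace)
}

#' Evolutionary fit of passive cable parameters
#'
#' Population-based global search in normalised log-parameter space
#' (Latin-hypercube initialisation, tournament selection, uniform
#' crossover, Gaussian mutation, elitism), followed by a derivative-free
#' direction-set refinement of the best candidate whose iteration exits as
#' soon as the error improvement drops below `eta` times the experimental
#' noise floor — parameters that the data cannot constrain beyond the noise
#' are deliberately left unpolished.
#'
#' @param problem a [fit_problem()].
#' @param budget list: `pop` (population size, default 64), `generations`
#'   (evaluation rounds, default 40; 1 evaluates the initial sample only),
#'   `refine_passes` (direction-set passes, default 6), `n_refine`
#'   (mutually distant elite candidates refined, default 3), `n_restarts`
#'   (independent evolutionary runs, default 1; the best solution across
#'   runs is returned, mirroring lowest-error selection over many
#'   independently seeded searches),
#'   `sigma` (initial mutation SD in normalised space, default 0.1,
#'   annealed over the run), `elite` (default 2).
#' @param seed RNG seed.
#' @param eta noise-exit fraction (default 1).
#' @return A `fit_result`: list with `solutions` (tibble of the final
#'   population: parameters, error, origin), `best` (a `fit_solution`),
#'   `exit`, `generations`, `seed`.
#' @export
optimize_fit <- function(problem, budget = list(), seed = 1, eta = 1) {
  b <- utils::modifyList(list(pop = 64, generations = 40, refine_passes = 6,
                              sigma = 0.1, elite = 2, n_restarts = 1), budget)
  if (b$n_restarts > 1) {
    runs <- lapply(seq_len(b$n_restarts), function(r) {
      bb <- b; bb$n_restarts <- 1
      optimize_fit(problem, bb, seed = seed + 7919L * (r - 1L), eta = eta)
    })
    best <- runs[[which.min(vapply(runs, function(f) f$best$error, numeric(1)))]]
    best$restarts <- length(runs)
    best$seed <- seed
    return(best)
  }
  set.seed(seed)
  k <- sum(problem$bounds$fit)
  if (k == 0) abort("no parameters marked for fitting")
  P <- max(1L, b$pop)
  Z <- lhs::randomLHS(P, k)
  err <- apply(Z, 1, function(z) eval_candidate(z, problem)$error)
  gen <- 1L
  while (gen < b$generations) {
    # mutation scale anneals over the run
    sig <- b$sigma * (1 - 0.8 * gen / b$generations)
    ord <- order(err)
    newZ <- Z[ord[seq_len(min(b$elite, P))], , drop = FALSE]
    while (nrow(newZ) < P) {
      pick <- function() {
        cand <- sample.int(P, 2)
        cand[which.min(err[cand])]
      }
      pa <- Z[pick(), ]; pb <- Z[pick(), ]
      child <- ifelse(stats::runif(k) < 0.5, pa, pb)
      child <- child + stats::rnorm(k, 0, sig)
      child <- pmin(pmax(child, 0), 1)
      newZ <- rbind(newZ, child)
    }
    keep <- seq_len(min(b$elite, P))
    newerr <- c(err[ord[keep]],
                apply(newZ[-keep, , drop = FALSE], 1,
                      function(z) eval_candidate(z, problem)$error))
    Z <- newZ; err <- newerr
    gen <- gen + 1L
  }

  best_i <- which.min(err)
  z_best <- Z[best_i, ]
  e_best <- err[best_i]
  exit <- "max_iter"
  if (b$generations > 1 && b$refine_passes > 0) {
    # refine several mutually distant elite candidates: distinct basins can
    # sit within a factor of the noise of each other and only local
    # polishing tells them apart
    ord <- order(err)
    starts <- ord[1]
    for (i in ord[-1]) {
      if (length(starts) >= (b$n_refine %||% 3)) break
      if (all(vapply(starts, function(s)
        sqrt(sum((Z[i, ] - Z[s, ])^2)) > 0.15, logical(1)))) {
        starts <- c(starts, i)
      }
    }
    for (s in starts) {
      ref <- refine_direction_set(Z[s, ], err[s], problem,
                                  passes = b$refine_passes,
                                  tol = eta * problem$noise_floor_mV2)
      # simplex polish: handles the curved flat valleys the direction set
      # converges into slowly; same noise-referenced stopping scale
      nm <- stats::optim(ref$z, function(zz)
        eval_candidate(pmin(pmax(zz, 0), 1), problem)$error,
        method = "Nelder-Mead",
        control = list(maxit = b$nm_evals %||% 600,
                       reltol = 1e-12))
      if (nm$value < ref$error) {
        ref$z <- pmin(pmax(nm$par, 0), 1); ref$error <- nm$value
      }
      if (ref$error < e_best) {
        z_best <- ref$z; e_best <- ref$error; exit <- ref$exit
      } else if (s == starts[1]) {
        exit <- ref$exit
      }
    }
  }

  bf <- problem$bounds[problem$bounds$fit, ]
  sol_tbl <- purrr::map_dfr(seq_len(P), function(i) {
    p <- z_to_params(Z[i, ], problem)
    out <- tibble(solution = i, error = err[i])
    for (nm in bf$parameter) out[[nm]] <- p[[nm]]
    out
  })
  sol_tbl <- sol_tbl[order(sol_tbl$error), ]
  best_eval <- eval_candidate(z_best, problem)
  structure(list(
    solutions = sol_tbl,
    best = list(params = z_to_params(z_best, problem), error = e_best,
                per_trace = best_eval$per_trace, z = z_best),
    exit = exit, generations = gen, seed = seed,
    problem = problem), class = "fit_result")
}

# Powell-style direction-set refinement with noise exit. Each pass line-
# minimises along every direction (coarse scan + golden section within the
# bracketing interval), then replaces the direction of largest decrease
# with the pass displacement — the update that lets a direction-set method
# follow correlated valleys. A pass improving the error by less than the
# noise tolerance stops the refinement.
refine_direction_set <- function(z, e, problem, passes, tol) {
  k <- length(z)
  exit <- "max_iter"
  dirs <- diag(k)
  line_min <- function(z, e, d) {
    # admissible extent of z + t*d inside the unit box
    with_d <- d != 0
    t_hi <- min(ifelse(d > 0, (1 - z) / d, ifelse(d < 0, -z / d, Inf))[with_d])
    t_lo <- max(ifelse(d > 0, -z / d, ifelse(d < 0, (1 - z) / d, -Inf))[with_d])
    if (!is.finite(t_hi) || !is.finite(t_lo) || t_hi <= t_lo) {
      return(list(z = z, e = e))
    }
    f1 <- function(t) eval_candidate(pmin(pmax(z + t * d, 0), 1), problem)$error
    grid <- seq(t_lo, t_hi, length.out = 9)
    ge <- vapply(grid, f1, numeric(1))
    gi <- which.min(ge)
    opt <- stats::optimize(f1, c(grid[max(1, gi - 1)], grid[min(9, gi + 1)]),
                           tol = 1e-3 * (t_hi - t_lo))
    if (min(opt$objective, ge[gi]) >= e) return(list(z = z, e = e))
    t_best <- if (opt$objective < ge[gi]) opt$minimum else grid[gi]
    e_best <- min(opt$objective, ge[gi])
    list(z = pmin(pmax(z + t_best * d, 0), 1), e = e_best)
  }
  for (pass in seq_len(passes)) {
    e_start <- e; z_start <- z
    drops <- numeric(k)
    for (d in seq_len(k)) {
      res <- line_min(z, e, dirs[, d])
      drops[d] <- e - res$e
      z <- res$z; e <- res$e
    }
    disp <- z - z_start
    if (sqrt(sum(disp^2)) > 1e-10) {
      res <- line_min(z, e, disp / sqrt(sum(disp^2)))
      z <- res$z; e <- res$e
      dirs[, which.max(drops)] <- disp / sqrt(sum(disp^2))
    }
    if (e_start - e < tol) { exit <- "noise_floor"; break }
  }
  list(z = z, error = e, exit = exit)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s circuit, best MSE %.4g mV^2, exit: %s after %d generation(s)\n",
              x$problem$circuit, x$best$error, x$exit, x$generations))
  print(x$best$params)
  invisible(x)
}

#' Compare circuit hypotheses on the same targets
#'
#' Fits each requested circuit mode to the same target traces with the same
#' budget and seed, and ranks them by best combined error. In
#' `"SC_expected"` mode the myelin stays tied to 20x R_m / 0.05x C_m while
#' the axolemma parameters are fitted; to score the expected single cable
#' at another mode's solution without re-optimisation, use
#' [evaluate_params()].
#'
#' @param problem a [fit_problem()] (its `circuit` field is overridden).
#' @param modes character vector of circuit modes.
#' @param budget,seed,eta as in [optimize_fit()].
#' @return A `circuit_comparison`: tibble `mode`, `error`, `rank` plus a
#'   `fits` attribute with the underlying `fit_result`s.
#' @export
compare_circuits <- function(problem,
                             modes = c("SC", "SC_expected", "DC"),
                             budget = list(), seed = 1, eta = 1) {
  fits <- purrr::map(modes, function(m) {
    pr <- fit_problem(problem$graph, problem$target, problem$sites,
                      problem$injection, circuit = m, bounds = problem$bounds,
                      base = problem$base,
                      noise_floor_mV2 = problem$noise_floor_mV2)
    optimize_fit(pr, budget = budget, seed = seed, eta = eta)
  })
  names(fits) <- modes
  out <- tibble(mode = modes,
                error = vapply(fits, function(f) f$best$error, numeric(1)))
  out$rank <- rank(out$error)
  structure(out[order(out$error), ], fits = fits,
            class = c("circuit_comparison", class(out)))
}

#' Perturb internodal diameters by the optical resolving distance
#'
#' Adds `rd_nm * z`, `z ~ N(0, 1)`, independently to every diameter sample
#' of every internode section, emulating the reconstruction uncertainty of
#' bright-field tracing through myelin. Perturbed diameters are floored at
#' a positive minimum (with a warning when clipping occurs).
#'
#' @param morph a [morphology()].
#' @param rd_nm perturbation scale, nm (default 300, the resolving
#'   distance of the imaging setup).
#' @param seed RNG seed.
#' @param floor_um minimum diameter after perturbation.
#' @return The perturbed [morphology()].
#' @export
perturb_morphology <- function(morph, rd_nm = 300, seed = 1, floor_um = 0.1) {
  set.seed(seed)
  clipped <- 0L
  rows <- which(morph$kind == "internode")
  for (i in rows) {
    prof <- morph$diam[[i]]
    d <- prof$diam + (rd_nm / 1000) * stats::rnorm(nrow(prof))
    clipped <- clipped + sum(d < floor_um)
    prof$diam <- pmax(d, floor_um)
    morph$diam[[i]] <- prof
  }
  if (clipped > 0) {
    warn(sprintf("%d perturbed diameter sample(s) clipped at %.2g um", clipped, floor_um))
  }
  morph
}
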