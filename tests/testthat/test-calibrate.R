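# Calibration tests run on the desk-scale fixture network, where fits take
# seconds and the true parameters are known by construction.

fixture_targets <- function(params = NULL, observables = c("A", "B", "P"),
                            cv = 0, seed = 1) {
  m <- fix_model()
  if (!is.null(params)) m$params[names(params)] <- params
  traj <- simulate_model(m, fix_expression(), params = m$params,
                         t_end_daf = 21)
  generate_observations(traj, observables = observables, cv = cv,
                        replicates = if (cv > 0) 4 else 1, seed = seed)
}

test_that("fitting model-generated data from the truth leaves parameters unchanged", {
  m <- fix_model()
  targets <- fixture_targets()
  fit <- fit_model(m, fix_expression(), targets,
                   free = c("k_UP", "k_R2"), starts = 1, maxit = 10)
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$params[["k_UP"]], m$params[["k_UP"]], tolerance = 0.01)
  expect_equal(fit$params[["k_R2"]], m$params[["k_R2"]], tolerance = 0.01)
})

test_that("noiseless recovery from a perturbed start is accurate to 1%", {
  m <- fix_model()
  targets <- fixture_targets()
  start <- m$params
  start[["k_UP"]] <- m$params[["k_UP"]] * 1.5
  start[["k_R2"]] <- m$params[["k_R2"]] * 0.5
  fit <- fit_model(m, fix_expression(), targets,
                   free = c("k_UP", "k_R2"), start = start,
                   starts = 1, maxit = 50)
  expect_lt(abs(fit$params[["k_UP"]] / m$params[["k_UP"]] - 1), 0.01)
  expect_lt(abs(fit$params[["k_R2"]] / m$params[["k_R2"]] - 1), 0.01)
})

test_that("sensitive parameters are recovered from noisy replicate data", {
  m <- fix_model()
  targets <- fixture_targets(cv = 0.1, seed = 7)
  start <- m$params
  start[["k_UP"]] <- m$params[["k_UP"]] * 1.7
  fit <- fit_model(m, fix_expression(), targets, free = "k_UP",
                   start = start, starts = 1, maxit = 50)
  expect_lt(abs(fit$params[["k_UP"]] / m$params[["k_UP"]] - 1), 0.25)
})

test_that("the fit objective is order-invariant and never worsens across starts", {
  m <- fix_model()
  targets <- fixture_targets()
  start <- m$params; start[["k_UP"]] <- start[["k_UP"]] * 1.4
  f1 <- fit_model(m, fix_expression(), targets, free = "k_UP",
                  start = start, starts = 3, seed = 11, maxit = 15)
  shuffled <- targets[sample(nrow(targets)), ]
  f2 <- fit_model(m, fix_expression(), shuffled, free = "k_UP",
                  start = start, starts = 3, seed = 11, maxit = 15)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  expect_true(all(diff(f1$history) <= 1e-12))
})

test_that("parameters fixed at identical bounds are excluded from optimization", {
  m <- fix_model()
  m$param_info$lower[m$param_info$name == "k_R3"] <- m$params[["k_R3"]]
  m$param_info$upper[m$param_info$name == "k_R3"] <- m$params[["k_R3"]]
  targets <- fixture_targets()
  start <- m$params; start[["k_UP"]] <- start[["k_UP"]] * 1.3
  fit <- fit_model(m, fix_expression(), targets, free = c("k_UP", "k_R3"),
                   start = start, starts = 1, maxit = 20)
  expect_false("k_R3" %in% fit$free)
  expect_equal(fit$params[["k_R3"]], m$params[["k_R3"]])
})

test_that("tidy and glance summarize fits in broom style", {
  m <- fix_model()
  targets <- fixture_targets()
  fit <- fit_model(m, fix_expression(), targets, free = "k_UP",
                   starts = 1, maxit = 5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "lower", "upper", "at_bound"))
  gl <- glance(fit)
  expect_equal(gl$n_free, 1)
  expect_equal(gl$n_obs, nrow(fit$residuals))
})

test_that("profile curvature separates identifiable from flat parameters", {
  m <- fix_model()
  # observe only the terminal product: the uptake constant controls the
  # observed flux (curved profile); the B->C constant merely shifts an
  # unobserved pool (flat profile)
  targets <- fixture_targets(observables = "P")
  start <- m$params
  fit <- fit_model(m, fix_expression(), targets, free = c("k_UP", "k_R3"),
                   start = start, starts = 1, maxit = 20)
  grid_up <- m$params[["k_UP"]] * c(0.5, 1, 2)
  prof_up <- identifiability_profile(fit, "k_UP", grid_up, maxit = 15)
  expect_true(attr(prof_up, "identifiable"))

  grid_r3 <- m$params[["k_R3"]] * c(0.8, 1, 1.25)
  prof_r3 <- identifiability_profile(fit, "k_R3", grid_r3, maxit = 15,
                                     flat_threshold = 1e-3)
  expect_lt(attr(prof_r3, "spread"), attr(prof_up, "spread"))

  expect_warning(identifiability_profile(fit, "k_UP", grid_up[2], maxit = 2),
                 "degenerate")
})

test_that("rough tuning accepts trivial envelopes and reports impossible ones", {
  m <- fix_model()
  open_env <- tibble::tibble(observable = c("A", "P"), min = 0, max = Inf)
  res <- rough_tune(m, fix_expression(), open_env, free = "k_UP", n = 1)
  expect_equal(nrow(res$violations), 0)

  # structurally impossible: product required with its synthesis switched off
  m2 <- m
  m2$params[["k_R4"]] <- 1e-9
  m2$param_info$lower[m2$param_info$name == "k_R4"] <- 1e-10
  m2$param_info$upper[m2$param_info$name == "k_R4"] <- 1e-8
  need_p <- tibble::tibble(observable = "P", min = 0.5, max = Inf,
                           time_daf = 20)
  expect_error(rough_tune(m2, fix_expression(), need_p, free = "k_R4", n = 3),
               "violates|no feasible")
})

test_that("rough tuning agrees with a bisection oracle on a one-parameter envelope", {
  m <- fix_model()
  e <- fix_expression()
  p_at_20 <- function(k_up) {
    pars <- m$params; pars[["k_UP"]] <- k_up
    traj <- simulate_model(m, e, params = pars, dt_out_daf = 0.25)
    traj$states[at_daf(traj, 20), "P"]
  }
  # P(20 DAF) rises with the uptake constant; find the feasibility threshold
  # for P >= 0.05 by bisection
  lo <- 0.001; hi <- 0.5
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    if (p_at_20(mid) >= 0.05) hi <- mid else lo <- mid
  }
  threshold <- hi
  env <- tibble::tibble(observable = "P", min = 0.05, max = Inf,
                        time_daf = 20)
  # a candidate set drawn above the threshold is feasible
  m3 <- m
  m3$params[["k_UP"]] <- threshold * 2
  res <- rough_tune(m3, e, env, free = "k_UP", n = 1)
  expect_equal(nrow(res$violations), 0)
  # and one below it is rejected
  m4 <- m
  m4$params[["k_UP"]] <- threshold * 0.5
  m4$param_info$lower[m4$param_info$name == "k_UP"] <- threshold * 0.25
  m4$param_info$upper[m4$param_info$name == "k_UP"] <- threshold * 0.8
  expect_error(rough_tune(m4, e, env, free = "k_UP", n = 2), "violates")
})
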