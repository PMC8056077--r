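#' Simulate observables for a parameter vector
#'
#' @keywords internal
simulate_observables <- function(model, expression, params, observables,
                                 times_daf, t_end_hr = NULL, ctx = NULL) {
  if (is.null(t_end_hr)) t_end_hr <- max(times_daf) * 24
  if (is.null(ctx)) {
    ctx <- prepare_simulation(model, expression, params, t_end_hr = t_end_hr)
  } else {
    ctx$params <- params
    ctx$flux_fn <- compile_network(model, params)
  }
  traj <- run_simulation(ctx, dt_out_hr = min(2.4, t_end_hr / 50))
  ser <- observable_series(traj, observables)
  at <- vapply(times_daf, function(t) which.min(abs(traj$time_daf - t)), 1L)
  list(values = ser[at, , drop = FALSE], traj = traj, ctx = ctx)
}

#' Fit model parameters to observed time courses
#'
#' Minimizes the weighted sum of squared residuals on log10-transformed
#' observables (a small floor is added before the log, since the storage
#' pools span orders of magnitude across development) using bounded
#' Levenberg--Marquardt least squares from multiple Latin-hypercube starting
#' points. Deterministic given the seed; the best-so-far objective never
#' increases across starts.
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()].
#' @param targets Target table (`observable`, `time_daf`, `value`,
#'   `weight`; a `replicate` column is averaged over).
#' @param free Names of parameters to optimize; defaults to all rate
#'   constants (`k_*`).
#' @param start Starting parameter vector; defaults to the model's.
#' @param starts Number of multi-start points (the first start is `start`
#'   itself).
#' @param seed Integer seed for the Latin-hypercube draw.
#' @param log_floor Floor added before the log transform.
#' @param maxit Maximum optimizer iterations per start.
#' @return An object of class `fa_fit` with the optimized parameters,
#'   objective, residuals and per-start history; see [tidy.fa_fit()] and
#'   [glance.fa_fit()].
#' @export
fit_model <- function(model, expression, targets, free = NULL,
                      start = model$params, starts = 20, seed = 1,
                      log_floor = 1e-6, maxit = 50) {
  stopifnot(nrow(targets) > 0)
  targets <- tibble::as_tibble(targets) |>
    dplyr::group_by(.data$observable, .data$time_daf) |>
    dplyr::summarise(value = mean(.data$value),
                     weight = mean(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$observable, .data$time_daf)
  if (is.null(free)) {
    free <- grep("^k_", names(model$params), value = TRUE)
  }
  pi <- model$param_info
  lower <- pi$lower[match(free, pi$name)]
  upper <- pi$upper[match(free, pi$name)]
  fixed_idx <- which(lower == upper)
  if (length(fixed_idx) > 0) {
    free <- free[-fixed_idx]
    lower <- lower[-fixed_idx]
    upper <- upper[-fixed_idx]
  }
  observables <- unique(targets$observable)
  times_daf <- sort(unique(targets$time_daf))
  t_end_hr <- max(times_daf) * 24

  ctx0 <- prepare_simulation(model, expression, start, t_end_hr = t_end_hr)

  resid_fn <- function(theta) {
    pars <- start
    pars[free] <- theta
    sim <- tryCatch(
      simulate_observables(model, expression, pars, observables, times_daf,
                           t_end_hr, ctx = ctx0),
      error = function(e) NULL
    )
    if (is.null(sim)) return(rep(1e3, nrow(targets)))
    pred <- vapply(seq_len(nrow(targets)), function(i) {
      sim$values[match(targets$time_daf[i], times_daf),
                 targets$observable[i]]
    }, 0)
    sqrt(targets$weight) *
      (log10(pred + log_floor) - log10(targets$value + log_floor))
  }

  # multi-start: supplied start + Latin-hypercube points within bounds
  set.seed(seed)
  n_extra <- max(starts - 1, 0)
  start_mat <- matrix(start[free], nrow = 1)
  if (n_extra > 0) {
    u <- lhs::randomLHS(n_extra, length(free))
    lh <- sweep(sweep(u, 2, log(upper / lower), "*"), 2, log(lower), "+")
    start_mat <- rbind(start_mat, exp(lh))
  }

  best <- NULL
  history <- numeric(0)
  any_ok <- FALSE
  for (s in seq_len(nrow(start_mat))) {
    fitted <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(start_mat[s, ], lower), upper),
                         lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxit)),
      error = function(e) NULL
    )
    if (is.null(fitted)) { history <- c(history, Inf); next }
    any_ok <- TRUE
    obj <- sum(fitted$fvec^2)
    if (is.null(best) || obj < best$objective) {
      best <- list(par = fitted$par, objective = obj, fvec = fitted$fvec)
    }
    history <- c(history, best$objective)
  }
  if (!any_ok) stop("all optimization starts failed to integrate", call. = FALSE)

  pars <- start
  pars[free] <- best$par
  residuals <- targets |>
    dplyr::mutate(residual = best$fvec / sqrt(.data$weight))
  structure(
    list(params = pars, free = free, lower = lower, upper = upper,
         objective = best$objective, residuals = residuals,
         history = history, model = model, expression = expression,
         targets = targets, log_floor = log_floor, seed = seed),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  cat(sprintf("Model fit: %d free parameters, objective %.6g (%d starts)\n",
              length(x$free), x$objective, length(x$history)))
  invisible(x)
}

#' Tidy a model fit
#'
#' @param x An `fa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per free parameter: `term`, `estimate`,
#'   `lower`, `upper`, `at_bound`.
#' @export
tidy.fa_fit <- function(x, ...) {
  est <- x$params[x$free]
  tibble::tibble(
    term = x$free, estimate = unname(est),
    lower = x$lower, upper = x$upper,
    at_bound = est <= x$lower * 1.0001 | est >= x$upper * 0.9999
  )
}

#' One-row summary of a model fit
#'
#' @param x An `fa_fit`.
#' @param ... Unused.
#' @return Tibble with `objective`, `n_obs`, `n_free`, `rmse_log10`.
#' @export
glance.fa_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_obs = nrow(x$residuals),
    n_free = length(x$free),
    rmse_log10 = sqrt(x$objective / nrow(x$residuals))
  )
}

#' Generic for broom-style tidying (re-exported minimal generics)
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Rough physiological tuning by randomized envelope search
#'
#' The first calibration step: find a parameter set whose simulated
#' observables stay inside physiological envelopes (concentration/flux
#' ranges per pathway). Candidate parameter sets are drawn from a Latin
#' hypercube within bounds (the supplied start is tried first); the first
#' candidate satisfying every envelope is returned. If none is found, the
#' envelope violations of the best candidate are reported in the error.
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()].
#' @param envelopes Tibble (`observable`, `min`, `max`, optionally
#'   `time_daf`; when `time_daf` is NA the envelope applies to the whole
#'   trajectory of that observable).
#' @param free Parameters to vary; defaults to rate constants.
#' @param n Number of candidates.
#' @param seed Integer seed.
#' @return List with `params` (feasible set) and `violations` (empty tibble
#'   when feasible).
#' @export
rough_tune <- function(model, expression, envelopes, free = NULL,
                       n = 50, seed = 1) {
  stopifnot(all(c("observable", "min", "max") %in% names(envelopes)))
  if (is.null(free)) free <- grep("^k_", names(model$params), value = TRUE)
  pi <- model$param_info
  lower <- pi$lower[match(free, pi$name)]
  upper <- pi$upper[match(free, pi$name)]
  if (!"time_daf" %in% names(envelopes)) envelopes$time_daf <- NA_real_

  set.seed(seed)
  cand <- matrix(model$params[free], nrow = 1)
  if (n > 1) {
    u <- lhs::randomLHS(n - 1, length(free))
    cand <- rbind(cand, exp(sweep(sweep(u, 2, log(upper / lower), "*"),
                                  2, log(lower), "+")))
  }
  check <- function(traj) {
    viol <- list()
    for (i in seq_len(nrow(envelopes))) {
      ob <- envelopes$observable[i]
      ser <- observable_series(traj, ob)[, 1]
      if (!is.na(envelopes$time_daf[i])) {
        ser <- ser[which.min(abs(traj$time_daf - envelopes$time_daf[i]))]
      }
      lo <- min(ser); hi <- max(ser)
      if (lo < envelopes$min[i] || hi > envelopes$max[i]) {
        viol[[length(viol) + 1]] <- tibble::tibble(
          observable = ob, min = envelopes$min[i], max = envelopes$max[i],
          observed_min = lo, observed_max = hi)
      }
    }
    if (length(viol) == 0) tibble::tibble() else dplyr::bind_rows(viol)
  }

  best <- NULL
  for (s in seq_len(nrow(cand))) {
    pars <- model$params
    pars[free] <- cand[s, ]
    traj <- tryCatch(
      simulate_model(model, expression, params = pars, dt_out_daf = 0.25),
      error = function(e) NULL
    )
    if (is.null(traj)) next
    viol <- check(traj)
    if (nrow(viol) == 0) {
      return(list(params = pars, violations = viol))
    }
    if (is.null(best) || nrow(viol) < nrow(best$violations)) {
      best <- list(params = pars, violations = viol)
    }
  }
  if (is.null(best)) {
    stop("no candidate parameter set produced a stable trajectory",
         call. = FALSE)
  }
  stop("no feasible parameter set found within the candidate budget; ",
       "closest candidate violates ", nrow(best$violations), " envelope(s): ",
       paste(best$violations$observable, collapse = ", "), call. = FALSE)
}

#' Profile-based identifiability diagnostic
#'
#' Re-optimizes the remaining free parameters at each grid value of one
#' parameter and reports the profile of the objective. A flat profile
#' (objective spread below `flat_threshold`) flags the parameter as
#' non-identifiable from the data.
#'
#' @param fit An `fa_fit`.
#' @param parameter Name of the profiled parameter.
#' @param grid Numeric grid of values; a single-point grid degenerates and
#'   triggers a warning.
#' @param flat_threshold Objective spread below which the profile counts as
#'   flat.
#' @param starts,maxit Optimizer settings for the re-fits.
#' @return Tibble (`value`, `objective`) with attributes `identifiable` and
#'   `spread`.
#' @export
identifiability_profile <- function(fit, parameter, grid,
                                    flat_threshold = 1e-4,
                                    starts = 1, maxit = 30) {
  stopifnot(inherits(fit, "fa_fit"))
  if (!parameter %in% fit$free) {
    stop(parameter, " is not a free parameter of the fit", call. = FALSE)
  }
  if (length(grid) < 2) {
    warning("single-point grid: the profile is degenerate", call. = FALSE)
  }
  other <- setdiff(fit$free, parameter)
  model <- fit$model
  prof <- vapply(grid, function(val) {
    m2 <- model
    m2$params <- fit$params
    m2$params[parameter] <- val
    m2$param_info$lower[m2$param_info$name == parameter] <- val
    m2$param_info$upper[m2$param_info$name == parameter] <- val
    if (length(other) == 0) {
      # nothing left to re-optimize: evaluate the objective directly
      sim <- simulate_observables(model, fit$expression, m2$params,
                                  unique(fit$targets$observable),
                                  sort(unique(fit$targets$time_daf)))
      pred <- vapply(seq_len(nrow(fit$targets)), function(i) {
        sim$values[match(fit$targets$time_daf[i],
                         sort(unique(fit$targets$time_daf))),
                   fit$targets$observable[i]]
      }, 0)
      r <- sqrt(fit$targets$weight) *
        (log10(pred + fit$log_floor) - log10(fit$targets$value + fit$log_floor))
      return(sum(r^2))
    }
    refit <- fit_model(m2, fit$expression, fit$targets, free = other,
                       start = m2$params, starts = starts, seed = fit$seed,
                       log_floor = fit$log_floor, maxit = maxit)
    refit$objective
  }, 0)
  out <- tibble::tibble(value = grid, objective = prof)
  spread <- diff(range(prof))
  attr(out, "spread") <- spread
  attr(out, "identifiable") <- spread > flat_threshold
  out
}
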