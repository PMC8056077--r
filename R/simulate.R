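#' Bundle expression inputs for the simulator
#'
#' @param profiles Long tibble (`enzyme`, `stage`, `rel_mrna`) of normalized
#'   per-enzyme mRNA profiles; a row set with enzyme `"SPRTS"` supplies the
#'   storage-protein mRNA signal.
#' @param rb Ribosome tibble (`stage`, `rb`), or `NULL` for a flat signal.
#' @param grid Stage grid from [stage_grid()].
#' @return An object of class `expression_input`.
#' @export
expression_input <- function(profiles, rb = NULL, grid = stage_grid()) {
  assert_stage_grid(grid)
  stopifnot(all(c("enzyme", "stage", "rel_mrna") %in% names(profiles)))
  structure(list(profiles = tibble::as_tibble(profiles), rb = rb, grid = grid),
            class = "expression_input")
}

#' @keywords internal
profile_fn <- function(expr_in, enzyme, interp = "monotone") {
  p <- expr_in$profiles[expr_in$profiles$enzyme == enzyme, ]
  if (nrow(p) == 0) return(NULL)
  p <- p[order(match(as.character(p$stage), as.character(expr_in$grid$stage))), ]
  stage_interpolant(expr_in$grid$time_hr, p$rel_mrna, method = interp)
}

#' @keywords internal
# Precompute everything reused across perturbed runs: enzyme trajectories on
# a uniform grid, the storage-protein mRNA interpolant, the compiled flux
# function and the stoichiometric machinery.
prepare_simulation <- function(model, expression, params = model$params,
                               t_end_hr = 504, enzyme_dt_hr = 2,
                               interp = "monotone") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(expression, "expression_input"))
  enz_ids <- unique(stats::na.omit(model$reactions$enzyme))
  have <- unique(expression$profiles$enzyme)
  missing_e <- setdiff(enz_ids, have)
  if (length(missing_e) > 0) {
    stop("expression input lacks profiles for enzyme(s): ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  turnover <- stats::setNames(model$reactions$turnover, model$reactions$enzyme)
  turnover <- turnover[!is.na(names(turnover))]

  e_times <- seq(0, t_end_hr, by = enzyme_dt_hr)
  if (length(enz_ids) > 0) {
    enz_long <- enzyme_trajectories(
      expression$profiles[expression$profiles$enzyme %in% enz_ids, ],
      grid = expression$grid, turnover = turnover, rb = expression$rb,
      growth = model$growth, t_end_hr = t_end_hr, dt_hr = enzyme_dt_hr,
      interp = interp
    )
    emat <- enz_long |>
      tidyr::pivot_wider(names_from = "enzyme", values_from = "level")
    e_times <- emat$time_hr
    emat <- as.matrix(emat[, enz_ids, drop = FALSE])
  } else {
    emat <- matrix(0, nrow = length(e_times), ncol = 0)
  }

  sprt_fn <- profile_fn(expression, model$sprt_mrna_reaction %||% "SPRTS",
                        interp)
  if (is.null(sprt_fn)) sprt_fn <- function(t) 1

  list(model = model, params = params,
       emat = emat, e_times = e_times, e_dt = enzyme_dt_hr,
       enz_ids = enz_ids,
       rxn_enz_col = match(model$reactions$enzyme, enz_ids),
       sprt_fn = sprt_fn,
       flux_fn = compile_network(model, params),
       S = stoich_matrix(model),
       dil = model$metabolites$dilute * 1.0,
       ext = which(model$metabolites$external),
       t_end_hr = t_end_hr)
}

#' @keywords internal
# One metabolic integration. enzyme_scale: named factors applied to enzyme
# levels (an exact solution of the scaled enzyme ODE, by linearity);
# k_scale: named factors on reaction rate constants (used to perturb
# non-enzymatic steps). A scale on "SPRTS" rescales the storage-protein
# mRNA signal.
run_simulation <- function(ctx, enzyme_scale = NULL, k_scale = NULL,
                           dt_out_hr = 2.4, rtol = 1e-6, atol = 1e-9) {
  model <- ctx$model
  n_rxn <- nrow(model$reactions)
  escale_cols <- rep(1, length(ctx$enz_ids))
  sprt_scale <- 1
  if (!is.null(enzyme_scale)) {
    for (nm in names(enzyme_scale)) {
      i <- match(nm, ctx$enz_ids)
      if (!is.na(i)) {
        escale_cols[i] <- enzyme_scale[[nm]]
      } else if (identical(nm, model$sprt_mrna_reaction)) {
        sprt_scale <- enzyme_scale[[nm]]
      } else {
        stop("unknown enzyme in perturbation: ", nm, call. = FALSE)
      }
    }
  }
  kscale <- rep(1, n_rxn)
  if (!is.null(k_scale)) {
    i <- match(names(k_scale), model$reactions$id)
    if (anyNA(i)) {
      stop("unknown reaction in k_scale: ",
           paste(names(k_scale)[is.na(i)], collapse = ", "), call. = FALSE)
    }
    kscale[i] <- unlist(k_scale)
  }

  emat <- sweep(ctx$emat, 2, escale_cols, "*")
  e_dt <- ctx$e_dt
  n_et <- length(ctx$e_times)
  enz_col <- ctx$rxn_enz_col
  growth <- model$growth
  S <- ctx$S
  dil <- ctx$dil
  ext <- ctx$ext
  flux_fn <- ctx$flux_fn
  f0 <- growth$f0; r <- growth$r

  # enzyme levels resolved to reaction order on the uniform grid (constant 1
  # for non-enzymatic steps) so the inner interpolation is a single blend
  ermat <- matrix(1, n_et, n_rxn)
  for (j in seq_len(n_rxn)) {
    if (!is.na(enz_col[j])) ermat[, j] <- emat[, enz_col[j]]
  }
  sprt_v <- sprt_scale * ctx$sprt_fn(ctx$e_times)

  e_at <- function(t) {
    i <- floor(t / e_dt) + 1
    if (i >= n_et) i <- n_et - 1L
    w <- t / e_dt - (i - 1)
    list(E = ermat[i, ] * (1 - w) + ermat[i + 1, ] * w,
         xin = sprt_v[i] * (1 - w) + sprt_v[i + 1] * w)
  }
  mu_at <- function(t) {
    f <- f0 / (f0 + (1 - f0) * exp(-r * t))
    r * (1 - f)
  }

  rhs <- function(t, M, parms) {
    Mc <- pmax(M, 0)
    ein <- e_at(t)
    mu <- mu_at(t)
    v <- flux_fn(Mc, ein$E, mu, ein$xin, kscale)
    dM <- as.vector(S %*% v) - mu * (dil * Mc)
    if (length(ext) > 0) dM[ext] <- 0
    list(dM)
  }

  times <- seq(0, ctx$t_end_hr, by = dt_out_hr)
  M0 <- model$metabolites$initial
  sol <- deSolve::lsodes(M0, times, rhs, parms = NULL, rtol = rtol,
                         atol = atol, maxsteps = 50000)
  istate <- attr(sol, "istate")[1]
  if (istate < 0 || nrow(sol) < length(times)) {
    got <- if (nrow(sol) > 1) sol[nrow(sol), -1] else M0
    worst <- model$metabolites$id[which.min(got)]
    stop("metabolic integration failed at t = ",
         signif(sol[nrow(sol), 1] / 24, 4), " DAF (lsoda istate ", istate,
         "); most negative state: ", worst, call. = FALSE)
  }
  states <- sol[, -1, drop = FALSE]
  colnames(states) <- model$metabolites$id
  if (min(states) < -1e-6) {
    bad <- colnames(states)[which(states == min(states), arr.ind = TRUE)[1, 2]]
    stop("negative excursion beyond tolerance in state ", bad,
         " (min ", signif(min(states), 3), ")", call. = FALSE)
  }
  states <- pmax(states, 0)

  fluxes <- vapply(seq_along(times), function(i) {
    ein <- e_at(times[i])
    flux_fn(states[i, ], ein$E, mu_at(times[i]), ein$xin, kscale)
  }, numeric(n_rxn))
  fluxes <- matrix(fluxes, nrow = n_rxn)
  fluxes <- t(fluxes)
  colnames(fluxes) <- model$reactions$id

  enz_out <- emat[findInterval(times, ctx$e_times), , drop = FALSE]
  colnames(enz_out) <- ctx$enz_ids
  gc_ <- growth_curve(growth, times)

  structure(
    list(time_hr = times, time_daf = times / 24,
         states = states, fluxes = fluxes, enzymes = enz_out,
         mass = gc_$mass, mu = gc_$mu,
         metabolites = model$metabolites, reactions = model$reactions),
    class = "fa_trajectory"
  )
}

#' Simulate the coupled expression/metabolism model
#'
#' Integrates the metabolic mass balances \eqn{dM/dt = S\,v(M, E(t)) -
#' \mu(t)\,M} over seed development with a stiff solver (lsoda), after
#' solving the enzyme-balance ODEs for every enzyme from the expression
#' input. Cofactor pairs are exempt from the dilution term (their totals are
#' homeostatically conserved); external boundary species are held fixed.
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()]; defaults to the canonical
#'   noise-free expression program from [default_expression()].
#' @param params Parameter vector (defaults to the model's).
#' @param enzyme_scale Named numeric factors applied to enzyme trajectories
#'   (perturbations).
#' @param k_scale Named numeric factors applied to reaction rate constants
#'   (perturbations of non-enzymatic steps).
#' @param t_end_daf End of simulation (DAF).
#' @param dt_out_daf Output grid spacing (DAF).
#' @param rtol,atol Solver tolerances.
#' @return An `fa_trajectory` object; see [trajectory_states()],
#'   [total_fa()], [physiological_ratios()].
#' @examples
#' \donttest{
#' model <- build_default_model()
#' traj <- simulate_model(model, t_end_daf = 2)
#' total_fa(traj)
#' }
#' @export
simulate_model <- function(model, expression = NULL, params = model$params,
                           enzyme_scale = NULL, k_scale = NULL,
                           t_end_daf = 21, dt_out_daf = 0.1,
                           rtol = 1e-6, atol = 1e-9) {
  if (is.null(expression)) expression <- default_expression(model)
  ctx <- prepare_simulation(model, expression, params,
                            t_end_hr = t_end_daf * 24)
  run_simulation(ctx, enzyme_scale = enzyme_scale, k_scale = k_scale,
                 dt_out_hr = dt_out_daf * 24, rtol = rtol, atol = atol)
}

#' Tidy views of a simulated trajectory
#'
#' @param traj An `fa_trajectory`.
#' @return A long tibble (`time_daf`, `variable`, `value`).
#' @export
trajectory_states <- function(traj) {
  stopifnot(inherits(traj, "fa_trajectory"))
  tibble::as_tibble(as.data.frame(traj$states)) |>
    dplyr::mutate(time_daf = traj$time_daf, .before = 1) |>
    tidyr::pivot_longer(-"time_daf", names_to = "variable", values_to = "value")
}

#' @rdname trajectory_states
#' @export
trajectory_fluxes <- function(traj) {
  stopifnot(inherits(traj, "fa_trajectory"))
  tibble::as_tibble(as.data.frame(traj$fluxes)) |>
    dplyr::mutate(time_daf = traj$time_daf, .before = 1) |>
    tidyr::pivot_longer(-"time_daf", names_to = "variable", values_to = "value")
}

#' Total fatty-acid content along a trajectory
#'
#' Total FA sums the free FA pool, the short-chain acyl-ACP intermediates,
#' the elongated (20--22C) acyls and three acyl equivalents per TAG (the
#' glycerol backbone is excluded), per unit seed mass.
#'
#' @param traj An `fa_trajectory`.
#' @return Tibble with `time_daf` and `total_fa`.
#' @export
total_fa <- function(traj) {
  stopifnot(inherits(traj, "fa_trajectory"))
  s <- traj$states
  tibble::tibble(
    time_daf = traj$time_daf,
    total_fa = s[, "FA"] + s[, "SCFA"] + s[, "FAE"] + 3 * s[, "TAG"]
  )
}

#' Storage-oil (TAG acyl) content along a trajectory
#'
#' Oil content counts the three acyl chains of each TAG plus the elongated
#' very-long-chain acyls destined for TAG.
#'
#' @param traj An `fa_trajectory`.
#' @return Tibble with `time_daf` and `tag_oil`.
#' @export
tag_oil <- function(traj) {
  stopifnot(inherits(traj, "fa_trajectory"))
  s <- traj$states
  tibble::tibble(time_daf = traj$time_daf,
                 tag_oil = 3 * s[, "TAG"] + s[, "FAE"])
}

#' Physiological ratios along a trajectory
#'
#' Computes the read-outs used to sanity-check embryo physiology: the
#' hexose-to-sucrose ratio, the plastid-to-cytosol pyruvate-kinase flux
#' ratio, the Rubisco-bypass contribution relative to FA biosynthesis
#' (v_RUB/v_FAB), and the ATP/ADP ratio. Denominators are floored at
#' `floor_eps`.
#'
#' @param traj An `fa_trajectory`.
#' @param floor_eps Denominator floor.
#' @return Tibble with `time_daf`, `hex_suc`, `pk_plastid_cytosol`,
#'   `rub_fab`, `atp_adp`.
#' @export
physiological_ratios <- function(traj, floor_eps = 1e-9) {
  stopifnot(inherits(traj, "fa_trajectory"))
  s <- traj$states; f <- traj$fluxes
  tibble::tibble(
    time_daf = traj$time_daf,
    hex_suc = s[, "GLC"] / pmax(s[, "SUC"], floor_eps),
    pk_plastid_cytosol = f[, "PKp"] / pmax(f[, "PKc"], floor_eps),
    rub_fab = f[, "RUB"] / pmax(f[, "FAS"], floor_eps),
    atp_adp = s[, "ATP"] / pmax(s[, "ADP"], floor_eps)
  )
}

#' Fatty-acid turnover rate over a time window
#'
#' Turnover is the mean FA degradation flux (three acyl equivalents per
#' oxidized TAG) divided by the mean total FA pool over the window,
#' expressed per day.
#'
#' @param traj An `fa_trajectory`.
#' @param window Two-element numeric window in DAF (default the mature
#'   plateau, 16--19 DAF).
#' @return Turnover rate (d^-1).
#' @export
fa_turnover <- function(traj, window = c(16, 19)) {
  stopifnot(inherits(traj, "fa_trajectory"), length(window) == 2)
  sel <- traj$time_daf >= window[1] & traj$time_daf <= window[2]
  if (!any(sel)) stop("window lies outside the simulated span", call. = FALSE)
  deg <- mean(3 * traj$fluxes[sel, "TAGD"])
  pool <- mean(total_fa(traj)$total_fa[sel])
  24 * deg / pool
}

#' @export
print.fa_trajectory <- function(x, ...) {
  tf <- total_fa(x)
  cat(sprintf("Simulated trajectory: %d states, %d reactions, 0-%.3g DAF\n",
              ncol(x$states), ncol(x$fluxes), max(x$time_daf)))
  cat(sprintf("  total FA at end: %.4g (model units)\n",
              tf$total_fa[nrow(tf)]))
  invisible(x)
}
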