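#' Normalize gene-level intensities into per-enzyme relative mRNA profiles
#'
#' Most metabolic enzymes are encoded by several genes; for each enzyme the
#' gene intensities are summed per stage and the summed series is scaled by
#' its value at the first stage, so every enzyme profile starts at 1. The
#' absolute microarray scale therefore never enters the model: only relative
#' changes drive enzyme synthesis.
#'
#' If an enzyme's stage-1 sum is zero the profile would be undefined; in that
#' case a pseudo-intensity (`zero_guard`, one intensity unit by default) is
#' added to every stage for that enzyme and a warning is emitted.
#'
#' @param expression Data frame with a `gene` column and one numeric column
#'   per stage, in developmental order (the format [read_expression()]
#'   returns).
#' @param mapping Data frame mapping genes to enzymes, with columns `gene`
#'   and `enzyme` (a `turnover` column, if present, is carried along
#'   elsewhere).
#' @param zero_guard Pseudo-intensity added when a stage-1 sum is zero.
#' @return A tibble in long form with columns `enzyme`, `stage` and
#'   `rel_mrna` (dimensionless, 1 at the first stage).
#' @examples
#' expr <- tibble::tibble(gene = "g1", zygote = 2000, octant = 4000, mature = 1000)
#' map <- tibble::tibble(gene = "g1", enzyme = "HK")
#' normalize_mrna(expr, map)
#' @export
normalize_mrna <- function(expression, mapping, zero_guard = 1) {
  stopifnot(is.data.frame(expression), is.data.frame(mapping))
  if (!"gene" %in% names(expression)) stop("expression needs a 'gene' column", call. = FALSE)
  if (!all(c("gene", "enzyme") %in% names(mapping))) {
    stop("mapping needs 'gene' and 'enzyme' columns", call. = FALSE)
  }
  stage_cols <- setdiff(names(expression), "gene")
  vals <- as.matrix(expression[stage_cols])
  if (!is.numeric(vals)) stop("stage columns must be numeric", call. = FALSE)
  if (any(vals < 0)) stop("intensities must be nonnegative", call. = FALSE)

  unmapped <- setdiff(unique(mapping$enzyme),
                      unique(mapping$enzyme[mapping$gene %in% expression$gene]))
  if (length(unmapped) > 0) {
    stop("enzyme(s) with no mapped gene in the expression matrix: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  long <- expression |>
    tidyr::pivot_longer(dplyr::all_of(stage_cols), names_to = "stage",
                        values_to = "intensity") |>
    dplyr::inner_join(mapping[, c("gene", "enzyme")], by = "gene",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$enzyme, .data$stage) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_cols, ordered = TRUE)) |>
    dplyr::arrange(.data$enzyme, .data$stage)

  guarded <- long |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::mutate(.zero = .data$intensity[1] == 0,
                  intensity = .data$intensity + ifelse(.data$.zero, zero_guard, 0),
                  rel_mrna = .data$intensity / .data$intensity[1]) |>
    dplyr::ungroup()

  if (any(guarded$.zero)) {
    warning("zero stage-1 intensity sum for enzyme(s) ",
            paste(unique(guarded$enzyme[guarded$.zero]), collapse = ", "),
            "; pseudo-intensity of ", zero_guard, " applied", call. = FALSE)
  }
  guarded[, c("enzyme", "stage", "rel_mrna")]
}

#' Ribosome abundance proxy from ribosomal-gene expression
#'
#' Ribosome content is taken proportional to a weighted sum of the ribosomal
#' genes' mRNA intensities, rescaled so that the signal equals 1 at the first
#' stage. By default every listed ribosomal gene whose mean intensity reaches
#' `weight_threshold` gets weight 1 and the rest weight 0, mirroring the
#' observation that about 150 of the ~200 ribosomal-protein genes are
#' expressed above an intensity of 2000.
#'
#' @param expression Data frame as in [normalize_mrna()].
#' @param ribosomal_genes Character vector of ribosomal gene IDs (must be
#'   nonempty).
#' @param weights Optional nonnegative weights, one per ribosomal gene. When
#'   `NULL`, thresholded 0/1 weights are used.
#' @param weight_threshold Mean-intensity cutoff for the default weights.
#' @return A tibble with columns `stage` and `rb`; `rb` equals 1 at the first
#'   stage.
#' @export
ribosome_signal <- function(expression, ribosomal_genes, weights = NULL,
                            weight_threshold = 2000) {
  if (length(ribosomal_genes) == 0) {
    stop("ribosomal gene list must be nonempty", call. = FALSE)
  }
  stage_cols <- setdiff(names(expression), "gene")
  sub <- expression[match(ribosomal_genes, expression$gene), , drop = FALSE]
  if (anyNA(sub$gene)) {
    stop("ribosomal gene(s) absent from the expression matrix: ",
         paste(ribosomal_genes[is.na(sub$gene)], collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(sub[stage_cols])
  if (is.null(weights)) {
    weights <- as.numeric(rowMeans(vals) >= weight_threshold)
  }
  if (length(weights) != length(ribosomal_genes)) {
    stop("weights must match the ribosomal gene list in length", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  wsum <- as.numeric(crossprod(weights, vals))
  if (wsum[1] <= 0) {
    stop("weighted ribosomal intensity is zero at the first stage", call. = FALSE)
  }
  tibble::tibble(
    stage = factor(stage_cols, levels = stage_cols, ordered = TRUE),
    rb = wsum / wsum[1]
  )
}

#' Enzyme turnover classes
#'
#' Enzyme degradation rate constants are grouped into three classes (fast,
#' average, slow). The synthesis rate constant balances degradation plus
#' growth dilution at the initial growth rate (`k_syn = k_deg + mu0`), so
#' that with unit mRNA and ribosome inputs the enzyme level holds steady
#' at 1.
#'
#' @param mu0 Initial growth rate (hr^-1).
#' @return Tibble with columns `class`, `k_deg`, `k_syn` (hr^-1).
#' @examples
#' turnover_classes()
#' @export
turnover_classes <- function(mu0 = 0.025) {
  tibble::tibble(
    class = c("fast", "average", "slow"),
    k_deg = c(0.03, 0.02, 0.01),
    k_syn = c(0.03, 0.02, 0.01) + mu0
  )
}

#' Rate constants for a turnover class
#'
#' @param class_label One of `"fast"`, `"average"`, `"slow"`.
#' @param mu0 Initial growth rate (hr^-1) used in the synthesis/removal
#'   balance.
#' @return Named list with `k_deg` and `k_syn` (hr^-1).
#' @examples
#' derive_rate_constants("fast")
#' @export
derive_rate_constants <- function(class_label, mu0 = 0.025) {
  stopifnot(is.numeric(mu0), mu0 > 0)
  tab <- turnover_classes(mu0)
  i <- match(class_label, tab$class)
  if (is.na(i)) {
    stop("unknown turnover class '", class_label,
         "' (expected fast, average or slow)", call. = FALSE)
  }
  list(k_deg = tab$k_deg[i], k_syn = tab$k_syn[i])
}

#' Continuous-time interpolant for a stage-resolved profile
#'
#' Stage profiles enter the enzyme ODE as continuous inputs. The default
#' interpolant is the shape-preserving monotone piecewise cubic
#' (`splinefun(method = "monoH.FC")`), which passes through the stage values
#' without overshoot, so nonnegative stage data yield a nonnegative input
#' function. Beyond the last stage the value is held constant; negative query
#' times are an error.
#'
#' @param times_hr Stage times in hours (strictly increasing).
#' @param values Profile values at the stage times (nonnegative).
#' @param method `"monotone"` (default) or `"linear"`.
#' @return A function of time (hours) returning interpolated values.
#' @export
stage_interpolant <- function(times_hr, values, method = c("monotone", "linear")) {
  method <- match.arg(method)
  stopifnot(length(times_hr) == length(values), all(diff(times_hr) > 0))
  t_last <- times_hr[length(times_hr)]
  v_last <- values[length(values)]
  base <- if (method == "monotone") {
    stats::splinefun(times_hr, values, method = "monoH.FC")
  } else {
    stats::approxfun(times_hr, values, rule = 2)
  }
  function(t) {
    if (any(t < 0)) stop("query times must be nonnegative", call. = FALSE)
    out <- ifelse(t >= t_last, v_last, base(t))
    pmax(out, 0)
  }
}

#' Simulate a single enzyme trajectory
#'
#' Integrates the enzyme balance
#' \deqn{dE/dt = k_{syn}\, mRNA(t)\, Rb(t) - (k_{deg} + \mu(t))\, E}
#' so the enzyme is produced in proportion to its transcript and the
#' ribosome proxy, and removed by degradation and growth dilution. The
#' default initial level is the steady state under the inputs at t = 0.
#'
#' @param mrna_fn,rb_fn,mu_fn Functions of time (hours) giving the relative
#'   mRNA, ribosome signal and growth rate.
#' @param k_syn,k_deg Synthesis and degradation rate constants (hr^-1).
#' @param t_end_hr End of the integration window (hours).
#' @param e0 Initial enzyme level; `NULL` for the t = 0 steady state.
#' @param dt_hr Output grid spacing (hours).
#' @return Tibble with columns `time_hr` and `level`.
#' @export
simulate_enzyme <- function(mrna_fn, rb_fn, k_syn, k_deg, mu_fn,
                            t_end_hr = 504, e0 = NULL, dt_hr = 1) {
  stopifnot(k_syn > 0, k_deg > 0)
  if (is.null(e0)) {
    e0 <- k_syn * mrna_fn(0) * rb_fn(0) / (k_deg + mu_fn(0))
  }
  times <- seq(0, t_end_hr, by = dt_hr)
  rhs <- function(t, y, parms) {
    list(k_syn * mrna_fn(t) * rb_fn(t) - (k_deg + mu_fn(t)) * y)
  }
  sol <- deSolve::lsoda(c(E = e0), times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("enzyme ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  tibble::tibble(time_hr = sol[, "time"], level = pmax(sol[, "E"], 0))
}

#' Enzyme trajectories for a whole profile set
#'
#' Solves the enzyme balance for every enzyme in `profiles` jointly (the
#' system is diagonal, one linear ODE per enzyme with shared ribosome and
#' growth inputs) and returns the levels on a uniform grid.
#'
#' @param profiles Long tibble (`enzyme`, `stage`, `rel_mrna`) as returned by
#'   [normalize_mrna()] or [default_expression()].
#' @param grid Stage grid from [stage_grid()].
#' @param turnover Named character vector or tibble (`enzyme`, `turnover`)
#'   assigning a turnover class to each enzyme; enzymes without an entry use
#'   the average class.
#' @param rb Ribosome tibble (`stage`, `rb`) or `NULL` for a flat signal.
#' @param growth Growth model from [growth_model()].
#' @param t_end_hr,dt_hr Output window and spacing (hours).
#' @param interp Interpolation method for the stage profiles.
#' @return Tibble with columns `time_hr`, `enzyme`, `level`.
#' @export
enzyme_trajectories <- function(profiles, grid = stage_grid(), turnover = NULL,
                                rb = NULL, growth = growth_model(),
                                t_end_hr = 504, dt_hr = 2,
                                interp = c("monotone", "linear")) {
  interp <- match.arg(interp)
  assert_stage_grid(grid)
  enzymes <- unique(profiles$enzyme)
  tv <- turnover_lookup(turnover, enzymes)

  prof_fns <- lapply(enzymes, function(e) {
    p <- profiles[profiles$enzyme == e, ]
    p <- p[order(match(as.character(p$stage), as.character(grid$stage))), ]
    stage_interpolant(grid$time_hr, p$rel_mrna, method = interp)
  })
  names(prof_fns) <- enzymes
  rb_fn <- if (is.null(rb)) function(t) rep(1, length(t)) else {
    stage_interpolant(grid$time_hr, rb$rb, method = interp)
  }
  mu_fn <- function(t) growth_curve(growth, t)$mu

  kd <- turnover_classes(growth$mu0)$k_deg[match(tv, turnover_classes()$class)]
  ks <- kd + growth$mu0
  mu0 <- mu_fn(0)
  e0 <- ks * vapply(prof_fns, function(f) f(0), 0) * rb_fn(0) / (kd + mu0)

  times <- seq(0, t_end_hr, by = dt_hr)
  rhs <- function(t, y, parms) {
    m <- vapply(prof_fns, function(f) f(t), 0)
    list(ks * m * rb_fn(t) - (kd + mu_fn(t)) * y)
  }
  sol <- deSolve::lsoda(e0, times, rhs, parms = NULL, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    stop("enzyme ODE integration failed", call. = FALSE)
  }
  mat <- pmax(sol[, -1, drop = FALSE], 0)
  colnames(mat) <- enzymes
  tibble::as_tibble(as.data.frame(mat)) |>
    dplyr::mutate(time_hr = times, .before = 1) |>
    tidyr::pivot_longer(-"time_hr", names_to = "enzyme", values_to = "level")
}

#' @keywords internal
turnover_lookup <- function(turnover, enzymes) {
  if (is.null(turnover)) {
    tv <- rep("average", length(enzymes))
  } else if (is.data.frame(turnover)) {
    tv <- turnover$turnover[match(enzymes, turnover$enzyme)]
  } else {
    tv <- unname(turnover[enzymes])
  }
  tv[is.na(tv)] <- "average"
  bad <- setdiff(unique(tv), turnover_classes()$class)
  if (length(bad) > 0) {
    stop("unknown turnover class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  names(tv) <- enzymes
  tv
}
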