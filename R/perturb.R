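#' Specify a single-gene perturbation
#'
#' Perturbations act constitutively (from t = 0) on the target reaction's
#' gene expression: knockdown divides the normalized mRNA profile by the
#' fold factor, overexpression multiplies it, and knockout multiplies by a
#' small floor factor (0.01 by default) rather than exactly zero, avoiding
#' structural singularities while abolishing the flux for practical
#' purposes. Non-enzymatic steps are perturbed by scaling their rate
#' constant by the same factor.
#'
#' @param target Reaction ID (its enzyme's expression is scaled).
#' @param mode One of `"knockout"`, `"knockdown"`, `"overexpression"`.
#' @param fold Fold factor for knockdown/overexpression (ignored for
#'   knockout).
#' @param ko_floor Residual expression factor used for knockouts.
#' @return A `perturbation_spec` with the resolved multiplicative `factor`.
#' @examples
#' perturbation_spec("PKp", "knockout")
#' perturbation_spec("ACL", "overexpression", fold = 10)
#' @export
perturbation_spec <- function(target,
                              mode = c("knockout", "knockdown", "overexpression"),
                              fold = NULL, ko_floor = 0.01) {
  mode <- match.arg(mode)
  if (mode != "knockout") {
    if (is.null(fold) || fold <= 1) {
      stop("knockdown/overexpression need a fold factor > 1", call. = FALSE)
    }
  }
  factor <- switch(mode,
    knockout = ko_floor,
    knockdown = 1 / fold,
    overexpression = fold
  )
  structure(list(target = target, mode = mode,
                 fold = if (mode == "knockout") NA_real_ else fold,
                 factor = factor),
            class = "perturbation_spec")
}

#' Apply a perturbation to expression inputs
#'
#' Multiplies the target enzyme's normalized mRNA profile by the spec's
#' factor at every stage; all other inputs are untouched.
#'
#' @param expression An [expression_input()].
#' @param spec A [perturbation_spec()].
#' @param enzyme Enzyme ID carrying the target's expression; defaults to the
#'   target reaction ID itself.
#' @return The modified `expression_input`.
#' @export
apply_perturbation <- function(expression, spec, enzyme = spec$target) {
  stopifnot(inherits(expression, "expression_input"),
            inherits(spec, "perturbation_spec"))
  hit <- expression$profiles$enzyme == enzyme
  if (!any(hit)) {
    stop("target enzyme not present in the expression input: ", enzyme,
         call. = FALSE)
  }
  expression$profiles$rel_mrna[hit] <-
    expression$profiles$rel_mrna[hit] * spec$factor
  expression
}

#' @keywords internal
# Resolve a perturbation into simulator knobs: enzymes (incl. the storage-
# protein mRNA signal) are scaled on the expression side, non-enzymatic
# reactions through their rate constant.
perturbation_knobs <- function(model, target, factor) {
  i <- match(target, model$reactions$id)
  if (is.na(i)) stop("unknown perturbation target: ", target, call. = FALSE)
  enz <- model$reactions$enzyme[i]
  if (!is.na(enz)) {
    list(enzyme_scale = stats::setNames(factor, enz), k_scale = NULL)
  } else if (identical(target, model$sprt_mrna_reaction)) {
    list(enzyme_scale = stats::setNames(factor, target), k_scale = NULL)
  } else {
    list(enzyme_scale = NULL, k_scale = stats::setNames(factor, target))
  }
}

#' Fatty-acid response to a single perturbation
#'
#' Runs the perturbed simulation with solver settings identical to the
#' wild-type run and reports the percent change in total FA at the
#' evaluation time (20 DAF by default) and the percent change in the target
#' reaction's mean flux over the FA-accumulation window (10--20 DAF).
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()]; default canonical program.
#' @param spec A [perturbation_spec()].
#' @param eval_daf Time at which FA content is compared (DAF).
#' @param flux_window Window (DAF) for the mean-flux comparison.
#' @param wt Optional precomputed wild-type `fa_trajectory`.
#' @param ctx Optional precomputed simulation context (internal reuse).
#' @return One-row tibble: `target`, `mode`, `fold`, `factor`,
#'   `delta_fa_pct`, `delta_flux_pct`, `ok` (FALSE if the perturbed
#'   integration failed).
#' @export
fa_response <- function(model, expression = NULL, spec,
                        eval_daf = 20, flux_window = c(10, 20),
                        wt = NULL, ctx = NULL) {
  if (is.null(expression)) expression <- default_expression(model)
  if (is.null(ctx)) ctx <- prepare_simulation(model, expression)
  if (is.null(wt)) wt <- run_simulation(ctx)
  knobs <- perturbation_knobs(model, spec$target, spec$factor)
  pt <- tryCatch(
    run_simulation(ctx, enzyme_scale = knobs$enzyme_scale,
                   k_scale = knobs$k_scale),
    error = function(e) e
  )
  if (inherits(pt, "error")) {
    return(tibble::tibble(target = spec$target, mode = spec$mode,
                          fold = spec$fold, factor = spec$factor,
                          delta_fa_pct = NA_real_, delta_flux_pct = NA_real_,
                          ok = FALSE))
  }
  at <- which.min(abs(wt$time_daf - eval_daf))
  fa_wt <- perturbation_readout(wt)[at]
  fa_pt <- perturbation_readout(pt)[at]
  sel <- wt$time_daf >= flux_window[1] & wt$time_daf <= flux_window[2]
  f_wt <- mean(wt$fluxes[sel, spec$target])
  f_pt <- mean(pt$fluxes[sel, spec$target])
  tibble::tibble(
    target = spec$target, mode = spec$mode, fold = spec$fold,
    factor = spec$factor,
    delta_fa_pct = 100 * (fa_pt - fa_wt) / fa_wt,
    delta_flux_pct = 100 * (f_pt - f_wt) / max(abs(f_wt), 1e-12),
    ok = TRUE
  )
}

#' @keywords internal
# FA-content readout; reduced models without the FA pools fall back to the
# total internal (diluted) metabolite mass, so the scan machinery stays
# exercisable on fixture networks.
perturbation_readout <- function(traj) {
  if (all(c("FA", "SCFA", "FAE", "TAG") %in% colnames(traj$states))) {
    total_fa(traj)$total_fa
  } else {
    keep <- traj$metabolites$dilute & !traj$metabolites$external
    rowSums(traj$states[, keep, drop = FALSE])
  }
}

#' Systematic perturbation scan over all reactions
#'
#' For every reaction, simulates knockdowns and overexpressions at each fold
#' factor plus a knockout and a 10-fold-style overexpression arm, and
#' collects the FA-content and flux responses. The result grid has exactly
#' `reactions x (2 x folds + 2)` rows; failed cells are flagged, not
#' dropped.
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()]; default canonical program.
#' @param folds Fold factors scanned in both directions.
#' @param eval_daf,flux_window As in [fa_response()].
#' @param oe_fold Fold used for the summary overexpression arm.
#' @param ko_floor Knockout floor factor.
#' @return Tibble of [fa_response()] rows; the wild-type trajectory is
#'   attached as attribute `"wild_type"`.
#' @export
scan_all <- function(model, expression = NULL,
                     folds = c(1.5, 2.5, 5, 10),
                     eval_daf = 20, flux_window = c(10, 20),
                     oe_fold = 10, ko_floor = 0.01) {
  if (is.null(expression)) expression <- default_expression(model)
  ctx <- prepare_simulation(model, expression)
  wt <- run_simulation(ctx)
  specs <- list()
  for (target in model$reactions$id) {
    for (f in folds) {
      specs[[length(specs) + 1]] <- perturbation_spec(target, "knockdown", f)
      specs[[length(specs) + 1]] <- perturbation_spec(target, "overexpression", f)
    }
    specs[[length(specs) + 1]] <- perturbation_spec(target, "knockout",
                                                    ko_floor = ko_floor)
    specs[[length(specs) + 1]] <- perturbation_spec(target, "overexpression",
                                                    oe_fold)
  }
  out <- dplyr::bind_rows(lapply(specs, function(s) {
    fa_response(model, expression, s, eval_daf = eval_daf,
                flux_window = flux_window, wt = wt, ctx = ctx)
  }))
  attr(out, "wild_type") <- wt
  out
}

#' Summary statistics of a perturbation scan
#'
#' @param scan Result of [scan_all()].
#' @return Tibble with the mean FA change over all knockouts and over all
#'   summary overexpressions.
#' @export
scan_summary <- function(scan) {
  ko <- scan$delta_fa_pct[scan$mode == "knockout" & scan$ok]
  oe <- scan$delta_fa_pct[scan$mode == "overexpression" &
                            scan$fold == max(scan$fold, na.rm = TRUE) & scan$ok]
  tibble::tibble(mean_ko_delta_fa_pct = mean(ko),
                 mean_oe_delta_fa_pct = mean(oe))
}

#' Classify a dose-response profile as asymmetric
#'
#' A reaction's modulation profile is called asymmetric when increasing its
#' expression barely raises FA content while decreasing it markedly lowers
#' FA: the maximum FA change over the overexpression arm stays below
#' `up_threshold` and the minimum over the knockdown arm falls below
#' `down_threshold`.
#'
#' @param up_deltas FA percent changes over the overexpression arm.
#' @param down_deltas FA percent changes over the knockdown/knockout arm.
#' @param up_threshold,down_threshold Classification thresholds (percent).
#' @return Logical.
#' @examples
#' asymmetry_classify(c(0, 1, 2), c(-15, -30, -60))  # TRUE
#' @export
asymmetry_classify <- function(up_deltas, down_deltas,
                               up_threshold = 5, down_threshold = -10) {
  if (length(up_deltas) == 0 || length(down_deltas) == 0) {
    stop("both perturbation arms are required", call. = FALSE)
  }
  max(up_deltas) < up_threshold && min(down_deltas) < down_threshold
}

#' Count asymmetric modulation profiles in a scan
#'
#' @param scan Result of [scan_all()].
#' @param up_threshold,down_threshold As in [asymmetry_classify()].
#' @return Tibble (`target`, `asymmetric`).
#' @export
asymmetry_table <- function(scan, up_threshold = 5, down_threshold = -10) {
  scan |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      asymmetric = asymmetry_classify(
        .data$delta_fa_pct[.data$mode == "overexpression"],
        .data$delta_fa_pct[.data$mode %in% c("knockdown", "knockout")],
        up_threshold, down_threshold),
      .groups = "drop"
    )
}

#' Model predictions for the engineered-line comparison table
#'
#' Reproduces the model-prediction column of the genetic-engineering
#' comparison: each row names an engineering intervention, the perturbation
#' used to emulate it, and the predicted percent change in the relevant FA
#' read-out. Most rows evaluate total FA at 20 DAF; the two heart-stage
#' rows (epimerase and cytosolic carboxylase knockouts) evaluate the
#' storage-oil (TAG acyl) pool at the heart stage.
#'
#' @param model A `metabolic_model`.
#' @param expression An [expression_input()]; default canonical program.
#' @param heart_daf Heart-stage time (DAF).
#' @param eval_daf Mature-stage evaluation time (DAF).
#' @return Tibble with `row`, `target`, `mode`, `factor`, `readout`,
#'   `predicted_pct`, `expected_sign`.
#' @export
prediction_table <- function(model, expression = NULL,
                             heart_daf = 4, eval_daf = 20) {
  if (is.null(expression)) expression <- default_expression(model)
  ctx <- prepare_simulation(model, expression)
  wt <- run_simulation(ctx)

  rows <- tibble::tribble(
    ~row,                               ~targets,                          ~factor, ~readout,  ~expected_sign,
    "WRI1 glycolysis downregulation",   list(c("HK", "PFK", "PKc", "PKp")), 0.01,   "total_fa", -1,
    "Plastidial pyruvate kinase KO",    list("PKp"),                        0.01,   "total_fa", -1,
    "ACCase 10-20x overexpression",     list("ACCp"),                       15,     "total_fa",  1,
    "Cell-wall invertase upregulation", list("CWI"),                        10,     "total_fa",  1,
    "Hexokinase upregulation",          list("HK"),                         10,     "total_fa",  1,
    "FA synthase overexpression",       list("FAS"),                        10,     "total_fa",  1,
    "PDH kinase KO (PDC activity up)",  list("PDHp"),                       2.5,    "total_fa",  1,
    "Cytosolic ATP citrate lyase OE",   list("ACL"),                        10,     "total_fa",  1,
    "Downstream SCFA processing",       list("FAT"),                        10,     "total_fa",  1,
    "Oil-body formation (GPD1) OE",     list("TAGS"),                       10,     "total_fa",  1,
    "Epimerase KO (heart stage)",       list("EPI"),                        0.01,   "tag_oil",  1,
    "Cytosolic ACCase KO (heart stage)", list("ACCc"),                      0.01,   "tag_oil",  -1
  )

  readout_at <- function(traj, readout, daf) {
    at <- which.min(abs(traj$time_daf - daf))
    if (readout == "total_fa") total_fa(traj)$total_fa[at] else
      tag_oil(traj)$tag_oil[at]
  }

  out <- lapply(seq_len(nrow(rows)), function(i) {
    targets <- rows$targets[[i]][[1]]
    escale <- list(); kscale <- list()
    for (tg in targets) {
      kn <- perturbation_knobs(model, tg, rows$factor[i])
      escale <- c(escale, as.list(kn$enzyme_scale))
      kscale <- c(kscale, as.list(kn$k_scale))
    }
    daf <- if (rows$readout[i] == "tag_oil") heart_daf else eval_daf
    pt <- tryCatch(
      run_simulation(ctx,
                     enzyme_scale = if (length(escale)) unlist(escale) else NULL,
                     k_scale = if (length(kscale)) unlist(kscale) else NULL),
      error = function(e) NULL
    )
    pred <- if (is.null(pt)) NA_real_ else {
      100 * (readout_at(pt, rows$readout[i], daf) /
               readout_at(wt, rows$readout[i], daf) - 1)
    }
    tibble::tibble(
      row = rows$row[i],
      target = paste(targets, collapse = "+"),
      mode = if (rows$factor[i] < 1) "knockout" else "overexpression",
      factor = rows$factor[i],
      readout = rows$readout[i],
      predicted_pct = pred,
      expected_sign = rows$expected_sign[i]
    )
  })
  dplyr::bind_rows(out)
}
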