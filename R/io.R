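# File formats: expression matrices are tab-separated (gene ID first column,
# one column per stage); everything else is comma-separated. Numbers are
# written with 9 significant digits so write -> read round-trips are exact
# at working precision. UTF-8, '.' decimal throughout.

#' Read a stage-resolved expression matrix
#'
#' Expects a TSV with a gene-ID first column and exactly 7 numeric stage
#' columns whose names match the configured stage grid.
#'
#' @param path Path to the TSV file.
#' @param grid Stage grid the header is validated against.
#' @return Tibble with `gene` plus the 7 stage columns.
#' @export
read_expression <- function(path, grid = stage_grid()) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 8) {
    stop("expected 8 columns (gene + 7 stages), found ", ncol(raw),
         if (ncol(raw) < 8) paste0("; missing stage(s): ",
           paste(setdiff(as.character(grid$stage), names(raw)[-1]),
                 collapse = ", ")),
         call. = FALSE)
  }
  names(raw)[1] <- "gene"
  stages <- as.character(grid$stage)
  missing_s <- setdiff(stages, names(raw)[-1])
  if (length(missing_s) > 0) {
    stop("stage column(s) missing from header: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  for (s in stages) {
    col <- raw[[s]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric value in column '", s, "' at data line ", bad,
           call. = FALSE)
    }
  }
  if (anyDuplicated(raw$gene)) {
    dup <- raw$gene[duplicated(raw$gene)][1]
    stop("duplicate gene ID '", dup, "' at data line ",
         which(raw$gene == dup)[2], call. = FALSE)
  }
  tibble::as_tibble(raw[, c("gene", stages)])
}

#' @rdname read_expression
#' @param expression Tibble as returned by `read_expression()`.
#' @export
write_expression <- function(expression, path) {
  out <- expression
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 9)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-to-enzyme mapping table
#'
#' Two- or three-column TSV: `gene`, `enzyme` and optionally `turnover`
#' (fast/average/slow).
#'
#' @param path Path to the TSV.
#' @return Tibble.
#' @export
read_mapping <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "enzyme") %in% names(raw))) {
    stop("mapping file needs 'gene' and 'enzyme' columns", call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Read/write calibration-target tables
#'
#' CSV with columns `observable`, `time_daf`, `value`, `weight` and
#' optionally `replicate`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_targets <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observable", "time_daf", "value")
  if (!all(need %in% names(raw))) {
    stop("target file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$weight)) raw$weight <- 1
  tibble::as_tibble(raw)
}

#' @rdname read_targets
#' @param x Tibble to write.
#' @export
write_targets <- function(x, path) {
  out <- x
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 9)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a model to a YAML configuration
#'
#' The declarative configuration (metabolites / reactions / parameters /
#' growth sections) round-trips losslessly through
#' [model_from_yaml()].
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @export
model_to_yaml <- function(model, path) {
  cfg <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, ])
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id, name = r$name,
           enzyme = if (is.na(r$enzyme)) NULL else r$enzyme,
           turnover = if (is.na(r$turnover)) NULL else r$turnover,
           reversible = r$reversible,
           stoich = as.list(r$stoich[[1]]),
           law = serialize_law(r$law[[1]]))
    }),
    parameters = lapply(seq_len(nrow(model$param_info)), function(i) {
      pi <- model$param_info[i, ]
      list(name = pi$name, value = unname(model$params[[pi$name]]),
           lower = pi$lower, upper = pi$upper, provenance = pi$provenance)
    }),
    growth = unclass(model$growth),
    cofactor_pairs = model$cofactor_pairs,
    sprt_mrna_reaction = model$sprt_mrna_reaction
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @keywords internal
# named length-1 vectors would lose their names as YAML scalars; emit maps
serialize_law <- function(law) {
  if (!is.null(law$substrates) && length(law$substrates) > 0 &&
      !is.null(names(law$substrates))) {
    law$substrates <- as.list(law$substrates)
  }
  if (!is.null(law$products)) law$products <- as.list(law$products)
  law
}

#' @rdname model_to_yaml
#' @return A `metabolic_model`.
#' @export
model_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  mets <- dplyr::bind_rows(lapply(cfg$metabolites, function(m) {
    m$cofactor_pair <- m$cofactor_pair %||% NA_character_
    tibble::as_tibble(m)
  }))
  rxns <- dplyr::bind_rows(lapply(cfg$reactions, function(r) {
    law <- r$law
    law$substrates <- unlist(law$substrates)
    if (!is.null(law$products)) law$products <- unlist(law$products)
    law$inhibitors <- lapply(law$inhibitors, function(x) x)
    tibble::tibble(id = r$id, name = r$name,
                   enzyme = r$enzyme %||% NA_character_,
                   turnover = r$turnover %||% NA_character_,
                   reversible = r$reversible,
                   stoich = list(unlist(r$stoich)),
                   law = list(law))
  }))
  params <- stats::setNames(
    vapply(cfg$parameters, function(x) x$value, 0),
    vapply(cfg$parameters, function(x) x$name, "")
  )
  param_info <- dplyr::bind_rows(lapply(cfg$parameters, function(x) {
    tibble::tibble(name = x$name, lower = x$lower, upper = x$upper,
                   provenance = x$provenance)
  }))
  g <- cfg$growth
  growth <- structure(g[c("mu0", "r", "f0", "mass_cap", "mu_mature",
                          "t_mature_hr")], class = "growth_model")
  metabolic_model(mets, rxns, params, param_info, growth = growth,
                  cofactor_pairs = cfg$cofactor_pairs,
                  sprt_mrna_reaction = cfg$sprt_mrna_reaction)
}

#' Write a tidy trajectory CSV
#'
#' @param traj An `fa_trajectory`.
#' @param path CSV path.
#' @export
write_trajectory <- function(traj, path) {
  out <- dplyr::bind_rows(
    trajectory_states(traj),
    trajectory_fluxes(traj) |>
      dplyr::mutate(variable = paste0("flux_", .data$variable)),
    tibble::tibble(time_daf = traj$time_daf, variable = "seed_mass",
                   value = traj$mass)
  )
  if (all(c("FA", "SCFA", "FAE", "TAG") %in% colnames(traj$states))) {
    out <- dplyr::bind_rows(
      out,
      total_fa(traj) |>
        dplyr::transmute(time_daf = .data$time_daf, variable = "total_fa",
                         value = .data$total_fa)
    )
  }
  out$value <- signif(out$value, 9)
  out$time_daf <- signif(out$time_daf, 9)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> physiological ratios -> perturbation scan ->
#' prediction table on a model and expression input, writing tidy CSV
#' outputs and a JSON run manifest (package version, seed, file checksums)
#' to `out_dir`. Any stage failure aborts with the stage name; outputs
#' written before the failure are preserved.
#'
#' @param out_dir Output directory (created if needed).
#' @param model A `metabolic_model`; default reference model.
#' @param expression An [expression_input()]; default canonical program.
#' @param folds Fold factors for the scan; `NULL` skips the scan stage.
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, model = build_default_model(),
                         expression = NULL, folds = c(1.5, 2.5, 5, 10),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(expression)) expression <- default_expression(model)
  outputs <- character(0)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  traj <- stage("simulate", function() simulate_model(model, expression))
  p <- file.path(out_dir, "trajectory.csv")
  write_trajectory(traj, p); outputs <- c(outputs, p)

  if (all(c("GLC", "SUC", "ATP", "ADP") %in% model$metabolites$id)) {
    ratios <- stage("ratios", function() physiological_ratios(traj))
    p <- file.path(out_dir, "ratios.csv")
    ratios_out <- ratios
    ratios_out[] <- lapply(ratios_out, signif, digits = 9)
    utils::write.csv(ratios_out, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }

  if (!is.null(folds)) {
    scan <- stage("scan", function() scan_all(model, expression, folds = folds))
    p <- file.path(out_dir, "scan.csv")
    scan_out <- scan
    scan_out$delta_fa_pct <- signif(scan_out$delta_fa_pct, 9)
    scan_out$delta_flux_pct <- signif(scan_out$delta_flux_pct, 9)
    utils::write.csv(scan_out, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
  }

  if (!is.null(model$sprt_mrna_reaction)) {
    tab <- stage("prediction_table", function() {
      prediction_table(model, expression)
    })
    p <- file.path(out_dir, "prediction_table.csv")
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "prediction_table.md")
    writeLines(c(
      "| Intervention | Target | Factor | Readout | Predicted % |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %.3g | %s | %.1f |",
              tab$row, tab$target, tab$factor, tab$readout, tab$predicted_pct)
    ), p)
    outputs <- c(outputs, p)
  }

  manifest <- list(
    package = "seedfa",
    version = as.character(utils::packageVersion("seedfa")),
    seed = seed,
    outputs = lapply(outputs, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
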