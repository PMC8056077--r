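#' Library of canonical stage-profile shapes
#'
#' Normalized (stage-1 = 1) template profiles over the 7-stage grid used to
#' emulate the expression atlas: `early_transient` (peaks around the octant/
#' globular stages), `mid_broad` (broad rise through the filling phase),
#' `mid_peak` (sharp peak in the 7--14 DAF oil-filling window, the pattern
#' of FA-synthesis, elongation and TAG genes), `late_up` (maturation
#' program), `late_down` (declining maternal program) and `flat`.
#'
#' @return Tibble with columns `shape` and the 7 stage values `s1`..`s7`.
#' @export
shape_library <- function() {
  tibble::tribble(
    ~shape,            ~s1, ~s2,  ~s3,  ~s4,  ~s5,  ~s6,   ~s7,
    "flat",              1,   1,    1,    1,    1,    1,     1,
    "early_transient",   1, 2.5,    3,    2,    1,  0.5,   0.3,
    "mid_broad",         1, 1.2,    2,    4,    6,    6,   1.5,
    "mid_peak",          1,   1,  1.5,    3,   10,   15,   0.5,
    "late_up",           1,   1,    1,  1.5,    3,    6,    10,
    "late_down",         1,   1,  0.9,  0.7,  0.5,  0.3,  0.15,
    "supply_ramp",       1, 0.9,  1.3,    3,  5.5,    6,   0.8
  )
}

#' @keywords internal
shape_values <- function(shape) {
  lib <- shape_library()
  i <- match(shape, lib$shape)
  if (anyNA(i)) {
    stop("unknown shape(s): ", paste(shape[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  as.matrix(lib[i, -1, drop = FALSE])
}

#' Default shape assignment for the reference network
#'
#' Encodes the expression program the model assumes: carbon supply and
#' glycolytic/PPP genes follow a broad filling-phase profile, FA synthesis,
#' elongation and TAG-assembly genes are confined to the 7--14 DAF window,
#' starch synthesis runs early with degradation in the filling phase, and
#' maturation genes (sucrose storage, TAG oxidation, glyoxylate shunt,
#' storage protein) rise late. Core TCA and housekeeping steps are flat.
#'
#' @param model A `metabolic_model` (defaults to the reference model).
#' @return Tibble with columns `enzyme` and `shape` (one row per enzyme plus
#'   the storage-protein mRNA signal `SPRTS`).
#' @export
default_shape_assignment <- function(model = NULL) {
  asg <- c(
    CWI = "supply_ramp", GLCT = "supply_ramp", HK = "mid_broad",
    PFK = "mid_broad", PGK = "mid_broad", NPG = "mid_broad",
    PKc = "mid_broad", G6PD = "mid_broad", EPI = "mid_broad",
    RUB = "mid_broad", PEPT = "mid_broad", PYRT = "mid_broad",
    PKp = "mid_broad", PDHp = "mid_broad",
    ACCc = "mid_broad", FAE = "mid_broad", ACL = "mid_broad",
    ACCp = "mid_peak", FAS = "mid_peak", FAT = "mid_peak",
    TAGS = "mid_peak", STAD = "mid_peak",
    STAS = "early_transient",
    SUS = "late_up", TAGD = "late_up", ICL = "late_up", SPRTS = "late_up",
    PDH = "flat", IDH = "flat", AKGD = "flat", MDH = "flat",
    PEPC = "flat", ME = "flat", AAT = "flat", GDH = "flat",
    AAup = "flat", OXPHOS = "flat"
  )
  out <- tibble::tibble(enzyme = names(asg), shape = unname(asg))
  if (!is.null(model)) {
    need <- unique(stats::na.omit(model$reactions$enzyme))
    missing_e <- setdiff(need, out$enzyme)
    if (length(missing_e) > 0) {
      out <- dplyr::bind_rows(
        out, tibble::tibble(enzyme = missing_e, shape = "flat"))
    }
  }
  out
}

#' Canonical ribosome profile
#'
#' Translation capacity rises slightly during early morphogenesis and
#' declines toward desiccation.
#'
#' @param grid Stage grid.
#' @return Tibble (`stage`, `rb`) with `rb = 1` at the first stage.
#' @export
default_ribosome_profile <- function(grid = stage_grid()) {
  tibble::tibble(stage = grid$stage,
                 rb = c(1, 1.1, 1.2, 1.2, 1.05, 0.8, 0.2))
}

#' Canonical noise-free expression input for a model
#'
#' The deterministic expression program used as the wild-type reference:
#' each enzyme's normalized profile is its assigned shape from
#' [default_shape_assignment()], the ribosome signal is
#' [default_ribosome_profile()], and no sampling noise is applied.
#'
#' @param model A `metabolic_model`.
#' @param grid Stage grid.
#' @param assignment Shape-assignment tibble (`enzyme`, `shape`).
#' @return An [expression_input()].
#' @export
default_expression <- function(model = build_default_model(),
                               grid = stage_grid(),
                               assignment = default_shape_assignment(model)) {
  vals <- shape_values(assignment$shape)
  profiles <- tibble::tibble(
    enzyme = rep(assignment$enzyme, each = 7),
    stage = rep(grid$stage, times = nrow(assignment)),
    rel_mrna = as.vector(t(vals))
  )
  expression_input(profiles, rb = default_ribosome_profile(grid), grid = grid)
}

#' Generate a synthetic gene-level expression atlas
#'
#' Emulates the structure of the embryo microarray atlas: each enzyme is
#' covered by 1--3 genes whose stage profiles follow the enzyme's assigned
#' shape times a gene-specific base intensity, with multiplicative
#' log-normal noise; a block of ~200 ribosomal genes is appended, of which
#' about 150 exceed the 2000-intensity expression threshold.
#'
#' @param seed Integer seed; the atlas is reproducible given the seed.
#' @param assignment Shape-assignment tibble (`enzyme`, `shape`); rows for
#'   every enzyme to include.
#' @param grid Stage grid.
#' @param genes_per_enzyme Range (min, max) of genes per enzyme.
#' @param noise_cv Coefficient of variation of the per-cell log-normal
#'   noise.
#' @param n_ribosomal Number of ribosomal genes in the appended block.
#' @param frac_expressed Fraction of ribosomal genes drawn above the
#'   expression threshold.
#' @return List with `expression` (gene x stage tibble), `mapping`
#'   (`gene`, `enzyme`), and `ribosomal_genes` (character).
#' @export
generate_mrna_atlas <- function(seed, assignment = default_shape_assignment(),
                                grid = stage_grid(),
                                genes_per_enzyme = c(1, 3),
                                noise_cv = 0.1, n_ribosomal = 200,
                                frac_expressed = 0.75) {
  stopifnot(all(c("enzyme", "shape") %in% names(assignment)))
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  stage_cols <- as.character(grid$stage)

  rows <- list()
  mapping <- list()
  for (i in seq_len(nrow(assignment))) {
    e <- assignment$enzyme[i]
    shp <- as.numeric(shape_values(assignment$shape[i]))
    ng <- sample(seq(genes_per_enzyme[1], genes_per_enzyme[2]), 1)
    for (g in seq_len(ng)) {
      base <- stats::rlnorm(1, meanlog = log(1500), sdlog = 0.6)
      noise <- stats::rlnorm(7, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      gene <- sprintf("AT%dG%05d", sample(1:5, 1), sample(0:99999, 1))
      rows[[length(rows) + 1]] <- c(list(gene = gene),
                                    stats::setNames(as.list(base * shp * noise),
                                                    stage_cols))
      mapping[[length(mapping) + 1]] <- tibble::tibble(gene = gene, enzyme = e)
    }
  }
  rb_shape <- default_ribosome_profile(grid)$rb
  rb_genes <- character(n_ribosomal)
  for (g in seq_len(n_ribosomal)) {
    expressed <- stats::runif(1) < frac_expressed
    base <- if (expressed) stats::rlnorm(1, log(8000), 0.5) else
      stats::rlnorm(1, log(500), 0.5)
    noise <- stats::rlnorm(7, -sdlog^2 / 2, sdlog)
    gene <- sprintf("ATRP%04d", g)
    rb_genes[g] <- gene
    rows[[length(rows) + 1]] <- c(list(gene = gene),
                                  stats::setNames(as.list(base * rb_shape * noise),
                                                  stage_cols))
  }
  expression <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  list(expression = expression,
       mapping = dplyr::bind_rows(mapping),
       ribosomal_genes = rb_genes)
}

#' Sample noisy pseudo-observations from a simulated truth
#'
#' Samples the listed observables at the stage times and applies
#' multiplicative log-normal noise per biological replicate (four
#' replicates by default, the design of the metabolite-profiling study).
#'
#' @param traj An `fa_trajectory` (the ground truth).
#' @param observables Character vector of observable names; any metabolite
#'   ID plus the derived read-outs `"total_fa"` and `"seed_mass"`.
#' @param grid Stage grid giving the sampling times.
#' @param cv Coefficient of variation of the log-normal noise.
#' @param replicates Number of biological replicates.
#' @param seed Integer seed.
#' @return Tibble (`observable`, `time_daf`, `replicate`, `value`,
#'   `weight`) usable as a calibration-target table.
#' @export
generate_observations <- function(traj, observables = c("STA", "SUC", "GLC",
                                                        "total_fa", "SPRT",
                                                        "SCFA", "TAG"),
                                  grid = stage_grid(), cv = 0.15,
                                  replicates = 4, seed = 1) {
  stopifnot(inherits(traj, "fa_trajectory"), cv >= 0, replicates >= 1)
  set.seed(seed)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  truth <- observable_series(traj, observables)
  at <- vapply(grid$time_daf, function(t) which.min(abs(traj$time_daf - t)), 1L)
  out <- tidyr::expand_grid(observable = observables,
                            time_daf = grid$time_daf,
                            replicate = seq_len(replicates))
  base <- truth[at, , drop = FALSE]
  out$value <- vapply(seq_len(nrow(out)), function(i) {
    mu <- base[match(out$time_daf[i], grid$time_daf), out$observable[i]]
    if (sdlog == 0) mu else mu * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
  }, 0)
  out$weight <- 1
  out
}

#' @keywords internal
observable_series <- function(traj, observables) {
  cols <- lapply(observables, function(ob) {
    switch(ob,
      total_fa = total_fa(traj)$total_fa,
      tag_oil = tag_oil(traj)$tag_oil,
      seed_mass = traj$mass,
      {
        if (!ob %in% colnames(traj$states)) {
          stop("unknown observable: ", ob, call. = FALSE)
        }
        traj$states[, ob]
      })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- observables
  m
}

#' Desk-scale fixture network
#'
#' A reduced, analytically tractable model used as the oracle network for
#' calibration and integrator tests: a linear chain from an external
#' substrate through A, B, C to product P with end-product feedback
#' inhibition on the A -> B step, a branch B -> D -> Q, a first-order leak
#' from A, and first-order removal of the terminal pools. Eight metabolites,
#' ten reactions, flat enzyme profiles and no growth dilution.
#'
#' @param growth Optional growth model; defaults to a negligible-growth
#'   curve so steady states are analytic.
#' @return A validated `metabolic_model`.
#' @export
fixture_model <- function(growth = growth_model(mu0 = 1e-6, mu_mature = 1e-7)) {
  metabolites <- tibble::tibble(
    id = c("S_e", "A", "B", "C", "P", "D", "Q", "W"),
    compartment = c("external", rep("cytosol", 7)),
    initial = c(1, 0.1, 0.1, 0.1, 0.01, 0.1, 0.01, 0.01),
    external = c(TRUE, rep(FALSE, 7)),
    dilute = c(FALSE, rep(TRUE, 7)),
    cofactor_pair = NA_character_
  )
  p <- new.env(parent = emptyenv())
  par <- function(name, value) { assign(name, value, envir = p); name }
  rxns <- list(
    tibble::tibble(id = "UP", name = "uptake", enzyme = "UP",
                   turnover = "average", reversible = FALSE,
                   stoich = list(c(S_e = -1, A = 1)),
                   law = list(mm_law(par("k_UP", 0.2),
                                     c(S_e = par("Km_UP_S", 0.5))))),
    tibble::tibble(id = "R2", name = "A to B (feedback-inhibited)",
                   enzyme = "R2", turnover = "average", reversible = FALSE,
                   stoich = list(c(A = -1, B = 1)),
                   law = list(mm_law(par("k_R2", 0.3),
                                     c(A = par("Km_R2_A", 0.3)),
                                     list(hill_inhibitor("P", par("Ki_R2_P", 0.5),
                                                         par("n_R2", 2)))))),
    tibble::tibble(id = "R3", name = "B to C", enzyme = "R3",
                   turnover = "average", reversible = FALSE,
                   stoich = list(c(B = -1, C = 1)),
                   law = list(mm_law(par("k_R3", 0.25),
                                     c(B = par("Km_R3_B", 0.3))))),
    tibble::tibble(id = "R4", name = "C to P", enzyme = "R4",
                   turnover = "average", reversible = FALSE,
                   stoich = list(c(C = -1, P = 1)),
                   law = list(mm_law(par("k_R4", 0.3),
                                     c(C = par("Km_R4_C", 0.3))))),
    tibble::tibble(id = "R5", name = "B to D (branch)", enzyme = "R5",
                   turnover = "average", reversible = FALSE,
                   stoich = list(c(B = -1, D = 1)),
                   law = list(mm_law(par("k_R5", 0.1),
                                     c(B = par("Km_R5_B", 0.4))))),
    tibble::tibble(id = "R6", name = "D to Q", enzyme = "R6",
                   turnover = "average", reversible = FALSE,
                   stoich = list(c(D = -1, Q = 1)),
                   law = list(mm_law(par("k_R6", 0.15),
                                     c(D = par("Km_R6_D", 0.3))))),
    tibble::tibble(id = "R7", name = "P removal", enzyme = NA_character_,
                   turnover = NA_character_, reversible = FALSE,
                   stoich = list(c(P = -1)),
                   law = list(mass_action_law(par("k_R7", 0.05), "P"))),
    tibble::tibble(id = "R8", name = "Q removal", enzyme = NA_character_,
                   turnover = NA_character_, reversible = FALSE,
                   stoich = list(c(Q = -1)),
                   law = list(mass_action_law(par("k_R8", 0.05), "Q"))),
    tibble::tibble(id = "R9", name = "A leak", enzyme = NA_character_,
                   turnover = NA_character_, reversible = FALSE,
                   stoich = list(c(A = -1, W = 1)),
                   law = list(mass_action_law(par("k_R9", 0.02), "A"))),
    tibble::tibble(id = "R10", name = "W removal", enzyme = NA_character_,
                   turnover = NA_character_, reversible = FALSE,
                   stoich = list(c(W = -1)),
                   law = list(mass_action_law(par("k_R10", 0.05), "W")))
  )
  params <- unlist(as.list(p))
  params <- params[sort(names(params))]
  param_info <- tibble::tibble(
    name = names(params),
    lower = ifelse(startsWith(names(params), "n_"), 1, unname(params) / 100),
    upper = ifelse(startsWith(names(params), "n_"), 4, unname(params) * 100),
    provenance = "default"
  )
  metabolic_model(metabolites, dplyr::bind_rows(rxns), params, param_info,
                  growth = growth, cofactor_pairs = list(),
                  sprt_mrna_reaction = NULL)
}

#' Flat expression input for the fixture network
#'
#' @param model The fixture model.
#' @param grid Stage grid.
#' @return An [expression_input()] with flat unit profiles.
#' @export
fixture_expression <- function(model = fixture_model(), grid = stage_grid()) {
  enz <- unique(stats::na.omit(model$reactions$enzyme))
  profiles <- tibble::tibble(
    enzyme = rep(enz, each = 7),
    stage = rep(grid$stage, times = length(enz)),
    rel_mrna = 1
  )
  expression_input(profiles, rb = NULL, grid = grid)
}
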