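#' Reference reconstruction of embryo carbon/energy metabolism
#'
#' Builds the default compartmented kinetic network: simplified glycolysis
#' (HK, PFK, PGK, the non-phosphorylating NADPH-producing bypass NPG, and
#' cytosolic/plastidial pyruvate kinase), the oxidative pentose-phosphate
#' pathway with the epimerase return route and the Rubisco carbon-conserving
#' bypass, plastid fatty-acid synthesis (acetyl-CoA carboxylase and the FA
#' synthase complex, both feedback-inhibited by the short-chain acyl-ACP
#' pool), cytosolic malonyl-CoA driven FA elongation, TAG assembly and
#' oxidation with an isocitrate-lyase glyoxylate shunt, a simplified
#' mitochondrial TCA cycle with anaplerotic/exchange reactions (PEPC, malic
#' enzyme, GDH, AAT, ATP citrate lyase), transport steps (cell-wall
#' invertase, glucose transporter, plastidial PEP and pyruvate
#' transporters), storage fluxes for starch, sucrose and storage protein,
#' and maintenance loads (oxidative phosphorylation, mitochondrial proton
#' leak on NADH, endogenous oxidative stress on NADPH, and a growth-
#' associated plus constant ATP demand).
#'
#' The network has 34 metabolic states, 40 reactions and about 125 named
#' kinetic parameters. Cofactors are modeled as conserved pairs (ATP/ADP, NAD(H),
#' NADP(H)) with fixed totals; compartment volumes are taken as equal, so
#' concentrations are directly comparable across compartments and transport
#' steps carry no volume correction. Gluconeogenic flux is absent: the
#' embryo operates in glycolytic mode.
#'
#' @param growth A [growth_model()]; defaults to the calibrated logistic
#'   curve.
#' @return A validated `metabolic_model`.
#' @examples
#' m <- build_default_model()
#' nrow(m$metabolites)  # 34
#' nrow(m$reactions)    # 40
#' @export
build_default_model <- function(growth = growth_model()) {
  metabolites <- tibble::tribble(
    ~id,      ~compartment,    ~initial, ~external, ~dilute, ~cofactor_pair,
    "SUC_e",  "external",      1.0,      TRUE,      FALSE,   NA,
    "AA_e",   "external",      0.5,      TRUE,      FALSE,   NA,
    "HEX_a",  "external",      0.05,     FALSE,     TRUE,    NA,
    "GLC",    "cytosol",       0.1,      FALSE,     TRUE,    NA,
    "SUC",    "cytosol",       1.0,      FALSE,     TRUE,    NA,
    "HP_c",   "cytosol",       0.3,      FALSE,     TRUE,    NA,
    "TP_c",   "cytosol",       0.1,      FALSE,     TRUE,    NA,
    "PEP_c",  "cytosol",       0.2,      FALSE,     TRUE,    NA,
    "PYR_c",  "cytosol",       0.3,      FALSE,     TRUE,    NA,
    "ACA_c",  "cytosol",       0.05,     FALSE,     TRUE,    NA,
    "MCA_c",  "cytosol",       0.02,     FALSE,     TRUE,    NA,
    "ALA",    "cytosol",       0.3,      FALSE,     TRUE,    NA,
    "GLU",    "cytosol",       0.3,      FALSE,     TRUE,    NA,
    "FA",     "cytosol",       0.01,     FALSE,     TRUE,    NA,
    "FAE",    "cytosol",       0.005,    FALSE,     TRUE,    NA,
    "R5P",    "plastid",       0.1,      FALSE,     TRUE,    NA,
    "PEP_p",  "plastid",       0.1,      FALSE,     TRUE,    NA,
    "PYR_p",  "plastid",       0.2,      FALSE,     TRUE,    NA,
    "ACA_p",  "plastid",       0.05,     FALSE,     TRUE,    NA,
    "MACP",   "plastid",       0.02,     FALSE,     TRUE,    NA,
    "SCFA",   "plastid",       0.01,     FALSE,     TRUE,    NA,
    "STA",    "plastid",       0.1,      FALSE,     TRUE,    NA,
    "OAA",    "mitochondrion", 0.05,     FALSE,     TRUE,    NA,
    "CIT",    "mitochondrion", 0.3,      FALSE,     TRUE,    NA,
    "AKG",    "mitochondrion", 0.2,      FALSE,     TRUE,    NA,
    "MAL",    "mitochondrion", 0.3,      FALSE,     TRUE,    NA,
    "TAG",    "cytosol",       0.002,    FALSE,     TRUE,    NA,
    "SPRT",   "cytosol",       0.01,     FALSE,     TRUE,    NA,
    "ATP",    "cytosol",       1.0,      FALSE,     FALSE,   "adenylate",
    "ADP",    "cytosol",       0.5,      FALSE,     FALSE,   "adenylate",
    "NADH",   "mitochondrion", 0.1,      FALSE,     FALSE,   "nad_pool",
    "NAD",    "mitochondrion", 0.9,      FALSE,     FALSE,   "nad_pool",
    "NADPH",  "plastid",       0.3,      FALSE,     FALSE,   "nadp_pool",
    "NADP",   "plastid",       0.7,      FALSE,     FALSE,   "nadp_pool"
  )

  p <- new.env(parent = emptyenv())
  par <- function(name, value) {
    assign(name, value, envir = p)
    name
  }

  rx <- list()
  add <- function(id, name, enzyme, turnover, reversible, stoich, law) {
    rx[[length(rx) + 1]] <<- tibble::tibble(
      id = id, name = name, enzyme = enzyme, turnover = turnover,
      reversible = reversible, stoich = list(stoich), law = list(law)
    )
  }

  # generic cofactor affinities are shared across consuming reactions
  mm <- function(id, k, subs, inhibitors = list()) {
    km <- vapply(names(subs), function(m) {
      if (m %in% c("ATP", "NAD")) par(paste0("Km_", m), subs[[m]])
      else par(paste0("Km_", id, "_", m), subs[[m]])
    }, "")
    names(km) <- names(subs)
    mm_law(par(paste0("k_", id), k), km, inhibitors)
  }
  hill <- function(id, met, ki, n) {
    hill_inhibitor(met, par(paste0("Ki_", id, "_", met), ki), par(paste0("n_", id), n))
  }

  # -- substrate supply and sugar handling ---------------------------------
  # hexose product inhibition keeps apoplastic sucrose cleavage demand-limited
  add("CWI", "cell-wall invertase", "CWI", "slow", FALSE,
      c(SUC_e = -1, HEX_a = 2),
      mm("CWI", 0.05, c(SUC_e = 0.5), list(hill("CWI", "HEX_a", 0.15, 2))))
  # trans-inhibition by internal glucose: uptake responds to downstream
  # demand (pull) but not to apoplastic accumulation (push)
  add("GLCT", "glucose transporter", "GLCT", "slow", FALSE,
      c(HEX_a = -1, GLC = 1),
      mm("GLCT", 0.08, c(HEX_a = 0.1), list(hill("GLCT", "GLC", 0.08, 2))))
  add("SUS", "sucrose synthase", "SUS", "fast", TRUE,
      c(GLC = -2, SUC = 1),
      rev_mm_law(par("k_SUS", 0.05),
                 c(GLC = par("Km_SUS_GLC", 0.5)),
                 c(SUC = par("Km_SUS_SUC", 1.0)),
                 par("Keq_SUS", 4)))
  add("STAS", "starch synthesis", "STAS", "average", FALSE,
      c(HP_c = -1, ATP = -1, STA = 1, ADP = 1),
      mm("STAS", 0.08, c(HP_c = 0.3, ATP = 0.1)))
  add("STAD", "starch degradation", "STAD", "fast", FALSE,
      c(STA = -1, GLC = 1), mm("STAD", 0.01, c(STA = 1.0)))

  # -- cytosolic glycolysis -------------------------------------------------
  add("HK", "hexokinase", "HK", "fast", FALSE,
      c(GLC = -1, ATP = -1, HP_c = 1, ADP = 1),
      mm("HK", 0.15, c(GLC = 0.3, ATP = 0.1),
         list(hill("HK", "HP_c", 2.0, 2))))
  add("PFK", "phosphofructokinase", "PFK", "average", FALSE,
      c(HP_c = -1, ATP = -1, TP_c = 2, ADP = 1),
      mm("PFK", 0.12, c(HP_c = 0.3, ATP = 0.1),
         list(hill("PFK", "PEP_c", 1.5, 2))))
  add("PGK", "phosphoglycerate kinase (lumped lower glycolysis)", "PGK",
      "average", FALSE,
      c(TP_c = -1, ADP = -1, NAD = -1, PEP_c = 1, ATP = 1, NADH = 1),
      mm("PGK", 0.3, c(TP_c = 0.3, ADP = 0.1, NAD = 0.1)))
  add("NPG", "non-phosphorylating NADPH-producing bypass", "NPG",
      "average", FALSE,
      c(TP_c = -1, NADP = -1, PEP_c = 1, NADPH = 1),
      mm("NPG", 0.08, c(TP_c = 0.3, NADP = 0.1)))
  add("PKc", "pyruvate kinase (cytosol)", "PKc", "average", FALSE,
      c(PEP_c = -1, ADP = -1, PYR_c = 1, ATP = 1),
      mm("PKc", 0.1, c(PEP_c = 0.3, ADP = 0.1)))

  # -- pentose phosphate pathway and Rubisco bypass ------------------------
  add("G6PD", "oxidative pentose-phosphate pathway (lumped)", "G6PD",
      "average", FALSE,
      c(HP_c = -1, NADP = -2, R5P = 1, NADPH = 2),
      mm("G6PD", 0.15, c(HP_c = 0.3, NADP = 0.05)))
  add("EPI", "ribulose-5-phosphate epimerase (non-oxidative return)", "EPI",
      "average", FALSE,
      c(R5P = -1, HP_c = 2 / 3, TP_c = 1 / 3),
      mm("EPI", 0.1, c(R5P = 0.2)))
  add("RUB", "Rubisco carbon-conserving bypass", "RUB", "slow", FALSE,
      c(R5P = -1, ATP = -1, PEP_p = 2, ADP = 1),
      mm("RUB", 0.08, c(R5P = 0.2, ATP = 0.1)))

  # -- plastid transport and glycolysis ------------------------------------
  # equilibrative antiporter: plastid congestion backs up into the cytosol
  add("PEPT", "plastidial PEP transporter", "PEPT", "average", TRUE,
      c(PEP_c = -1, PEP_p = 1),
      rev_mm_law(par("k_PEPT", 0.25),
                 c(PEP_c = par("Km_PEPT_PEP_c", 0.2)),
                 c(PEP_p = par("Km_PEPT_PEP_p", 0.2)),
                 par("Keq_PEPT", 1)))
  add("PYRT", "plastidial pyruvate transporter", "PYRT", "average", FALSE,
      c(PYR_c = -1, PYR_p = 1), mm("PYRT", 0.02, c(PYR_c = 0.3)))
  add("PKp", "pyruvate kinase (plastid)", "PKp", "average", FALSE,
      c(PEP_p = -1, ADP = -1, PYR_p = 1, ATP = 1),
      mm("PKp", 0.4, c(PEP_p = 0.2, ADP = 0.1),
         list(hill("PKp", "PYR_p", 0.4, 2))))
  add("PDHp", "plastidial pyruvate dehydrogenase", "PDHp", "fast", FALSE,
      c(PYR_p = -1, NAD = -1, ACA_p = 1, NADH = 1),
      mm("PDHp", 0.35, c(PYR_p = 0.2, NAD = 0.1),
         list(hill("PDHp", "ACA_p", 0.5, 2))))

  # -- fatty-acid synthesis, elongation and storage ------------------------
  add("ACCp", "plastidial acetyl-CoA carboxylase", "ACCp", "fast", FALSE,
      c(ACA_p = -1, ATP = -1, MACP = 1, ADP = 1),
      mm_law(par("k_ACCp", 0.5),
             c(ACA_p = par("Km_ACCp_ACA_p", 0.2), ATP = par("Km_ATP", 0.1)),
             list(hill_inhibitor("SCFA", par("Ki_SCFA", 0.1), par("n_SCFA", 2)),
                  hill_inhibitor("MACP", par("Ki_ACCp_MACP", 0.3),
                                 par("n_ACCp", 2)))))
  add("FAS", "fatty-acid synthase complex", "FAS", "fast", FALSE,
      c(ACA_p = -1, MACP = -7, NADPH = -7, NADH = -7,
        SCFA = 1, NADP = 7, NAD = 7),
      mm_law(par("k_FAS", 0.1),
             c(ACA_p = par("Km_FAS_ACA_p", 0.2), MACP = par("Km_FAS_MACP", 0.1),
               NADPH = par("Km_FAS_NADPH", 0.1), NADH = par("Km_FAS_NADH", 0.1)),
             list(hill_inhibitor("SCFA", "Ki_SCFA", "n_SCFA"))))
  add("FAT", "acyl-ACP thioesterase / plastid FA export", "FAT", "fast", FALSE,
      c(SCFA = -1, FA = 1),
      mm("FAT", 0.3, c(SCFA = 0.1), list(hill("FAT", "FA", 2.0, 2))))
  # the FAE pool tracks the 2-carbon extension mass added to existing acyl
  # chains from cytosolic malonyl-CoA (the chains themselves remain in the
  # FA/TAG pools), so elongation competes for reductant and malonyl-CoA but
  # not for an acyl primer pool
  add("FAE", "fatty-acid elongation", "FAE", "slow", FALSE,
      c(MCA_c = -2, NADPH = -2, NADH = -2, FAE = 1, NADP = 2, NAD = 2),
      mm("FAE", 0.1, c(MCA_c = 0.3, NADPH = 0.02, FA = 0.01)))
  add("TAGS", "TAG assembly", "TAGS", "fast", FALSE,
      c(FA = -3, ATP = -1, TAG = 1, ADP = 1),
      mm("TAGS", 0.08, c(FA = 0.5, ATP = 0.1)))
  add("TAGD", "TAG oxidation (lipase + beta-oxidation)", "TAGD", "average", FALSE,
      c(TAG = -1, NAD = -21, ACA_c = 24, NADH = 21),
      mm("TAGD", 0.001, c(TAG = 1.0, NAD = 0.1)))
  add("ICL", "isocitrate lyase (glyoxylate shunt, lumped)", "ICL", "average", FALSE,
      c(ACA_c = -2, MAL = 1), mm("ICL", 0.05, c(ACA_c = 0.2)))

  # -- mitochondrial TCA cycle and exchanges -------------------------------
  add("PDH", "pyruvate dehydrogenase + citrate synthase (lumped)", "PDH",
      "average", FALSE,
      c(PYR_c = -1, OAA = -1, NAD = -2, CIT = 1, NADH = 2),
      mm("PDH", 0.2, c(PYR_c = 0.3, OAA = 0.1, NAD = 0.1)))
  add("IDH", "isocitrate dehydrogenase (lumped)", "IDH", "average", FALSE,
      c(CIT = -1, NAD = -1, AKG = 1, NADH = 1),
      mm("IDH", 0.15, c(CIT = 0.3, NAD = 0.1)))
  add("AKGD", "2-oxoglutarate-to-malate segment (lumped)", "AKGD",
      "average", FALSE,
      c(AKG = -1, NAD = -2, ADP = -1, MAL = 1, NADH = 2, ATP = 1),
      mm("AKGD", 0.15, c(AKG = 0.3, NAD = 0.1, ADP = 0.1)))
  add("MDH", "malate dehydrogenase", "MDH", "average", TRUE,
      c(MAL = -1, NAD = -1, OAA = 1, NADH = 1),
      rev_mm_law(par("k_MDH", 0.3),
                 c(MAL = par("Km_MDH_MAL", 0.3), NAD = par("Km_MDH_NAD", 0.1)),
                 c(OAA = par("Km_MDH_OAA", 0.1), NADH = par("Km_MDH_NADH", 0.1)),
                 par("Keq_MDH", 0.2)))
  add("PEPC", "PEP carboxylase", "PEPC", "average", FALSE,
      c(PEP_c = -1, OAA = 1), mm("PEPC", 0.03, c(PEP_c = 0.3)))
  add("ME", "malic enzyme (NADP)", "ME", "average", FALSE,
      c(MAL = -1, NADP = -1, PYR_c = 1, NADPH = 1),
      mm("ME", 0.05, c(MAL = 0.3, NADP = 0.1)))
  add("ACL", "ATP citrate lyase (cytosol)", "ACL", "average", FALSE,
      c(CIT = -1, ATP = -1, ACA_c = 1, OAA = 1, ADP = 1),
      mm("ACL", 0.08, c(CIT = 0.3, ATP = 0.1)))
  add("ACCc", "cytosolic acetyl-CoA carboxylase", "ACCc", "slow", FALSE,
      c(ACA_c = -1, ATP = -1, MCA_c = 1, ADP = 1),
      mm("ACCc", 0.15, c(ACA_c = 0.1, ATP = 0.1),
         list(hill("ACCc", "MCA_c", 0.5, 2))))

  # -- amino-acid exchange and storage protein -----------------------------
  add("AAT", "alanine aminotransferase", "AAT", "average", FALSE,
      c(ALA = -1, AKG = -1, PYR_c = 1, GLU = 1),
      mm("AAT", 0.08, c(ALA = 0.3, AKG = 0.2)))
  add("GDH", "glutamate dehydrogenase", "GDH", "average", FALSE,
      c(GLU = -1, NAD = -1, AKG = 1, NADH = 1),
      mm("GDH", 0.05, c(GLU = 0.3, NAD = 0.1)))
  add("AAup", "amino-acid import from maternal tissue", "AAup",
      "average", FALSE,
      c(AA_e = -1, ALA = 1),
      mm("AAup", 0.05, c(AA_e = 0.3), list(hill("AAup", "ALA", 0.3, 2))))
  add("SPRTS", "storage-protein synthesis (mRNA-driven)", NA_character_,
      NA_character_, FALSE,
      c(ALA = -2, GLU = -2, ATP = -4, SPRT = 1, ADP = 4),
      mrna_law(par("k_SPRTS", 0.015),
               c(ALA = par("Km_SPRTS_ALA", 0.2), GLU = par("Km_SPRTS_GLU", 0.2),
                 ATP = par("Km_ATP", 0.1))))

  # -- energy metabolism and maintenance -----------------------------------
  add("OXPHOS", "oxidative phosphorylation (P/O 2.5)", "OXPHOS",
      "average", FALSE,
      c(NADH = -1, ADP = -2.5, NAD = 1, ATP = 2.5),
      mm("OXPHOS", 1.2, c(NADH = 0.05, ADP = 0.05)))
  add("LEAK", "mitochondrial proton leak (NADH sink)", NA_character_,
      NA_character_, FALSE,
      c(NADH = -1, NAD = 1), mm("LEAK", 0.05, c(NADH = 0.1)))
  add("OX", "endogenous oxidative stress (NADPH sink)", NA_character_,
      NA_character_, FALSE,
      c(NADPH = -1, NADP = 1), mm("OX", 0.02, c(NADPH = 0.1)))
  add("ATPM", "ATP maintenance (growth-associated + constant)", NA_character_,
      NA_character_, FALSE,
      c(ATP = -1, ADP = 1),
      maintenance_law(par("alpha_ATPM", 2.0), par("beta_ATPM", 0.01),
                      c(ATP = par("Km_ATPM_ATP", 0.02))))

  reactions <- dplyr::bind_rows(rx)
  params <- unlist(as.list(p))
  params <- params[sort(names(params))]
  # the values registered above sketch the topology; the shipped model uses
  # the calibrated reference set
  cal <- default_parameter_values()
  common <- intersect(names(params), names(cal))
  params[common] <- cal[common]

  param_info <- tibble::tibble(
    name = names(params),
    lower = ifelse(startsWith(names(params), "n_"), 1, unname(params) / 100),
    upper = ifelse(startsWith(names(params), "n_"), 4, unname(params) * 100),
    provenance = ifelse(grepl("^(Km|Ki|Keq)_", names(params)),
                        "literature", "fitted")
  )

  metabolic_model(
    metabolites = metabolites,
    reactions = reactions,
    params = params,
    param_info = param_info,
    growth = growth,
    cofactor_pairs = list(adenylate = c("ATP", "ADP"),
                          nad_pool = c("NADH", "NAD"),
                          nadp_pool = c("NADPH", "NADP")),
    sprt_mrna_reaction = "SPRTS"
  )
}
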