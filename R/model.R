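#' Rate-law constructors
#'
#' A rate law is a small spec list interpreted by [eval_flux()] and inlined
#' by the model compiler. All parameters are referenced by name into the
#' model's parameter vector so they can be fitted or bounded without touching
#' the network structure.
#'
#' * `mm_law()` -- irreversible Michaelis--Menten, one saturating term per
#'   substrate: \eqn{v = E\,k\,\prod_s S/(K_m+S)} times any inhibition
#'   multipliers.
#' * `rev_mm_law()` -- reversible Michaelis--Menten with a pooled
#'   denominator: \eqn{v = E\,k\,(\pi_S - \pi_P/K_{eq})/(1+\pi_S+\pi_P)}
#'   with \eqn{\pi_S = \prod S/K_m}, \eqn{\pi_P = \prod P/K_m}.
#' * `mass_action_law()` -- \eqn{v = E\,k\,\prod_s S}.
#' * `mrna_law()` -- rate proportional to an mRNA input signal rather than a
#'   modeled enzyme pool (used for storage-protein synthesis):
#'   \eqn{v = k\,mRNA(t)\,\prod_s S/(K_m+S)}.
#' * `maintenance_law()` -- growth-associated plus constant load:
#'   \eqn{v = \alpha\,\mu(t) + \beta}.
#'
#' @param k,keq,alpha,beta Parameter names (character scalars).
#' @param substrates,products Named character vectors mapping metabolite IDs
#'   to Km parameter names (for `mass_action_law`, a character vector of
#'   metabolite IDs).
#' @param inhibitors List of [hill_inhibitor()] specs.
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
mm_law <- function(k, substrates, inhibitors = list()) {
  list(type = "michaelis_menten", k = k, substrates = substrates,
       inhibitors = inhibitors)
}

#' @rdname rate_laws
#' @export
rev_mm_law <- function(k, substrates, products, keq, inhibitors = list()) {
  list(type = "reversible_mm", k = k, substrates = substrates,
       products = products, keq = keq, inhibitors = inhibitors)
}

#' @rdname rate_laws
#' @export
mass_action_law <- function(k, substrates, inhibitors = list()) {
  list(type = "mass_action", k = k, substrates = substrates,
       inhibitors = inhibitors)
}

#' @rdname rate_laws
#' @export
mrna_law <- function(k, substrates, inhibitors = list()) {
  list(type = "mrna_proportional", k = k, substrates = substrates,
       inhibitors = inhibitors)
}

#' @rdname rate_laws
#' @export
maintenance_law <- function(alpha, beta, substrates = NULL) {
  # the optional saturating substrate term shuts the load off as the pool
  # empties (a constant draw would push the state negative)
  list(type = "constant_maintenance", alpha = alpha, beta = beta,
       substrates = substrates %||% character(), inhibitors = list())
}

#' Hill inhibition term
#'
#' Multiplies a rate law by \eqn{K_i^n/(K_i^n + I^n)}: 1 with no inhibitor,
#' 0.5 at \eqn{I = K_i}, approaching 0 at saturating inhibitor. A Hill
#' coefficient above 1 gives the threshold-like response used for product
#' feedback (acyl-ACP inhibition of fatty-acid synthesis).
#'
#' @param met Inhibiting metabolite ID.
#' @param ki Parameter name of the half-inhibition constant.
#' @param n Parameter name of the Hill coefficient.
#' @export
hill_inhibitor <- function(met, ki, n) {
  list(met = met, ki = ki, n = n)
}

#' Feedback-inhibition multiplier
#'
#' The factor applied to the carboxylase and fatty-acid synthase fluxes by
#' the short-chain acyl-ACP (SCFA) pool: \eqn{K_i^n/(K_i^n + S^n)}, strictly
#' decreasing in the inhibitor concentration.
#'
#' @param scfa Inhibitor concentration(s), nonnegative.
#' @param ki Half-inhibition constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Multiplier in (0, 1].
#' @examples
#' scfa_feedback_multiplier(c(0, 1, 100), ki = 1, n = 2)
#' @export
scfa_feedback_multiplier <- function(scfa, ki, n = 2) {
  stopifnot(all(scfa >= 0), ki > 0, n >= 1)
  ki^n / (ki^n + scfa^n)
}

#' Assemble a kinetic metabolic model
#'
#' @param metabolites Tibble with columns `id`, `compartment`, `initial`,
#'   and optionally `external` (boundary species with fixed level),
#'   `dilute` (subject to the growth-dilution term) and `cofactor_pair`.
#' @param reactions Tibble with columns `id`, `name`, `enzyme` (NA for
#'   non-enzymatic steps), `turnover`, `reversible`, and list-columns
#'   `stoich` (named numeric) and `law` (a rate-law spec).
#' @param params Named numeric vector of kinetic parameters.
#' @param param_info Optional tibble (`name`, `lower`, `upper`,
#'   `provenance`); defaults to wide bounds with provenance `"default"`.
#' @param growth A [growth_model()].
#' @param cofactor_pairs Named list of metabolite ID pairs whose totals are
#'   conserved (e.g. adenylate = ATP + ADP).
#' @param sprt_mrna_reaction ID of the reaction driven directly by the
#'   storage-protein mRNA signal.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, params,
                            param_info = NULL, growth = growth_model(),
                            cofactor_pairs = list(),
                            sprt_mrna_reaction = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  if (is.null(metabolites$external)) metabolites$external <- FALSE
  if (is.null(metabolites$dilute)) metabolites$dilute <- !metabolites$external
  if (is.null(metabolites$cofactor_pair)) metabolites$cofactor_pair <- NA_character_
  reactions <- tibble::as_tibble(reactions)
  if (is.null(param_info)) {
    param_info <- tibble::tibble(
      name = names(params),
      lower = unname(params) / 100,
      upper = unname(params) * 100,
      provenance = "default"
    )
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         params = params, param_info = tibble::as_tibble(param_info),
         growth = growth, cofactor_pairs = cofactor_pairs,
         sprt_mrna_reaction = sprt_mrna_reaction),
    class = "metabolic_model"
  )
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks structural consistency: all stoichiometry entries refer to declared
#' metabolites, every rate-law parameter exists, every enzymatic reaction
#' carries a turnover class, cofactor pairs refer to declared metabolites,
#' and parameter values sit within their bounds.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe the first inconsistency.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$id
  if (anyDuplicated(mets)) stop("duplicate metabolite IDs", call. = FALSE)
  if (anyDuplicated(model$reactions$id)) stop("duplicate reaction IDs", call. = FALSE)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- r$stoich[[1]]
    if (length(st) == 0) stop("empty stoichiometry in ", r$id, call. = FALSE)
    missing_met <- setdiff(names(st), mets)
    if (length(missing_met) > 0) {
      stop("reaction ", r$id, " references unknown metabolite(s): ",
           paste(missing_met, collapse = ", "), call. = FALSE)
    }
    law <- r$law[[1]]
    law_mets <- c(names(law$substrates) %||% law$substrates,
                  names(law$products),
                  vapply(law$inhibitors, function(x) x$met, ""))
    missing_met <- setdiff(law_mets, mets)
    if (length(missing_met) > 0) {
      stop("rate law of ", r$id, " references unknown metabolite(s): ",
           paste(missing_met, collapse = ", "), call. = FALSE)
    }
    for (pn in law_param_names(law)) {
      if (!pn %in% names(model$params)) {
        stop("reaction ", r$id, " references missing parameter ", pn, call. = FALSE)
      }
    }
    if (!is.na(r$enzyme) && (is.na(r$turnover) ||
        !r$turnover %in% turnover_classes()$class)) {
      stop("enzymatic reaction ", r$id, " needs a valid turnover class", call. = FALSE)
    }
  }
  for (pair in model$cofactor_pairs) {
    if (!all(pair %in% mets)) {
      stop("cofactor pair refers to unknown metabolite(s): ",
           paste(setdiff(pair, mets), collapse = ", "), call. = FALSE)
    }
  }
  pi <- model$param_info
  vals <- model$params[pi$name]
  bad <- which(vals < pi$lower | vals > pi$upper)
  if (length(bad) > 0) {
    stop("parameter(s) outside bounds: ", paste(pi$name[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(model)
}

#' @keywords internal
law_param_names <- function(law) {
  out <- character()
  if (law$type == "constant_maintenance") {
    out <- c(law$alpha, law$beta, unname(law$substrates))
  } else {
    out <- law$k
    if (law$type %in% c("michaelis_menten", "reversible_mm", "mrna_proportional")) {
      out <- c(out, unname(law$substrates))
    }
    if (law$type == "reversible_mm") out <- c(out, unname(law$products), law$keq)
    for (inh in law$inhibitors) out <- c(out, inh$ki, inh$n)
  }
  out
}

#' Stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @return Numeric matrix, metabolites (rows) by reactions (columns).
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = nrow(model$reactions),
              dimnames = list(mets, model$reactions$id))
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoich[[i]]
    S[names(st), i] <- st
  }
  S
}

#' Evaluate a single reaction flux
#'
#' Reference (interpreted) evaluation of one reaction's rate law at a given
#' state: \eqn{v = E\,k\,f(M, p)} with saturating substrate terms and Hill
#' inhibition multipliers. The compiled simulator inlines the same algebra;
#' the two routes are cross-checked in the test suite.
#'
#' @param model A `metabolic_model`.
#' @param reaction Reaction ID.
#' @param state Named numeric vector of metabolite concentrations (>= 0).
#' @param enzyme_level Enzyme level for the reaction (>= 0).
#' @param params Parameter vector; defaults to the model's.
#' @param mu Growth rate (hr^-1), used by maintenance laws.
#' @param mrna mRNA signal, used by mRNA-proportional laws.
#' @return Flux (model units per hour).
#' @export
eval_flux <- function(model, reaction, state, enzyme_level = 1,
                      params = model$params, mu = 0, mrna = 1) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) stop("unknown reaction ", reaction, call. = FALSE)
  if (any(state < 0)) stop("state values must be nonnegative", call. = FALSE)
  if (enzyme_level < 0) stop("enzyme level must be nonnegative", call. = FALSE)
  law <- model$reactions$law[[i]]
  p <- function(nm) {
    v <- params[nm]
    if (anyNA(v)) stop("missing parameter ", nm, call. = FALSE)
    unname(v)
  }
  inh_mult <- 1
  for (inh in law$inhibitors) {
    inh_mult <- inh_mult *
      scfa_feedback_multiplier(state[[inh$met]], p(inh$ki), p(inh$n))
  }
  v <- switch(law$type,
    michaelis_menten = {
      f <- 1
      for (m in names(law$substrates)) {
        f <- f * state[[m]] / (p(law$substrates[[m]]) + state[[m]])
      }
      enzyme_level * p(law$k) * f
    },
    mass_action = {
      f <- 1
      for (m in law$substrates) f <- f * state[[m]]
      enzyme_level * p(law$k) * f
    },
    reversible_mm = {
      ps <- 1
      for (m in names(law$substrates)) ps <- ps * state[[m]] / p(law$substrates[[m]])
      pp <- 1
      for (m in names(law$products)) pp <- pp * state[[m]] / p(law$products[[m]])
      enzyme_level * p(law$k) * (ps - pp / p(law$keq)) / (1 + ps + pp)
    },
    mrna_proportional = {
      f <- 1
      for (m in names(law$substrates)) {
        f <- f * state[[m]] / (p(law$substrates[[m]]) + state[[m]])
      }
      p(law$k) * mrna * f
    },
    constant_maintenance = {
      f <- 1
      for (m in names(law$substrates)) {
        f <- f * state[[m]] / (p(law$substrates[[m]]) + state[[m]])
      }
      (p(law$alpha) * mu + p(law$beta)) * f
    },
    stop("unknown law type ", law$type, call. = FALSE)
  )
  unname(v * inh_mult)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Kinetic metabolic model\n")
  cat(sprintf("  %d metabolites (%d external), %d reactions (%d enzymatic), %d parameters\n",
              nrow(x$metabolites), sum(x$metabolites$external),
              nrow(x$reactions), sum(!is.na(x$reactions$enzyme)),
              length(x$params)))
  cat("  compartments:",
      paste(sort(unique(x$metabolites$compartment)), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
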