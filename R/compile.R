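# Model compiler: turns the declarative reaction table into a single
# byte-compiled R function evaluating all fluxes, with every parameter
# inlined as a numeric constant. Recompilation is cheap (milliseconds), so
# fitted parameter vectors are handled by recompiling.

#' @keywords internal
num_const <- function(x) sprintf("%.17g", x)

#' @keywords internal
compile_network <- function(model, params = model$params) {
  mets <- model$metabolites$id
  midx <- function(m) match(m, mets)
  pval <- function(nm) {
    v <- params[[nm]]
    if (is.null(v) || is.na(v)) stop("missing parameter ", nm, call. = FALSE)
    v
  }
  mm_term <- function(m, km) {
    sprintf("(M[%d]/(%s+M[%d]))", midx(m), num_const(pval(km)), midx(m))
  }
  inh_term <- function(inh) {
    kin <- pval(inh$ki)^pval(inh$n)
    sprintf("(%s/(%s+M[%d]^%s))", num_const(kin), num_const(kin),
            midx(inh$met), num_const(pval(inh$n)))
  }

  n_rxn <- nrow(model$reactions)
  lines <- character(n_rxn)
  for (j in seq_len(n_rxn)) {
    r <- model$reactions[j, ]
    law <- r$law[[1]]
    inh <- vapply(law$inhibitors, inh_term, "")
    core <- switch(law$type,
      michaelis_menten = {
        terms <- vapply(names(law$substrates),
                        function(m) mm_term(m, law$substrates[[m]]), "")
        paste(c(num_const(pval(law$k)), sprintf("E[%d]", j), terms),
              collapse = "*")
      },
      mass_action = {
        terms <- vapply(law$substrates,
                        function(m) sprintf("M[%d]", midx(m)), "")
        paste(c(num_const(pval(law$k)), sprintf("E[%d]", j), terms),
              collapse = "*")
      },
      reversible_mm = {
        ps <- paste(vapply(names(law$substrates), function(m) {
          sprintf("(M[%d]/%s)", midx(m), num_const(pval(law$substrates[[m]])))
        }, ""), collapse = "*")
        pp <- paste(vapply(names(law$products), function(m) {
          sprintf("(M[%d]/%s)", midx(m), num_const(pval(law$products[[m]])))
        }, ""), collapse = "*")
        sprintf("%s*E[%d]*((%s)-(%s)/%s)/(1+(%s)+(%s))",
                num_const(pval(law$k)), j, ps, pp,
                num_const(pval(law$keq)), ps, pp)
      },
      mrna_proportional = {
        terms <- vapply(names(law$substrates),
                        function(m) mm_term(m, law$substrates[[m]]), "")
        paste(c(num_const(pval(law$k)), "xin", terms), collapse = "*")
      },
      constant_maintenance = {
        terms <- vapply(names(law$substrates),
                        function(m) mm_term(m, law$substrates[[m]]), "")
        paste(c(sprintf("(%s*mu+%s)", num_const(pval(law$alpha)),
                        num_const(pval(law$beta))), terms),
              collapse = "*")
      },
      stop("unknown law type ", law$type, call. = FALSE)
    )
    rhs <- paste(c(core, inh), collapse = "*")
    lines[j] <- sprintf("v[%d] <- %s", j, rhs)
  }

  body <- paste(
    "function(M, E, mu, xin, kscale) {",
    sprintf("v <- numeric(%d)", n_rxn),
    paste(lines, collapse = "\n"),
    "v * kscale",
    "}",
    sep = "\n"
  )
  flux_fn <- eval(parse(text = body), envir = baseenv())
  compiler::cmpfun(flux_fn)
}
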