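test_that("rate-law algebra matches its closed forms", {
  m <- fix_model()
  # single substrate at S = Km gives half the limiting rate
  p <- m$params
  s <- c(S_e = p[["Km_UP_S"]], A = 0, B = 0, C = 0, P = 0, D = 0, Q = 0, W = 0)
  expect_equal(eval_flux(m, "UP", s, enzyme_level = 2),
               0.5 * 2 * p[["k_UP"]])

  # Hill inhibition multiplier is 1/2 at I = Ki (n = 2)
  expect_equal(scfa_feedback_multiplier(1, ki = 1, n = 2), 0.5)
  expect_equal(scfa_feedback_multiplier(0, ki = 1, n = 2), 1)
  expect_lt(scfa_feedback_multiplier(1e6, ki = 1, n = 2), 1e-9)
  expect_true(all(diff(scfa_feedback_multiplier(seq(0, 5, 0.1), 0.5, 2)) < 0))

  s2 <- s; s2["A"] <- p[["Km_R2_A"]]; s2["P"] <- p[["Ki_R2_P"]]
  expect_equal(eval_flux(m, "R2", s2, enzyme_level = 1),
               p[["k_R2"]] * 0.5 * 0.5)

  # doubling the enzyme level doubles the flux
  expect_equal(eval_flux(m, "R2", s2, enzyme_level = 2),
               2 * eval_flux(m, "R2", s2, enzyme_level = 1))
})

test_that("reversible laws change sign across equilibrium", {
  # two-metabolite toy: the sucrose-synthase law flips direction as the
  # reaction quotient crosses Keq (oracle: evaluate on both sides)
  m <- ref_model()
  p <- m$params
  keq <- p[["Keq_SUS"]]
  kmg <- p[["Km_SUS_GLC"]]; kms <- p[["Km_SUS_SUC"]]
  state <- stats::setNames(rep(0.1, nrow(m$metabolites)), m$metabolites$id)
  # at equilibrium: GLC/KmG == (SUC/KmS)/Keq  =>  SUC = Keq*KmS*GLC/KmG
  glc <- 0.2
  suc_eq <- keq * kms * glc / kmg
  state["GLC"] <- glc
  state["SUC"] <- suc_eq
  expect_equal(eval_flux(m, "SUS", state, 1), 0, tolerance = 1e-12)
  state["SUC"] <- suc_eq * 0.5
  expect_gt(eval_flux(m, "SUS", state, 1), 0)   # net storage
  state["SUC"] <- suc_eq * 2
  expect_lt(eval_flux(m, "SUS", state, 1), 0)   # net release
})

test_that("flux evaluation validates its inputs", {
  m <- fix_model()
  s <- stats::setNames(rep(0.1, 8), m$metabolites$id)
  expect_error(eval_flux(m, "NOPE", s), "unknown reaction")
  s_bad <- s; s_bad["A"] <- -1
  expect_error(eval_flux(m, "R2", s_bad), "nonnegative")
  p <- m$params[names(m$params) != "Km_R2_A"]
  expect_error(eval_flux(m, "R2", s, params = p), "missing parameter")
})

test_that("model validation flags structural inconsistencies", {
  m <- fix_model()
  bad <- m
  bad$reactions$stoich[[1]] <- c(NOT_A_MET = 1)
  expect_error(validate_model(bad), "unknown metabolite")

  bad2 <- m
  bad2$reactions$turnover[1] <- NA_character_
  expect_error(validate_model(bad2), "turnover class")

  bad3 <- m
  bad3$params[["k_UP"]] <- 1e9  # outside declared bounds
  expect_error(validate_model(bad3), "outside bounds")
})

test_that("compiled fluxes agree with the interpreted evaluator", {
  # dual route: the generated code is checked against eval_flux() on random
  # states for every reaction of both models
  set.seed(42)
  for (m in list(fix_model(), ref_model())) {
    flux_fn <- seedfa:::compile_network(m)
    n <- nrow(m$metabolites)
    for (rep in 1:5) {
      state <- stats::setNames(stats::runif(n, 0, 2), m$metabolites$id)
      E <- stats::runif(nrow(m$reactions), 0, 3)
      mu <- stats::runif(1, 0, 0.03)
      xin <- stats::runif(1, 0, 5)
      v <- flux_fn(unname(state), E, mu, xin, rep(1, nrow(m$reactions)))
      for (j in seq_len(nrow(m$reactions))) {
        expect_equal(
          v[j],
          eval_flux(m, m$reactions$id[j], state, enzyme_level = E[j],
                    mu = mu, mrna = xin),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("unit flux through each reaction reproduces its stoichiometry column", {
  # reaction-by-reaction oracle: with all other reactions silenced and no
  # dilution, the state derivative equals flux times the declared column
  m <- ref_model()
  S <- stoich_matrix(m)
  flux_fn <- seedfa:::compile_network(m)
  state <- stats::setNames(rep(0.5, nrow(m$metabolites)), m$metabolites$id)
  E <- rep(1, nrow(m$reactions))
  for (j in seq_len(nrow(m$reactions))) {
    kscale <- rep(0, nrow(m$reactions)); kscale[j] <- 1
    v <- flux_fn(unname(state), E, 0.01, 1, kscale)
    expect_true(all(v[-j] == 0))
    dM <- as.vector(S %*% v)
    expect_equal(dM, unname(v[j] * S[, j]), tolerance = 1e-12)
  }
})

test_that("irreversible reactions return no flux without substrate", {
  m <- ref_model()
  zero <- stats::setNames(rep(0, nrow(m$metabolites)), m$metabolites$id)
  for (j in seq_len(nrow(m$reactions))) {
    r <- m$reactions[j, ]
    if (r$law[[1]]$type %in% c("constant_maintenance")) next
    expect_equal(eval_flux(m, r$id, zero, enzyme_level = 1, mu = 0.02,
                           mrna = 1), 0,
                 info = r$id)
  }
})

test_that("fluxes respond monotonically to substrates and inhibitors", {
  m <- ref_model()
  base <- stats::setNames(rep(0.3, nrow(m$metabolites)), m$metabolites$id)
  # substrate monotonicity for a representative saturating law
  vals <- vapply(seq(0, 2, by = 0.1), function(x) {
    s <- base; s["PEP_p"] <- x
    eval_flux(m, "PKp", s, 1)
  }, 0)
  expect_true(all(diff(vals) >= 0))
  # inhibitor monotonicity (acyl-ACP on the synthase complex)
  vals2 <- vapply(seq(0, 2, by = 0.1), function(x) {
    s <- base; s["SCFA"] <- x
    eval_flux(m, "FAS", s, 1)
  }, 0)
  expect_true(all(diff(vals2) <= 0))
})
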