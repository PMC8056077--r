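test_that("with all reactions silenced metabolites only dilute", {
  m <- ref_model()
  e <- ref_expression()
  enz <- unique(stats::na.omit(m$reactions$enzyme))
  off <- stats::setNames(rep(0, length(enz) + 1), c(enz, "SPRTS"))
  koff <- stats::setNames(rep(0, 3), c("LEAK", "OX", "ATPM"))
  traj <- simulate_model(m, e, enzyme_scale = off, k_scale = as.list(koff),
                         t_end_daf = 5)
  expect_true(all(abs(traj$fluxes) < 1e-12))
  # dilution oracle: since mu = d log m / dt, M(t) = M0 * m(0)/m(t)
  g <- m$growth
  ratio <- growth_curve(g, 0)$mass / growth_curve(g, traj$time_hr)$mass
  for (i in which(m$metabolites$dilute)) {
    expect_equal(traj$states[, i],
                 m$metabolites$initial[i] * ratio, tolerance = 1e-5)
  }
  # non-diluted (cofactors) and external pools stay put
  for (i in which(!m$metabolites$dilute)) {
    expect_equal(traj$states[, i],
                 rep(m$metabolites$initial[i], nrow(traj$states)),
                 tolerance = 1e-8)
  }
})

test_that("cofactor pools are conserved along the reference trajectory", {
  traj <- ref_trajectory()
  m <- ref_model()
  for (pair in m$cofactor_pairs) {
    tot <- rowSums(traj$states[, pair, drop = FALSE])
    drift <- max(abs(tot - tot[1])) / tot[1]
    expect_lt(drift, 0.005)
  }
})

test_that("solutions are stable under tolerance and grid refinement", {
  m <- ref_model(); e <- ref_expression()
  base <- ref_trajectory()
  fa_base <- total_fa(base)$total_fa[at_daf(base, 20)]

  tight <- simulate_model(m, e, rtol = 5e-7, atol = 5e-10)
  fa_tight <- total_fa(tight)$total_fa[at_daf(tight, 20)]
  expect_lt(abs(fa_tight - fa_base) / fa_base, 1e-3)

  fine <- simulate_model(m, e, dt_out_daf = 0.05)
  shared <- match(round(base$time_daf, 6), round(fine$time_daf, 6))
  expect_equal(fine$states[shared, ], base$states,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("physiological ratios are computed with floored denominators", {
  r <- physiological_ratios(ref_trajectory())
  expect_true(all(is.finite(r$hex_suc)))
  expect_true(all(is.finite(r$atp_adp)))
  expect_named(r, c("time_daf", "hex_suc", "pk_plastid_cytosol",
                    "rub_fab", "atp_adp"))
  # the Rubisco bypass contributes measurably to FA biosynthesis mid-filling
  sel <- r$time_daf >= 7 & r$time_daf <= 14
  expect_true(mean(r$rub_fab[sel]) > 0)
})

test_that("fa_turnover recovers a known first-order oxidation rate", {
  # single-pool oracle: TAG decays by mass action at k; with the oil all in
  # TAG the turnover read-out equals k (converted to per day)
  k_per_day <- 0.1
  mets <- tibble::tibble(
    id = c("TAG", "FA", "SCFA", "FAE", "X"),
    compartment = "cytosol",
    initial = c(2, 0, 0, 0, 0),
    external = FALSE, dilute = FALSE, cofactor_pair = NA_character_
  )
  rxns <- tibble::tibble(
    id = "TAGD", name = "first-order oxidation", enzyme = NA_character_,
    turnover = NA_character_, reversible = FALSE,
    stoich = list(c(TAG = -1, X = 24)),
    law = list(mass_action_law("k_TAGD", "TAG"))
  )
  m1 <- metabolic_model(mets, rxns,
                        params = c(k_TAGD = k_per_day / 24),
                        growth = growth_model(mu0 = 1e-6, mu_mature = 1e-7))
  e1 <- expression_input(
    tibble::tibble(enzyme = "none", stage = stage_grid()$stage, rel_mrna = 1))
  traj <- simulate_model(m1, e1, t_end_daf = 21)
  expect_equal(fa_turnover(traj, c(16, 19)), k_per_day, tolerance = 1e-3)
  expect_error(fa_turnover(traj, c(30, 31)), "outside")

  # and with oxidation off the turnover is zero
  traj0 <- simulate_model(m1, e1, k_scale = list(TAGD = 0), t_end_daf = 21)
  expect_equal(fa_turnover(traj0, c(16, 19)), 0)
})

test_that("trajectory accessors return aligned tidy tables", {
  traj <- ref_trajectory()
  st <- trajectory_states(traj)
  fl <- trajectory_fluxes(traj)
  expect_equal(nrow(st), length(traj$time_daf) * ncol(traj$states))
  expect_equal(nrow(fl), length(traj$time_daf) * ncol(traj$fluxes))
  expect_true(all(total_fa(traj)$total_fa >= 0))
  expect_equal(tag_oil(traj)$tag_oil,
               3 * traj$states[, "TAG"] + traj$states[, "FAE"])
})
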