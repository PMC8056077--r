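test_that("per-enzyme normalization scales summed gene intensities to the first stage", {
  stages <- as.character(stage_grid()$stage)
  expr <- tibble::tibble(gene = c("g1", "g2"))
  expr[stages] <- list(c(2000, 1000), c(4000, 1000), c(1000, 1000),
                       c(2000, 1000), c(500, 1000), c(250, 1000),
                       c(100, 1000))
  map <- tibble::tibble(gene = c("g1", "g2"), enzyme = c("HK", "HK"))

  prof <- normalize_mrna(expr, map)
  # sums: 3000, 5000, 2000, 3000, 1500, 1250, 1100 -> scaled by 3000
  expect_equal(prof$rel_mrna,
               c(3000, 5000, 2000, 3000, 1500, 1250, 1100) / 3000)
  expect_equal(prof$rel_mrna[1], 1)

  # single-gene case is plain scaling by the first value
  prof1 <- normalize_mrna(expr[1, ], map[1, ])
  expect_equal(prof1$rel_mrna[1:2], c(1, 2))
})

test_that("zero stage-1 sums trigger the pseudo-intensity guard with a warning", {
  stages <- as.character(stage_grid()$stage)
  expr <- tibble::tibble(gene = "g1")
  expr[stages] <- as.list(c(0, 10, 20, 10, 5, 2, 1))
  map <- tibble::tibble(gene = "g1", enzyme = "X")
  expect_warning(prof <- normalize_mrna(expr, map), "pseudo-intensity")
  expect_equal(prof$rel_mrna, (c(0, 10, 20, 10, 5, 2, 1) + 1) / 1)
  expect_error(normalize_mrna(dplyr::mutate(expr, zygote = -1), map),
               "nonnegative")
  expect_error(normalize_mrna(expr, tibble::tibble(gene = "gX", enzyme = "Y")),
               "no mapped gene")
})

test_that("ribosome signal is the normalized weighted intensity sum", {
  stages <- as.character(stage_grid()$stage)
  expr <- tibble::tibble(gene = c("r1", "r2", "r3"))
  expr[stages] <- list(c(5000, 3000, 100), c(5000, 3000, 100),
                       c(5000, 3000, 100), c(10000, 6000, 200),
                       c(5000, 3000, 100), c(5000, 3000, 100),
                       c(5000, 3000, 100))
  # constant profiles give a flat signal
  rb_flat <- ribosome_signal(expr[c(1, 1), ] |>
                               dplyr::mutate(gene = c("r1", "r2")),
                             c("r1", "r2"))
  expect_true(all(abs(rb_flat$rb[-4] - 1) < 1e-12))

  # doubling all intensities at stage 4 doubles the signal there
  rb <- ribosome_signal(expr, c("r1", "r2", "r3"))
  expect_equal(rb$rb[4], 2)
  expect_equal(rb$rb[1], 1)

  # hand-computed weighted sum on a 3-gene table with weights (1, 1, 0):
  # the low-expressed gene falls below the 2000 default threshold
  w_manual <- colSums(as.matrix(expr[1:2, stages]))
  expect_equal(rb$rb, unname(w_manual / w_manual[1]))
  expect_error(ribosome_signal(expr, character(0)), "nonempty")
})

test_that("turnover classes obey the synthesis/removal balance", {
  tc <- turnover_classes()
  expect_equal(tc$k_deg, c(0.03, 0.02, 0.01))
  expect_equal(tc$k_syn, tc$k_deg + 0.025)

  expect_equal(derive_rate_constants("fast", mu0 = 0.025)$k_syn, 0.055)
  expect_equal(derive_rate_constants("slow", mu0 = 0.025)$k_syn, 0.035)
  # a 23.1 h half-life lands in the fast class: k_deg = ln2 / t_half
  expect_equal(log(2) / 23.1, 0.03, tolerance = 0.01)
  expect_error(derive_rate_constants("nope"), "unknown turnover class")
})

test_that("stage interpolant matches knots, preserves bounds and rejects negative times", {
  f <- stage_interpolant(c(0, 24), c(1, 2))
  expect_equal(f(c(0, 24)), c(1, 2))
  expect_true(f(12) >= 1 && f(12) <= 2)
  expect_equal(f(100), 2)  # constant extrapolation
  expect_error(f(-1), "nonnegative")

  g <- stage_interpolant(c(0, 10, 20), c(3, 3, 3))
  expect_equal(g(seq(0, 25, by = 2.5)), rep(3, 11))

  # monotone method never overshoots below zero on nonnegative data
  h <- stage_interpolant(c(0, 5, 10, 15), c(0, 10, 0, 0))
  expect_true(all(h(seq(0, 15, by = 0.1)) >= 0))
})

test_that("enzyme ODE reaches the analytic steady state and scales linearly", {
  one <- function(t) rep(1, length(t))
  mu <- function(t) rep(0.025, length(t))

  tr <- simulate_enzyme(one, one, k_syn = 0.055, k_deg = 0.03, mu_fn = mu,
                        t_end_hr = 400)
  # k_syn = k_deg + mu forces a unit steady state
  expect_equal(tr$level[nrow(tr)], 1, tolerance = 1e-3)

  # doubled mRNA doubles the trajectory (linearity)
  two <- function(t) rep(2, length(t))
  tr2 <- simulate_enzyme(two, one, 0.055, 0.03, mu, t_end_hr = 400)
  expect_equal(tr2$level, 2 * tr$level, tolerance = 1e-6)

  # zero mRNA: pure exponential decay from E0
  zero <- function(t) rep(0, length(t))
  tr0 <- simulate_enzyme(zero, one, 0.02 + 0.005, 0.02,
                         function(t) rep(0.005, length(t)),
                         t_end_hr = 100, e0 = 1)
  expect_equal(tr0$level, exp(-0.025 * tr0$time_hr), tolerance = 1e-5)

  # steady-state agreement within 0.1% once t_end >= 10 time constants
  for (cls in c("fast", "average", "slow")) {
    k <- derive_rate_constants(cls)
    t_end <- 10 / (k$k_deg + 0.025)
    tr <- simulate_enzyme(function(t) rep(1.7, length(t)), one,
                          k$k_syn, k$k_deg, mu, t_end_hr = t_end, e0 = 0.2)
    e_star <- k$k_syn * 1.7 / (k$k_deg + 0.025)
    expect_equal(tr$level[nrow(tr)], e_star, tolerance = 1e-3)
  }
})

test_that("faster turnover classes equilibrate earlier", {
  one <- function(t) rep(1, length(t))
  mu <- function(t) rep(0.025, length(t))
  t95 <- vapply(c("fast", "average", "slow"), function(cls) {
    k <- derive_rate_constants(cls)
    tr <- simulate_enzyme(one, one, k$k_syn, k$k_deg, mu,
                          t_end_hr = 600, e0 = 0, dt_hr = 0.5)
    tr$time_hr[which(tr$level >= 0.95)[1]]
  }, 0)
  expect_true(t95[["fast"]] < t95[["average"]])
  expect_true(t95[["average"]] < t95[["slow"]])
})
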