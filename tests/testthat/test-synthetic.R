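test_that("atlas generation is reproducible and structured as documented", {
  a1 <- generate_mrna_atlas(seed = 5)
  a2 <- generate_mrna_atlas(seed = 5)
  expect_identical(a1$expression, a2$expression)
  expect_identical(a1$mapping, a2$mapping)

  # 1-3 genes per enzyme
  per <- table(a1$mapping$enzyme)
  expect_true(all(per >= 1 & per <= 3))
  expect_true(all(as.matrix(a1$expression[-1]) >= 0))

  # ribosomal block: ~200 genes with roughly 150 above the 2000 threshold
  expect_length(a1$ribosomal_genes, 200)
  rb <- a1$expression[a1$expression$gene %in% a1$ribosomal_genes, -1]
  n_hi <- sum(rowMeans(as.matrix(rb)) >= 2000)
  expect_gt(n_hi, 120)
  expect_lt(n_hi, 180)
})

test_that("the oil-window shape peaks inside 7-14 DAF and flat shapes normalize to one", {
  grid <- stage_grid()
  shp <- as.numeric(seedfa:::shape_values("mid_peak"))
  f <- stage_interpolant(grid$time_hr, shp)
  tq <- seq(0, 21 * 24, by = 1)
  expect_true(tq[which.max(f(tq))] / 24 >= 7)
  expect_true(tq[which.max(f(tq))] / 24 <= 14)

  asg <- tibble::tibble(enzyme = "E1", shape = "flat")
  a <- generate_mrna_atlas(seed = 1, assignment = asg, noise_cv = 1e-12,
                           n_ribosomal = 1)
  map <- a$mapping
  prof <- normalize_mrna(a$expression[a$expression$gene %in% map$gene, ], map)
  expect_equal(prof$rel_mrna, rep(1, 7), tolerance = 1e-6)

  expect_error(generate_mrna_atlas(1, tibble::tibble(enzyme = "E", shape = "zig")),
               "unknown shape")
})

test_that("observation noise has the configured replicate structure", {
  traj <- simulate_model(fix_model(), fix_expression(), t_end_daf = 21)

  # zero noise reproduces the truth at the stage times
  obs0 <- generate_observations(traj, observables = c("A", "P"), cv = 0,
                                replicates = 4, seed = 3)
  expect_equal(nrow(obs0), 2 * 7 * 4)  # default replicate count is 4
  means <- obs0 |>
    dplyr::group_by(observable, time_daf) |>
    dplyr::summarise(v = mean(value), s = stats::sd(value), .groups = "drop")
  expect_true(all(means$s == 0))

  # multiplicative log-normal noise: empirical replicate CV near the target
  # for the large majority of observable x time cells (Monte Carlo check
  # with many replicates)
  obs <- generate_observations(traj, observables = c("A", "B", "P"),
                               cv = 0.15, replicates = 1000, seed = 11)
  cvs <- obs |>
    dplyr::filter(value > 0) |>
    dplyr::group_by(observable, time_daf) |>
    dplyr::summarise(cv = stats::sd(value) / mean(value), .groups = "drop")
  expect_true(mean(cvs$cv > 0.05 & cvs$cv < 0.30) >= 0.9)
  expect_true(all(obs$value >= 0))
})

test_that("the fixture network validates and matches an explicit Euler integration", {
  m <- fix_model()
  expect_silent(validate_model(m))
  expect_equal(nrow(m$metabolites), 8)
  expect_equal(nrow(m$reactions), 10)

  # independent integrator oracle: explicit Euler at dt = 1e-3 h
  e <- fix_expression()
  t_end <- 120
  traj <- simulate_model(m, e, t_end_daf = t_end / 24, dt_out_daf = 0.5 / 24)
  flux_fn <- seedfa:::compile_network(m)
  S <- stoich_matrix(m)
  dil <- m$metabolites$dilute * 1.0
  ext <- which(m$metabolites$external)
  g <- m$growth
  M <- m$metabolites$initial
  dt <- 1e-3
  E <- rep(1, nrow(m$reactions))
  for (i in seq_len(t_end / dt)) {
    t <- (i - 1) * dt
    mu <- growth_curve(g, t)$mu
    v <- flux_fn(pmax(M, 0), E, mu, 1, rep(1, nrow(m$reactions)))
    dM <- as.vector(S %*% v) - mu * (dil * pmax(M, 0))
    dM[ext] <- 0
    M <- M + dt * dM
  }
  stiff <- traj$states[nrow(traj$states), ]
  expect_lt(max(abs(M - stiff) / pmax(abs(stiff), 1e-6)), 0.005)
})

test_that("with saturating substrate the chain flux approaches the limiting step", {
  m <- fix_model()
  # saturate every Michaelis-Menten term and lift the feedback
  p <- m$params
  p[["Ki_R2_P"]] <- 1e6
  state <- stats::setNames(rep(100, 8), m$metabolites$id)
  caps <- vapply(c("UP", "R2", "R3", "R4"), function(id) {
    eval_flux(m, id, state, enzyme_level = 1, params = p)
  }, 0)
  # every step saturates at its k (E = 1), so the least k limits the chain
  ks <- m$params[c("k_UP", "k_R2", "k_R3", "k_R4")]
  expect_equal(unname(caps), unname(ks), tolerance = 0.01)
})

test_that("the pipeline closes: atlas to fit recovers fixture parameters", {
  # atlas -> normalized profiles -> simulate -> observe -> fit, noiseless
  m <- fix_model()
  asg <- tibble::tibble(enzyme = unique(stats::na.omit(m$reactions$enzyme)),
                        shape = "flat")
  atlas <- generate_mrna_atlas(seed = 2, assignment = asg, noise_cv = 1e-9,
                               n_ribosomal = 10)
  profiles <- normalize_mrna(atlas$expression, atlas$mapping)
  e <- expression_input(profiles)
  truth <- simulate_model(m, e, t_end_daf = 21)
  targets <- generate_observations(truth, observables = c("A", "B", "P"),
                                   cv = 0, replicates = 1, seed = 1)
  start <- m$params
  start[["k_UP"]] <- m$params[["k_UP"]] * 1.4
  fit <- fit_model(m, e, targets, free = "k_UP", start = start,
                   starts = 1, maxit = 40)
  expect_lt(abs(fit$params[["k_UP"]] / m$params[["k_UP"]] - 1), 0.01)
})
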