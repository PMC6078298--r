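test_that("vectorization is a linear Gaussian quadrature of the peak list", {
  cl1 <- centroid_list(2165, 1)
  v1 <- vectorize_envelope(cl1, c(2160, 2170), n = 500, sigma = 0.5)
  step <- attr(v1, "step")
  expect_length(v1, 500)
  expect_equal(sum(v1) * step, 1, tolerance = 1e-6)
  cl2 <- centroid_list(2167, 2)
  v2 <- vectorize_envelope(cl2, c(2160, 2170), n = 500, sigma = 0.5)
  both <- vectorize_envelope(centroid_list(c(2165, 2167), c(1, 2)),
                             c(2160, 2170), n = 500, sigma = 0.5)
  expect_equal(both, v1 + v2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(vectorize_envelope(centroid_list(2200, 1), c(2160, 2170),
                                    sigma = 0.5), "outside")
})

test_that("the fraction-0 family member vectorizes to the natural envelope", {
  nat <- wt_natural()
  fam <- build_family(nat, 29, grid = 20)
  rng <- range(nat$mass) + c(-5, 35)
  A <- family_design_matrix(fam, rng, n = 400, sigma = 1.5)
  v_nat <- vectorize_envelope(nat, rng, n = 400, sigma = 1.5)
  expect_equal(A[, 1], v_nat / sum(v_nat), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colSums(A), rep(1, 20), tolerance = 1e-12)
  expect_true(all(A >= 0))
})

test_that("Gold updates preserve non-negativity and recover pure states", {
  nat <- wt_natural()
  fam <- build_family(nat, 29, grid = 50)
  rng <- range(nat$mass) + c(-5, 35)
  A <- family_design_matrix(fam, rng, n = 300, sigma = 1.5)
  for (k in c(1, 17, 50)) {
    sol <- gold_deconvolve(A[, k], A, iterations = 2000, boosts = 20)
    expect_true(all(sol$weights >= 0))
    # >= 99% of the weight on member k or its bracketing neighbors
    near <- max(1, k - 1):min(50, k + 1)
    expect_gte(sum(sol$weights[near]) / sum(sol$weights), 0.99)
  }
  expect_error(gold_deconvolve(numeric(300), A), "all zero")
  expect_error(gold_deconvolve(-A[, 1], A), "non-negative")
})

test_that("residual norm is non-increasing over boost blocks on noiseless input", {
  nat <- wt_natural()
  fam <- build_family(nat, 29, grid = 40)
  rng <- range(nat$mass) + c(-5, 35)
  A <- family_design_matrix(fam, rng, n = 300, sigma = 1.5)
  y <- 0.5 * A[, 8] + 0.5 * A[, 30]
  res <- vapply(c(200, 1000, 5000), function(it)
    gold_deconvolve(y, A, iterations = it, boosts = max(1, it / 100),
                    tol = 0)$residual_norm, numeric(1))
  expect_true(all(diff(res) <= 1e-9))
})

test_that("boosted Gold agrees with the non-negative least-squares oracle on small systems", {
  nat <- wt_natural()
  fam <- build_family(nat, 29, grid = 18)
  rng <- range(nat$mass) + c(-5, 35)
  A <- family_design_matrix(fam, rng, n = 300, sigma = 1.5)
  grid_res <- diff(fam$uptakes)[1]
  cases <- list(c(j = 4L, k = 14L), c(j = 2L, k = 10L), c(j = 6L, k = 17L))
  for (cs in cases) {
    y <- 0.5 * A[, cs["j"]] + 0.5 * A[, cs["k"]]
    gold <- merge_components(gold_deconvolve(y, A, iterations = 5000,
                                             boosts = 50)$weights, fam)
    nn <- pracma::lsqnonneg(A, y)$x
    oracle <- merge_components(nn, fam)
    expect_equal(nrow(gold), nrow(oracle))
    expect_equal(gold$uptake, oracle$uptake, tolerance = grid_res)
    expect_equal(gold$weight, oracle$weight, tolerance = 0.05)
    expect_equal(gold$weight, c(0.5, 0.5), tolerance = 0.05)
  }
})

test_that("noiseless three-component mixtures are recovered against ground truth", {
  nat <- wt_natural()
  fam <- build_family(nat, 29, grid = 200)
  rng <- range(nat$mass) + c(-5, 35)
  A <- family_design_matrix(fam, rng, n = 500, sigma = 1.5)
  truth_idx <- c(30, 90, 170)
  truth_w <- c(0.2, 0.3, 0.5)
  y <- as.numeric(A[, truth_idx] %*% truth_w)
  comp <- merge_components(gold_deconvolve(y, A)$weights, fam)
  expect_equal(nrow(comp), 3)
  expect_equal(comp$uptake, fam$uptakes[truth_idx], tolerance = 1)
  expect_equal(comp$weight, truth_w, tolerance = 0.05)
  # NNLS oracle sees the same components
  nn <- merge_components(pracma::lsqnonneg(A, y)$x, fam)
  expect_equal(nrow(nn), 3)
  expect_equal(nn$uptake, fam$uptakes[truth_idx], tolerance = 1)
})

test_that("neighbor merging interpolates uptake linearly and thresholds weights", {
  up <- c(9.4, 9.8, 10.2, 14, 18)
  w <- c(0, 0.5, 0.5, 0, 0)
  comp <- merge_components(w, up)
  expect_equal(nrow(comp), 1)
  expect_equal(comp$uptake, 10.0)
  expect_equal(comp$weight, 1.0)
  # single non-zero member reports that member's uptake
  comp1 <- merge_components(c(0, 0, 1, 0, 0), up)
  expect_equal(comp1$uptake, 10.2)
  # sub-threshold weights vanish; four isolated clusters stay four
  w4 <- c(0.3, 0, 0.002, 0, 0.3, 0, 0.2, 0, 0.198)
  comp4 <- merge_components(w4, seq(2, 18, by = 2), min_weight = 0.01)
  expect_equal(nrow(comp4), 4)
  expect_equal(sum(comp4$weight), 1, tolerance = 1e-12)
  # all-below-threshold input degrades to one flagged component
  tiny <- merge_components(c(1e-9, 1e-9), c(5, 15), min_weight = 0.6)
  expect_equal(nrow(tiny), 1)
  expect_true(attr(tiny, "low_confidence"))
  expect_equal(tiny$uptake, 10)
})

test_that("deuterated = control deconvolves to a single component at 0 D", {
  sim <- simulate_spectrum(mon2_scenario(c(10), c(1), flow_scaling = 0,
                                         seed = 41))
  cl <- centroid_spectrum(sim$spectrum)
  fit <- deconvolve_envelope(cl, cl, MON2, peptide = ABETA40_WT,
                             iterations = 3000, boosts = 30)
  expect_equal(nrow(fit$components), 1)
  expect_equal(fit$components$uptake, 0, tolerance = 0.2)
})

test_that("a single-state dimer envelope yields one component", {
  n_sites <- total_exchangeable(oligomer_ion(2, 4), 27)
  cfg <- scenario_config(species = list(scenario_species(oligomer_ion(2, 4),
    conformers = list(scenario_conformer(20 / n_sites, 1)))),
    flow_scaling = 1, noise_sigma = 0.002, seed = 43)
  cfg0 <- scenario_config(species = cfg$species, flow_scaling = 0,
                          noise_sigma = 0.002, seed = 44)
  deut <- centroid_spectrum(smooth_spectrum(simulate_spectrum(cfg)$spectrum))
  ctrl <- centroid_spectrum(smooth_spectrum(simulate_spectrum(cfg0)$spectrum))
  fit <- deconvolve_envelope(ctrl, deut, oligomer_ion(2, 4),
                             peptide = ABETA40_WT)
  expect_equal(nrow(fit$components), 1)
  expect_equal(fit$components$uptake, 10, tolerance = 1)
})

test_that("the monomer mixture at 4/10/18/28 D is recovered within 1 D", {
  r <- mon2_fit(c(4, 10, 18, 28), c(0.3, 0.3, 0.2, 0.2), seed = 45)
  expect_equal(nrow(r$fit$components), 4)
  expect_equal(r$fit$components$uptake, c(4, 10, 18, 28), tolerance = 1)
  expect_equal(r$fit$components$weight, c(0.3, 0.3, 0.2, 0.2),
               tolerance = 0.05)
})

test_that("a heterogeneous-rate single state is never split into several components", {
  # Poisson-binomial deuteration (site probabilities spread around the
  # mean) is narrower than the equal-probability model, so the fit must
  # report exactly one state
  nat <- wt_natural()
  n_sites <- 29
  set.seed(46)
  for (rep_i in 1:3) {
    pbar <- runif(1, 0.3, 0.7)
    p <- pmin(1, pmax(0, pbar + runif(n_sites, -0.25, 0.25)))
    pmf <- poisson_binomial_pmf(p)
    # forward-construct the deuterated envelope independent of single_state()
    mass <- as.vector(outer(nat$mass, (0:n_sites) * DELTA_MASS_D, `+`))
    prob <- as.vector(outer(nat$prob, pmf))
    mz <- (mass + 2 * PROTON_MASS) / 2
    grid <- seq(min(mz) - 1, max(mz) + 1, by = 0.005)
    y <- numeric(length(grid))
    for (i in seq_along(mz))
      y <- y + prob[i] * dnorm(grid, mz[i], 0.02)
    deut <- centroid_spectrum(new_spectrum(grid, y))
    ctrl_sim <- simulate_spectrum(mon2_scenario(10, 1, flow_scaling = 0,
                                                seed = 100 + rep_i))
    ctrl <- centroid_spectrum(ctrl_sim$spectrum)
    fit <- deconvolve_envelope(ctrl, deut, MON2, peptide = ABETA40_WT)
    expect_equal(nrow(fit$components), 1)
    expect_equal(fit$components$uptake, sum(p), tolerance = 1)
  }
})

test_that("fit accessors expose weights, fitted values and residuals coherently", {
  r <- mon2_fit(c(6, 20), c(0.5, 0.5), seed = 47, iterations = 4000,
                boosts = 40)
  fit <- r$fit
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$components$uptake) > 0))
  expect_equal(length(coef(fit)), nrow(fit$components))
  expect_equal(fitted(fit) + residuals(fit), fit$y, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_lt(fit$residual_norm, 0.1)
  s <- summary(fit)
  expect_equal(s$mean_uptake, 13, tolerance = 0.5)
  expect_output(print(fit), "component")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deconvolution(fit, f, sample = "wt")
  expect_named(read.delim(f),
               c("sample", "ion", "uptake_D_per_monomer", "weight",
                 "residual_norm"))
})
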