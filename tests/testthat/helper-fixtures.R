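# Shared builders for synthetic test scenarios. Everything is generated
# in code from fixed seeds; nothing is read from disk except what the
# tests themselves write.

MON2 <- oligomer_ion(1, 2)

wt_natural <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- natural_isotope_distribution(peptide_composition(ABETA40_WT))
    memo
  }
})

# monomer 2+ scenario with given per-monomer uptakes (D) and weights
mon2_scenario <- function(uptakes, weights, noise_sigma = 0.002, seed = 1,
                          flow_scaling = 1, mz_range = NULL) {
  n_sites <- total_exchangeable(MON2, 27)
  scenario_config(species = list(scenario_species(MON2,
    conformers = Map(scenario_conformer, uptakes / n_sites, weights))),
    flow_scaling = flow_scaling, noise_sigma = noise_sigma, seed = seed,
    mz_range = mz_range)
}

# simulate, preprocess and deconvolve a monomer-2+ mixture; returns the fit
mon2_fit <- function(uptakes, weights, seed = 1, noise_sigma = 0.002, ...) {
  sim_d <- simulate_spectrum(mon2_scenario(uptakes, weights,
                                           noise_sigma = noise_sigma,
                                           seed = seed))
  sim_c <- simulate_spectrum(mon2_scenario(uptakes, weights,
                                           noise_sigma = noise_sigma,
                                           seed = seed + 5000L,
                                           flow_scaling = 0))
  ctrl <- centroid_spectrum(smooth_spectrum(sim_c$spectrum))
  deut <- centroid_spectrum(smooth_spectrum(sim_d$spectrum))
  list(fit = deconvolve_envelope(ctrl, deut, MON2, peptide = ABETA40_WT, ...),
       truth = sim_d$truth, control = ctrl, deuterated = deut)
}

# random well-separated mixture on the monomer 2+ ion (parameter-recovery
# study conditions: 2-4 components, >= 3 D separation, noise 1/500 of max)
random_mixture <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  repeat {
    u <- sort(runif(k, 1, 27))
    if (k == 1 || min(diff(u)) >= 3.5) break
  }
  w <- runif(k, 1, 3)
  w <- w / sum(w)
  list(uptakes = u, weights = w, k = k)
}

# Poisson-binomial count distribution by sequential Bernoulli convolution
poisson_binomial_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}
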