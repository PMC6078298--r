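test_that("charge density follows the charge / n_monomers rule", {
  expect_equal(charge_per_monomer(oligomer_ion(2, 7)), 3.5)
  expect_equal(round(charge_per_monomer(oligomer_ion(6, 7)), 2), 1.17)
  for (n in 1:6) expect_equal(charge_per_monomer(oligomer_ion(n, 2 * n)), 2)
})

test_that("the 2164-2169 window contains exactly the charge-density-2 family", {
  m <- average_mass(peptide_composition(ABETA40_WT))
  fam <- isobar_family(m, c(2164, 2169), n_max = 4, z_max = 8)
  got <- vapply(fam$members, function(i) sprintf("%d/%d", i$n_monomers, i$charge), "")
  expect_identical(got, c("1/2", "2/4", "3/6", "4/8"))
  expect_equal(fam$cpm, 2)
  # raising n_max adds only the higher multiples of the same density
  fam8 <- isobar_family(m, c(2164, 2169), n_max = 8, z_max = 16)
  got8 <- vapply(fam8$members, function(i) sprintf("%d/%d", i$n_monomers, i$charge), "")
  expect_identical(got8, sprintf("%d/%d", 1:8, 2 * (1:8)))
  # empty window far from any signal
  expect_length(isobar_family(m, c(900, 905), 4, 8)$members, 0)
})

test_that("isobar families are closed under scaling (n, z) -> (cn, cz)", {
  m <- average_mass(peptide_composition(ABETA40_WT))
  fam <- isobar_family(m, c(2164, 2169), n_max = 6, z_max = 12)
  key <- vapply(fam$members, function(i) sprintf("%d/%d", i$n_monomers, i$charge), "")
  for (ion in fam$members) for (c_ in 2:3) {
    n2 <- ion$n_monomers * c_; z2 <- ion$charge * c_
    if (n2 <= 6 && z2 <= 12)
      expect_true(sprintf("%d/%d", n2, z2) %in% key)
  }
})

test_that("charge is inferred from isotope spacing", {
  m0 <- 2165.0
  mk_comb <- function(z, n = 6, area = 1)
    list(pos = m0 + (0:(n - 1)) * ISOTOPE_SPACING / z,
         area = area * dnorm(0:(n - 1), 2, 2))
  c2 <- mk_comb(2)
  r2 <- infer_charge_from_spacing(centroid_list(c2$pos, c2$area))
  expect_identical(r2$charge, 2L)
  expect_false(r2$mixed)
  c6 <- mk_comb(6)
  r6 <- infer_charge_from_spacing(centroid_list(c6$pos, c6$area))
  expect_identical(r6$charge, 6L)
  expect_gt(r6$confidence, 0.8)
  # irregular spacing is unassignable
  set.seed(7)
  bad <- centroid_list(m0 + cumsum(runif(6, 0.2, 0.8)), rep(1, 6))
  expect_true(is.na(infer_charge_from_spacing(bad)$charge))
  expect_error(infer_charge_from_spacing(centroid_list(c(1, 2), c(1, 1))),
               "at least 3")
})

test_that("spacing inference inverts the generator charge at SNR >= 20", {
  set.seed(8)
  n_ok <- 0L; n_trials <- 20L
  for (t in seq_len(n_trials)) {
    z <- sample(1:8, 1)
    cfg <- scenario_config(species = list(scenario_species(oligomer_ion(1, z),
      conformers = list(scenario_conformer(0.3, 1)))),
      flow_scaling = 1, noise_sigma = 0.01, peak_sigma = 0.01,
      seed = 1000 + t)
    sim <- simulate_spectrum(cfg)
    cl <- centroid_spectrum(smooth_spectrum(sim$spectrum), min_rel_height = 0.05)
    r <- infer_charge_from_spacing(cl)
    if (identical(r$charge, as.integer(z))) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_trials, 0.95)
})

test_that("overlapped combs report the dominant charge flagged as mixed", {
  m0 <- 2165.0
  pos2 <- m0 + (0:5) * ISOTOPE_SPACING / 2
  pos6 <- m0 + 0.08 + (0:11) * ISOTOPE_SPACING / 6
  pos <- c(pos2, pos6)
  area <- c(rep(1, 6), rep(3, 12))      # z = 6 dominates
  o <- order(pos)
  r <- infer_charge_from_spacing(centroid_list(pos[o], area[o]))
  expect_identical(r$charge, 6L)
  expect_true(r$mixed)
})

test_that("drift profiles conserve windowed intensity and detect bimodality", {
  mzs <- rep(seq(2164, 2166, by = 0.1), times = 61)
  drs <- rep(seq(2, 14, by = 0.2), each = 21)
  int <- dnorm(drs, 5, 0.5) * 0.6 + dnorm(drs, 8, 0.5) * 0.4
  map <- drift_map(mzs, drs, int)
  prof <- drift_profile(map, c(2164, 2166))
  expect_equal(sum(prof$intensity), sum(int))
  split <- detect_conformer_split(prof)
  expect_true(attr(split, "split"))
  expect_equal(split$drift, c(5, 8), tolerance = 0.2)
  expect_equal(split$share, c(0.6, 0.4), tolerance = 0.05)
  expect_equal(sum(split$share), 1, tolerance = 1e-12)
  expect_identical(split$label, c("compact", "extended"))
  expect_error(drift_profile(map, c(3000, 3001)), "overlap")
})

test_that("unimodal drift profiles yield a single apex and no split flag", {
  drs <- seq(2, 14, by = 0.2)
  prof <- drift_profile(drift_map(rep(2165, length(drs)), drs,
                                  dnorm(drs, 6, 0.6)), c(2164, 2166))
  split <- detect_conformer_split(prof)
  expect_false(attr(split, "split"))
  expect_equal(nrow(split), 1)
  expect_equal(split$share, 1)
  expect_equal(split$drift, 6, tolerance = 0.2)
})

test_that("drift slices recover envelopes and programmed uptake differences", {
  cfg <- scenario_config(species = list(scenario_species(oligomer_ion(3, 6),
    conformers = list(
      scenario_conformer(18 / 87, 0.6, drift_apex = 5, drift_width = 0.5),
      scenario_conformer(30 / 87, 0.4, drift_apex = 8, drift_width = 0.5)))),
    flow_scaling = 1, noise_sigma = 0.001, seed = 51)
  sim <- simulate_drift_map(cfg)
  s5 <- slice_envelope_at_drift(sim$map, 5, 0.5)
  s8 <- slice_envelope_at_drift(sim$map, 8, 0.5)
  c5 <- centroid_spectrum(s5, min_rel_height = 0.02)
  c8 <- centroid_spectrum(s8, min_rel_height = 0.02)
  ion <- oligomer_ion(3, 6)
  d_mz <- weighted_centroid(c8) - weighted_centroid(c5)
  # programmed 4 D/monomer difference between extended and compact
  expect_equal(d_mz * 6 / (3 * DELTA_MASS_D), 4, tolerance = 0.3)
  # zero half-width takes the nearest drift bin column, same shape
  col <- slice_envelope_at_drift(sim$map, 5.01, 0)
  expect_equal(weighted_centroid(centroid_spectrum(col, min_rel_height = 0.02)),
               weighted_centroid(c5), tolerance = 0.01)
  expect_error(slice_envelope_at_drift(sim$map, 99, 0.5), "drift range")
})

test_that("assignment reports tabulate family, density and split results", {
  m <- average_mass(peptide_composition(ABETA40_WT))
  fam <- isobar_family(m, c(2164, 2169), 4, 8)
  drs <- seq(2, 14, by = 0.2)
  prof <- drift_profile(drift_map(rep(2165, length(drs)), drs,
                                  dnorm(drs, 5, 0.5) + dnorm(drs, 8, 0.5)),
                        c(2164, 2166))
  split <- detect_conformer_split(prof)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- assignment_report(fam, split, path = f)
  expect_equal(nrow(df), 4)
  expect_equal(df$cpm, rep(2, 4))
  expect_true(all(df$split))
  expect_true(file.exists(f))
})
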