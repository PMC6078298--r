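test_that("sequence parsing accepts canonical residues and rejects others", {
  p <- parse_sequence(ABETA40_WT)
  expect_s3_class(p, "peptide_spec")
  expect_length(p$residues, 40)
  expect_identical(parse_sequence("G")$sequence, "G")
  expect_identical(parse_sequence(" d a e f ")$sequence, "DAEF")
  expect_error(parse_sequence("DAEFBX"), "position 5")
  expect_error(parse_sequence(""), "empty")
})

test_that("FASTA input yields the same peptide as the raw string", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">wt", substr(ABETA40_WT, 1, 20), substr(ABETA40_WT, 21, 40)), f)
  expect_identical(parse_sequence(f, fasta = TRUE)$sequence, ABETA40_WT)
})

test_that("peptide composition follows the condensation rule", {
  g <- peptide_composition("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O")], c(C = 2, H = 5, N = 1, O = 2))
  gg <- peptide_composition("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O")], c(C = 4, H = 8, N = 2, O = 3))
  # sum of free amino acids minus one water
  expect_equal(unclass(gg), unclass(g) + unclass(g) -
                 c(C = 0, H = 2, N = 0, O = 1, S = 0))
})

test_that("masses of water and carbon-bearing compositions are correct", {
  h2o <- elemental_composition(H = 2, O = 1)
  expect_equal(average_mass(h2o), 18.015, tolerance = 0.001)
  expect_equal(monoisotopic_mass(h2o), 18.0106, tolerance = 0.0005)
  for (s in c("G", "YGGFL", ABETA40_WT)) {
    comp <- peptide_composition(s)
    expect_lt(monoisotopic_mass(comp), average_mass(comp))
  }
  expect_error(average_mass(c(Zz = 1)), "unknown")
})

test_that("single-element isotope envelopes match the natural table", {
  h <- natural_isotope_distribution(elemental_composition(H = 1), prune = 0)
  expect_length(h$mass, 2)
  expect_equal(h$prob[1] / h$prob[2], 0.999885 / 0.000115, tolerance = 1e-9)
  c1 <- natural_isotope_distribution(elemental_composition(C = 1), prune = 0)
  expect_equal(c1$prob[1] / c1$prob[2], 98.93 / 1.07, tolerance = 1e-6)
})

test_that("isotope distributions normalize and their mean matches the per-element moment oracle", {
  for (s in c("G", "YGGFL", "DAEFRHDSGYEVHHQK", ABETA40_WT)) {
    comp <- peptide_composition(s)
    d <- natural_isotope_distribution(comp)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(diff(d$mass) > 0))
    # independent oracle: abundance-weighted per-element first moments
    expect_equal(distribution_mean(d), average_mass(comp), tolerance = 0.01)
  }
})

test_that("m/z arithmetic obeys the proton-adduct formula and isobar identity", {
  expect_equal(ion_mz(1000, oligomer_ion(1, 1)), 1001.007276)
  M <- 4329.8
  expect_equal(ion_mz(M, oligomer_ion(2, 4)), ion_mz(M, oligomer_ion(1, 2)))
  # isobar identity under (n, z) -> (c n, c z)
  for (c_ in 2:4)
    expect_equal(ion_mz(M, oligomer_ion(3 * c_, 6 * c_)),
                 ion_mz(M, oligomer_ion(3, 6)))
  # adjacent isotopes of a 3-mer 6+ (1 Da apart in oligomer mass) are 1/6
  # m/z units apart
  expect_equal(ion_mz(M + ISOTOPE_SPACING / 3, oligomer_ion(3, 6)) -
                 ion_mz(M, oligomer_ion(3, 6)),
               ISOTOPE_SPACING / 6, tolerance = 1e-9)
  expect_error(oligomer_ion(1, 0), "charge")
})

test_that("WT amyloid-beta 1-40 [M+2H]2+ lands inside the 2164-2169 window", {
  m <- average_mass(peptide_composition(ABETA40_WT))
  mz2 <- ion_mz(m, oligomer_ion(1, 2))
  expect_gt(mz2, 2164)
  expect_lt(mz2, 2169)
})

test_that("exchangeable-proton accounting reproduces the region totals", {
  expect_identical(exchangeable_protons(ABETA40_WT), 27L)
  expect_identical(exchangeable_protons(ABETA40_WT, c(1, 16)), 19L)
  expect_identical(exchangeable_protons(ABETA40_WT, c(17, 40)), 8L)
  expect_error(exchangeable_protons(ABETA40_WT, c(0, 10)), "out of bounds")
  expect_error(exchangeable_protons(ABETA40_WT, c(20, 10)), "out of bounds")
})

test_that("exchangeable counts are additive over any partition of the sequence", {
  for (k in c(1, 5, 16, 25, 39)) {
    expect_identical(exchangeable_protons(ABETA40_WT, c(1, k)) +
                       exchangeable_protons(ABETA40_WT, c(k + 1, 40)),
                     exchangeable_protons(ABETA40_WT))
  }
})

test_that("charging protons add to the exchangeable total", {
  expect_identical(total_exchangeable(oligomer_ion(1, 5), 27), 32L)
  expect_identical(total_exchangeable(oligomer_ion(2, 4), 27), 58L)
  expect_identical(total_exchangeable(oligomer_ion(3, 6), 27), 87L)
})

test_that("exchange table round-trips through YAML and JSON configs", {
  tab <- default_exchange_table()
  expect_identical(sum(tab[strsplit(ABETA40_WT, "")[[1]]]) +
                     tab[["n_term"]] + tab[["c_term"]], 27L)
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(H = 2L, n_term = 3L), fy)
  tab2 <- read_exchange_table(fy)
  expect_identical(tab2[["H"]], 2L)
  expect_identical(tab2[["n_term"]], 3L)
  expect_identical(tab2[["R"]], tab[["R"]])
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(H = 2L), fj, auto_unbox = TRUE)
  expect_identical(read_exchange_table(fj)[["H"]], 2L)
  writeLines("ZZ: 1", fy)
  expect_error(read_exchange_table(fy), "unknown")
})

test_that("synthetic scrambled stand-ins preserve composition and counts", {
  scr <- abeta_scrambles()
  for (s in scr) {
    expect_identical(sort(strsplit(s, "")[[1]]),
                     sort(strsplit(ABETA40_WT, "")[[1]]))
    expect_identical(exchangeable_protons(s), 27L)
    expect_equal(average_mass(peptide_composition(s)),
                 average_mass(peptide_composition(ABETA40_WT)))
  }
  expect_identical(substr(abeta_scrambles()$NSCR, 17, 40),
                   substr(ABETA40_WT, 17, 40))
})
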