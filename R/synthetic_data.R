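# Ground-truthed synthetic ESI spectra and 2D IM-MS maps.
#
# The forward model is exactly the structure the analysis assumes:
# overlapping oligomer/charge-state isotopic envelopes, each a mixture of
# conformers with distinct fractional deuterium uptake (binomial
# single-state model), Gaussian peak shapes in m/z, separable Gaussian
# drift-time profiles, and additive noise from a seeded RNG. It emulates
# the phenomenology of gentle native ESI of amyloid-beta oligomers; it
# does not model reagent collision kinetics, instrument transmission, or
# chemical noise.

.FLOW_SCALING <- c("20" = 0.4, "30" = 0.6, "40" = 0.8, "50" = 1.0)

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' One conformer of a simulated species
#'
#' @param fraction per-site exchange probability in \[0, 1\] (before flow
#'   scaling).
#' @param weight conformer population weight; weights of one species must
#'   sum to 1.
#' @param drift_apex,drift_width Gaussian drift-time profile parameters in
#'   ms (needed only for drift-map simulation).
#' @export
scenario_conformer <- function(fraction, weight, drift_apex = NA_real_,
                               drift_width = NA_real_) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  if (weight <= 0) stop("weight must be positive")
  list(fraction = fraction, weight = weight,
       drift_apex = drift_apex, drift_width = drift_width)
}

#' One simulated oligomer ion species
#'
#' @param ion an `oligomer_ion`.
#' @param abundance relative species abundance (> 0).
#' @param conformers list of [scenario_conformer()]; weights must sum to 1.
#' @export
scenario_species <- function(ion, abundance = 1, conformers) {
  stopifnot(inherits(ion, "oligomer_ion"))
  if (abundance <= 0) stop("abundance must be positive")
  w <- vapply(conformers, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("conformer weights must sum to 1 (got ", sum(w), ")")
  list(ion = ion, abundance = abundance, conformers = conformers)
}

#' Simulation scenario configuration
#'
#' @param peptide sequence string or `peptide_spec` (default WT
#'   amyloid-beta 1-40).
#' @param species list of [scenario_species()].
#' @param peak_sigma Gaussian peak width (sd) in m/z units (default 0.02,
#'   resolving isotopes up to charge 8).
#' @param mz_step profile grid step in m/z (default 0.005).
#' @param mz_range optional length-2 m/z window; computed from the
#'   species envelopes when omitted.
#' @param noise_sigma additive Gaussian noise sd as a fraction of the
#'   maximum signal (default 0.005).
#' @param poisson also apply Poisson counting noise (default FALSE).
#' @param poisson_scale counts at the maximum signal when `poisson = TRUE`.
#' @param flow HDX reagent flow-rate label (20/30/40/50 mL/min), mapped
#'   to a multiplicative fraction scaling \{0.4, 0.6, 0.8, 1.0\}. Purely
#'   phenomenological, not a physical model.
#' @param flow_scaling explicit scaling override (0 gives an undeuterated
#'   control).
#' @param drift_step drift grid step in ms (drift maps).
#' @param drift_range optional length-2 drift window in ms.
#' @param seed RNG seed; all randomness flows through it.
#' @param exchange_table exchangeable-proton table.
#' @export
scenario_config <- function(peptide = ABETA40_WT, species,
                            peak_sigma = 0.02, mz_step = 0.005,
                            mz_range = NULL,
                            noise_sigma = 0.005, poisson = FALSE,
                            poisson_scale = 1e4,
                            flow = 50, flow_scaling = NULL,
                            drift_step = 0.2, drift_range = NULL,
                            seed = 1,
                            exchange_table = default_exchange_table()) {
  if (is.character(peptide)) peptide <- parse_sequence(peptide)
  if (!length(species)) stop("at least one species required")
  if (is.null(flow_scaling)) {
    key <- as.character(flow)
    if (!key %in% names(.FLOW_SCALING))
      stop("flow must be one of ", paste(names(.FLOW_SCALING), collapse = "/"),
           " mL/min (or give flow_scaling directly)")
    flow_scaling <- .FLOW_SCALING[[key]]
  }
  if (flow_scaling < 0 || flow_scaling > 1)
    stop("flow_scaling must lie in [0, 1]")
  if (peak_sigma <= 0 || mz_step <= 0) stop("peak_sigma and mz_step must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(peptide = peptide, species = species,
                 peak_sigma = peak_sigma, mz_step = mz_step,
                 mz_range = mz_range, noise_sigma = noise_sigma,
                 poisson = poisson, poisson_scale = poisson_scale,
                 flow = flow, flow_scaling = flow_scaling,
                 drift_step = drift_step, drift_range = drift_range,
                 seed = seed, exchange_table = exchange_table),
            class = "scenario_config")
}

# per-species deuterated envelopes in the m/z domain
.species_envelopes <- function(cfg) {
  per_monomer <- exchangeable_protons(cfg$peptide, table = cfg$exchange_table)
  comp1 <- peptide_composition(cfg$peptide)
  lapply(cfg$species, function(sp) {
    n <- sp$ion$n_monomers; z <- sp$ion$charge
    comp_n <- do.call(elemental_composition, as.list(unclass(comp1) * n))
    nat <- natural_isotope_distribution(comp_n)
    n_sites <- total_exchangeable(sp$ion, per_monomer)
    confs <- lapply(sp$conformers, function(cf) {
      f_eff <- cf$fraction * cfg$flow_scaling
      env <- single_state(nat, n_sites, f_eff, prune = 1e-8)$distribution
      list(mz = (env$mass + z * PROTON_MASS) / z,
           prob = env$prob,
           uptake_total = f_eff * n_sites,
           weight = cf$weight,
           drift_apex = cf$drift_apex, drift_width = cf$drift_width)
    })
    list(ion = sp$ion, abundance = sp$abundance, n_sites = n_sites,
         conformers = confs)
  })
}

.ground_truth <- function(cfg, envs) {
  rows <- do.call(rbind, lapply(seq_along(envs), function(i) {
    sp <- envs[[i]]
    do.call(rbind, lapply(sp$conformers, function(cf)
      data.frame(species = i,
                 ion = .ion_label(sp$ion),
                 n_monomers = sp$ion$n_monomers,
                 charge = sp$ion$charge,
                 n_sites = sp$n_sites,
                 abundance = sp$abundance,
                 weight = cf$weight,
                 uptake_total_D = cf$uptake_total,
                 uptake_D_per_monomer = cf$uptake_total / sp$ion$n_monomers,
                 drift_apex = cf$drift_apex,
                 drift_width = cf$drift_width)))
  }))
  attr(rows, "seed") <- cfg$seed
  attr(rows, "flow_scaling") <- cfg$flow_scaling
  rows
}

#' Simulate a 1D ESI spectrum with ground truth
#'
#' For every species and conformer the natural n-mer envelope is
#' convolved with the binomial deuteration model at
#' `fraction * flow_scaling`, placed at its m/z, rendered with Gaussian
#' peak shapes on a uniform grid, summed and degraded with seeded noise.
#'
#' @param cfg a [scenario_config()].
#' @return list with `spectrum` (an `ms_spectrum`) and `truth` (a
#'   data.frame of per-conformer uptakes, weights, drift parameters, with
#'   the seed recorded as an attribute).
#' @export
simulate_spectrum <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  envs <- .species_envelopes(cfg)
  all_mz <- unlist(lapply(envs, function(sp)
    unlist(lapply(sp$conformers, `[[`, "mz"))))
  rng <- if (is.null(cfg$mz_range))
    c(min(all_mz) - 1, max(all_mz) + 1) else cfg$mz_range
  grid <- seq(rng[1], rng[2], by = cfg$mz_step)
  signal <- numeric(length(grid))
  for (sp in envs) for (cf in sp$conformers) {
    amp <- sp$abundance * cf$weight
    keep <- cf$mz >= rng[1] - 4 * cfg$peak_sigma &
            cf$mz <= rng[2] + 4 * cfg$peak_sigma
    for (i in which(keep))
      signal <- signal + amp * cf$prob[i] * stats::dnorm(grid, cf$mz[i], cfg$peak_sigma)
  }
  spec <- .with_seed(cfg$seed, {
    y <- signal
    if (cfg$poisson && max(y) > 0)
      y <- stats::rpois(length(y), y / max(y) * cfg$poisson_scale) *
        max(y) / cfg$poisson_scale
    if (cfg$noise_sigma > 0)
      y <- y + stats::rnorm(length(y), 0, cfg$noise_sigma * max(signal))
    y[y < 0] <- 0
    y
  })
  list(spectrum = new_spectrum(grid, spec,
                               metadata = list(flow = cfg$flow,
                                               flow_scaling = cfg$flow_scaling,
                                               seed = cfg$seed,
                                               polarity = "positive")),
       truth = .ground_truth(cfg, envs))
}

#' Simulate a 2D IM-MS drift map with ground truth
#'
#' Each conformer contributes a separable product of its m/z envelope and
#' a Gaussian drift-time profile; compact (shorter-drift) and extended
#' (longer-drift) populations may carry distinct uptake fractions.
#'
#' @param cfg a [scenario_config()] whose conformers carry `drift_apex`
#'   and `drift_width`.
#' @return list with `map` (a `drift_map`) and `truth`.
#' @export
simulate_drift_map <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  envs <- .species_envelopes(cfg)
  for (sp in envs) for (cf in sp$conformers)
    if (!is.finite(cf$drift_apex) || !is.finite(cf$drift_width))
      stop("all conformers need drift_apex and drift_width for drift maps")
  all_mz <- unlist(lapply(envs, function(sp)
    unlist(lapply(sp$conformers, `[[`, "mz"))))
  rng <- if (is.null(cfg$mz_range))
    c(min(all_mz) - 1, max(all_mz) + 1) else cfg$mz_range
  apexes <- unlist(lapply(envs, function(sp)
    vapply(sp$conformers, `[[`, 0, "drift_apex")))
  widths <- unlist(lapply(envs, function(sp)
    vapply(sp$conformers, `[[`, 0, "drift_width")))
  drng <- if (is.null(cfg$drift_range))
    c(max(0, min(apexes - 4 * widths)), max(apexes + 4 * widths))
  else cfg$drift_range
  mz_grid <- seq(rng[1], rng[2], by = max(cfg$mz_step, 0.01))
  dr_grid <- seq(drng[1], drng[2], by = cfg$drift_step)
  M <- matrix(0, length(mz_grid), length(dr_grid))
  for (sp in envs) for (cf in sp$conformers) {
    amp <- sp$abundance * cf$weight
    prof_mz <- numeric(length(mz_grid))
    keep <- cf$mz >= rng[1] - 4 * cfg$peak_sigma &
            cf$mz <= rng[2] + 4 * cfg$peak_sigma
    for (i in which(keep))
      prof_mz <- prof_mz + cf$prob[i] * stats::dnorm(mz_grid, cf$mz[i], cfg$peak_sigma)
    prof_dr <- stats::dnorm(dr_grid, cf$drift_apex, cf$drift_width)
    M <- M + amp * outer(prof_mz, prof_dr)
  }
  M <- .with_seed(cfg$seed, {
    if (cfg$noise_sigma > 0)
      M <- M + matrix(stats::rnorm(length(M), 0, cfg$noise_sigma * max(M)),
                      nrow(M))
    M[M < 0] <- 0
    M
  })
  list(map = drift_map(rep(mz_grid, times = length(dr_grid)),
                       rep(dr_grid, each = length(mz_grid)),
                       as.vector(M)),
       truth = .ground_truth(cfg, envs))
}

# --- canonical fixtures ------------------------------------------------------

.fixture_scenarios <- function() {
  wt_mon <- function(flow_scaling, seed)
    scenario_config(species = list(scenario_species(
      oligomer_ion(1, 2), conformers = list(
        scenario_conformer(4 / 29, 0.30),
        scenario_conformer(10 / 29, 0.30),
        scenario_conformer(18 / 29, 0.20),
        scenario_conformer(28 / 29, 0.20)))),
      flow_scaling = flow_scaling, noise_sigma = 0.002, seed = seed)
  wt_dim <- function(flow_scaling, seed)
    scenario_config(species = list(scenario_species(
      oligomer_ion(2, 4), conformers = list(
        scenario_conformer(8 / 58, 0.40),
        scenario_conformer(18 / 58, 0.35),
        scenario_conformer(28 / 58, 0.25)))),
      flow_scaling = flow_scaling, noise_sigma = 0.002, seed = seed)
  tri_map <- function(flow_scaling, seed)
    scenario_config(species = list(scenario_species(
      oligomer_ion(3, 6), conformers = list(
        scenario_conformer(18 / 87, 0.60, drift_apex = 5, drift_width = 0.5),
        scenario_conformer(30 / 87, 0.40, drift_apex = 8, drift_width = 0.5)))),
      flow_scaling = flow_scaling, noise_sigma = 0.002, seed = seed)
  # fully scrambled variant: same composition as WT, single population,
  # no alternative conformer (synthetic scramble, see ?abeta_scrambles)
  scr_map <- function(flow_scaling, seed)
    scenario_config(peptide = abeta_scrambles()$SCR,
      species = list(scenario_species(
        oligomer_ion(3, 6), conformers = list(
          scenario_conformer(20 / 87, 1.0, drift_apex = 6, drift_width = 0.5)))),
      flow_scaling = flow_scaling, noise_sigma = 0.002, seed = seed)
  leu_enk <- function(flow_scaling, seed)
    scenario_config(peptide = "YGGFL",
      species = list(scenario_species(
        oligomer_ion(1, 1), conformers = list(
          scenario_conformer(0.8, 1.0)))),
      flow_scaling = flow_scaling, noise_sigma = 0.002, seed = seed)
  list(
    wt_monomer  = list(build = wt_mon,  kind = "spectrum", seed = 101L),
    wt_dimer    = list(build = wt_dim,  kind = "spectrum", seed = 102L),
    wt_trimer_im = list(build = tri_map, kind = "map",     seed = 103L),
    scr_trimer_im = list(build = scr_map, kind = "map",    seed = 104L),
    leu_enk_control = list(build = leu_enk, kind = "spectrum", seed = 105L))
}

#' Write the canonical synthetic test fixtures
#'
#' Generates the bundled scenarios — WT-like monomer (components at
#' 4/10/18/28 D), WT-like dimer (4/9/14 D per monomer), trimer
#' compact/extended drift map, fully-scrambled-like single-population
#' map, and a small unimodal Leu-enkephalin-style control — each as a
#' deuterated/control file pair plus a JSON ground-truth manifest. All
#' seeds are fixed: regeneration is byte-identical.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, a data.frame listing scenario, kind and files.
#' @export
fixture_suite <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scen <- .fixture_scenarios()
  rows <- lapply(names(scen), function(nm) {
    sc <- scen[[nm]]
    cfg_d <- sc$build(1.0, sc$seed)
    cfg_c <- sc$build(0.0, sc$seed + 1000L)
    if (sc$kind == "spectrum") {
      sim_d <- simulate_spectrum(cfg_d); sim_c <- simulate_spectrum(cfg_c)
      fd <- file.path(dir, paste0(nm, "_deut.xy"))
      fc <- file.path(dir, paste0(nm, "_control.xy"))
      write_spectrum_xy(sim_d$spectrum, fd)
      write_spectrum_xy(sim_c$spectrum, fc)
    } else {
      sim_d <- simulate_drift_map(cfg_d); sim_c <- simulate_drift_map(cfg_c)
      fd <- file.path(dir, paste0(nm, "_deut.imms"))
      fc <- file.path(dir, paste0(nm, "_control.imms"))
      write_drift_map(sim_d$map, fd)
      write_drift_map(sim_c$map, fc)
    }
    manifest <- file.path(dir, paste0(nm, "_manifest.json"))
    jsonlite::write_json(
      list(scenario = nm, kind = sc$kind, seed = sc$seed,
           deuterated = basename(fd), control = basename(fc),
           truth = sim_d$truth),
      manifest, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    data.frame(scenario = nm, kind = sc$kind,
               deuterated = fd, control = fc, manifest = manifest)
  })
  invisible(do.call(rbind, rows))
}

#' Synthetic scrambled-sequence stand-ins for the NSCR and SCR variants
#'
#' Fixed, documented permutations of the WT amyloid-beta 1-40 sequence:
#' `NSCR` permutes only residues 1-16, `SCR` permutes the full sequence.
#' These are synthetic stand-ins — the genuine variant sequences are not
#' reproduced here — but every in-scope quantity (elemental composition,
#' masses, envelopes, exchangeable-proton counts) is permutation
#' invariant, so they behave identically to the real variants in this
#' pipeline.
#'
#' @return list with character elements `NSCR` and `SCR`.
#' @export
abeta_scrambles <- function() {
  wt <- strsplit(ABETA40_WT, "")[[1]]
  perm16 <- c(9L, 4L, 14L, 1L, 12L, 7L, 16L, 3L, 10L, 5L, 15L, 2L, 8L, 13L, 6L, 11L)
  nscr <- wt; nscr[1:16] <- wt[perm16]
  perm40 <- c(23L, 7L, 31L, 15L, 2L, 38L, 11L, 27L, 4L, 19L, 34L, 9L, 25L,
              1L, 40L, 13L, 29L, 6L, 21L, 36L, 16L, 3L, 32L, 10L, 26L, 5L,
              39L, 14L, 30L, 8L, 22L, 37L, 12L, 28L, 18L, 33L, 20L, 35L,
              17L, 24L)
  scr <- wt[perm40]
  list(NSCR = paste(nscr, collapse = ""), SCR = paste(scr, collapse = ""))
}

#' Read or write a scenario configuration as YAML
#'
#' Flat schema: `peptide` (string), `flow` or `flow_scaling`,
#' `peak_sigma`, `mz_step`, `noise_sigma`, `seed`, and `species`, a list
#' of records with `n_monomers`, `charge`, `abundance` and `conformers`
#' (records with `fraction`, `weight`, optional `drift_apex`,
#' `drift_width`).
#'
#' @param path YAML file.
#' @return a [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  species <- lapply(y$species, function(sp)
    scenario_species(oligomer_ion(sp$n_monomers, sp$charge),
                     abundance = if (is.null(sp$abundance)) 1 else sp$abundance,
                     conformers = lapply(sp$conformers, function(cf)
                       scenario_conformer(cf$fraction, cf$weight,
                                          drift_apex = if (is.null(cf$drift_apex)) NA_real_ else cf$drift_apex,
                                          drift_width = if (is.null(cf$drift_width)) NA_real_ else cf$drift_width))))
  args <- list(species = species)
  for (k in c("peptide", "peak_sigma", "mz_step", "noise_sigma", "flow",
              "flow_scaling", "drift_step", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(scenario_config, args)
}

#' @rdname read_scenario_yaml
#' @param cfg a `scenario_config` to serialize.
#' @export
write_scenario_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  y <- list(peptide = cfg$peptide$sequence,
            flow_scaling = cfg$flow_scaling,
            peak_sigma = cfg$peak_sigma, mz_step = cfg$mz_step,
            noise_sigma = cfg$noise_sigma, drift_step = cfg$drift_step,
            seed = cfg$seed,
            species = lapply(cfg$species, function(sp)
              list(n_monomers = sp$ion$n_monomers, charge = sp$ion$charge,
                   abundance = sp$abundance,
                   conformers = lapply(sp$conformers, function(cf) {
                     out <- list(fraction = cf$fraction, weight = cf$weight)
                     if (is.finite(cf$drift_apex)) {
                       out$drift_apex <- cf$drift_apex
                       out$drift_width <- cf$drift_width
                     }
                     out
                   }))))
  yaml::write_yaml(y, path)
  invisible(path)
}
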