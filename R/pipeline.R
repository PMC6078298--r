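# Config-driven end-to-end runs: read -> smooth -> centroid -> assign ->
# (optional drift split + slice) -> uptake -> deconvolve -> report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

.as_spectrum_input <- function(x, format) {
  if (inherits(x, "ms_spectrum")) return(x)
  read_spectrum(x, format = format)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param control non-deuterated control: path or `ms_spectrum`.
#' @param deuterated deuterated sample: path or `ms_spectrum`; `NULL` for
#'   a control-only run (assignments and envelopes only).
#' @param peptide sequence string or `peptide_spec`.
#' @param ions list of assignments, each a list with `n`, `z` and
#'   `window` (length-2 m/z interval isolating that ion's envelope).
#' @param format input format passed to [read_spectrum()].
#' @param smooth_window,smooth_order,smooth_passes Savitzky-Golay
#'   parameters.
#' @param centroid_threshold relative peak height threshold.
#' @param family_size,iterations,boosts,p,min_weight deconvolution
#'   parameters, see [deconvolve_envelope()].
#' @param drift_map optional path or `drift_map` for IM split analysis.
#' @param drift_windows optional named list (by ion index) of m/z windows
#'   for drift projection; defaults to the ion windows.
#' @param split_prominence prominence threshold for
#'   [detect_conformer_split()].
#' @param slice_half_width drift slab half-width in ms.
#' @param out_dir optional output directory for TSV/JSON report and log.
#' @export
run_config <- function(control, deuterated = NULL, peptide = ABETA40_WT,
                       ions, format = "auto",
                       smooth_window = 5, smooth_order = 3, smooth_passes = 1,
                       centroid_threshold = 0.01,
                       family_size = 200, iterations = 10000, boosts = 100,
                       p = 1.2, min_weight = 0.01,
                       drift_map = NULL, drift_windows = NULL,
                       split_prominence = 0.1, slice_half_width = 0.5,
                       out_dir = NULL) {
  if (!length(ions)) stop("at least one ion assignment required")
  for (a in ions)
    if (is.null(a$n) || is.null(a$z) || is.null(a$window))
      stop("each ion assignment needs n, z and window")
  structure(as.list(environment()), class = "hdx_run_config")
}

.subset_centroids <- function(c, window) {
  keep <- c$position >= window[1] & c$position <= window[2]
  centroid_list(c$position[keep], c$area[keep], c$domain)
}

#' Execute an end-to-end pipeline run
#'
#' @param cfg an [run_config()] object.
#' @return an object of class `hdx_report`: per-ion centroid uptake
#'   (HDX/M), deconvolution fit, charge density, optional drift-split
#'   results, plus resolved configuration for provenance. Written as TSV
#'   and JSON (plus a plain-text log with per-stage timings) when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "hdx_run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  ctrl <- .stage("read", .as_spectrum_input(cfg$control, cfg$format))
  deut <- if (!is.null(cfg$deuterated))
    .stage("read", .as_spectrum_input(cfg$deuterated, cfg$format))
  tick("read")

  ctrl_s <- .stage("smooth", smooth_spectrum(ctrl, cfg$smooth_window,
                                             cfg$smooth_order, cfg$smooth_passes))
  deut_s <- if (!is.null(deut))
    .stage("smooth", smooth_spectrum(deut, cfg$smooth_window,
                                     cfg$smooth_order, cfg$smooth_passes))
  tick("smooth")

  ctrl_c <- .stage("centroid", centroid_spectrum(ctrl_s, cfg$centroid_threshold))
  deut_c <- if (!is.null(deut_s))
    .stage("centroid", centroid_spectrum(deut_s, cfg$centroid_threshold))
  tick("centroid")

  dmap <- if (!is.null(cfg$drift_map)) .stage("drift",
    if (inherits(cfg$drift_map, "drift_map")) cfg$drift_map
    else read_drift_map(cfg$drift_map))

  ions <- lapply(seq_along(cfg$ions), function(i) {
    a <- cfg$ions[[i]]
    ion <- oligomer_ion(a$n, a$z)
    ctrl_w <- .stage("assign", .subset_centroids(ctrl_c, a$window))
    if (!length(ctrl_w$position))
      stop(sprintf("stage 'assign': no control peaks in window [%g, %g] for %s",
                   a$window[1], a$window[2], .ion_label(ion)), call. = FALSE)
    entry <- list(ion = ion, label = .ion_label(ion),
                  cpm = charge_per_monomer(ion), window = a$window,
                  control_centroid = weighted_centroid(ctrl_w),
                  uptake = NA_real_, deconv = NULL, split = NULL,
                  conformer_fits = NULL)
    if (!is.null(deut_c)) {
      deut_w <- .subset_centroids(deut_c, a$window)
      if (!length(deut_w$position))
        stop(sprintf("stage 'uptake': no deuterated peaks in window for %s",
                     entry$label), call. = FALSE)
      entry$uptake <- .stage("uptake",
        hdx_uptake(weighted_centroid(deut_w), entry$control_centroid, ion))
      entry$deconv <- .stage("deconvolve",
        deconvolve_envelope(ctrl_w, deut_w, ion, peptide = cfg$peptide,
                            family_size = cfg$family_size,
                            iterations = cfg$iterations, boosts = cfg$boosts,
                            p = cfg$p, min_weight = cfg$min_weight))
    }
    if (!is.null(dmap)) {
      dwin <- if (!is.null(cfg$drift_windows) && length(cfg$drift_windows) >= i &&
                  !is.null(cfg$drift_windows[[i]]))
        cfg$drift_windows[[i]] else a$window
      prof <- .stage("drift", drift_profile(dmap, dwin))
      entry$split <- .stage("drift",
        detect_conformer_split(prof, cfg$split_prominence))
      if (isTRUE(attr(entry$split, "split")) && !is.null(deut_c)) {
        entry$conformer_fits <- lapply(seq_len(nrow(entry$split)), function(k) {
          sl <- .stage("drift-slice",
            slice_envelope_at_drift(dmap, entry$split$drift[k],
                                    cfg$slice_half_width))
          sl_c <- centroid_spectrum(sl, cfg$centroid_threshold)
          sl_w <- .subset_centroids(sl_c, a$window)
          fit <- .stage("deconvolve",
            deconvolve_envelope(ctrl_w, sl_w, ion, peptide = cfg$peptide,
                                family_size = cfg$family_size,
                                iterations = cfg$iterations,
                                boosts = cfg$boosts, p = cfg$p,
                                min_weight = cfg$min_weight))
          list(drift = entry$split$drift[k], share = entry$split$share[k],
               label = entry$split$label[k],
               uptake = hdx_uptake(weighted_centroid(sl_w),
                                   entry$control_centroid, ion),
               deconv = fit)
        })
      }
    }
    entry
  })
  tick("analyze")

  resolved <- cfg
  resolved$control <- if (is.character(cfg$control)) cfg$control else "<in-memory>"
  resolved$deuterated <- if (is.character(cfg$deuterated) ||
                             is.null(cfg$deuterated)) cfg$deuterated
                         else "<in-memory>"
  resolved$drift_map <- if (is.character(cfg$drift_map) ||
                            is.null(cfg$drift_map)) cfg$drift_map
                        else "<in-memory>"
  report <- structure(
    list(ions = ions,
         provenance = list(
           package = "hdxgold",
           version = as.character(utils::packageVersion("hdxgold")),
           config = resolved[setdiff(names(resolved), "out_dir")])),
    class = "hdx_report")
  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir, timings)
  report
}

.report_table <- function(report) {
  do.call(rbind, lapply(report$ions, function(e) {
    comps <- if (is.null(e$deconv)) "" else
      paste(sprintf("%.2f:%.3f", e$deconv$components$uptake,
                    e$deconv$components$weight), collapse = ";")
    data.frame(ion = e$label, n_monomers = e$ion$n_monomers,
               charge = e$ion$charge, cpm = e$cpm,
               hdx_per_monomer = e$uptake,
               n_components = if (is.null(e$deconv)) NA_integer_
                              else nrow(e$deconv$components),
               components = comps,
               split = if (is.null(e$split)) NA else attr(e$split, "split"),
               drift_apexes = if (is.null(e$split)) "" else
                 paste(sprintf("%.2f", e$split$drift), collapse = ";"),
               drift_shares = if (is.null(e$split)) "" else
                 paste(sprintf("%.3f", e$split$share), collapse = ";"))
  }))
}

.write_report <- function(report, dir, timings) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- .report_table(report)
  utils::write.table(tab, file.path(dir, "report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  json <- list(provenance = report$provenance[c("package", "version")],
               ions = lapply(report$ions, function(e) list(
                 ion = e$label, cpm = e$cpm, uptake = e$uptake,
                 components = if (is.null(e$deconv)) NULL else e$deconv$components,
                 split = if (is.null(e$split)) NULL else e$split)))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log <- c(sprintf("hdxgold pipeline run, package version %s",
                   report$provenance$version),
           sprintf("stage %-10s %8.3f s", names(timings), unlist(timings)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.hdx_report <- function(x, ...) {
  cat(sprintf("<hdx_report> %d ion(s)\n", length(x$ions)))
  print(.report_table(x), row.names = FALSE)
  invisible(x)
}

#' Compare deuterium uptake across matched ions of replicate runs
#'
#' For each report, every ion sharing the monomer's charge density (the
#' isobaric family) is compared to the monomer: the per-monomer uptake
#' difference is computed, then aggregated across replicate reports as
#' mean, standard deviation and replicate count.
#'
#' @param reports list of `hdx_report` replicates sharing ion
#'   assignments.
#' @param path optional TSV output path.
#' @return data.frame `(ion, cpm, mean_diff, sd_diff, n)`; empty (with a
#'   warning) when no report contains a matched monomer/oligomer pair.
#' @export
compare_variants <- function(reports, path = NULL) {
  if (inherits(reports, "hdx_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(seq_along(reports), function(r) {
    rep_i <- reports[[r]]
    mono <- Filter(function(e) e$ion$n_monomers == 1L, rep_i$ions)
    if (!length(mono)) return(NULL)
    mono <- mono[[1]]
    do.call(rbind, lapply(rep_i$ions, function(e) {
      if (e$ion$n_monomers == 1L) return(NULL)
      if (abs(e$cpm - mono$cpm) > 1e-9) return(NULL)
      data.frame(replicate = r, ion = e$label, cpm = e$cpm,
                 diff = e$uptake - mono$uptake)
    }))
  }))
  if (is.null(rows) || !nrow(rows)) {
    warning("no matched monomer/oligomer ion pairs across reports")
    out <- data.frame(ion = character(0), cpm = numeric(0),
                      mean_diff = numeric(0), sd_diff = numeric(0),
                      n = integer(0))
  } else {
    out <- do.call(rbind, lapply(split(rows, rows$ion), function(g)
      data.frame(ion = g$ion[1], cpm = g$cpm[1],
                 mean_diff = mean(g$diff),
                 sd_diff = if (nrow(g) > 1) stats::sd(g$diff) else NA_real_,
                 n = nrow(g))))
    rownames(out) <- NULL
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
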