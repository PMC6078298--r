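# Isobaric oligomer/charge-state assignment and ion-mobility drift-time
# conformer splitting. Oligomers sharing a charge density (charge per
# monomer) overlap exactly in m/z and are distinguishable only by the
# 1/z isotope-peak spacing or by drift time.

#' Average peptide isotope spacing in Da
#'
#' The mean gap between adjacent isotope peaks of a peptide envelope
#' (slightly below the pure 13C gap of 1.00336 Da because of N/O/S
#' contributions).
#' @export
ISOTOPE_SPACING <- 1.00235

#' Charge per monomer (charge density) of an oligomer ion
#' @param ion an `oligomer_ion`.
#' @examples
#' charge_per_monomer(oligomer_ion(2, 7))  # 3.5
#' @export
charge_per_monomer <- function(ion) {
  stopifnot(inherits(ion, "oligomer_ion"))
  ion$charge / ion$n_monomers
}

#' Enumerate oligomer ions whose envelopes fall in an m/z window
#'
#' All (n-mer, charge) combinations with `n <= n_max`, `z <= z_max` whose
#' envelope head — the average-mass m/z position — lies inside `window`.
#' Ions of equal charge density land on identical m/z and form an
#' isobaric family.
#'
#' @param monomer_mass average neutral monomer mass in Da.
#' @param window length-2 m/z interval.
#' @param n_max,z_max enumeration bounds.
#' @return object of class `isobar_family`: `window`, `members` (list of
#'   `oligomer_ion`, sorted by n_monomers then charge), `cpm` (common
#'   charge density or NA).
#' @export
isobar_family <- function(monomer_mass, window, n_max, z_max) {
  stopifnot(length(window) == 2L, window[2] > window[1],
            n_max >= 1, z_max >= 1)
  members <- list()
  for (n in seq_len(n_max)) for (z in seq_len(z_max)) {
    ion <- oligomer_ion(n, z)
    m <- ion_mz(monomer_mass, ion)
    if (m >= window[1] && m <= window[2]) members[[length(members) + 1L]] <- ion
  }
  if (length(members)) {
    o <- order(vapply(members, `[[`, 0L, "n_monomers"),
               vapply(members, `[[`, 0L, "charge"))
    members <- members[o]
  }
  cpms <- vapply(members, charge_per_monomer, numeric(1))
  cpm <- if (length(cpms) && diff(range(cpms)) < 1e-9) cpms[1] else NA_real_
  structure(list(window = window, members = members, cpm = cpm),
            class = "isobar_family")
}

#' @export
print.isobar_family <- function(x, ...) {
  cat(sprintf("<isobar_family> m/z %.2f-%.2f: %s%s\n",
              x$window[1], x$window[2],
              if (length(x$members))
                paste(vapply(x$members, .ion_label, ""), collapse = ", ")
              else "(empty)",
              if (!is.na(x$cpm)) sprintf(" [CpM %.2f]", x$cpm) else ""))
  invisible(x)
}

#' Infer the charge state from isotope-peak spacing
#'
#' Adjacent gaps vote for the charge implied by
#' `z = round(spacing_constant / gap)`, weighted by the smaller flanking
#' peak area; the winning charge must hold over 60% of the weighted vote
#' and its gaps must agree to within 20% dispersion, otherwise the comb
#' is unassignable. A mixed flag is raised when the remaining peaks do
#' not sit on the winner's isotope lattice (overlapping combs): peaks
#' off-lattice by more than a fifth of the winner's gap, holding more
#' than `foreign_share` of the total area.
#'
#' @param c a `centroid_list` with at least 3 resolved isotope peaks.
#' @param spacing isotope gap constant in Da (default [ISOTOPE_SPACING]).
#' @param z_max largest charge considered.
#' @param foreign_share off-lattice area fraction above which the comb is
#'   flagged mixed (default 10%).
#' @return list: `charge` (integer or NA), `confidence` (1 - relative gap
#'   dispersion), `mixed` (logical).
#' @export
infer_charge_from_spacing <- function(c, spacing = ISOTOPE_SPACING, z_max = 16,
                                      foreign_share = 0.1) {
  stopifnot(inherits(c, "centroid_list"))
  if (length(c$position) < 3) stop("need at least 3 resolved isotope peaks")
  gaps <- diff(c$position)
  wts <- pmin(utils::head(c$area, -1), utils::tail(c$area, -1))
  z_gap <- round(spacing / gaps)
  ok <- z_gap >= 1 & z_gap <= z_max & abs(spacing / gaps - z_gap) < 0.35
  if (!any(ok)) return(list(charge = NA_integer_, confidence = 0, mixed = FALSE))
  votes <- tapply(wts[ok], z_gap[ok], sum)
  votes <- sort(votes, decreasing = TRUE)
  z <- as.integer(names(votes)[1])
  if (votes[1] <= 0.6 * sum(wts))
    return(list(charge = NA_integer_, confidence = 0, mixed = length(votes) > 1))
  sel <- ok & z_gap == z
  disp <- stats::mad(gaps[sel], constant = 1.4826) / stats::median(gaps[sel])
  if (!is.finite(disp)) disp <- 0
  if (disp > 0.2) return(list(charge = NA_integer_, confidence = 0, mixed = FALSE))
  # peaks not on the winner's lattice signal a second, overlapped comb
  gap_z <- spacing / z
  anchor <- c$position[which.max(c$area)]
  resid <- abs(((c$position - anchor + gap_z / 2) %% gap_z) - gap_z / 2)
  foreign <- sum(c$area[resid > 0.2 * gap_z]) / sum(c$area)
  list(charge = z, confidence = max(0, 1 - disp),
       mixed = foreign > foreign_share)
}

# --- drift maps --------------------------------------------------------------

#' Construct a 2D IM-MS drift map
#'
#' Sparse or rectangular (m/z, drift time, intensity) triples.
#'
#' @param mz,drift,intensity equal-length numeric vectors; drift in ms.
#' @export
drift_map <- function(mz, drift, intensity) {
  stopifnot(length(mz) == length(drift), length(drift) == length(intensity))
  if (any(drift < 0)) stop("drift times must be non-negative")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = as.numeric(mz), drift = as.numeric(drift),
                 intensity = as.numeric(intensity)),
            class = "drift_map")
}

#' @export
print.drift_map <- function(x, ...) {
  cat(sprintf("<drift_map> %d points, m/z %.2f-%.2f, drift %.2f-%.2f ms\n",
              length(x$mz), min(x$mz), max(x$mz), min(x$drift), max(x$drift)))
  invisible(x)
}

#' Read a drift map from three-column text (mz, drift_ms, intensity)
#' @param path input file.
#' @export
read_drift_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("mz", "drift", "intensity"))
  drift_map(d$mz, d$drift, d$intensity)
}

#' Write a drift map as three-column text
#' @param map a `drift_map`.
#' @param path output file.
#' @export
write_drift_map <- function(map, path) {
  stopifnot(inherits(map, "drift_map"))
  utils::write.table(data.frame(map$mz, map$drift, map$intensity), path,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Project an m/z window of a drift map onto the drift-time axis
#'
#' @param map a `drift_map`.
#' @param window length-2 m/z interval.
#' @return object of class `drift_profile`: `drift` (unique sorted bins),
#'   `intensity` (summed per bin), `window`.
#' @export
drift_profile <- function(map, window) {
  stopifnot(inherits(map, "drift_map"), length(window) == 2L)
  keep <- map$mz >= window[1] & map$mz <= window[2]
  if (!any(keep)) stop("m/z window does not overlap the map")
  drift <- map$drift[keep]; int <- map$intensity[keep]
  bins <- sort(unique(drift))
  prof <- as.numeric(rowsum(int, match(drift, bins)))
  structure(list(drift = bins, intensity = prof, window = window),
            class = "drift_profile")
}

#' @export
print.drift_profile <- function(x, ...) {
  cat(sprintf("<drift_profile> %d bins over %.2f-%.2f ms (m/z %.2f-%.2f)\n",
              length(x$drift), min(x$drift), max(x$drift),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Detect conformer splitting in a drift-time profile
#'
#' Local maxima with prominence at least `min_prominence` of the profile
#' maximum are apexes; shares are integrated valley-to-valley. Two or
#' more apexes flag a split: the shortest-drift apex is the compact
#' conformer, the longest-drift the extended one.
#'
#' @param p a `drift_profile`.
#' @param min_prominence relative prominence threshold (default 10%).
#' @return data.frame `(drift, share, label)` sorted by drift, with
#'   attribute `split` (logical).
#' @export
detect_conformer_split <- function(p, min_prominence = 0.1) {
  stopifnot(inherits(p, "drift_profile"))
  y <- p$intensity
  n <- length(y)
  if (n == 0 || max(y) <= 0) stop("empty drift profile")
  apex <- which(y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  # prominence: height above the higher of the two bounding valleys
  keep <- vapply(apex, function(i) {
    left <- if (i > 1) min(y[1:i]) else y[i]
    right <- if (i < n) min(y[i:n]) else y[i]
    others <- apex[apex != i]
    lv <- if (any(others < i)) min(y[max(others[others < i]):i]) else min(y[1:i])
    rv <- if (any(others > i)) min(y[i:min(others[others > i])]) else min(y[i:n])
    (y[i] - max(lv, rv)) >= min_prominence * max(y)
  }, logical(1))
  apex <- apex[keep]
  if (!length(apex)) apex <- which.max(y)
  # valley boundaries between consecutive retained apexes
  bounds <- c(0L, vapply(seq_len(length(apex) - 1L), function(k) {
    seg <- apex[k]:apex[k + 1]
    seg[which.min(y[seg])]
  }, integer(1)), n)
  share <- vapply(seq_along(apex), function(k)
    sum(y[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
  share <- share / sum(share)
  lab <- rep("", length(apex))
  if (length(apex) >= 2) {
    lab[1] <- "compact"; lab[length(apex)] <- "extended"
  }
  out <- data.frame(drift = p$drift[apex], share = share, label = lab)
  attr(out, "split") <- length(apex) >= 2
  out
}

#' Extract the m/z spectrum of a drift-time slab
#'
#' Sums map intensity over `apex +/- half_width` ms per m/z bin; with
#' `half_width = 0` the nearest drift bin column is returned. Feeds
#' conformer-specific deconvolution of compact vs extended populations.
#'
#' @param map a `drift_map`.
#' @param apex drift time (ms) at the slab center.
#' @param half_width slab half-width in ms.
#' @return an `ms_spectrum`.
#' @export
slice_envelope_at_drift <- function(map, apex, half_width = 0.5) {
  stopifnot(inherits(map, "drift_map"))
  if (apex < min(map$drift) || apex > max(map$drift))
    stop("apex outside the map's drift range")
  if (half_width == 0) {
    bins <- sort(unique(map$drift))
    nearest <- bins[which.min(abs(bins - apex))]
    keep <- map$drift == nearest
  } else {
    keep <- abs(map$drift - apex) <= half_width
  }
  if (!any(keep)) stop("empty drift slab")
  mz <- map$mz[keep]; int <- map$intensity[keep]
  bins <- sort(unique(mz))
  acc <- as.numeric(rowsum(int, match(mz, bins)))
  new_spectrum(bins, acc, metadata = list(drift_apex = apex,
                                          half_width = half_width))
}

#' Assignment report for an isobaric window
#'
#' One row per family member: ion label, charge density, window, plus
#' optional drift-split results.
#'
#' @param fam an `isobar_family`.
#' @param split optional result of [detect_conformer_split()].
#' @param path optional TSV output path.
#' @export
assignment_report <- function(fam, split = NULL, path = NULL) {
  stopifnot(inherits(fam, "isobar_family"))
  df <- data.frame(
    ion = vapply(fam$members, .ion_label, ""),
    n_monomers = vapply(fam$members, `[[`, 0L, "n_monomers"),
    charge = vapply(fam$members, `[[`, 0L, "charge"),
    cpm = vapply(fam$members, charge_per_monomer, numeric(1)),
    window_lo = fam$window[1], window_hi = fam$window[2])
  if (!is.null(split)) {
    df$split <- isTRUE(attr(split, "split"))
    df$drift_apexes <- paste(sprintf("%.2f", split$drift), collapse = ";")
    df$drift_shares <- paste(sprintf("%.3f", split$share), collapse = ";")
  }
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
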