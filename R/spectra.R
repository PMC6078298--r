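# Spectrum containers, I/O, Savitzky-Golay smoothing, centroiding,
# intensity-weighted centroid masses, uptake, and the m/z -> per-monomer
# mass-domain conversion.

#' Construct a 1D mass spectrum
#'
#' @param mz strictly increasing m/z vector.
#' @param intensity non-negative intensities, same length.
#' @param metadata free-form named list (sample, flow rate, polarity, ...).
#' @export
new_spectrum <- function(mz, intensity, metadata = list()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) == 0) stop("empty spectrum")
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 metadata = metadata),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %d points, m/z %.3f-%.3f, TIC %.4g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Supported formats: `"xy"` — plain two-column text (whitespace or comma
#' separated, `#` comments allowed); `"mzML"` — read via the mzR package;
#' multiple scans are averaged onto the first scan's m/z grid when
#' `scans = "average"` (the default), or a single scan is selected by
#' index.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"xy"` or `"mzML"`.
#' @param scans `"average"` or a single scan index (mzML only).
#' @return an `ms_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "xy", "mzML"),
                          scans = "average") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "xy"
  if (format == "xy") .read_spectrum_xy(path) else .read_spectrum_mzml(path, scans)
}

.read_spectrum_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines), "[,;[:space:]]+")
  n_bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(n_bad)) stop(sprintf("malformed row %d in %s", n_bad[1], path))
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad)) stop(sprintf("non-numeric values at row %d in %s", bad[1], path))
  new_spectrum(mz, it, metadata = list(source = path))
}

.read_spectrum_mzml <- function(path, scans) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  ns <- nrow(mzR::header(h))
  if (ns < 1) stop("no scans in ", path)
  if (identical(scans, "average")) {
    p1 <- mzR::peaks(h, 1L)
    acc <- p1[, 2]
    if (ns > 1) {
      for (i in 2:ns) {
        pi <- mzR::peaks(h, i)
        acc <- acc + stats::approx(pi[, 1], pi[, 2], xout = p1[, 1],
                                   yleft = 0, yright = 0)$y
      }
      acc <- acc / ns
    }
    new_spectrum(p1[, 1], acc, metadata = list(source = path, scans = ns))
  } else {
    i <- as.integer(scans)
    if (i < 1 || i > ns) stop(sprintf("scan %d out of range (1-%d) in %s", i, ns, path))
    p <- mzR::peaks(h, i)
    new_spectrum(p[, 1], p[, 2], metadata = list(source = path, scan = i))
  }
}

#' Write a spectrum as plain two-column text
#' @param s an `ms_spectrum`.
#' @param path output file.
#' @export
write_spectrum_xy <- function(s, path) {
  stopifnot(inherits(s, "ms_spectrum"))
  utils::write.table(data.frame(mz = s$mz, intensity = s$intensity), path,
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.b64_doubles <- function(x)
  gsub("[\r\n]", "",
       jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                     endian = "little")))

#' Write a spectrum as a minimal single-scan mzML file
#'
#' Uncompressed 64-bit little-endian arrays, readable by standard mzML
#' readers (round-trips bit-exactly through mzR).
#'
#' @param s an `ms_spectrum`.
#' @param path output file.
#' @export
write_spectrum_mzml <- function(s, path) {
  stopifnot(inherits(s, "ms_spectrum"))
  emz <- .b64_doubles(s$mz); eint <- .b64_doubles(s$intensity)
  bda <- function(enc, acc, name)
    paste0('          <binaryDataArray encodedLength="', nchar(enc), '">\n',
           '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
           '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
           '            <cvParam cvRef="MS" accession="', acc, '" name="', name, '" value=""/>\n',
           '            <binary>', enc, '</binary>\n',
           '          </binaryDataArray>')
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://psi.hupo.org"/></cvList>\n',
    '  <fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>\n',
    '  <softwareList count="1"><software id="sw" version="0"/></softwareList>\n',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC"/></instrumentConfigurationList>\n',
    '  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '  <run id="run" defaultInstrumentConfigurationRef="IC">\n',
    '    <spectrumList count="1" defaultDataProcessingRef="dp">\n',
    '      <spectrum index="0" id="scan=1" defaultArrayLength="', length(s$mz), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '        <binaryDataArrayList count="2">\n',
    bda(emz, "MS:1000514", "m/z array"), '\n',
    bda(eint, "MS:1000515", "intensity array"), '\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>\n',
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Savitzky-Golay smoothing
#'
#' Polynomial least-squares smoothing applied `passes` times. The vendor
#' convention "(3, 5)" is ambiguous between (order, window) and (window,
#' order); both parameters are therefore explicit, defaulting to a cubic
#' over a 5-point window.
#'
#' @param s an `ms_spectrum`.
#' @param window odd filter length in points, `>= order + 2`.
#' @param order polynomial order.
#' @param passes number of repeated applications.
#' @export
smooth_spectrum <- function(s, window = 5, order = 3, passes = 1) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window < order + 2) stop("window must be >= order + 2")
  if (window > length(s$mz)) stop("window larger than spectrum")
  y <- s$intensity
  for (i in seq_len(passes)) y <- signal::sgolayfilt(y, p = order, n = window)
  y[y < 0] <- 0
  new_spectrum(s$mz, y, metadata = s$metadata)
}

#' Construct a centroid list
#'
#' @param position strictly increasing positions (m/z or Da).
#' @param area non-negative areas.
#' @param domain `"m/z"`, `"mass"` or `"mass-per-monomer"`.
#' @export
centroid_list <- function(position, area, domain = "m/z") {
  stopifnot(length(position) == length(area))
  o <- order(position)
  position <- position[o]; area <- area[o]
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  if (any(area < 0)) stop("areas must be non-negative")
  structure(list(position = as.numeric(position), area = as.numeric(area),
                 domain = domain),
            class = "centroid_list")
}

#' @export
print.centroid_list <- function(x, ...) {
  cat(sprintf("<centroid_list> %d peaks in %s domain\n", length(x$position), x$domain))
  invisible(x)
}

#' Centroid a profile spectrum
#'
#' Peaks are local maxima above `min_rel_height` of the global maximum;
#' each peak's support is the contiguous above-threshold run around it,
#' valley-split at interior local minima. Centroid position is the
#' intensity-weighted mean over the support, area the summed intensity.
#'
#' @param s an `ms_spectrum` (smoothed or raw).
#' @param min_rel_height relative height threshold (fraction of the
#'   spectrum maximum, default 1%).
#' @return a `centroid_list` (possibly empty) in the m/z domain.
#' @export
centroid_spectrum <- function(s, min_rel_height = 0.01) {
  stopifnot(inherits(s, "ms_spectrum"))
  y <- s$intensity
  thr <- min_rel_height * max(y)
  above <- y >= thr & y > 0
  if (!any(above)) return(centroid_list(numeric(0), numeric(0), "m/z"))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- numeric(0); area <- numeric(0)
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- i0:i1
    ys <- y[seg]
    # split at interior local minima (valleys)
    if (length(seg) >= 3) {
      interior <- 2:(length(seg) - 1)
      valleys <- interior[ys[interior] < ys[interior - 1] & ys[interior] <= ys[interior + 1]]
    } else valleys <- integer(0)
    bounds <- c(1L, valleys, length(seg) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      sub <- seg[bounds[b]:(bounds[b + 1] - 1L)]
      if (max(y[sub]) < thr) next
      pos <- c(pos, sum(s$mz[sub] * y[sub]) / sum(y[sub]))
      area <- c(area, sum(y[sub]))
    }
  }
  centroid_list(pos, area, "m/z")
}

#' Intensity-weighted centroid position over a window
#'
#' @param c a `centroid_list`.
#' @param window length-2 interval `c(lo, hi)`; peaks with positions
#'   inside it (inclusive) contribute.
#' @return the area-weighted mean position.
#' @export
weighted_centroid <- function(c, window = NULL) {
  stopifnot(inherits(c, "centroid_list"))
  keep <- if (is.null(window)) rep(TRUE, length(c$position))
          else c$position >= window[1] & c$position <= window[2]
  if (!any(keep)) stop("no peaks in window")
  sum(c$position[keep] * c$area[keep]) / sum(c$area[keep])
}

#' Deuterium uptake per monomer from centroid masses
#'
#' `(deut - control) * charge / (DELTA_MASS_D * n_monomers)` for centroids
#' in the m/z domain — the HDX/M quantity. Negative uptake beyond
#' `tolerance` deuterons triggers a warning; the value is still returned.
#'
#' @param deut,control centroid m/z of the deuterated and the
#'   non-deuterated control envelope for the same ion assignment.
#' @param ion an `oligomer_ion`.
#' @param tolerance negative-uptake warning threshold in deuterons.
#' @return uptake in deuterons per monomer.
#' @export
hdx_uptake <- function(deut, control, ion, tolerance = 0.5) {
  stopifnot(inherits(ion, "oligomer_ion"))
  up <- (deut - control) * ion$charge / (DELTA_MASS_D * ion$n_monomers)
  if (up < -tolerance)
    warning(sprintf("negative uptake %.2f D/monomer for %s", up, .ion_label(ion)))
  up
}

#' Convert m/z-domain centroids to the per-monomer mass domain
#'
#' `(position * charge - charge * m_proton) / n_monomers`: isobaric ions
#' of equal charge density map to identical per-monomer masses.
#'
#' @param c a `centroid_list` in the m/z domain.
#' @param ion an `oligomer_ion`.
#' @return a `centroid_list` with domain `"mass-per-monomer"`.
#' @export
to_monomer_mass_domain <- function(c, ion) {
  stopifnot(inherits(c, "centroid_list"), inherits(ion, "oligomer_ion"))
  pos <- (c$position * ion$charge - ion$charge * PROTON_MASS) / ion$n_monomers
  centroid_list(pos, c$area, "mass-per-monomer")
}

#' Export a centroid list as TSV
#' @param c a `centroid_list`.
#' @param path output file.
#' @export
write_centroids_tsv <- function(c, path) {
  stopifnot(inherits(c, "centroid_list"))
  utils::write.table(
    data.frame(position = c$position, area = c$area, domain = c$domain),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
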