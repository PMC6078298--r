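# Sequence parsing, elemental composition, isotope envelopes and the
# exchangeable-proton inventory of the neutral peptide.

# Residue (chain) elemental compositions: amino acid minus one water.
.RESIDUE_COMP <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

# Isotope masses (Da) and abundances, IUPAC-style standard table.
.ISOTOPES <- list(
  H = list(mass = c(1.00782503207, 2.01410177785),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.00307400443, 15.00010889888),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Mass of a proton in Da (charge carrier in positive-mode ESI)
#' @export
PROTON_MASS <- 1.007276

#' Mass difference between deuterium and protium in Da
#'
#' Uptake in deuterons is obtained by dividing mass (or mass-domain
#' centroid) shifts by this increment.
#' @export
DELTA_MASS_D <- 1.006277

#' WT amyloid-beta 1-40 sequence
#' @export
ABETA40_WT <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

#' Parse a one-letter peptide sequence
#'
#' Accepts a raw character string (whitespace is stripped) or a path to a
#' single-record FASTA file. Only the 20 canonical one-letter residue
#' codes are allowed; termini default to the free amine / free acid forms
#' relevant for an intact peptide.
#'
#' @param text character scalar: the sequence, or a FASTA file path when
#'   `fasta = TRUE`.
#' @param fasta logical; read `text` as a FASTA file path.
#' @return an object of class `peptide_spec` with fields `sequence`
#'   (string), `residues` (character vector), `n_term` ("free-amine"),
#'   `c_term` ("free-acid").
#' @examples
#' parse_sequence(ABETA40_WT)
#' @export
parse_sequence <- function(text, fasta = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (fasta) {
    lines <- readLines(text)
    lines <- lines[nzchar(trimws(lines))]
    headers <- grepl("^>", lines)
    if (!any(headers) || sum(headers) > 1L)
      stop("expected a single-record FASTA file: ", text)
    text <- paste(lines[!headers], collapse = "")
  }
  seq <- gsub("[[:space:]]", "", text)
  if (!nzchar(seq)) stop("empty sequence")
  residues <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(residues %in% names(.RESIDUE_COMP)))
  if (length(bad))
    stop(sprintf("invalid residue code '%s' at position %d",
                 residues[bad[1]], bad[1]))
  structure(list(sequence = paste(residues, collapse = ""),
                 residues = residues,
                 n_term = "free-amine", c_term = "free-acid"),
            class = "peptide_spec")
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %d residues, %s N-terminus, %s C-terminus\n",
              length(x$residues), x$n_term, x$c_term))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Residue compositions are summed and one water is added for the free
#' termini (equivalently: free amino acid compositions minus `n - 1`
#' waters for the condensation bonds).
#'
#' @param p a `peptide_spec` or a character sequence.
#' @return named integer vector over C, H, N, O, S with class
#'   `elemental_composition`.
#' @examples
#' peptide_composition("G")  # glycine, C2 H5 N1 O2
#' @export
peptide_composition <- function(p) {
  if (is.character(p)) p <- parse_sequence(p)
  stopifnot(inherits(p, "peptide_spec"))
  comp <- Reduce(`+`, .RESIDUE_COMP[p$residues])
  comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # terminal H + OH
  structure(as.integer(comp), names = names(comp),
            class = "elemental_composition")
}

#' Build an elemental composition from explicit counts
#' @param ... named element counts, e.g. `elemental_composition(H = 2, O = 1)`.
#' @export
elemental_composition <- function(...) {
  counts <- c(...)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all counts must be named by element symbol")
  unknown <- setdiff(names(counts), names(.ISOTOPES))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be non-negative")
  full <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  full[names(counts)] <- as.integer(counts)
  structure(full, class = "elemental_composition")
}

.check_composition <- function(c) {
  if (!inherits(c, "elemental_composition")) {
    if (is.numeric(c) && !is.null(names(c))) c <- do.call(elemental_composition, as.list(c))
    else stop("expected an elemental_composition")
  }
  unknown <- setdiff(names(c)[c > 0], names(.ISOTOPES))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  c
}

#' Average (abundance-weighted) mass of a composition in Da
#' @param c an `elemental_composition`.
#' @export
average_mass <- function(c) {
  c <- .check_composition(c)
  sum(vapply(names(c), function(el) {
    if (c[[el]] == 0) return(0)
    iso <- .ISOTOPES[[el]]
    c[[el]] * sum(iso$mass * iso$abundance) / sum(iso$abundance)
  }, numeric(1)))
}

#' Monoisotopic (lightest-isotope) mass of a composition in Da
#' @param c an `elemental_composition`.
#' @export
monoisotopic_mass <- function(c) {
  c <- .check_composition(c)
  sum(vapply(names(c), function(el) {
    if (c[[el]] == 0) return(0)
    c[[el]] * .ISOTOPES[[el]]$mass[1]
  }, numeric(1)))
}

# --- discrete isotope distributions -----------------------------------------

#' Construct an isotope distribution
#'
#' A discrete (mass, probability) distribution; probabilities are
#' normalized to sum to one and entries sorted by mass.
#'
#' @param mass numeric vector of masses (Da or m/z per `domain`).
#' @param prob non-negative weights, recycled-free, same length as `mass`.
#' @param domain one of "mass", "m/z", "mass-per-monomer".
#' @export
isotope_distribution <- function(mass, prob, domain = "mass") {
  stopifnot(length(mass) == length(prob), all(prob >= 0), sum(prob) > 0)
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  if (any(diff(mass) <= 0)) {
    # collapse exact duplicates
    g <- cumsum(c(TRUE, diff(mass) > 0))
    mass <- as.numeric(tapply(mass, g, `[`, 1L))
    prob <- as.numeric(tapply(prob, g, sum))
  }
  structure(list(mass = mass, prob = prob / sum(prob), domain = domain),
            class = "isotope_dist")
}

#' @export
print.isotope_dist <- function(x, ...) {
  cat(sprintf("<isotope_dist> %d entries in %s domain, mean %.4f\n",
              length(x$mass), x$domain, sum(x$mass * x$prob)))
  invisible(x)
}

#' Probability-weighted mean of an isotope distribution
#' @param d an `isotope_dist`.
#' @export
distribution_mean <- function(d) sum(d$mass * d$prob)

# Convolve two discrete distributions; peaks closer than merge_tol are
# pooled into their probability-weighted mean, which preserves the overall
# mean exactly.
.iso_convolve <- function(d1, d2, merge_tol = 0.05, prune = 0) {
  m <- outer(d1$mass, d2$mass, `+`)
  p <- outer(d1$prob, d2$prob)
  .iso_collapse(as.vector(m), as.vector(p), merge_tol, prune)
}

.iso_collapse <- function(mass, prob, merge_tol, prune) {
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  g <- cumsum(c(TRUE, diff(mass) > merge_tol))
  pm <- rowsum(prob, g)
  mm <- rowsum(prob * mass, g) / pm
  keep <- pm > prune
  p <- pm[keep]
  list(mass = mm[keep], prob = p / sum(p))
}

# k atoms of one element, by binary exponentiation of the natural pattern.
.element_dist <- function(el, k, merge_tol, prune) {
  iso <- .ISOTOPES[[el]]
  base <- list(mass = iso$mass, prob = iso$abundance / sum(iso$abundance))
  acc <- NULL
  sq <- base
  while (k > 0) {
    if (k %% 2 == 1)
      acc <- if (is.null(acc)) sq else .iso_convolve(acc, sq, merge_tol, prune)
    k <- k %/% 2
    if (k > 0) sq <- .iso_convolve(sq, sq, merge_tol, prune)
  }
  acc
}

#' Natural isotope envelope of an elemental composition
#'
#' Exact per-element pattern convolution; isotopologues closer than
#' `merge_tol` (within one nominal isotope peak) are pooled into
#' probability-weighted centroids, so the mean mass is preserved. The
#' final distribution is pruned at `prune` and renormalized.
#'
#' @param c an `elemental_composition`.
#' @param prune probability threshold below which entries are dropped.
#' @param merge_tol pooling width in Da for near-coincident isotopologues.
#' @return an `isotope_dist` in the "mass" domain.
#' @export
natural_isotope_distribution <- function(c, prune = 1e-6, merge_tol = 0.05) {
  c <- .check_composition(c)
  # intermediate pruning well below the final threshold keeps sizes bounded
  # without biasing the retained envelope
  ptmp <- min(prune, 1e-9) / 10
  acc <- NULL
  for (el in names(c)) {
    if (c[[el]] == 0) next
    d <- .element_dist(el, c[[el]], merge_tol, ptmp)
    acc <- if (is.null(acc)) d else .iso_convolve(acc, d, merge_tol, ptmp)
  }
  if (is.null(acc)) stop("empty composition")
  acc <- .iso_collapse(acc$mass, acc$prob, merge_tol, prune)
  isotope_distribution(acc$mass, acc$prob, domain = "mass")
}

# --- oligomer ions -----------------------------------------------------------

#' An oligomer ion: (number of monomers, charge)
#'
#' Positive-mode convention: charge carriers are protons. The standard
#' naming is e.g. MON2+ = `oligomer_ion(1, 2)`, TRI6+ = `oligomer_ion(3, 6)`.
#'
#' @param n_monomers positive integer.
#' @param charge positive integer (proton count).
#' @export
oligomer_ion <- function(n_monomers, charge) {
  stopifnot(length(n_monomers) == 1L, length(charge) == 1L)
  if (n_monomers < 1 || n_monomers != round(n_monomers))
    stop("n_monomers must be a positive integer")
  if (charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  structure(list(n_monomers = as.integer(n_monomers),
                 charge = as.integer(charge)),
            class = "oligomer_ion")
}

.ion_label <- function(ion) {
  nm <- c("MON", "DIM", "TRI", "TET", "PEN", "HEX", "HEP", "OCT")
  base <- if (ion$n_monomers <= length(nm)) nm[ion$n_monomers]
          else paste0(ion$n_monomers, "MER")
  sprintf("%s%d+", base, ion$charge)
}

#' @export
print.oligomer_ion <- function(x, ...) {
  cat(sprintf("<oligomer_ion> %s (%d-mer, %d+)\n",
              .ion_label(x), x$n_monomers, x$charge))
  invisible(x)
}

#' m/z of an oligomer ion from its monomer neutral mass
#'
#' `(n_monomers * mass + charge * m_proton) / charge`, positive mode.
#'
#' @param mass neutral monomer mass in Da.
#' @param ion an `oligomer_ion`.
#' @export
ion_mz <- function(mass, ion) {
  stopifnot(inherits(ion, "oligomer_ion"))
  (ion$n_monomers * mass + ion$charge * PROTON_MASS) / ion$charge
}

# --- exchangeable-proton inventory ------------------------------------------

#' Neutral-form exchangeable side-chain hydrogen table
#'
#' Number of non-amide heteroatom-bound hydrogens per residue side chain
#' in the neutral form, plus the two-terminus contributions (free
#' N-terminal amine: 2, free C-terminal acid: 1). Backbone amide NH are
#' excluded throughout: they exchange too slowly in the gas phase to be
#' observed. Override entries via a YAML/JSON flat key -> integer config
#' with [read_exchange_table()].
#'
#' @return named integer vector; residue one-letter codes plus `n_term`
#'   and `c_term`.
#' @export
default_exchange_table <- function() {
  c(A = 0L, R = 4L, N = 2L, D = 1L, C = 1L, E = 1L, Q = 2L, G = 0L,
    H = 1L, I = 0L, L = 0L, K = 2L, M = 0L, F = 0L, P = 0L, S = 1L,
    T = 1L, W = 1L, Y = 1L, V = 0L,
    n_term = 2L, c_term = 1L)
}

#' Read an exchangeable-hydrogen table from a YAML or JSON config
#'
#' The file is a flat mapping of one-letter residue codes (plus optional
#' `n_term` / `c_term`) to non-negative integer counts; entries override
#' the defaults of [default_exchange_table()].
#'
#' @param path file path; format chosen by extension (.yml/.yaml/.json).
#' @export
read_exchange_table <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  tab <- default_exchange_table()
  unknown <- setdiff(names(vals), names(tab))
  if (length(unknown)) stop("unknown table keys: ", paste(unknown, collapse = ", "))
  if (any(unlist(vals) < 0)) stop("counts must be non-negative")
  tab[names(vals)] <- as.integer(unlist(vals))
  tab
}

#' Count exchangeable side-chain/terminus protons over a residue range
#'
#' Sums the neutral-form table over `region`; the N-terminal amine
#' contribution is added only when the region starts at residue 1, the
#' C-terminal acid contribution only when it ends at the last residue.
#'
#' @param p a `peptide_spec` or sequence string.
#' @param region integer length-2 `c(from, to)`, 1-based inclusive;
#'   default the full sequence.
#' @param table exchange table, see [default_exchange_table()].
#' @return integer proton count.
#' @examples
#' exchangeable_protons(ABETA40_WT)              # 27
#' exchangeable_protons(ABETA40_WT, c(1, 16))    # 19
#' exchangeable_protons(ABETA40_WT, c(17, 40))   # 8
#' @export
exchangeable_protons <- function(p, region = NULL,
                                 table = default_exchange_table()) {
  if (is.character(p)) p <- parse_sequence(p)
  n <- length(p$residues)
  if (is.null(region)) region <- c(1L, n)
  stopifnot(length(region) == 2L)
  from <- region[1]; to <- region[2]
  if (from < 1 || to > n || from > to)
    stop(sprintf("region [%d, %d] out of bounds for %d residues", from, to, n))
  count <- sum(table[p$residues[from:to]])
  if (from == 1L) count <- count + table[["n_term"]]
  if (to == n)    count <- count + table[["c_term"]]
  as.integer(count)
}

#' Total exchangeable protons of an oligomer ion
#'
#' `n_monomers * per_monomer + charge`: each charging proton of a
#' positive-mode ion is itself exchangeable.
#'
#' @param ion an `oligomer_ion`.
#' @param per_monomer neutral-form count from [exchangeable_protons()].
#' @examples
#' total_exchangeable(oligomer_ion(1, 5), 27)  # 32
#' @export
total_exchangeable <- function(ion, per_monomer) {
  stopifnot(inherits(ion, "oligomer_ion"), per_monomer >= 0)
  as.integer(ion$n_monomers * per_monomer + ion$charge)
}
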