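# Equal-probability (binomial) single-state deuteration model.
#
# Under the assumption that every exchangeable site of one conformational
# state exchanges with the same probability f, the number of incorporated
# deuterons is Binomial(n_sites, f) and the deuterated envelope is the
# natural envelope convolved with that distribution, each deuteron adding
# DELTA_MASS_D. Unequal per-site probabilities at the same mean can only
# narrow the count distribution (Poisson-binomial variance bound), so the
# binomial envelope is the widest a single state can produce and the
# number of states resolved against this family is a lower bound.

#' Single-state deuterated envelope
#'
#' Convolves a natural isotope envelope with an exact
#' `Binomial(n_sites, fraction)` deuteration distribution; each exchanged
#' site shifts mass by [DELTA_MASS_D]. The binomial is computed exactly
#' (no normal approximation).
#'
#' @param natural an `isotope_dist` (mass domain) for the undeuterated
#'   species.
#' @param n_sites number of exchangeable sites (>= 0).
#' @param fraction per-site exchange probability in \[0, 1\].
#' @param prune probability threshold applied after convolution (0 keeps
#'   everything; the mean shift is then exact).
#' @return object of class `single_state_envelope`: fields `fraction`,
#'   `n_sites`, `distribution` (an `isotope_dist`).
#' @export
single_state <- function(natural, n_sites, fraction, prune = 0) {
  stopifnot(inherits(natural, "isotope_dist"))
  if (n_sites < 0 || n_sites != round(n_sites))
    stop("n_sites must be a non-negative integer")
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  if (n_sites == 0 || fraction == 0) {
    dist <- natural
  } else {
    k <- 0:n_sites
    deut <- list(mass = k * DELTA_MASS_D, prob = stats::dbinom(k, n_sites, fraction))
    conv <- .iso_convolve(list(mass = natural$mass, prob = natural$prob),
                          deut, merge_tol = 0.05, prune = prune)
    dist <- isotope_distribution(conv$mass, conv$prob, domain = natural$domain)
  }
  structure(list(fraction = fraction, n_sites = as.integer(n_sites),
                 distribution = dist, natural_mean = distribution_mean(natural)),
            class = "single_state_envelope")
}

#' @export
print.single_state_envelope <- function(x, ...) {
  cat(sprintf("<single_state_envelope> %d sites at fraction %.4f (%.2f D)\n",
              x$n_sites, x$fraction, expected_uptake(x)))
  invisible(x)
}

#' Expected deuterium uptake of a single-state envelope, in deuterons
#'
#' `fraction * n_sites`; identical (to numerical precision) to the
#' centroid shift relative to the natural envelope divided by
#' [DELTA_MASS_D].
#'
#' @param e a `single_state_envelope`.
#' @export
expected_uptake <- function(e) {
  stopifnot(inherits(e, "single_state_envelope"))
  e$fraction * e$n_sites
}

#' Family of uniformly spaced single-state envelopes
#'
#' The theoretical dictionary for envelope deconvolution: `grid` members
#' at uptake fractions `k / (grid - 1)`, k = 0 ... grid - 1, spanning 0%
#' to 100% deuteration inclusive. The default grid of 200 members gives a
#' fraction step of 1/199.
#'
#' @param natural natural (undeuterated) `isotope_dist`.
#' @param n_sites exchangeable sites per particle whose envelope this is.
#' @param grid number of members (>= 2).
#' @param prune pruning threshold passed to [single_state()].
#' @return object of class `deuteration_family`: lists `members`,
#'   `fractions`, `uptakes` (deuterons), `n_sites`, `natural`.
#' @export
build_family <- function(natural, n_sites, grid = 200, prune = 1e-8) {
  if (grid < 2 || grid != round(grid)) stop("grid must be an integer >= 2")
  fractions <- seq(0, 1, length.out = grid)
  members <- lapply(fractions, function(f) single_state(natural, n_sites, f, prune = prune))
  structure(list(members = members, fractions = fractions,
                 uptakes = fractions * n_sites,
                 n_sites = as.integer(n_sites), natural = natural),
            class = "deuteration_family")
}

#' @export
print.deuteration_family <- function(x, ...) {
  cat(sprintf("<deuteration_family> %d members, %d sites, uptake 0-%d D\n",
              length(x$members), x$n_sites, x$n_sites))
  invisible(x)
}

#' Serialize a deuteration family to a columnar text file
#'
#' Writes one row per (member, isotopologue): columns `fraction`, `mass`,
#' `probability`, tab-separated with a header. Intended for inspection
#' and for rebuilding deconvolution design matrices outside R.
#'
#' @param family a `deuteration_family`.
#' @param path output file path.
#' @export
write_family_tsv <- function(family, path) {
  stopifnot(inherits(family, "deuteration_family"))
  rows <- do.call(rbind, lapply(seq_along(family$members), function(i) {
    d <- family$members[[i]]$distribution
    data.frame(fraction = family$fractions[i], mass = d$mass, probability = d$prob)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
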