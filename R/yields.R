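# Site-specific cleavage yields and the guanosine-preference statistics.
#
# Conventions: yields are percentages of the total c/y signal; base-loss
# variants count toward their parent fragment; cleavage site k is the
# phosphodiester between residues k and k+1, so "5' side of G at position p"
# is site p - 1. A site is a G-site when residue k+1 is guanosine-class
# (modified guanosines included, inosine excluded by default).

g_sites_of <- function(seq, include = NULL) {
  seq <- parse_rna(seq)
  include <- include %||% g_class_codes()
  which(seq$residues[-1] %in% include)
}

#' Site-specific c/y fragment yields
#'
#' Computes, for each cleavage site k, the yield of the c_k and y_(N-k)
#' fragments as a percentage of total c + y abundance. Base-loss variants
#' are pooled into their parent fragment; a/w and other channels do not
#' enter the total.
#'
#' @param assignments Assignment tibble from [match_fragments()] or the
#'   pooled form from [aggregate_charge_states()].
#' @param seq The `rna_sequence` (or string) the run was acquired on.
#' @param n Precursor charge of the run (carried for reporting).
#' @param include Residue codes classified as guanosine; defaults to all
#'   guanosine variants, excluding inosine.
#' @return A `cleavage_yields` tibble: `site`, `residue` (3' of the site),
#'   `g_site`, `yield_c`, `yield_y`, `yield` (their sum, all percent).
#'   Yields sum to 100 over sites. Sequence, N and n are attributes.
#' @export
site_specific_yields <- function(assignments, seq, n = NA_integer_,
                                 include = NULL) {
  seq <- parse_rna(seq)
  N <- length(seq)
  if (!is.null(assignments) && "charge" %in% names(assignments)) {
    assignments <- aggregate_charge_states(assignments)
  }
  cy <- assignments[assignments$ion_type %in% c("c", "y"), , drop = FALSE]
  if (nrow(cy) == 0 || sum(cy$abundance) <= 0) {
    stop("no c/y fragments assigned: total abundance is zero", call. = FALSE)
  }
  # pool base-loss variants into the parent fragment
  pooled <- dplyr::summarise(
    dplyr::group_by(cy, .data$ion_type, .data$index),
    abundance = sum(.data$abundance), .groups = "drop"
  )
  total <- sum(pooled$abundance)
  pooled$site <- ifelse(pooled$ion_type == "c", pooled$index,
                        N - pooled$index)
  g_idx <- g_sites_of(seq, include)
  out <- tibble::tibble(
    site = seq_len(N - 1L),
    residue = seq$residues[2:N],
    g_site = seq_len(N - 1L) %in% g_idx
  )
  cab <- pooled[pooled$ion_type == "c", ]
  yab <- pooled[pooled$ion_type == "y", ]
  out$yield_c <- 100 * as.numeric(cab$abundance[match(out$site, cab$site)]) /
    total
  out$yield_y <- 100 * as.numeric(yab$abundance[match(out$site, yab$site)]) /
    total
  out$yield_c[is.na(out$yield_c)] <- 0
  out$yield_y[is.na(out$yield_y)] <- 0
  out$yield <- out$yield_c + out$yield_y
  attr(out, "sequence") <- as.character(seq)
  attr(out, "N") <- N
  attr(out, "n") <- n
  class(out) <- c("cleavage_yields", class(out))
  out
}

#' Overall guanosine cleavage yield and its random-cleavage null
#'
#' The observed statistic is the summed c/y yield over all sites immediately
#' 5' of a guanosine residue; the random-cleavage expectation is
#' 100 x (number of G-sites) / (number of sites), a pure topology quantity.
#'
#' @param yields A `cleavage_yields` table from [site_specific_yields()],
#'   or `NULL` to compute the expectation alone.
#' @param seq Sequence (defaults to the one stored in `yields`).
#' @param include Residue codes counted as guanosine.
#' @return A one-row tibble: `observed` (`NA` if no yields given),
#'   `random_expectation`, `n_g_sites`, `n_sites` (percentages at full
#'   precision; round to the nearest percent for reporting).
#' @examples
#' overall_g_yield(NULL, "ACCCGCAAGGCCGACGGC") # expectation 6/17 = 35%
#' @export
overall_g_yield <- function(yields, seq = NULL, include = NULL) {
  if (is.null(seq)) seq <- attr(yields, "sequence")
  seq <- parse_rna(seq)
  S <- length(seq) - 1L
  g_idx <- g_sites_of(seq, include)
  observed <- if (is.null(yields)) NA_real_ else {
    sum(yields$yield[yields$site %in% g_idx])
  }
  tibble::tibble(
    observed = observed,
    random_expectation = 100 * length(g_idx) / S,
    n_g_sites = length(g_idx),
    n_sites = S
  )
}

#' Charge density of a precursor ion
#'
#' @param n Precursor charge.
#' @param N Nucleotide count.
#' @return Charges per nucleotide, rounded to 2 decimals for reporting.
#' @examples
#' charge_density(7, 18) # 0.39
#' @export
charge_density <- function(n, N) {
  stopifnot(N >= 1, n >= 0)
  round(n / N, 2)
}

#' Fraction of phosphodiester moieties deprotonated
#'
#' An (M - nH)^n- ion of an N-mer has N - 1 phosphodiester moieties, of
#' which on average n carry the deprotonation.
#'
#' @param n Precursor charge.
#' @param N Nucleotide count (N >= 2).
#' @return Percentage of phosphodiesters deprotonated.
#' @examples
#' phosphodiester_deprotonation(13, 27) # 50%
#' @export
phosphodiester_deprotonation <- function(n, N) {
  stopifnot(N >= 2, n >= 0, n <= N - 1)
  100 * n / (N - 1)
}

#' Effective guanosine-preference factor
#'
#' Inverts the random-cleavage null: if G-sites cleave gamma-fold faster
#' than the rest, the expected overall G-yield is
#' 100 n_G gamma / (n_G gamma + S - n_G). Solving for gamma turns an
#' observed yield Y into the preference factor
#' gamma_hat = Y / (100 - Y) x (S - n_G) / n_G, with gamma_hat = 1 exactly
#' at the random expectation.
#'
#' @param observed_g_yield Observed overall G-yield in percent, strictly
#'   between 0 and 100.
#' @param seq Sequence defining the topology.
#' @param include Residue codes counted as guanosine.
#' @return The estimated preference factor (dimensionless).
#' @examples
#' effective_preference_factor(60, "ACCCGCAAGGCCGACGGC") # 2.75
#' @export
effective_preference_factor <- function(observed_g_yield, seq,
                                        include = NULL) {
  if (observed_g_yield <= 0 || observed_g_yield >= 100) {
    stop("observed yield must be strictly between 0 and 100 ",
         "(odds undefined otherwise)", call. = FALSE)
  }
  seq <- parse_rna(seq)
  S <- length(seq) - 1L
  n_g <- length(g_sites_of(seq, include))
  if (n_g == 0 || n_g == S) {
    stop("topology has no informative G/non-G contrast", call. = FALSE)
  }
  observed_g_yield / (100 - observed_g_yield) * (S - n_g) / n_g
}

#' Analytic overall G-yield under a preference factor
#'
#' @param gamma Preference factor (> 0).
#' @param seq Sequence defining the topology.
#' @param include Residue codes counted as guanosine.
#' @return Expected overall G-yield in percent,
#'   100 n_G gamma / (n_G gamma + S - n_G).
#' @export
analytic_g_yield <- function(gamma, seq, include = NULL) {
  stopifnot(gamma > 0)
  seq <- parse_rna(seq)
  S <- length(seq) - 1L
  n_g <- length(g_sites_of(seq, include))
  100 * n_g * gamma / (n_g * gamma + S - n_g)
}

#' Fold-change correlation between a modified and a reference run
#'
#' Pairs individual c/y fragment signals (matched by ion type, index,
#' charge and base loss) from two runs of equal length and precursor
#' charge, after normalizing each run to its total c/y signal, and reports
#' the fold change at a site of interest as the ratio of normalized
#' c_k + y_(N-k) sums, reference over modified.
#'
#' @param assignments_ref,assignments_mod Assignment tibbles from
#'   [match_fragments()] for the reference and modified RNA.
#' @param site Cleavage site of interest.
#' @param seq Sequence (either run's; lengths must agree).
#' @return A `fold_change` object: `pairs` (tibble of normalized abundance
#'   pairs), `site`, `fold_change`.
#' @export
fold_change_correlation <- function(assignments_ref, assignments_mod, site,
                                    seq) {
  seq <- parse_rna(seq)
  N <- length(seq)
  prep <- function(a, label) {
    a <- a[a$ion_type %in% c("c", "y") & !a$ambiguous, , drop = FALSE]
    if (nrow(a) == 0) stop("no c/y assignments in ", label, call. = FALSE)
    a$norm_abundance <- a$abundance / sum(a$abundance)
    a[, c("ion_type", "index", "charge", "base_loss", "norm_abundance")]
  }
  ref <- prep(assignments_ref, "reference run")
  mod <- prep(assignments_mod, "modified run")
  pairs <- dplyr::full_join(
    ref, mod, by = c("ion_type", "index", "charge", "base_loss"),
    suffix = c("_ref", "_mod")
  )
  pairs$norm_abundance_ref[is.na(pairs$norm_abundance_ref)] <- 0
  pairs$norm_abundance_mod[is.na(pairs$norm_abundance_mod)] <- 0
  pairs$site <- ifelse(pairs$ion_type == "c", pairs$index, N - pairs$index)

  at_site <- pairs[pairs$site == site, , drop = FALSE]
  if (nrow(at_site) == 0) {
    stop("no fragments from site ", site, " in either run", call. = FALSE)
  }
  num <- sum(at_site$norm_abundance_ref)
  den <- sum(at_site$norm_abundance_mod)
  structure(
    list(pairs = tibble::as_tibble(pairs), site = site,
         fold_change = num / den),
    class = "fold_change"
  )
}

#' @export
print.fold_change <- function(x, ...) {
  cat("<fold_change> site ", x$site, ": ref/mod = ",
      sprintf("%.2f", x$fold_change), " (", nrow(x$pairs),
      " fragment pairs)\n", sep = "")
  invisible(x)
}

#' Charge-value distribution of assigned fragments
#'
#' @param assignments Assignment tibble (non-empty).
#' @param seq Sequence, to map fragment indices onto cleavage sites.
#' @return A tibble with `ion_type`, `index`, `site`, `charge`, `abundance`
#'   plus a per-site abundance-weighted `mean_charge` table in the
#'   `site_summary` attribute.
#' @export
charge_value_distribution <- function(assignments, seq) {
  if (is.null(assignments) || nrow(assignments) == 0) {
    stop("no assignments", call. = FALSE)
  }
  seq <- parse_rna(seq)
  N <- length(seq)
  a <- assignments[assignments$ion_type %in% c("c", "y") &
                     !assignments$ambiguous, , drop = FALSE]
  hist <- dplyr::summarise(
    dplyr::group_by(a, .data$ion_type, .data$index, .data$charge),
    abundance = sum(.data$abundance), .groups = "drop"
  )
  hist$site <- ifelse(hist$ion_type == "c", hist$index, N - hist$index)
  summary <- dplyr::summarise(
    dplyr::group_by(hist, .data$ion_type, .data$site),
    mean_charge = sum(.data$charge * .data$abundance) /
      sum(.data$abundance),
    .groups = "drop"
  )
  out <- hist[, c("ion_type", "index", "site", "charge", "abundance")]
  attr(out, "site_summary") <- summary
  out
}

#' Compare charge values between two runs
#'
#' @param dist_a,dist_b Outputs of [charge_value_distribution()].
#' @return Maximum absolute difference of per-site mean fragment charge
#'   between the runs (over sites present in both).
#' @export
compare_charge_values <- function(dist_a, dist_b) {
  sa <- attr(dist_a, "site_summary")
  sb <- attr(dist_b, "site_summary")
  j <- dplyr::inner_join(sa, sb, by = c("ion_type", "site"),
                         suffix = c("_a", "_b"))
  if (nrow(j) == 0) return(NA_real_)
  max(abs(j$mean_charge_a - j$mean_charge_b))
}

#' Overall dissociation yield
#'
#' Percentage of total signal carried by backbone fragments, relative to
#' all species: backbone fragments, undissociated precursor and precursor
#' base losses (the latter two both count as undissociated).
#'
#' @param assignments Assignment tibble including precursor species
#'   (`ion_type == "precursor"`, base-loss variants included).
#' @return Percent fragmented.
#' @export
dissociation_yield <- function(assignments) {
  a <- assignments[!assignments$ambiguous, , drop = FALSE]
  backbone <- sum(a$abundance[a$ion_type %in% c(.ION_TYPES_5P,
                                                .ION_TYPES_3P)])
  precursor <- sum(a$abundance[a$ion_type == "precursor"])
  total <- backbone + precursor
  if (total <= 0) stop("no species assigned: denominator is zero",
                       call. = FALSE)
  100 * backbone / total
}
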