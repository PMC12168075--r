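# Isotope-pattern generation.
#
# Patterns are indexed by the extra-neutron number k (offset ~ k * 1.00336
# Da from the monoisotopic peak), which is the resolution FT-ICR deisotoping
# works at; fine structure within an isotopologue is not resolved here.

# relative isotopic abundances by extra-neutron count (IUPAC representative)
.ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99632, 0.00368),
  O = c(0.99757, 0.00038, 0.00205),
  P = c(1)
)

# convolution with truncation of negligible tail terms
.convolve_dist <- function(a, b, cap = 64L) {
  out <- numeric(min(length(a) + length(b) - 1L, cap))
  for (i in seq_along(a)) {
    jmax <- min(length(b), cap - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out[out < 1e-15] <- 0
  out
}

# distribution of one element to the power n (exponentiation by squaring)
.element_power <- function(dist, n, cap = 64L) {
  result <- 1
  base <- dist
  while (n > 0) {
    if (n %% 2 == 1) result <- .convolve_dist(result, base, cap)
    n <- n %/% 2
    if (n > 0) base <- .convolve_dist(base, base, cap)
  }
  result
}

# mean residue of an equimolar A/C/G/U RNA: nucleotide = nucleoside + HPO3
# - H2O. Used to approximate isotope patterns when only a mass is known.
.RNA_AVERAGINE <- c(C = 9.5, H = 11.75, N = 3.75, O = 7, P = 1)

rna_averagine_composition <- function(mass) {
  if (mass <= 0) stop("mass must be positive", call. = FALSE)
  res_mass <- sum(.RNA_AVERAGINE * .ATOMIC_MASS[names(.RNA_AVERAGINE)])
  scale <- mass / res_mass
  counts <- round(.RNA_AVERAGINE * scale)
  counts["H"] <- max(0, counts["H"] +
    round((mass - sum(counts * .ATOMIC_MASS[names(counts)])) /
            .ATOMIC_MASS["H"]))
  new_composition(counts)
}

#' Isotope pattern of a composition or mass
#'
#' Exact mode convolves the isotopic distributions of all atoms in an
#' elemental composition; averagine mode builds a surrogate composition from
#' the mean equimolar A/C/G/U RNA residue scaled to the target mass and
#' returns its exact pattern. Patterns are truncated at 99.9% cumulative
#' abundance.
#'
#' @param x An `elemental_composition` (exact mode) or a neutral mass in Da
#'   (averagine mode).
#' @param mode `"exact"` or `"averagine"`. Defaults to `"exact"` for a
#'   composition and `"averagine"` for a bare mass.
#' @return A tibble with `k` (extra-neutron count), `offset` (Da from the
#'   monoisotopic peak), `abundance` (fraction of the full distribution) and
#'   `relative` (most abundant isotopologue = 1).
#' @examples
#' isotope_pattern(comp(P = 1))          # single peak: P is monoisotopic
#' isotope_pattern(5764.87, "averagine") # ~5.8 kDa RNA-like envelope
#' @export
isotope_pattern <- function(x, mode = NULL) {
  if (is.null(mode)) {
    mode <- if (inherits(x, "elemental_composition")) "exact" else "averagine"
  }
  mode <- match.arg(mode, c("exact", "averagine"))
  if (mode == "exact") {
    if (!inherits(x, "elemental_composition")) {
      stop("exact mode requires an elemental composition", call. = FALSE)
    }
    cc <- unclass(x)
  } else {
    if (inherits(x, "elemental_composition")) x <- monoisotopic_mass(x)
    stopifnot(is.numeric(x), length(x) == 1L)
    cc <- unclass(rna_averagine_composition(x))
  }
  dist <- 1
  for (el in names(cc)) {
    if (cc[el] > 0) {
      dist <- .convolve_dist(dist,
                             .element_power(.ISOTOPE_ABUNDANCE[[el]], cc[el]))
    }
  }
  keep <- which(cumsum(dist) < 0.999)
  keep <- seq_len(min(length(dist), length(keep) + 1L))
  dist <- dist[keep]
  tibble::tibble(
    k = keep - 1L,
    offset = (keep - 1L) * .ISOTOPE_SPACING,
    abundance = dist,
    relative = dist / max(dist)
  )
}
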