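# Backbone fragment chemistry (McLuckey a/b/c/d/w/x/y/z nomenclature).
#
# Every fragment mass derives from the intact-subsequence masses: with
# B_i the neutral mass of the 5' i-mer (OH/OH) and Y_j that of the 3' j-mer
# (OH/OH), and W = H2O, P = HPO3, L = P - W:
#
#   a = B_i - W   b = B_i       c = B_i + L   d = B_i + P
#   z = Y_j - W   y = Y_j       x = Y_j + L   w = Y_j + P
#
# c carries the 2',3'-cyclic phosphate and y the 5'-OH, i.e. the c/y pair is
# the transesterification channel: atom conservation a+w = b+x = c+y = d+z =
# parent mass holds by construction.

.ION_TYPES_5P <- c("a", "b", "c", "d")
.ION_TYPES_3P <- c("w", "x", "y", "z")

ion_end_adjustment <- function(ion_type) {
  W <- mass_h2o()
  P <- mass_hpo3()
  L <- P - W
  adj <- c(a = -W, b = 0, c = L, d = P, y = 0, z = -W, w = P, x = L,
           precursor = 0)
  unname(adj[ion_type])
}

# per-element count matrix of nucleosides along the sequence
seq_element_matrix <- function(seq, residues = residue_table()) {
  seq <- parse_rna(seq, residues = residues)
  idx <- match(seq$residues, residues$code)
  mat <- t(vapply(residues$nucleoside[idx],
                  function(f) unclass(parse_formula(f)),
                  numeric(length(.ELEMENTS))))
  rownames(mat) <- NULL
  mat
}

subsequence_composition <- function(seq, from, to,
                                    residues = residue_table()) {
  mat <- seq_element_matrix(seq, residues)
  counts <- colSums(mat[from:to, , drop = FALSE])
  k <- to - from + 1L
  link <- unclass(.COMP_HPO3()) - unclass(.COMP_H2O())
  new_composition(counts + (k - 1L) * link)
}

#' Neutral mass of a backbone fragment
#'
#' @param seq An `rna_sequence` or string; parent termini must be OH/OH.
#' @param ion_type One of `"a","b","c","d"` (5' fragments, index counts
#'   residues from the 5' end) or `"w","x","y","z"` (3' fragments, index
#'   counts residues from the 3' end); `"precursor"` gives the intact mass.
#' @param index Residue count covered, `1 <= index <= N - 1` for backbone
#'   fragments. Vectorised over `ion_type`/`index`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' fragment_neutral_mass("ACCCGCAAGGCCGACGGC", "c", 4) # ACCC>p, 1244.176 Da
#' @export
fragment_neutral_mass <- function(seq, ion_type, index) {
  seq <- parse_rna(seq)
  if (seq$five_prime != "OH" || seq$three_prime != "OH") {
    stop("fragment chemistry is defined for OH/OH parent termini",
         call. = FALSE)
  }
  n <- length(seq)
  k <- pmax(length(ion_type), length(index))
  ion_type <- rep_len(ion_type, k)
  index <- rep_len(index, k)
  bad <- ion_type != "precursor" & (index < 1 | index > n - 1)
  if (any(bad)) {
    stop("fragment index out of range [1, N-1]: ",
         paste(index[bad], collapse = ", "), call. = FALSE)
  }
  rt <- residue_table()
  nuc_mass <- rt$nucleoside_mass[match(seq$residues, rt$code)]
  L <- mass_linkage()
  prefix <- cumsum(nuc_mass) + (seq_len(n) - 1L) * L       # B_i
  suffix <- rev(cumsum(rev(nuc_mass))) + (n - seq_len(n)) * L
  suffix <- rev(suffix)                                     # Y_j, j = 1..n

  base <- numeric(k)
  is5 <- ion_type %in% .ION_TYPES_5P
  is3 <- ion_type %in% .ION_TYPES_3P
  ispre <- ion_type == "precursor"
  if (any(!(is5 | is3 | ispre))) {
    stop("unknown ion type(s): ",
         paste(unique(ion_type[!(is5 | is3 | ispre)]), collapse = ", "),
         call. = FALSE)
  }
  base[is5] <- prefix[index[is5]]
  base[is3] <- suffix[index[is3]]
  base[ispre] <- prefix[n]
  base + ion_end_adjustment(ion_type)
}

fragment_composition <- function(seq, ion_type, index) {
  seq <- parse_rna(seq)
  n <- length(seq)
  cc <- switch(
    substr(ion_type, 1, 9),
    precursor = composition_of(seq),
    if (ion_type %in% .ION_TYPES_5P) {
      subsequence_composition(seq, 1L, as.integer(index))
    } else {
      subsequence_composition(seq, n - as.integer(index) + 1L, n)
    }
  )
  if (ion_type %in% c("a", "z")) cc <- cc - .COMP_H2O()
  if (ion_type %in% c("c", "x")) {
    cc <- cc + .COMP_HPO3()
    cc <- cc - .COMP_H2O()
  }
  if (ion_type %in% c("d", "w")) cc <- cc + .COMP_HPO3()
  cc
}

#' m/z of a deprotonated ion
#'
#' Negative-mode convention: an (M - zH)^z- ion has lost z protons, so
#' m/z = (M - z * 1.00727646) / z.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Charge magnitude, a positive integer.
#' @return m/z in Da per charge.
#' @examples
#' mz_negative(5764.869, 7) # the (M - 7H)7- ion of the 18-mer, 822.545
#' @export
mz_negative <- function(neutral_mass, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass - z * .PROTON_MASS) / z
}

#' Neutral mass from negative-mode m/z
#'
#' @param mz Observed m/z.
#' @param z Charge magnitude.
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  mz * z + z * .PROTON_MASS
}

# number of phosphate moieties in a fragment (deprotonation sites); every
# species can carry at least one charge regardless
n_phosphates <- function(ion_type, index, n) {
  ifelse(ion_type %in% c("a", "b"), index - 1L,
  ifelse(ion_type %in% c("c", "d"), index,
  ifelse(ion_type %in% c("y", "z"), index - 1L,
  ifelse(ion_type %in% c("w", "x"), index,
         n - 1L))))
}

#' Enumerate theoretical fragment ions
#'
#' All (ion type, cleavage index, charge, optional single-base-loss)
#' combinations for a sequence, deduplicated and sorted by m/z. Base-loss
#' variants lose one neutral nucleobase BH from a residue position retained
#' by the fragment.
#'
#' @param seq An `rna_sequence` or string.
#' @param ion_types Subset of `c("a","b","c","d","w","x","y","z")`, plus
#'   optionally `"precursor"`.
#' @param max_charge Maximum charge magnitude to enumerate.
#' @param base_loss If `TRUE`, add single-base-loss variants.
#' @return A tibble with `ion_type`, `index`, `base_loss` (residue position
#'   or `NA`), `charge`, `neutral_mass`, `mz`, and a `composition`
#'   list-column used for isotope-pattern generation.
#' @examples
#' enumerate_fragments("GGCUAGCC", c("c", "y"), max_charge = 2)
#' @export
enumerate_fragments <- function(seq, ion_types = c("c", "y"), max_charge = 1,
                                base_loss = FALSE) {
  if (length(ion_types) == 0) stop("ion_types must be non-empty", call. = FALSE)
  seq <- parse_rna(seq)
  n <- length(seq)
  stopifnot(max_charge >= 1)
  rt <- residue_table()

  backbone <- setdiff(ion_types, "precursor")
  rows <- list()
  if (length(backbone) > 0) {
    grid <- expand.grid(ion_type = backbone, index = seq_len(n - 1L),
                        stringsAsFactors = FALSE)
    rows <- c(rows, list(grid))
  }
  if ("precursor" %in% ion_types) {
    rows <- c(rows, list(data.frame(ion_type = "precursor", index = n)))
  }
  grid <- do.call(rbind, rows)
  grid$neutral_mass <- fragment_neutral_mass(seq, grid$ion_type, grid$index)

  # base-loss variants: one per retained residue position
  variants <- list(
    tibble::tibble(ion_type = grid$ion_type, index = grid$index,
                   base_loss = NA_integer_, neutral_mass = grid$neutral_mass)
  )
  if (isTRUE(base_loss)) {
    for (r in seq_len(nrow(grid))) {
      it <- grid$ion_type[r]
      ix <- grid$index[r]
      positions <- if (it %in% .ION_TYPES_3P) {
        seq.int(n - ix + 1L, n)
      } else {
        seq_len(ix)
      }
      bm <- rt$base_mass[match(seq$residues[positions], rt$code)]
      variants <- c(variants, list(tibble::tibble(
        ion_type = it, index = ix, base_loss = as.integer(positions),
        neutral_mass = grid$neutral_mass[r] - bm
      )))
    }
  }
  out <- dplyr::bind_rows(variants)

  out <- tidyr::crossing(out, charge = seq_len(max_charge))
  out$charge <- as.integer(out$charge)
  chargeable <- pmax(1L, n_phosphates(out$ion_type, out$index, n))
  out <- out[out$charge <= chargeable, , drop = FALSE]
  out$mz <- mz_negative(out$neutral_mass, out$charge)

  # collapse isobaric variants: losing the same base from different retained
  # positions gives indistinguishable ions; keep the 5'-most position as
  # representative
  out$mass_key <- round(out$neutral_mass, 6)
  out <- dplyr::distinct(
    out, .data$ion_type, .data$index, .data$charge, .data$mass_key,
    .keep_all = TRUE
  )
  out$mass_key <- NULL
  out <- dplyr::arrange(out, .data$mz)

  # compositions, computed once per (ion_type, index) and adjusted for loss
  key <- paste(out$ion_type, out$index)
  ukey <- !duplicated(key)
  comp_map <- stats::setNames(
    purrr::map2(out$ion_type[ukey], out$index[ukey],
                function(it, ix) fragment_composition(seq, it, ix)),
    key[ukey]
  )
  out$composition <- purrr::pmap(
    list(key, out$base_loss),
    function(k, bl) {
      cc <- comp_map[[k]]
      if (!is.na(bl)) {
        cc <- cc - residue_composition(seq$residues[bl], "base", rt)
      }
      cc
    }
  )
  tibble::as_tibble(out[, c("ion_type", "index", "base_loss", "charge",
                            "neutral_mass", "mz", "composition")])
}
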