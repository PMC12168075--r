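# Residue alphabet. The definitions live in a plain-text table
# (inst/extdata/residues.tsv) so that further modified nucleosides can be
# added without touching code: one row per token with the nucleoside and
# neutral-base (BH) formulas.

.rnacleave_env <- new.env(parent = emptyenv())

#' Residue definition table
#'
#' Returns the residue alphabet: one row per residue token with its
#' nucleoside elemental formula, the neutral nucleobase (BH) formula released
#' on base loss, and whether the residue counts as a guanosine for
#' cleavage-preference statistics (`g_class`; all guanosine variants
#' including deaza and N2-methyl forms, but not inosine).
#'
#' Every row must satisfy the ribose bookkeeping identity: nucleoside minus
#' base leaves the C5H8O4 ribose remainder. This is checked on load.
#'
#' @param path Optional path to a user-supplied residue table with the same
#'   columns (`code`, `nucleoside`, `base`, `g_class`, `description`).
#' @return A tibble with columns `code`, `nucleoside`, `base`, `g_class`,
#'   `description`, `nucleoside_mass`, `base_mass`.
#' @export
residue_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rnacleave_env$residues)) return(.rnacleave_env$residues)
    path <- system.file("extdata", "residues.tsv", package = "rnacleave")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("code", "nucleoside", "base", "g_class")
  if (!all(required %in% names(tab))) {
    stop("residue table must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  ribose <- comp(C = 5, H = 8, O = 4)
  for (i in seq_len(nrow(tab))) {
    nuc <- parse_formula(tab$nucleoside[i])
    base <- parse_formula(tab$base[i])
    rem <- nuc - base
    if (!isTRUE(rem == ribose)) {
      stop("residue '", tab$code[i], "': nucleoside minus base is not the ",
           "C5H8O4 ribose remainder", call. = FALSE)
    }
  }
  out <- tibble::as_tibble(tab)
  out$g_class <- as.logical(out$g_class)
  out$nucleoside_mass <- vapply(
    out$nucleoside, function(f) monoisotopic_mass(parse_formula(f)), 0,
    USE.NAMES = FALSE
  )
  out$base_mass <- vapply(
    out$base, function(f) monoisotopic_mass(parse_formula(f)), 0,
    USE.NAMES = FALSE
  )
  if (cache) .rnacleave_env$residues <- out
  out
}

residue_composition <- function(code, what = c("nucleoside", "base"),
                                residues = residue_table()) {
  what <- match.arg(what)
  i <- match(code, residues$code)
  if (anyNA(i)) {
    stop("unknown residue code(s): ",
         paste(unique(code[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  if (length(code) == 1L) return(parse_formula(residues[[what]][i]))
  lapply(residues[[what]][i], parse_formula)
}

#' Residue codes counted as guanosine
#'
#' @param residues A residue table, see [residue_table()].
#' @return Character vector of tokens treated as guanosine when classifying
#'   cleavage sites ("5' side of G").
#' @export
g_class_codes <- function(residues = residue_table()) {
  residues$code[residues$g_class]
}
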