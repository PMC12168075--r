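#' Parse an RNA sequence string
#'
#' Accepts plain 5'->3' sequence text with optional bracketed modification
#' tokens (`"ACCC[c3G]CAAGG..."`). Whitespace is ignored, so sequences
#' printed in 5-residue blocks parse as written. Bare modification tokens
#' (`"ACCCc3G..."`) are also accepted: tokenisation is greedy
#' longest-match, which is unambiguous because modified tokens start with a
#' lowercase letter.
#'
#' @param text Sequence string.
#' @param five_prime,three_prime Terminus chemistry. All fixture sequences
#'   are synthesized 5'-OH to 3'-OH, the default.
#' @param residues Residue table, see [residue_table()].
#' @return An `rna_sequence`: residues in 1-based 5'->3' order plus terminus
#'   chemistry. Cleavage site k denotes the phosphodiester between residues
#'   k and k+1.
#' @examples
#' parse_rna("GGCUA GCC")
#' parse_rna("ACCC[c3G] CAAGG CCGAC GGC")
#' @export
parse_rna <- function(text, five_prime = c("OH", "phosphate"),
                      three_prime = c("OH", "phosphate", "cyclic_phosphate"),
                      residues = residue_table()) {
  if (inherits(text, "rna_sequence")) return(text)
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  stopifnot(is.character(text), length(text) == 1L)

  codes <- residues$code[order(-nchar(residues$code))]
  chars <- strsplit(text, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)
      if (length(close) == 0) {
        stop("unclosed '[' at offset ", i, call. = FALSE)
      }
      close <- close[1]
      token <- paste(chars[(i + 1):(close - 1)], collapse = "")
      if (!token %in% codes) {
        stop("unknown residue token '", token, "' at offset ", i,
             call. = FALSE)
      }
      out <- c(out, token)
      i <- close + 1L
      next
    }
    matched <- FALSE
    for (code in codes) {
      len <- nchar(code)
      if (i + len - 1L <= n &&
          paste(chars[i:(i + len - 1L)], collapse = "") == code) {
        out <- c(out, code)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("unknown residue token '", ch, "' at offset ", i, call. = FALSE)
    }
  }
  if (length(out) == 0) stop("empty sequence", call. = FALSE)
  new_rna_sequence(out, five_prime, three_prime)
}

new_rna_sequence <- function(residues, five_prime = "OH", three_prime = "OH") {
  structure(
    list(residues = residues, five_prime = five_prime,
         three_prime = three_prime),
    class = "rna_sequence"
  )
}

#' @export
length.rna_sequence <- function(x) length(x$residues)

#' @export
print.rna_sequence <- function(x, ...) {
  tokens <- ifelse(nchar(x$residues) > 1, paste0("[", x$residues, "]"),
                   x$residues)
  cat("<rna_sequence> ", length(x), " nt, 5'-", x$five_prime, " / 3'-",
      x$three_prime, "\n  ", paste(tokens, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rna_sequence <- function(x, ...) {
  tokens <- ifelse(nchar(x$residues) > 1, paste0("[", x$residues, "]"),
                   x$residues)
  paste(tokens, collapse = "")
}

#' Sequence as a position table
#'
#' @param x An `rna_sequence`.
#' @param ... Unused.
#' @return A tibble with `position` (1-based, 5'->3'), `code` and `g_class`.
#' @importFrom tibble as_tibble
#' @method as_tibble rna_sequence
#' @export
as_tibble.rna_sequence <- function(x, ...) {
  rt <- residue_table()
  tibble::tibble(
    position = seq_along(x$residues),
    code = x$residues,
    g_class = x$residues %in% g_class_codes(rt)
  )
}

#' Elemental composition of an RNA
#'
#' Sum of the nucleoside compositions plus one HPO3 - H2O condensation per
#' internal phosphodiester linkage (N - 1 of them), adjusted for non-hydroxyl
#' termini: a terminal phosphate adds HPO3, a 2',3'-cyclic phosphate adds
#' HPO3 - H2O.
#'
#' @param seq An `rna_sequence` or sequence string.
#' @param residues Residue table.
#' @return An `elemental_composition`.
#' @examples
#' composition_of("G") # guanosine, C10H13N5O5
#' @export
composition_of <- function(seq, residues = residue_table()) {
  seq <- parse_rna(seq, residues = residues)
  n <- length(seq)
  total <- comp()
  for (code in seq$residues) {
    total <- total + residue_composition(code, "nucleoside", residues)
  }
  # (n - 1) linkages: add HPO3 then remove H2O so intermediates stay valid
  total <- total + (n - 1) * .COMP_HPO3()
  total <- total - (n - 1) * .COMP_H2O()
  if (seq$five_prime == "phosphate") total <- total + .COMP_HPO3()
  if (seq$three_prime == "phosphate") total <- total + .COMP_HPO3()
  if (seq$three_prime == "cyclic_phosphate") {
    total <- total + .COMP_HPO3()
    total <- total - .COMP_H2O()
  }
  total
}

#' Mass difference between two residues
#'
#' Monoisotopic nucleoside mass difference `code_a - code_b`; the mass shift
#' a single substitution imparts on an intact RNA or any fragment retaining
#' that position.
#'
#' @param code_a,code_b Residue codes.
#' @return Mass difference in Da.
#' @examples
#' modification_delta("m22G", "G") # +28.031 Da, dimethylation
#' modification_delta("I", "G")    # -15.011 Da, loss of NH
#' @export
modification_delta <- function(code_a, code_b) {
  rt <- residue_table()
  i <- match(c(code_a, code_b), rt$code)
  if (anyNA(i)) {
    stop("unknown residue code(s): ",
         paste(c(code_a, code_b)[is.na(i)], collapse = ", "), call. = FALSE)
  }
  rt$nucleoside_mass[i[1]] - rt$nucleoside_mass[i[2]]
}

#' The packaged study sequences
#'
#' The twelve synthetic RNAs used throughout the package examples and tests:
#' an 18-nt twister-sister-derived sequence, a 27-nt XIST-repeat sequence and
#' a palindromic 8-mer, each unmodified and with site-specific deaza, methyl
#' or inosine substitutions. All have 5'-OH and 3'-OH termini.
#'
#' @return A tibble with `id`, `sequence`, `nt` and `note`.
#' @examples
#' rna_studied()
#' @export
rna_studied <- function() {
  path <- system.file("extdata", "rna_studied.tsv", package = "rnacleave")
  out <- tibble::as_tibble(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  )
  out
}
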