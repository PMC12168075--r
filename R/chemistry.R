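# Elemental bookkeeping for RNA mass calculations.
#
# All masses are monoisotopic (lightest isotope); constants carry >= 7
# decimals so that sequence masses agree with reference calculators at the
# third decimal even for ~9 kDa oligonucleotides.

.ELEMENTS <- c("C", "H", "N", "O", "P")

.ATOMIC_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)

.PROTON_MASS <- 1.00727646

# mean spacing between adjacent isotopologues of C/H/N/O/P species
.ISOTOPE_SPACING <- 1.00336

#' Elemental composition
#'
#' Builds an elemental composition over C, H, N, O and P, the only elements
#' occurring in unlabelled RNA. Compositions support `+`, `-` and scalar `*`;
#' subtraction that would drive any element negative is an error, because a
#' molecular composition cannot owe atoms.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return An object of class `elemental_composition` (a named numeric
#'   vector).
#' @examples
#' comp(C = 10, H = 13, N = 5, O = 5) # guanosine
#' @export
comp <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  x <- c(C = C, H = H, N = N, O = O, P = P)
  new_composition(x)
}

new_composition <- function(x) {
  stopifnot(is.numeric(x), all(.ELEMENTS %in% names(x)))
  x <- x[.ELEMENTS]
  if (any(x < 0)) {
    bad <- names(x)[x < 0]
    stop("negative atom count for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(x, class = "elemental_composition")
}

#' Parse a molecular formula string
#'
#' @param formula A formula such as `"C10H13N5O5"`. Only C, H, N, O, P are
#'   accepted.
#' @return An `elemental_composition`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("\\s", "", formula)
  x <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  if (nzchar(s)) {
    pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(nchar(pieces)) != nchar(s)) {
      stop("cannot parse formula: ", formula, call. = FALSE)
    }
    for (p in pieces) {
      el <- gsub("[0-9]", "", p)
      n <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% .ELEMENTS) {
        stop("unsupported element '", el, "' in formula ", formula,
             call. = FALSE)
      }
      x[el] <- x[el] + n
    }
  }
  new_composition(x)
}

#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (.Generic == "+") {
    return(new_composition(unclass(e1) + unclass(e2)))
  }
  if (.Generic == "-") {
    res <- unclass(e1) - unclass(e2)
    if (any(res < -1e-9)) {
      bad <- names(res)[res < 0]
      stop("composition subtraction would give negative count for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(new_composition(pmax(res, 0)))
  }
  if (.Generic == "*") {
    scalar <- if (inherits(e1, "elemental_composition")) e2 else e1
    cc <- if (inherits(e1, "elemental_composition")) e1 else e2
    stopifnot(is.numeric(scalar), length(scalar) == 1L, scalar >= 0)
    return(new_composition(unclass(cc) * scalar))
  }
  if (.Generic == "==") {
    return(isTRUE(all.equal(unclass(e1)[.ELEMENTS], unclass(e2)[.ELEMENTS])))
  }
  stop("operation '", .Generic, "' not defined for compositions",
       call. = FALSE)
}

#' @export
format.elemental_composition <- function(x, ...) {
  v <- unclass(x)
  v <- v[v != 0]
  if (length(v) == 0) return("(empty)")
  paste0(names(v), ifelse(v == 1, "", format(v, trim = TRUE)), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition> ", format(x), "  (", sprintf("%.4f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass
#'
#' Computes the neutral monoisotopic mass, i.e. the sum over all atoms of the
#' lightest-isotope atomic mass.
#'
#' @param x An `elemental_composition`, an `rna_sequence`, or a character
#'   sequence string (parsed with [parse_rna()]).
#' @param ... Passed to methods.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(comp(H = 2, O = 1)) # water, 18.0106 Da
#' monoisotopic_mass("GGCUAGCC")
#' @export
monoisotopic_mass <- function(x, ...) UseMethod("monoisotopic_mass")

#' @export
monoisotopic_mass.elemental_composition <- function(x, ...) {
  sum(unclass(x) * .ATOMIC_MASS[names(unclass(x))])
}

#' @export
monoisotopic_mass.rna_sequence <- function(x, ...) {
  monoisotopic_mass(composition_of(x))
}

#' @export
monoisotopic_mass.character <- function(x, ...) {
  monoisotopic_mass(parse_rna(x, ...))
}

# fixed small-molecule compositions used throughout the fragment chemistry
.COMP_H2O <- function() comp(H = 2, O = 1)
.COMP_HPO3 <- function() comp(H = 1, O = 3, P = 1)

mass_h2o <- function() monoisotopic_mass(.COMP_H2O())
mass_hpo3 <- function() monoisotopic_mass(.COMP_HPO3())
# internal phosphodiester linkage increment: condensation of HPO3 with loss
# of water (net H-1 O2 P per linkage)
mass_linkage <- function() mass_hpo3() - mass_h2o()

#' Proton mass used for m/z conversion
#'
#' Charged species are modelled as pure deprotonation: an (M - nH)^n- ion has
#' lost n protons. No further electron-mass correction is applied.
#'
#' @return The proton mass in Da.
#' @export
proton_mass <- function() .PROTON_MASS
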