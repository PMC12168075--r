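# Peak-list to fragment matching.
#
# The isotope-fit rule is deliberately transparent (vendor deisotoping
# algorithms are proprietary): a candidate is accepted when a run of
# consecutive isotopologues matches within tolerance and the observed
# intensities correlate with the theoretical envelope (cosine >= 0.9).

#' Match a peak list against theoretical fragments
#'
#' For each candidate ion, the peak cluster at `mz + k * 1.00336 / z` is
#' located. The candidate is accepted if at least `min_isotopologues`
#' consecutive isotopologues each match within `tol_ppm` and the matched
#' intensities have cosine similarity >= `min_cosine` with the theoretical
#' pattern. For heavy fragments whose monoisotopic peak is below the noise
#' floor, the matched run may start at k > 0, up to the theoretical pattern
#' apex. A major isotopologue peak (>= 5% of the envelope) claimed by more
#' than one accepted candidate marks all involved assignments ambiguous;
#' ambiguous assignments are excluded from statistics by default.
#'
#' @param peaks A tibble with `mz` and `intensity` (centroided).
#' @param candidates Fragment table from [enumerate_fragments()] (the
#'   `composition` list-column, when present, drives exact isotope
#'   patterns; otherwise an averagine pattern is used).
#' @param tol_ppm Match tolerance in ppm.
#' @param min_isotopologues Minimum consecutive isotopologues (capped at the
#'   pattern length).
#' @param min_cosine Minimum isotope-envelope cosine similarity.
#' @return A tibble of assignments: fragment identity columns, `mz_theo`
#'   (monoisotopic), `mz_obs` (first matched isotopologue), `abundance`
#'   (summed matched intensity), `mass_error_ppm` (intensity-weighted),
#'   `n_isotopologues`, `ambiguous`, `calibrant`.
#' @export
match_fragments <- function(peaks, candidates, tol_ppm = 3,
                            min_isotopologues = 2, min_cosine = 0.9) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("candidate list is empty", call. = FALSE)
  }
  stopifnot(tol_ppm > 0)
  empty <- tibble::tibble(
    ion_type = character(), index = integer(), base_loss = integer(),
    charge = integer(), neutral_mass = numeric(), mz_theo = numeric(),
    mz_obs = numeric(), abundance = numeric(), mass_error_ppm = numeric(),
    n_isotopologues = integer(), ambiguous = logical(), calibrant = logical()
  )
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)
  peaks <- dplyr::arrange(peaks, .data$mz)
  mzv <- peaks$mz
  intv <- peaks$intensity

  has_comp <- "composition" %in% names(candidates)
  pat_cache <- new.env(parent = emptyenv())
  results <- list()
  used_peaks <- list()
  for (r in seq_len(nrow(candidates))) {
    if (has_comp && !is.null(candidates$composition[[r]])) {
      key <- format(candidates$composition[[r]])
      pat <- pat_cache[[key]]
      if (is.null(pat)) {
        pat <- isotope_pattern(candidates$composition[[r]])
        pat_cache[[key]] <- pat
      }
    } else {
      pat <- isotope_pattern(candidates$neutral_mass[r], mode = "averagine")
    }
    z <- candidates$charge[r]
    theo_mz <- candidates$mz[r] + pat$offset / z
    # nearest peak per isotopologue
    lo <- findInterval(theo_mz, mzv)
    hi <- pmin(lo + 1L, length(mzv))
    lo <- pmax(lo, 1L)
    d_lo <- abs(mzv[lo] - theo_mz)
    d_hi <- abs(mzv[hi] - theo_mz)
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    err_ppm <- (mzv[nearest] - theo_mz) / theo_mz * 1e6
    matched <- abs(err_ppm) <= tol_ppm

    if (!any(matched)) next
    runs <- rle(matched)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    apex <- which.max(pat$abundance)
    need <- min(min_isotopologues, nrow(pat))
    ok <- which(runs$values & runs$lengths >= need & starts <= apex)
    if (length(ok) == 0) next
    # prefer the run covering the most theoretical abundance
    cover <- vapply(ok, function(i) sum(pat$abundance[starts[i]:ends[i]]), 0)
    best <- ok[which.max(cover)]
    ks <- starts[best]:ends[best]
    obs <- intv[nearest[ks]]
    theo <- pat$abundance[ks]
    cosine <- sum(obs * theo) / sqrt(sum(obs^2) * sum(theo^2))
    if (length(ks) > 1 && cosine < min_cosine) next

    w <- obs / sum(obs)
    results[[length(results) + 1L]] <- tibble::tibble(
      ion_type = candidates$ion_type[r], index = candidates$index[r],
      base_loss = candidates$base_loss[r], charge = z,
      neutral_mass = candidates$neutral_mass[r],
      mz_theo = candidates$mz[r], mz_obs = mzv[nearest[ks[1]]],
      abundance = sum(obs), mass_error_ppm = sum(w * err_ppm[ks]),
      n_isotopologues = length(ks), ambiguous = FALSE, calibrant = FALSE
    )
    # only major isotopologues (>= 5% of the envelope) assert ownership of
    # a peak; tail isotopologues overlapping another cluster do not make
    # two otherwise clean assignments ambiguous
    used_peaks[[length(used_peaks) + 1L]] <- nearest[ks][pat$relative[ks] >=
                                                           0.05]
  }
  if (length(results) == 0) return(empty)
  out <- dplyr::bind_rows(results)
  all_used <- unlist(used_peaks)
  shared <- unique(all_used[duplicated(all_used)])
  if (length(shared) > 0) {
    out$ambiguous <- vapply(used_peaks, function(u) any(u %in% shared),
                            logical(1))
  }
  out
}

#' Internal recalibration against assigned fragments
#'
#' Fits a least-squares linear model of theoretical on observed m/z over the
#' calibrant assignments and applies it to every peak, the standard internal
#' calibration used when confidently assigned c/y fragments span the m/z
#' range.
#'
#' @param peaks A peak-list tibble (`mz`, `intensity`).
#' @param calibrants An assignment tibble (needs `mz_obs`, `mz_theo`), at
#'   least two distinct m/z values spanning the range.
#' @return The recalibrated peak list; the fitted model, the
#'   post-calibration calibrant residuals (ppm) and their median absolute
#'   value are attached as the `calibration` attribute.
#' @export
recalibrate_internal <- function(peaks, calibrants) {
  if (is.null(calibrants) || nrow(calibrants) < 2) {
    stop("internal recalibration needs at least 2 calibrant assignments",
         call. = FALSE)
  }
  if (stats::sd(calibrants$mz_obs) < 1e-9) {
    stop("degenerate calibrant set: all calibrants at one m/z",
         call. = FALSE)
  }
  fit <- stats::lm(mz_theo ~ mz_obs, data = calibrants)
  corrected <- stats::predict(fit,
                              newdata = data.frame(mz_obs = peaks$mz))
  out <- peaks
  out$mz <- as.numeric(corrected)
  cal_fit <- stats::predict(fit)
  residual_ppm <- (cal_fit - calibrants$mz_theo) / calibrants$mz_theo * 1e6
  attr(out, "calibration") <- list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    residual_ppm = residual_ppm,
    median_abs_residual_ppm = stats::median(abs(residual_ppm)),
    n_calibrants = nrow(calibrants)
  )
  out
}

#' Pool assignments over charge states
#'
#' Sums abundance over charge for each (ion type, index, base loss),
#' keeping the per-charge breakdown for charge-value analyses. Ambiguous
#' assignments are dropped first.
#'
#' @param assignments Output of [match_fragments()].
#' @return A tibble keyed by `ion_type`, `index`, `base_loss` with
#'   `abundance` (charge-summed) and a `charges` list-column of per-charge
#'   tibbles.
#' @export
aggregate_charge_states <- function(assignments) {
  empty <- tibble::tibble(
    ion_type = character(), index = integer(), base_loss = integer(),
    abundance = numeric(), charges = list()
  )
  if (is.null(assignments) || nrow(assignments) == 0) return(empty)
  keep <- assignments[!assignments$ambiguous, , drop = FALSE]
  if (nrow(keep) == 0) return(empty)
  grp <- dplyr::group_by(keep, .data$ion_type, .data$index, .data$base_loss)
  out <- dplyr::summarise(
    grp,
    charges = list(tibble::tibble(charge = charge, abundance = abundance)),
    abundance = sum(.data$abundance),
    .groups = "drop"
  )
  out[, c("ion_type", "index", "base_loss", "abundance", "charges")]
}
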