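# Alkaline-hydrolysis products h_i-j and their kinetics.
#
# Hydrolysis in basic solution cleaves the backbone by the same
# transesterification as gas-phase c/y formation: the 5'-terminal product
# carries a 2',3'-cyclic phosphate (which can open to the linear
# 2'/3'-phosphate, isobaric forms not distinguished) and the 3'-terminal
# product a 5'-OH. Only products retaining an original terminus are
# analysed; interior (multiply cleaved) products are representable but
# flagged excluded.

#' Enumerate hydrolysis products
#'
#' All single-cut products of an N-mer: for every site k the 5'-terminal
#' piece h_1-k in its cyclic and linear 3'-phosphate forms, and the
#' 3'-terminal piece h_(k+1)-N with free 5'-OH - 3(N-1) species.
#'
#' @param seq An `rna_sequence` or string (OH/OH termini).
#' @return A tibble with `species`, `i`, `j`, `form` (`"cyclic"`,
#'   `"linear"`, `"OH"`), `site` (generating cut site), `neutral_mass` and
#'   a `composition` list-column.
#' @examples
#' enumerate_h_products("GGCUAGCC") # 21 species for an 8-mer
#' @export
enumerate_h_products <- function(seq) {
  seq <- parse_rna(seq)
  N <- length(seq)
  sites <- seq_len(N - 1L)
  cyc <- tibble::tibble(
    species = paste0("h_1-", sites), i = 1L, j = sites, form = "cyclic",
    site = sites,
    neutral_mass = fragment_neutral_mass(seq, "c", sites)
  )
  lin <- tibble::tibble(
    species = paste0("h_1-", sites), i = 1L, j = sites, form = "linear",
    site = sites,
    neutral_mass = fragment_neutral_mass(seq, "d", sites)
  )
  oh <- tibble::tibble(
    species = paste0("h_", sites + 1L, "-", N), i = sites + 1L, j = N,
    form = "OH", site = sites,
    neutral_mass = fragment_neutral_mass(seq, "y", N - sites)
  )
  out <- dplyr::bind_rows(cyc, lin, oh)
  out$composition <- purrr::pmap(
    list(out$form, out$site),
    function(fm, k) {
      it <- switch(fm, cyclic = "c", linear = "d", OH = "y")
      ix <- if (fm == "OH") N - k else k
      fragment_composition(seq, it, ix)
    }
  )
  out
}

#' Render a hydrolysis abundance table as a peak list
#'
#' Turns the species counts of one time point from
#' [simulate_hydrolysis_timecourse()] into an ESI peak list: every
#' non-excluded species (plus intact RNA) becomes its isotope envelope at
#' the given charge, with the same noise model as the CAD simulator.
#'
#' @param abundances One time point of a hydrolysis time course.
#' @param seq The sequence.
#' @param charge Charge state at which species are observed.
#' @param noise Noise settings, see [noise_default()].
#' @return A peak-list tibble (`mz`, `intensity`).
#' @export
render_hydrolysis_spectrum <- function(abundances, seq, charge = 1,
                                       noise = noise_off()) {
  seq <- parse_rna(seq)
  stopifnot(length(unique(abundances$time)) == 1)
  ab <- abundances[!abundances$excluded, , drop = FALSE]
  rows <- purrr::pmap(
    list(ab$species, ab$form, ab$site, ab$count),
    function(sp, fm, k, cnt) {
      if (cnt == 0) return(NULL)
      cc <- if (sp == "intact") {
        composition_of(seq)
      } else {
        it <- switch(fm, cyclic = "c", linear = "d", OH = "y")
        ix <- if (fm == "OH") length(seq) - k else k
        fragment_composition(seq, it, ix)
      }
      pat <- isotope_pattern(cc)
      mz0 <- mz_negative(monoisotopic_mass(cc), charge)
      tibble::tibble(mz = mz0 + pat$offset / charge,
                     intensity = cnt * pat$abundance)
    }
  )
  peaks <- dplyr::bind_rows(rows)
  if (noise$cv > 0 && nrow(peaks) > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    peaks$intensity <- peaks$intensity *
      stats::rlnorm(nrow(peaks), -sdlog^2 / 2, sdlog)
  }
  if (noise$ppm_sd > 0 && nrow(peaks) > 0) {
    peaks$mz <- peaks$mz * (1 + stats::rnorm(nrow(peaks)) *
                              noise$ppm_sd * 1e-6)
  }
  dplyr::arrange(peaks, .data$mz)
}

#' Assign a hydrolysis spectrum and compute site-specific yields
#'
#' Matches a peak list against all single-cut hydrolysis products plus the
#' intact RNA, then computes per-site yields: 100 x (abundance of both
#' terminal products of the site, cyclic and linear 3'-forms pooled) /
#' (total assigned product + intact abundance).
#'
#' @param peaks Peak-list tibble.
#' @param seq The sequence.
#' @param tol_ppm Match tolerance in ppm.
#' @param max_charge Highest charge state to consider.
#' @return A list with `assignments` and `site_yields` (tibble of `site`,
#'   `yield` percent, `g_site`).
#' @export
assign_hydrolysis_spectrum <- function(peaks, seq, tol_ppm = 3,
                                       max_charge = 1) {
  seq <- parse_rna(seq)
  N <- length(seq)
  products <- enumerate_h_products(seq)
  intact <- tibble::tibble(
    species = "intact", i = 1L, j = N, form = "intact", site = NA_integer_,
    neutral_mass = monoisotopic_mass(seq),
    composition = list(composition_of(seq))
  )
  cand <- dplyr::bind_rows(products, intact)
  cand <- tidyr::crossing(cand, charge = seq_len(max_charge))
  cand$charge <- as.integer(cand$charge)
  cand$mz <- mz_negative(cand$neutral_mass, cand$charge)
  # reuse the fragment matcher; carry species identity through ion_type
  cand$ion_type <- paste(cand$species, cand$form)
  cand$index <- cand$site
  cand$base_loss <- NA_integer_
  asg <- match_fragments(peaks, cand, tol_ppm = tol_ppm)
  if (nrow(asg) == 0) stop("no hydrolysis species assigned", call. = FALSE)
  asg <- dplyr::left_join(
    asg,
    dplyr::distinct(cand[, c("ion_type", "species", "form", "site")]),
    by = "ion_type"
  )
  keep <- asg[!asg$ambiguous, , drop = FALSE]
  total <- sum(keep$abundance)
  site_ab <- dplyr::summarise(
    dplyr::group_by(keep[!is.na(keep$site), , drop = FALSE], .data$site),
    abundance = sum(.data$abundance), .groups = "drop"
  )
  g_idx <- g_sites_of(seq)
  yields <- tibble::tibble(site = seq_len(N - 1L))
  yields$yield <- 100 *
    as.numeric(site_ab$abundance[match(yields$site, site_ab$site)]) / total
  yields$yield[is.na(yields$yield)] <- 0
  yields$g_site <- yields$site %in% g_idx
  list(assignments = asg, site_yields = yields)
}

#' Per-site yields from a simulated hydrolysis time course
#'
#' The counting analogue of [assign_hydrolysis_spectrum()]: per-site yield
#' at each time is the summed count of both terminal products of the site
#' (3'-forms pooled) over the total non-excluded product plus intact count.
#'
#' @param timecourse Output of [simulate_hydrolysis_timecourse()].
#' @param seq The sequence.
#' @return A tibble with `time`, `site`, `yield` (percent), `g_site`.
#' @export
hydrolysis_site_yields <- function(timecourse, seq) {
  seq <- parse_rna(seq)
  N <- length(seq)
  g_idx <- g_sites_of(seq)
  tc <- timecourse[!timecourse$excluded, , drop = FALSE]
  out <- purrr::map(unique(tc$time), function(t) {
    at <- tc[tc$time == t, , drop = FALSE]
    total <- sum(at$count)
    per_site <- dplyr::summarise(
      dplyr::group_by(at[!is.na(at$site), , drop = FALSE], .data$site),
      count = sum(.data$count), .groups = "drop"
    )
    y <- tibble::tibble(time = t, site = seq_len(N - 1L))
    y$yield <- 100 *
      as.numeric(per_site$count[match(y$site, per_site$site)]) / total
    y$yield[is.na(y$yield)] <- 0
    y$g_site <- y$site %in% g_idx
    y
  })
  dplyr::bind_rows(out)
}

#' Estimate per-site hydrolysis rate constants
#'
#' Fits the competing-risks single-cut model to time-resolved site yields.
#' Yields are first converted to per-molecule first-cut fractions f_k(t)
#' (inverting the yield denominator, which counts two products per cut plus
#' intact), then the total rate k_tot is fitted by nonlinear least squares
#' on f(t) = 1 - exp(-k_tot t) and the per-site shares s_k by least squares
#' through the origin of f_k(t) on f(t); k_site = s_k k_tot with standard
#' errors combined by the delta method.
#'
#' @param site_yields Tibble with `time`, `site`, `yield` as produced by
#'   [hydrolysis_site_yields()] (at least 3 time points).
#' @return A `hydrolysis_rates` object; use [generics::tidy()] for per-site
#'   estimates and [generics::glance()] for the fit summary.
#' @export
rate_estimate <- function(site_yields) {
  times <- sort(unique(site_yields$time))
  if (length(times) < 3) {
    stop("rate estimation needs at least 3 time points", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    site_yields[, c("time", "site", "yield")],
    names_from = "site", values_from = "yield", values_fill = 0
  )
  wide <- wide[order(wide$time), , drop = FALSE]
  ymat <- as.matrix(wide[, -1, drop = FALSE]) / 100 # site x time fractions
  sites <- as.integer(colnames(wide)[-1])
  tv <- wide$time

  # invert the yield convention: y_k = 2 f_k / (1 + f), sum_k y = 2f/(1+f)
  S <- rowSums(ymat)
  S <- pmin(S, 2 - 1e-9)
  f_tot <- S / (2 - S)
  fmat <- ymat * (1 + f_tot) / 2

  nonmono <- any(diff(f_tot) < -0.05)
  if (max(f_tot) < 1e-9) {
    est <- tibble::tibble(site = sites, k = 0, se = 0)
    return(structure(list(estimates = est, k_tot = 0, k_tot_se = 0,
                          n_times = length(tv), warning_nonmonotone = FALSE),
                     class = "hydrolysis_rates"))
  }
  fit <- stats::nls(f_tot ~ 1 - exp(-k * tv),
                    start = list(k = max(1e-6, -log(1 - max(f_tot) * 0.9) /
                                           max(tv))),
                    control = stats::nls.control(warnOnly = TRUE))
  k_tot <- unname(stats::coef(fit)["k"])
  k_tot_se <- tryCatch(sqrt(stats::vcov(fit)[1, 1]), error = function(e) NA)

  # shares: regression through the origin of f_k on f_tot
  denom <- sum(f_tot^2)
  shares <- as.numeric(crossprod(fmat, f_tot)) / denom
  shares <- pmax(shares, 0)
  resid <- fmat - outer(f_tot, shares)
  df <- max(1L, length(tv) - 1L)
  share_se <- sqrt(colSums(resid^2) / df / denom)

  k_site <- shares * k_tot
  k_se <- sqrt(shares^2 * k_tot_se^2 + k_tot^2 * share_se^2)
  est <- tibble::tibble(site = sites, k = k_site, se = k_se,
                        share = shares)
  structure(
    list(estimates = est, k_tot = k_tot, k_tot_se = k_tot_se,
         n_times = length(tv), warning_nonmonotone = nonmono),
    class = "hydrolysis_rates"
  )
}

#' @export
print.hydrolysis_rates <- function(x, ...) {
  cat("<hydrolysis_rates> k_tot = ", sprintf("%.4g", x$k_tot), " 1/h over ",
      x$n_times, " time points\n", sep = "")
  if (x$warning_nonmonotone) {
    cat("  warning: grossly non-monotone yields\n")
  }
  print(x$estimates)
  invisible(x)
}

#' @method tidy hydrolysis_rates
#' @export
tidy.hydrolysis_rates <- function(x, ...) {
  tibble::tibble(site = x$estimates$site, estimate = x$estimates$k,
                 std.error = x$estimates$se)
}

#' @method glance hydrolysis_rates
#' @export
glance.hydrolysis_rates <- function(x, ...) {
  tibble::tibble(k_tot = x$k_tot, k_tot_se = x$k_tot_se,
                 n_times = x$n_times,
                 nonmonotone = x$warning_nonmonotone)
}
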