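# Fragment matching, recalibration and charge-state pooling.

test_that("empty inputs behave as declared", {
  cand <- enumerate_fragments(SEQ8, c("c", "y"), 2)
  expect_error(match_fragments(tibble::tibble(mz = 1, intensity = 1),
                               cand[0, ]), "empty")
  out <- match_fragments(tibble::tibble(mz = numeric(),
                                        intensity = numeric()), cand)
  expect_equal(nrow(out), 0)
})

test_that("wrong-sequence candidates fail where the masses shift", {
  sim <- simulate_cad_spectrum(SEQ18, 7, cleavage_model(
    base_loss_fraction = 0), n_ions = 2e4, noise = noise_off(), seed = 14)
  # change residue 9 (G -> A): every fragment retaining position 9 shifts
  s <- parse_rna(SEQ18)
  wrong <- s
  wrong$residues[9] <- "A"
  cand <- enumerate_fragments(wrong, c("c", "y"), max_charge = 7)
  asg <- match_fragments(sim$peaks, cand)
  # c_i with i >= 9 and y_j with j >= 10 span the changed residue
  spanning <- (asg$ion_type == "c" & asg$index >= 9) |
    (asg$ion_type == "y" & asg$index >= 10)
  expect_equal(sum(spanning), 0)
  expect_gt(sum(!spanning), 0)
})

test_that("recovery stays above 95% under realistic noise", {
  sim <- simulate_cad_spectrum(SEQ18, 7, n_ions = 5e4,
                               noise = noise_default(cv = 0.1, ppm_sd = 1,
                                                     n_noise_peaks = 20),
                               seed = 77)
  cand <- cy_candidates(SEQ18, 7)
  asg <- match_fragments(sim$peaks, cand, tol_ppm = 3)
  truth <- sim$truth$species_visible
  truth <- truth[truth$ion_type %in% c("c", "y", "precursor"), ]
  # fragments with >= 3 isotopologues above ~1% envelope abundance count
  # as confidently visible; require nearly all of them recovered
  visible_key <- species_key(truth, SEQ18)
  matched_key <- species_key(asg, SEQ18)
  # confidently visible species: enough ions that >= 3 isotopologues are
  # clearly above the chemical-noise floor
  confident <- truth$count >= 3
  recovered <- mean(visible_key[confident] %in% matched_key)
  expect_gte(recovered, 0.95)
})

test_that("internal recalibration removes an injected linear error", {
  sim <- simulate_cad_spectrum(SEQ18, 7, n_ions = 1e4,
                               noise = noise_off(), seed = 19)
  pk <- sim$peaks
  pk$mz <- pk$mz * (1 + 2e-6) + 0.001 # +2 ppm plus constant offset
  cand <- enumerate_fragments(SEQ18, c("c", "y"), max_charge = 7)
  cal_asg <- match_fragments(pk, cand, tol_ppm = 10)
  expect_gt(stats::median(abs(cal_asg$mass_error_ppm)), 1)
  rec <- recalibrate_internal(pk, cal_asg)
  cal <- attr(rec, "calibration")
  expect_lt(cal$median_abs_residual_ppm, 0.5)

  # re-matching the corrected list confirms the residual error is gone
  asg2 <- match_fragments(rec, cand, tol_ppm = 10)
  expect_lt(stats::median(abs(asg2$mass_error_ppm)), 0.5)

  # an already-calibrated spectrum passes through unchanged
  asg0 <- match_fragments(sim$peaks, cand, tol_ppm = 10)
  rec0 <- recalibrate_internal(sim$peaks, asg0)
  expect_equal(rec0$mz, sim$peaks$mz, tolerance = 1e-9)

  # recalibration never worsens the median calibrant residual
  before <- stats::median(abs(cal_asg$mass_error_ppm))
  expect_lte(cal$median_abs_residual_ppm, before)

  expect_error(recalibrate_internal(pk, cal_asg[1, ]), "at least 2")
  degen <- cal_asg[c(1, 1), ]
  expect_error(recalibrate_internal(pk, degen), "degenerate")
})

test_that("charge-state pooling sums abundance and keeps the breakdown", {
  asg <- tibble::tibble(
    ion_type = c("c", "c"), index = c(8L, 8L), base_loss = NA_integer_,
    charge = c(2L, 3L), abundance = c(100, 50), ambiguous = FALSE
  )
  agg <- aggregate_charge_states(asg)
  expect_equal(agg$abundance, 150)
  expect_equal(sort(agg$charges[[1]]$charge), c(2, 3))
  empty <- aggregate_charge_states(asg[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("pooled synthetic abundances track ground-truth event counts", {
  sim <- simulate_cad_spectrum(SEQ18, 7, cleavage_model(
    base_loss_fraction = 0), n_ions = 5e4, noise = noise_off(), seed = 23)
  cand <- enumerate_fragments(SEQ18, c("c", "y"), max_charge = 7)
  asg <- match_fragments(sim$peaks, cand)
  agg <- aggregate_charge_states(asg)
  # per (type, index) abundance should equal charge-weighted truth counts
  sp <- sim$truth$species_visible
  sp <- sp[sp$ion_type %in% c("c", "y"), ]
  truth_tot <- dplyr::summarise(
    dplyr::group_by(sp, ion_type, index),
    truth = sum(count * charge), .groups = "drop"
  )
  j <- dplyr::inner_join(agg, truth_tot, by = c("ion_type", "index"))
  expect_gt(nrow(j), 25)
  expect_equal(j$abundance, j$truth, tolerance = 0.02)
})
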