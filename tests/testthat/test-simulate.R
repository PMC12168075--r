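# Synthetic CAD spectra: determinism, ground-truth accounting, noise model.

test_that("the same seed reproduces the identical peak list", {
  a <- simulate_cad_spectrum(SEQ8, 3, n_ions = 5000, seed = 11)
  b <- simulate_cad_spectrum(SEQ8, 3, n_ions = 5000, seed = 11)
  expect_identical(a$peaks$mz, b$peaks$mz)
  expect_identical(a$peaks$intensity, b$peaks$intensity)
  c <- simulate_cad_spectrum(SEQ8, 3, n_ions = 5000, seed = 12)
  expect_false(identical(a$peaks$mz, c$peaks$mz))
})

test_that("precursor charge cannot exceed the phosphodiester count", {
  expect_error(simulate_cad_spectrum(SEQ8, 8, n_ions = 10), "charges")
  expect_silent({
    sim <- simulate_cad_spectrum(SEQ8, 7, n_ions = 10, seed = 1,
                                 noise = noise_off())
  })
})

test_that("with a flat model the site distribution is uniform", {
  m <- cleavage_model(gamma = 1 + 1e-12, precursor_survival = 0,
                      base_loss_fraction = 0)
  sim <- simulate_cad_spectrum(SEQ18, 7, m, n_ions = 4e5, seed = 5,
                               noise = noise_off(), render = FALSE)
  counts <- sim$truth$site_counts$count
  expect_equal(max(abs(counts / mean(counts) - 1)), 0, tolerance = 0.02)
})

test_that("ground-truth bookkeeping is self-consistent", {
  sim <- simulate_cad_spectrum(SEQ18, 7, n_ions = 1e5, seed = 9,
                               render = FALSE)
  tr <- sim$truth
  expect_equal(sum(tr$site_counts$count) + tr$n_survived, tr$n_ions)
  expect_equal(tr$site_counts$count,
               tr$site_counts$count_cy + tr$site_counts$count_aw)
  # multinomial expectation within 3 sd at each site
  p <- site_propensities(parse_rna(SEQ18), tr$model)
  exp_counts <- (1 - tr$model$precursor_survival) * tr$n_ions * p / sum(p)
  sd3 <- 3 * sqrt(exp_counts)
  expect_true(all(abs(tr$site_counts$count - exp_counts) <= sd3 + 1))
})

test_that("noise-free peaks sit exactly on theoretical fragment m/z", {
  sim <- simulate_cad_spectrum(SEQ8, 3, cleavage_model(ay_fraction = 0.2),
                               n_ions = 3000, noise = noise_off(), seed = 2)
  cand <- enumerate_fragments(SEQ8,
                              c("a", "c", "w", "y", "precursor"),
                              max_charge = 3, base_loss = TRUE)
  theo <- sort(unlist(purrr::map2(cand$composition, cand$charge, function(cc, z) {
    pat <- isotope_pattern(cc)
    mz_negative(monoisotopic_mass(cc), z) + pat$offset / z
  })))
  nearest <- theo[pmax(1, findInterval(sim$peaks$mz, theo))]
  nearest2 <- theo[pmin(length(theo),
                        findInterval(sim$peaks$mz, theo) + 1)]
  d <- pmin(abs(sim$peaks$mz - nearest), abs(sim$peaks$mz - nearest2))
  expect_lt(max(d), 1e-6)
})

test_that("charge is conserved across every complementary pair", {
  sim <- simulate_cad_spectrum(SEQ18, 7, n_ions = 2e4, seed = 21,
                               render = FALSE)
  sp <- sim$truth$species_visible
  # aggregate: summed 5'-side charge-weighted counts must mirror 3' side
  cy <- sp[sp$ion_type %in% c("c", "y") & is.na(sp$base_loss), ]
  n5 <- sum(cy$charge[cy$ion_type == "c"] * cy$count[cy$ion_type == "c"])
  n3 <- sum(cy$charge[cy$ion_type == "y"] * cy$count[cy$ion_type == "y"])
  events <- sim$truth$site_counts
  # total charge carried by all c/y fragments = 7 x (number of c/y events
  # without base loss); base loss moves events out of the c/y pool
  all_cy <- sp[sp$ion_type %in% c("c", "y"), ]
  expect_equal(sum(all_cy$charge * all_cy$count), 7 * sum(events$count_cy))
  expect_gt(n5, 0)
  expect_gt(n3, 0)
})

test_that("raising gamma raises the guanosine share of cleavages", {
  shares <- vapply(c(1, 2.75, 8), function(g) {
    m <- cleavage_model(gamma = g, precursor_survival = 0,
                        base_loss_fraction = 0)
    sim <- simulate_cad_spectrum(SEQ18, 7, m, n_ions = 5e4, seed = 33,
                                 render = FALSE)
    sc <- sim$truth$site_counts
    g_sites <- which(parse_rna(SEQ18)$residues[-1] == "G")
    sum(sc$count[g_sites]) / sum(sc$count)
  }, 0)
  expect_true(all(diff(shares) > 0))
  # and the analytic expectation is strictly increasing too
  expect_true(all(diff(vapply(c(1, 2, 4, 8), analytic_g_yield, 0,
                              seq = SEQ18)) > 0))
})

test_that("hydrolysis kinetics follow closed-form expectations", {
  N <- length(parse_rna(SEQ18))
  # all rates zero: intact forever
  tc0 <- simulate_hydrolysis_timecourse(SEQ18, rep(0, N - 1), c(0, 1, 10),
                                        n_molecules = 500, seed = 4)
  expect_true(all(tc0$species == "intact"))
  expect_true(all(tc0$count == 500))

  # one active site at its half-life: ~50% intact
  rates <- rep(0, N - 1)
  rates[5] <- 0.3
  tc <- simulate_hydrolysis_timecourse(SEQ18, rates, log(2) / 0.3,
                                       n_molecules = 1e4, seed = 8)
  intact <- tc$count[tc$species == "intact"]
  expect_equal(intact / 1e4, 0.5, tolerance = 3 * sqrt(0.25 / 1e4) / 0.5)

  # G-site rates doubled, long time: G share of first cuts ~ 12/23
  rates2 <- rep(1, N - 1)
  g_sites <- which(parse_rna(SEQ18)$residues[-1] == "G")
  rates2[g_sites] <- 2
  tc2 <- simulate_hydrolysis_timecourse(SEQ18, rates2, times = 50,
                                        n_molecules = 2e4, seed = 12)
  cuts <- tc2[tc2$species != "intact" & tc2$form != "OH", ]
  share <- sum(cuts$count[cuts$site %in% g_sites]) / sum(cuts$count)
  expect_equal(share, 2 * 6 / (2 * 6 + 11), tolerance = 0.03)

  expect_error(simulate_hydrolysis_timecourse(SEQ18, rates2, -1), "times")
  expect_error(simulate_hydrolysis_timecourse(SEQ18, -rates2, 1), "rates")
})

test_that("second cuts are flagged as excluded interior products", {
  N <- length(parse_rna(SEQ18))
  tc <- simulate_hydrolysis_timecourse(SEQ18, rep(0.5, N - 1), times = 4,
                                       n_molecules = 2000,
                                       multiple_cuts = TRUE, seed = 6)
  interior <- tc[tc$excluded, ]
  expect_gt(nrow(interior), 0)
  expect_true(all(interior$i > 1 & interior$j < N))
})
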