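# Cleavage-yield statistics and the guanosine-preference machinery.

make_asg <- function(...) {
  d <- tibble::tibble(...)
  if (!"base_loss" %in% names(d)) d$base_loss <- NA_integer_
  if (!"charge" %in% names(d)) d$charge <- 1L
  if (!"ambiguous" %in% names(d)) d$ambiguous <- FALSE
  d
}

test_that("site yields normalize to 100% and localize correctly", {
  # a single complementary pair: all yield at its site
  asg <- make_asg(ion_type = c("c", "y"), index = c(4L, 14L),
                  abundance = c(3, 5))
  yt <- site_specific_yields(asg, SEQ18, n = 7)
  expect_equal(sum(yt$yield), 100, tolerance = 1e-9)
  expect_equal(yt$yield[yt$site == 4], 100)
  expect_true(all(yt$yield[yt$site != 4] == 0))
  expect_equal(yt$yield_c[yt$site == 4], 37.5)
  expect_equal(yt$yield_y[yt$site == 4], 62.5)

  # base-loss variants pool into the parent before normalization
  asg2 <- make_asg(ion_type = c("c", "c"), index = c(4L, 4L),
                   base_loss = c(NA_integer_, 2L), abundance = c(3, 1))
  yt2 <- site_specific_yields(asg2, SEQ18)
  expect_equal(yt2$yield_c[yt2$site == 4], 100)

  expect_error(site_specific_yields(make_asg(
    ion_type = "a", index = 1L, abundance = 5), SEQ18), "no c/y")
})

test_that("a uniform run spreads yield evenly over all sites", {
  m <- cleavage_model(gamma = 1 + 1e-12, precursor_survival = 0,
                      base_loss_fraction = 0)
  sim <- simulate_cad_spectrum(SEQ18, 7, m, n_ions = 4e5, seed = 31,
                               render = FALSE)
  yt <- site_specific_yields(truth_assignments(sim), SEQ18, 7)
  expect_equal(yt$yield, rep(100 / 17, 17), tolerance = 0.05)
})

test_that("the random-cleavage null depends only on topology", {
  g18 <- overall_g_yield(NULL, SEQ18)
  expect_equal(round(g18$random_expectation), 35)
  expect_equal(g18$n_g_sites, 6)
  g8 <- overall_g_yield(NULL, SEQ8)
  expect_equal(round(g8$random_expectation), 29)
  expect_equal(g8$n_g_sites, 2)
  # the 27-mer has 9 G-sites of 26 -> also ~35%
  g27 <- overall_g_yield(NULL, SEQ27)
  expect_equal(g27$n_g_sites, 9)
  expect_equal(round(g27$random_expectation), 35)
  # no G at all
  gnone <- overall_g_yield(NULL, "ACUCAUCA")
  expect_equal(gnone$random_expectation, 0)
})

test_that("modified guanosines count as G-sites, inosine does not", {
  # c3G at position 5 still marks site 4
  y <- overall_g_yield(NULL, fixtures$sequence[fixtures$id == 2])
  expect_equal(y$n_g_sites, 6)
  # inosine at 5, 9, 13 drops three G-sites
  y5 <- overall_g_yield(NULL, fixtures$sequence[fixtures$id == 5])
  expect_equal(y5$n_g_sites, 3)
})

test_that("charge bookkeeping reproduces the reference values", {
  expect_equal(charge_density(7, 18), 0.39)
  expect_equal(charge_density(11, 27), 0.41)
  expect_equal(charge_density(0, 18), 0)
  expect_equal(phosphodiester_deprotonation(13, 27), 50)
  expect_equal(round(phosphodiester_deprotonation(5, 27)), 19)
})

test_that("the preference factor inverts its own analytic yield", {
  for (seqstr in c(SEQ18, SEQ27, SEQ8)) {
    for (g in c(0.3, 1, 2.75, 5, 20)) {
      y <- analytic_g_yield(g, seqstr)
      expect_equal(effective_preference_factor(y, seqstr), g,
                   tolerance = 1e-9)
    }
  }
  # the null recovers unity, and the 60% headline gives 2.75
  expect_equal(effective_preference_factor(
    overall_g_yield(NULL, SEQ18)$random_expectation, SEQ18), 1,
    tolerance = 1e-9)
  expect_equal(effective_preference_factor(60, SEQ18), 1.5 * 11 / 6,
               tolerance = 1e-9)
  expect_error(effective_preference_factor(0, SEQ18), "strictly")
  expect_error(effective_preference_factor(100, SEQ18), "strictly")
})

test_that("identical runs give unit fold change on the diagonal", {
  asg <- make_asg(ion_type = c("c", "y", "c"), index = c(4L, 14L, 8L),
                  charge = c(2L, 5L, 2L), abundance = c(10, 20, 5))
  fc <- fold_change_correlation(asg, asg, site = 4, seq = SEQ18)
  expect_equal(fc$fold_change, 1)
  expect_equal(fc$pairs$norm_abundance_ref, fc$pairs$norm_abundance_mod)
  expect_error(fold_change_correlation(asg, asg, site = 9, seq = SEQ18),
               "site 9")
})

test_that("charge-value distributions summarize per-site charge", {
  asg <- make_asg(ion_type = "c", index = 5L, charge = 3L, abundance = 1)
  d <- charge_value_distribution(asg, SEQ18)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 3L)
  expect_equal(d$site, 5)
  expect_error(charge_value_distribution(asg[0, ], SEQ18), "no assignments")

  # two simulations differing only in site propensities keep the same
  # charge-partition law: mean charge per site barely moves
  m1 <- cleavage_model(base_loss_fraction = 0)
  m2 <- cleavage_model(base_loss_fraction = 0,
                       site_overrides = c(`4` = 0.1))
  s1 <- simulate_cad_spectrum(SEQ18, 7, m1, n_ions = 2e5, seed = 41,
                              render = FALSE)
  s2 <- simulate_cad_spectrum(SEQ18, 7, m2, n_ions = 2e5, seed = 42,
                              render = FALSE)
  d1 <- charge_value_distribution(truth_assignments(s1), SEQ18)
  d2 <- charge_value_distribution(truth_assignments(s2), SEQ18)
  expect_lt(compare_charge_values(d1, d2), 0.2)
})

test_that("dissociation yield handles the edge cases", {
  frag_only <- make_asg(ion_type = c("c", "y"), index = c(3L, 5L),
                        abundance = c(5, 5))
  expect_equal(dissociation_yield(frag_only), 100)
  prec_only <- make_asg(ion_type = "precursor", index = 18L,
                        abundance = 10)
  expect_equal(dissociation_yield(prec_only), 0)
  expect_error(dissociation_yield(prec_only[0, ]), "denominator")
  # precursor base losses count as undissociated
  mixed <- make_asg(ion_type = c("c", "precursor", "precursor"),
                    index = c(3L, 18L, 18L),
                    base_loss = c(NA_integer_, NA_integer_, 2L),
                    abundance = c(30, 50, 20))
  expect_equal(dissociation_yield(mixed), 30)
})

test_that("the cleavage map renders the sequence with site marks", {
  asg <- make_asg(ion_type = c("c", "y"), index = c(4L, 14L),
                  abundance = c(3, 5))
  yt <- site_specific_yields(asg, SEQ18, n = 7)
  map <- cleavage_map(yt)
  expect_length(map, 4)
  expect_match(map[2], "ACCCGCAAGGCCGACGGC")
  expect_match(map[1], "#") # >= 10% c yield at site 4
})
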