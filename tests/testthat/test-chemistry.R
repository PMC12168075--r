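# Residue alphabet, parsing, compositions and monoisotopic masses.

test_that("sequence parsing handles blocks, brackets and bare tokens", {
  s <- parse_rna("GGCUA GCC")
  expect_equal(length(s), 8)
  expect_equal(which(s$residues == "G"), c(1, 2, 6))

  s2 <- parse_rna("ACCC[c3G]CAAGGCCGACGGC")
  expect_equal(length(s2), 18)
  expect_equal(s2$residues[5], "c3G")
  # bare token, greedy longest-match
  expect_equal(parse_rna("ACCCc3GCAAGG")$residues[5], "c3G")
  expect_equal(parse_rna("GGCUA [m22G]CC")$residues[6], "m22G")
})

test_that("parsing errors name the offending token and offset", {
  expect_error(parse_rna(""), "empty")
  expect_error(parse_rna("ACGX"), "X.*offset 4")
  expect_error(parse_rna("AC[xyz]G"), "xyz")
  expect_error(parse_rna("AC[foo"), "unclosed")
})

test_that("compositions do element-wise arithmetic and refuse debt", {
  g <- comp(C = 10, H = 13, N = 5, O = 5)
  ribose <- comp(C = 5, H = 8, O = 4)
  guanine <- g - ribose
  expect_true(guanine == comp(C = 5, H = 5, N = 5, O = 1))
  expect_true(g + comp(P = 1) == comp(C = 10, H = 13, N = 5, O = 5, P = 1))
  expect_error(comp(H = 1) - comp(H = 2), "negative")
  expect_equal(monoisotopic_mass(comp()), 0)
})

test_that("single guanosine has the textbook formula and mass", {
  cc <- composition_of("G")
  expect_true(cc == parse_formula("C10H13N5O5"))
  expect_equal(monoisotopic_mass(cc), oracle_mass(10, 13, 5, 5), tolerance = 1e-9)
})

test_that("all twelve study sequences reproduce their reference masses", {
  # monoisotopic masses of the synthesized RNAs, +-0.001 Da
  expected <- c(`1` = 5764.869, `2` = 5763.874, `3` = 5763.874,
                `4` = 5749.858, `5` = 5719.836, `6` = 8612.152,
                `7` = 8626.168, `8` = 8626.168, `9` = 8640.183,
                `10` = 2523.388, `11` = 2522.393, `12` = 2522.393)
  got <- vapply(fixtures$sequence, monoisotopic_mass, 0)
  expect_equal(unname(got), unname(expected), tolerance = 0.0015)
  # and the unmodified ones against the fully independent oracle
  expect_equal(monoisotopic_mass(SEQ18),
               oracle_seq_mass(strsplit("ACCCGCAAGGCCGACGGC", "")[[1]]),
               tolerance = 1e-6)
  expect_equal(monoisotopic_mass(SEQ8),
               oracle_seq_mass(strsplit("GGCUAGCC", "")[[1]]),
               tolerance = 1e-6)
})

test_that("modification deltas match reference mass differences", {
  expect_equal(modification_delta("G", "c3G"), 0.995, tolerance = 1e-3)
  expect_equal(modification_delta("I", "G"), -15.011, tolerance = 1e-3)
  expect_equal(modification_delta("m22G", "G"), 28.031, tolerance = 1e-3)
  expect_error(modification_delta("Q", "G"), "unknown")
})

test_that("modified residues differ from G by the documented compositions", {
  g <- composition_of("G")
  for (deaza in c("c1G", "c3G", "c7G")) {
    expect_true(composition_of(deaza) + comp(N = 1) ==
                  g + comp(C = 1, H = 1), label = deaza)
  }
  expect_true(composition_of("m2G") == g + comp(C = 1, H = 2))
  expect_true(composition_of("m22G") == g + comp(C = 2, H = 4))
  expect_true(composition_of("I") + comp(N = 1, H = 1) == g)
})

test_that("composition_of is additive across any split point", {
  for (seqstr in c(SEQ18, SEQ8)) {
    s <- parse_rna(seqstr)
    full <- unclass(composition_of(s))
    for (k in c(1, 3, length(s) - 1)) {
      left <- new_rna_sequence(s$residues[1:k])
      right <- new_rna_sequence(s$residues[(k + 1):length(s)])
      rejoined <- unclass(composition_of(left)) +
        unclass(composition_of(right)) +
        unclass(comp(O = 3, H = 1, P = 1)) - unclass(comp(H = 2, O = 1))
      expect_equal(rejoined, full, tolerance = 1e-12)
    }
  }
})

test_that("a dimer exceeds its two monomers by one linkage", {
  d <- monoisotopic_mass("AG")
  m <- monoisotopic_mass("A") + monoisotopic_mass("G")
  expect_equal(d - m, monoisotopic_mass(comp(H = 1, O = 3, P = 1)) -
                 monoisotopic_mass(comp(H = 2, O = 1)), tolerance = 1e-9)
})

test_that("terminal phosphates adjust the composition as declared", {
  base <- monoisotopic_mass(parse_rna("ACG"))
  p5 <- monoisotopic_mass(parse_rna("ACG", five_prime = "phosphate"))
  cyc <- monoisotopic_mass(parse_rna("ACG",
                                     three_prime = "cyclic_phosphate"))
  hpo3 <- monoisotopic_mass(comp(H = 1, O = 3, P = 1))
  h2o <- monoisotopic_mass(comp(H = 2, O = 1))
  expect_equal(p5 - base, hpo3, tolerance = 1e-9)
  expect_equal(cyc - base, hpo3 - h2o, tolerance = 1e-9)
})

test_that("the residue table validates the ribose remainder", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("code\tnucleoside\tbase\tg_class\tdescription",
               "Z\tC10H13N5O5\tC5H6N5O\tFALSE\tbroken"), tmp)
  expect_error(residue_table(tmp), "ribose")
})
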