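test_that("formula parsing returns exact element counts and rejects garbage", {
  comp <- parse_formula("C8H9NO3")
  expect_equal(comp[["C"]], 8L)
  expect_equal(comp[["H"]], 9L)
  expect_equal(comp[["N"]], 1L)
  expect_equal(comp[["O"]], 3L)
  expect_equal(unclass(parse_formula("H2O"))[c("H", "O")], c(H = 2L, O = 1L))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("C8Hx3"), "malformed|unknown")
  expect_error(parse_formula("Xx2"), "unknown element")
})

test_that("monoisotopic masses agree with an independent atomic table", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C8H9NO3"), 167.0582, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C9H7N5O3"), 233.0549, tolerance = 1e-4)
  expect_identical(monoisotopic_mass(parse_formula("")), 0)
})

test_that("peptide masses match the independent residue-table oracle", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(peptide_mass("DSVTRQKEPRAPW"), 1568.8059, tolerance = 1e-4)
  expect_error(peptide_mass("DSVTRQZ"), "non-standard residue")
  expect_error(peptide(""), "empty")

  set.seed(421)
  for (i in 1:100) {
    s <- random_peptide()
    expect_equal(peptide_mass(s), oracle_peptide_mass(s), tolerance = 1e-4)
  }
})

test_that("peptide mass is additive over concatenation up to one water", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_peptide(); b <- random_peptide()
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - monoisotopic_mass("H2O"),
                 tolerance = 1e-9)
  }
})

test_that("peptide validates site index and protein span", {
  p <- peptide("DSVTRQKEPRAPW", site_index = 7, protein_span = c(37, 49))
  expect_equal(p$site_index, 7L)
  expect_error(peptide("DSVTRQK", site_index = 8), "out of range")
  expect_error(peptide("DSVTRQK", protein_span = c(1, 9)), "does not match")
})

test_that("ligand adduct bookkeeping recovers the free-ligand mass exactly", {
  pyr <- adduct_from_ligand(monoisotopic_mass("C8H9NO3"))
  expect_equal(round(pyr$delta_mass, 2), 151.06)
  expect_equal(pyr$delta_mass, 151.0633, tolerance = 1e-4)
  acfp <- adduct_from_ligand(monoisotopic_mass("C9H7N5O3"))
  expect_equal(acfp$delta_mass, 217.0600, tolerance = 1e-4)
  expect_equal(acfp$free_ligand_mass - acfp$delta_mass,
               monoisotopic_mass("O"), tolerance = 1e-12)
  expect_error(adduct_from_ligand(15.994915), "oxygen")

  set.seed(11)
  for (m in runif(20, 17, 500)) {
    ad <- adduct_from_ligand(m)
    expect_equal(ad$delta_mass + monoisotopic_mass("O"), m,
                 tolerance = 1e-9)
  }
})

test_that("neutral mass and m/z round-trip at all charges", {
  expect_equal(neutral_mass(19.017841, 1), 18.010565, tolerance = 1e-5)
  expect_equal(neutral_mass(523.942581, 3), 1568.8059, tolerance = 1e-4)
  expect_error(neutral_mass(100, 0), "positive")
  set.seed(5)
  for (i in 1:50) {
    m <- runif(1, 100, 5000); z <- sample(1:5, 1)
    expect_equal(neutral_mass(mz_from_neutral(m, z), z), m,
                 tolerance = 1e-9)
  }
})

test_that("b/y fragment ions match the residue-table oracle and complement", {
  p <- mr1_peptide()
  expect_equal(fragment_mz(p, "y", 1), 205.0972, tolerance = 1e-4)
  expect_equal(fragment_mz(p, "b", 2), 203.0662, tolerance = 1e-4)
  expect_error(fragment_mz(p, "b", 13), "out of range")
  # NH3 loss shifts the singly charged ion by exactly the ammonia mass
  expect_equal(fragment_mz(p, "y", 3, 1, "none") -
                 fragment_mz(p, "y", 3, 1, "NH3"),
               17.026549, tolerance = 1e-5)

  set.seed(99)
  for (r in 1:20) {
    s <- random_peptide()
    n <- nchar(s)
    pm <- peptide_mass(s)
    for (i in seq_len(n - 1)) {
      b_neut <- neutral_mass(fragment_mz(s, "b", i), 1)
      y_neut <- neutral_mass(fragment_mz(s, "y", n - i), 1)
      expect_equal(b_neut + y_neut, pm, tolerance = 1e-9)
    }
  }
})

test_that("isotope targets are spaced by 1.003355/z and round-trip", {
  tg <- isotope_targets(1000, 2, 3)
  expect_length(tg, 3)
  expect_equal(diff(tg), rep(0.5016775, 2), tolerance = 1e-6)
  expect_length(isotope_targets(1000, 2, 1), 1)
  expect_equal(neutral_mass(isotope_targets(1568.8059, 3, 3)[1], 3),
               1568.8059, tolerance = 1e-9)
})
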