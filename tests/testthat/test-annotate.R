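test_that("error propagation reproduces the 40-45 ppm band for Ac-6-FP", {
  tm <- tolerance_model("DSVTRQKEPRAPW", precursor_ppm = 5,
                        denominator = "delta")
  tol <- propagated_tolerance_ppm(tm, monoisotopic_mass("C9H7N5O3"))
  expect_equal(tol, 41.1, tolerance = 0.01)
  expect_gte(tol, 40); expect_lte(tol, 45)

  # 20 ppm scenario is exactly linear
  tm20 <- tolerance_model("DSVTRQKEPRAPW", precursor_ppm = 20,
                          denominator = "delta")
  expect_equal(propagated_tolerance_ppm(tm20, 233.0549),
               4 * propagated_tolerance_ppm(tm, 233.0549),
               tolerance = 1e-12)
  expect_error(propagated_tolerance_ppm(tm, 10), "oxygen")
})

test_that("the tolerance curve is monotone and consistent with the point op", {
  tm <- tolerance_model("DSVTRQKEPRAPW")
  cv <- tolerance_curve(tm, c(100, 200, 400))
  expect_true(all(diff(cv$tolerance_ppm) < 0))
  expect_equal(tolerance_curve(tm, 233.0549)$tolerance_ppm,
               propagated_tolerance_ppm(tm, 233.0549))
  tm20 <- tolerance_model("DSVTRQKEPRAPW", precursor_ppm = 20)
  grid <- seq(50, 500, by = 25)
  expect_true(all(tolerance_curve(tm, grid)$tolerance_ppm <
                    tolerance_curve(tm20, grid)$tolerance_ppm))
  expect_error(tolerance_curve(tm, numeric()), "empty")
})

test_that("the bundled compound table loads with formula-derived masses", {
  tab <- read_compound_table(system.file("extdata", "compounds_mr1.tsv",
                                         package = "xlscreen"))
  expect_true(all(c("pyridoxal", "acetyl-6-formylpterin") %in% tab$name))
  expect_equal(tab$monoisotopic_mass[tab$name == "pyridoxal"],
               167.0582, tolerance = 1e-4)
  expect_true(all(tab$monoisotopic_mass > 0))
})

test_that("inconsistent or incomplete compound rows are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tformula\tmonoisotopic_mass",
               "bad\tC8H9NO3\t200.0"), f)
  expect_error(read_compound_table(f), "disagrees")
  writeLines(c("name\tformula\tmonoisotopic_mass", "void\t\t"), f)
  expect_error(read_compound_table(f), "neither")
})

test_that("compound matching ranks the true compound first", {
  tab <- read_compound_table(system.file("extdata", "compounds_mr1.tsv",
                                         package = "xlscreen"))
  tm <- tolerance_model("DSVTRQKEPRAPW")
  m <- match_compounds(167.0582, tab, tm)
  expect_equal(m$name[1], "pyridoxal")
  expect_lt(abs(m$ppm_error[1]), 1)
  expect_true(m$within_propagated_tolerance[1])

  m2 <- match_compounds(233.0549, tab, tm)
  expect_equal(m2$name[1], "acetyl-6-formylpterin")
  expect_true(m2$within_propagated_tolerance[1])

  expect_equal(nrow(match_compounds(167.0582, tab[0, ], tm)), 0L)
  # emitted matches never exceed the 200 ppm cap and the flag is consistent
  for (mass in c(100.05, 167.06, 300.1)) {
    mm <- match_compounds(mass, tab, tm)
    if (nrow(mm) == 0L) next
    expect_true(all(abs(mm$ppm_error) <= 200))
    expect_equal(mm$within_propagated_tolerance,
                 abs(mm$ppm_error) <= mm$applied_tolerance_ppm)
  }
})

test_that("the applied tolerance clamps to the practical 30-60 ppm band", {
  tab <- data.frame(name = "x", formula = "",
                    monoisotopic_mass = 50.0, source = "")
  tm <- tolerance_model("DSVTRQKEPRAPW")
  # tiny ligand: raw propagation is enormous, applied tolerance capped at 60
  m <- match_compounds(50.001, tab, tm)
  expect_equal(m$applied_tolerance_ppm, 60)
  # huge ligand: raw propagation would drop below 30, floor applies
  tab2 <- data.frame(name = "y", formula = "",
                     monoisotopic_mass = 1200.0, source = "")
  m2 <- match_compounds(1200.01, tab2, tm)
  expect_equal(m2$applied_tolerance_ppm, 30)
})

test_that("planted ligands annotate as the rank-1 compound through the screen", {
  tab <- read_compound_table(system.file("extdata", "compounds_mr1.tsv",
                                         package = "xlscreen"))
  tm <- tolerance_model("DSVTRQKEPRAPW")
  planted <- c("pyridoxal" = "C8H9NO3",
               "acetyl-6-formylpterin" = "C9H7N5O3",
               "riboflavin" = "C17H20N4O6")
  for (trial in 1:10) {
    nm <- names(planted)[(trial - 1) %% 3 + 1]
    cfg <- simulation_config(
      ligands = data.frame(name = nm, formula = planted[[nm]], n_ms2 = 3L,
                           auc_ratio = 0.1, rt_offset = 0.5,
                           stringsAsFactors = FALSE),
      decoy_n = 10L, seed = 600 + trial)
    sim <- simulate_run(cfg)
    res <- screen_spectra(sim$run, mr1_peptide())
    cl <- cluster_hits(res$candidates)
    expect_equal(nrow(cl), 1L)
    m <- match_compounds(cl$free_ligand_mass[1], tab, tm)
    expect_equal(m$name[1], nm)
  }
})
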