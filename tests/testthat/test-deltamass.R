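test_that("the reporter set contains exactly the site-free ladder ions", {
  rs <- build_reporter_set(mr1_peptide())
  expect_equal(nrow(rs$ladder), 24L)
  expect_equal(rs$n_precursor, 4L)
  expect_equal(sum(rs$ladder$series == "b"), 12L)  # b1..b6 x 2 charges
  expect_equal(sum(rs$ladder$series == "y"), 12L)  # y1..y6 x 2 charges
  # no ladder fragment reaches the site residue
  expect_true(all(rs$ladder$index[rs$ladder$series == "b"] < 7))
  expect_true(all(rs$ladder$index[rs$ladder$series == "y"] <= 13 - 7))

  # site at position 1: no b reporters, full y ladder
  rs1 <- build_reporter_set(peptide("DSVTRQKEPRAPW", site_index = 1))
  expect_equal(sum(rs1$ladder$series == "b"), 0L)
  expect_equal(sum(rs1$ladder$series == "y"), 24L)
  expect_error(build_reporter_set(peptide("DSVTRQKEPRAPW")), "site_index")
})

test_that("matching finds the full reporter complement and tolerates shifts", {
  p <- mr1_peptide()
  rs <- build_reporter_set(p)
  prec_neutral <- peptide_mass(p) + 217.06
  s <- mk_full_reporter_spectrum(p, prec_neutral, z = 3L)
  m <- match_reporters(s, rs)
  expect_equal(m$n_reporters, 28L)

  # empty spectrum
  s0 <- spectrum_record("e", 2, 1, numeric(), numeric(), precursor_mz = 500,
                        precursor_z = 2L)
  expect_equal(match_reporters(s0, rs)$n_reporters, 0L)

  # a simulated ligand-bound spectrum: site-containing ions are shifted but
  # every unaffected reporter still matches
  sim <- simulate_run(simulation_config(noise_peaks = 0L, decoy_n = 0L,
                                        seed = 13))
  cand <- sim$manifest$scan_id[sim$manifest$class == "candidate"]
  ids <- vapply(sim$run$ms2, `[[`, "", "scan_id")
  for (id in cand) {
    expect_equal(match_reporters(sim$run$ms2[[match(id, ids)]],
                                 rs)$n_reporters, 28L)
  }
})

test_that("a peak satisfies at most one reporter", {
  p <- mr1_peptide()
  rs <- build_reporter_set(p)
  # single peak exactly between y1 (205.0972) and nothing else
  s <- mk_spectrum(c(205.0972), precursor_mz = 523.9426, precursor_z = 3L)
  m <- match_reporters(s, rs)
  expect_equal(m$n_reporters, 1L)
  matched <- m$assignments[!is.na(m$assignments$peak_mz), ]
  expect_equal(nrow(matched), 1L)
  expect_equal(matched$label, "y1_z1")
})

test_that("tightening the fragment tolerance never gains reporters", {
  set.seed(71)
  sim <- simulate_run(simulation_config(fragment_ppm_sd = 20, decoy_n = 0L,
                                        seed = 71))
  rs <- build_reporter_set(mr1_peptide())
  tols <- c(0.05, 0.03, 0.01, 0.003, 0.001)
  for (s in sim$run$ms2[1:5]) {
    counts <- vapply(tols, function(tol)
      match_reporters(s, rs, frag_tol = tol)$n_reporters, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("delta-mass arithmetic recovers planted adducts exactly", {
  p <- mr1_peptide()
  acfp_delta <- monoisotopic_mass("C9H7N5O3") - monoisotopic_mass("O")
  s <- mk_spectrum(100, precursor_mz = (peptide_mass(p) + acfp_delta +
                                          3 * 1.00727646688) / 3,
                   precursor_z = 3L)
  d <- compute_delta_mass(s, p)
  expect_equal(d$delta_mass, 217.0600, tolerance = 1e-4)
  expect_equal(d$free_ligand_mass, 233.0549, tolerance = 1e-4)

  s2 <- mk_spectrum(100, precursor_mz = (peptide_mass(p) +
                                           2 * 1.00727646688) / 2,
                    precursor_z = 2L)
  expect_equal(compute_delta_mass(s2, p)$delta_mass, 0, tolerance = 1e-9)

  pyr <- monoisotopic_mass("C8H9NO3") - monoisotopic_mass("O")
  s3 <- mk_spectrum(100, precursor_mz = (peptide_mass(p) + pyr +
                                           2 * 1.00727646688) / 2,
                    precursor_z = 2L)
  d3 <- compute_delta_mass(s3, p)
  expect_equal(d3$free_ligand_mass, 167.0582, tolerance = 1e-4)
  expect_equal(round(d3$delta_mass, 2), 151.06)

  # unknown charge enumerates one row per charge, flagged
  s4 <- mk_spectrum(100, precursor_mz = 600, precursor_z = NA)
  d4 <- compute_delta_mass(s4, p)
  expect_equal(nrow(d4), 4L)
  expect_true(all(d4$charge_enumerated))
})

test_that("reference retention time is the weighted median of controls", {
  one <- data.frame(rt = 42, matched_intensity = 5)
  expect_equal(reference_rt(one), 42)
  three <- data.frame(rt = c(40, 41, 43), matched_intensity = c(1, 1, 1))
  expect_equal(reference_rt(three), 41)
  expect_error(reference_rt(three[0, ]), "reference")

  sim <- simulate_run(simulation_config(decoy_n = 0L, seed = 23))
  res <- screen_spectra(sim$run, mr1_peptide())
  # within the simulated elution width of the planted apex
  expect_lt(abs(res$reference_rt - 42), 0.2)
})

test_that("screening separates planted candidates, controls and decoys", {
  sim <- simulate_run(simulation_config(seed = 41))
  res <- screen_spectra(sim$run, mr1_peptide())
  man <- sim$manifest
  expect_setequal(res$candidates$scan_id,
                  man$scan_id[man$class == "candidate"])
  expect_true(all(man$scan_id[man$class == "control"] %in%
                    res$controls$scan_id))
  expect_false(any(man$scan_id[man$class == "decoy"] %in%
                     c(res$candidates$scan_id, res$controls$scan_id)))
  expect_true(all(res$candidates$n_reporters >= 10))
  # classes are disjoint and controls sit inside the window by construction
  expect_length(intersect(res$candidates$scan_id, res$controls$scan_id), 0)
  expect_true(all(res$controls$delta_mass >= -0.05 &
                    res$controls$delta_mass <= 4.05))
  expect_true(all(res$candidates$delta_mass > 40))
})

test_that("a run with only the free peptide yields controls but no candidates", {
  cfg <- simulation_config(ligands = NULL, decoy_n = 0L, seed = 8)
  sim <- simulate_run(cfg)
  res <- screen_spectra(sim$run, mr1_peptide())
  expect_equal(nrow(res$candidates), 0L)
  expect_gt(nrow(res$controls), 0L)
})

test_that("the retention-time criterion excludes far-eluting candidates", {
  cfg <- simulation_config(
    ligands = data.frame(name = "far", formula = "C9H7N5O3", n_ms2 = 3L,
                         auc_ratio = 0.1, rt_offset = 20,
                         stringsAsFactors = FALSE),
    decoy_n = 0L, seed = 15)
  sim <- simulate_run(cfg)
  res <- screen_spectra(sim$run, mr1_peptide())
  expect_equal(nrow(res$candidates), 0L)
  # widening the window through a longer effective gradient readmits them
  res2 <- screen_spectra(sim$run, mr1_peptide(),
                         screen_config(rt_window = 25))
  expect_equal(nrow(res2$candidates), 3L)
})

test_that("quality scores behave at their boundary cases", {
  p <- mr1_peptide()
  rs <- build_reporter_set(p)
  prec_neutral <- peptide_mass(p)
  s <- mk_full_reporter_spectrum(p, prec_neutral, z = 3L)
  m <- match_reporters(s, rs)
  q <- quality_scores(s, m)
  expect_equal(q$matched_tic_fraction, 1.0)  # every peak is a reporter
  expect_equal(q$ladder_continuity, 6L)
  expect_true(is.na(q$control_similarity))
  vec <- m$assignments$peak_intensity
  vec[is.na(vec)] <- 0
  q2 <- quality_scores(s, m, control_consensus = vec)
  expect_equal(q2$control_similarity, 1.0)

  # single isolated match cannot have continuity > 1
  s1 <- mk_spectrum(205.0972, precursor_mz = 500, precursor_z = 2L)
  q3 <- quality_scores(s1, match_reporters(s1, rs))
  expect_lte(q3$ladder_continuity, 1L)
})

test_that("a control screened against its own consensus scores similarity 1", {
  cfg <- simulation_config(ligands = NULL, n_unmodified_ms2 = 1L,
                           decoy_n = 0L, seed = 55)
  sim <- simulate_run(cfg)
  res <- screen_spectra(sim$run, mr1_peptide())
  expect_equal(nrow(res$controls), 1L)
  expect_equal(res$controls$control_similarity, 1.0, tolerance = 1e-12)
})

test_that("delta-mass clustering merges repeats and respects tolerance", {
  mk <- function(deltas) data.frame(
    scan_id = paste0("s", seq_along(deltas)), rt = 42,
    precursor_z = 3L, charge_enumerated = FALSE, precursor_mz = 600,
    observed_neutral = 1800, delta_mass = deltas,
    free_ligand_mass = deltas + 15.9949146221,
    n_reporters = 20L, matched_intensity = 1,
    matched_tic_fraction = 0.5, ladder_continuity = 6L,
    control_similarity = NA_real_,
    isotope_corrected_delta = deltas, isotope_k = 0L,
    flag_low_tic = FALSE, flag_low_continuity = FALSE,
    flag_low_similarity = FALSE, stringsAsFactors = FALSE)

  cl <- cluster_hits(mk(c(217.0600, 217.0608)), tol_ppm = 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_spectra, 2L)

  cl2 <- cluster_hits(mk(c(151.06, 217.06)), tol_ppm = 10)
  expect_equal(nrow(cl2), 2L)

  set.seed(3)
  deltas <- runif(60, 50, 400)
  cl3 <- cluster_hits(mk(deltas), tol_ppm = 10)
  members <- attr(cl3, "members")
  for (g in unique(members$cluster_id)) {
    d <- members$delta_mass[members$cluster_id == g]
    rep_d <- mean(d)
    expect_true(all(abs(d - rep_d) <= 10e-6 * rep_d + 1e-12))
  }
  expect_equal(nrow(cluster_hits(mk(1)[0, ])), 0L)
})
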