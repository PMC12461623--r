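# Independent mass oracle for cross-checking the package's arithmetic.
# These residue monoisotopic masses are transcribed from a standard
# proteomics reference table (5-6 decimals) -- deliberately NOT derived from
# the package's elemental-composition route, so agreement between the two is
# a genuine dual-route check.

oracle_residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
oracle_water <- 18.010565
oracle_proton <- 1.007276

oracle_peptide_mass <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  sum(oracle_residue_mass[aa]) + oracle_water
}

random_peptide <- function(len = sample(5:25, 1)) {
  paste(sample(names(oracle_residue_mass), len, replace = TRUE),
        collapse = "")
}

# reporter peptide used throughout
mr1_peptide <- function() peptide("DSVTRQKEPRAPW", site_index = 7)

# a minimal MS2 spectrum containing exactly the given peak positions
mk_spectrum <- function(mz, intensity = rep(1000, length(mz)),
                        precursor_mz = 500, precursor_z = 2L,
                        scan_id = "s1", rt = 42) {
  spectrum_record(scan_id, 2L, rt, mz, intensity,
                  precursor_mz = precursor_mz, precursor_z = precursor_z)
}

# spectrum holding the complete reporter complement of a peptide at the
# given precursor (ladder reporters + 4 survivors), plus optional extras
mk_full_reporter_spectrum <- function(p, precursor_neutral, z = 3L,
                                      extra_mz = numeric(),
                                      extra_int = numeric()) {
  rs <- build_reporter_set(p)
  surv_z <- c(2L, 3L, 2L, 3L)
  surv_loss <- c(0, 0, 17.026549, 17.026549)
  surv_mz <- (precursor_neutral - surv_loss + surv_z * 1.007276) / surv_z
  mz <- c(rs$ladder$mz, surv_mz, extra_mz)
  int <- c(rep(1e4, nrow(rs$ladder) + 4L), extra_int)
  mk_spectrum(mz, int, precursor_mz = (precursor_neutral + z * 1.007276) / z,
              precursor_z = z)
}
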