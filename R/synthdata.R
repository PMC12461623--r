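#' Configuration for a synthetic LC-MS/MS run
#'
#' Describes a deterministic simulated bottom-up run containing the free
#' reporter peptide, zero or more site-cross-linked ligand forms, and decoy
#' spectra, emulating a data-dependent acquisition: precursor charge states
#' 2-5 (triply charged dominant), b/y fragment ladders at charges 1-2 with
#' site-containing fragments shifted by the adduct delta-mass, four
#' precursor-survivor ions (+/- NH3 loss), 3-isotope MS1 envelopes following
#' Gaussian elution, ppm-scale Gaussian mass errors, uniform noise peaks and
#' random-sequence decoy ladders at random precursor masses.
#'
#' @param peptide Reporter peptide sequence.
#' @param site 1-based cross-linking site within the peptide.
#' @param ligands `data.frame` with columns `name`, `formula` (or
#'   `mass`), `n_ms2` (MS2 spectra to plant), `auc_ratio` (planted MS1 AUC
#'   relative to the unmodified peptide) and optional `rt_offset` (apex
#'   shift, minutes). Default: one Ac-6-FP-like ligand at the 8 percent
#'   yield regime.
#' @param n_unmodified_ms2 MS2 spectra of the free peptide.
#' @param apex_rt Elution apex of the free peptide, minutes.
#' @param elution_sigma Gaussian elution sigma, minutes (> 0).
#' @param gradient_length Gradient length, minutes.
#' @param charges,charge_probs Precursor charge states and their sampling
#'   probabilities.
#' @param precursor_ppm_sd Gaussian precursor m/z error sd, ppm (default 5/3
#'   so ~99.7 percent of precursors fall within the 5 ppm instrument spec).
#' @param fragment_ppm_sd Gaussian fragment m/z error sd, ppm.
#' @param ladder_completeness Probability each ladder fragment is present.
#' @param noise_peaks Uniform-m/z noise peaks per MS2 spectrum.
#' @param noise_intensity Length-2 range of noise peak intensities.
#' @param reporter_meanlog,reporter_sdlog Log-normal fragment intensity
#'   parameters.
#' @param decoy_n Number of decoy MS2 spectra.
#' @param ms1_charge Charge of the simulated MS1 envelopes.
#' @param ms1_interval MS1 scan spacing, minutes.
#' @param ms1_halfwidth Half-width of the simulated MS1 window around the
#'   apexes, minutes.
#' @param base_intensity MS1 apex intensity of the unmodified peptide.
#' @param ms1_noise_cv Coefficient of variation of multiplicative Gaussian
#'   noise applied to every MS1 peak intensity (0 = noiseless).
#' @param isotope_abundance Relative abundances of M, M+1, M+2.
#' @param control_mispick_k Optional integer vector recycled over the
#'   unmodified MS2 spectra: precursor picked on the M+k isotope, emulating
#'   monoisotopic mis-assignment.
#' @param seed Mandatory RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(peptide = "DSVTRQKEPRAPW", site = 7L,
                              ligands = data.frame(
                                name = "Ac-6-FP", formula = "C9H7N5O3",
                                n_ms2 = 3L, auc_ratio = 0.08,
                                rt_offset = 0.5,
                                stringsAsFactors = FALSE),
                              n_unmodified_ms2 = 6L,
                              apex_rt = 42, elution_sigma = 0.15,
                              gradient_length = 120,
                              charges = 2:5,
                              charge_probs = c(0.2, 0.55, 0.15, 0.1),
                              precursor_ppm_sd = 5 / 3,
                              fragment_ppm_sd = 3,
                              ladder_completeness = 1,
                              noise_peaks = 30L,
                              noise_intensity = c(10, 500),
                              reporter_meanlog = log(1e4),
                              reporter_sdlog = 0.5,
                              decoy_n = 100L,
                              ms1_charge = 3L,
                              ms1_interval = 0.03,
                              ms1_halfwidth = 1.2,
                              base_intensity = 1e6,
                              ms1_noise_cv = 0,
                              isotope_abundance = c(1, 0.85, 0.45),
                              control_mispick_k = NULL,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (elution_sigma <= 0) stop("elution_sigma must be > 0", call. = FALSE)
  if (ladder_completeness < 0 || ladder_completeness > 1) {
    stop("ladder_completeness must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(charges) == length(charge_probs), all(charge_probs >= 0),
            sum(charge_probs) > 0, gradient_length > 0)
  if (!is.null(ligands) && nrow(ligands) > 0L) {
    if (!"rt_offset" %in% names(ligands)) ligands$rt_offset <- 0.5
    if (!"mass" %in% names(ligands)) ligands$mass <- NA_real_
    for (i in seq_len(nrow(ligands))) {
      if (is.na(ligands$mass[i])) {
        ligands$mass[i] <- monoisotopic_mass(ligands$formula[i])
      }
      if (ligands$mass[i] <= OXYGEN_MASS) {
        stop("ligand '", ligands$name[i], "' lighter than one oxygen",
             call. = FALSE)
      }
    }
  }
  structure(
    list(peptide = peptide, site = as.integer(site), ligands = ligands,
         n_unmodified_ms2 = as.integer(n_unmodified_ms2),
         apex_rt = apex_rt, elution_sigma = elution_sigma,
         gradient_length = gradient_length,
         charges = as.integer(charges), charge_probs = charge_probs,
         precursor_ppm_sd = precursor_ppm_sd,
         fragment_ppm_sd = fragment_ppm_sd,
         ladder_completeness = ladder_completeness,
         noise_peaks = as.integer(noise_peaks),
         noise_intensity = noise_intensity,
         reporter_meanlog = reporter_meanlog,
         reporter_sdlog = reporter_sdlog,
         decoy_n = as.integer(decoy_n),
         ms1_charge = as.integer(ms1_charge),
         ms1_interval = ms1_interval, ms1_halfwidth = ms1_halfwidth,
         base_intensity = base_intensity,
         ms1_noise_cv = ms1_noise_cv,
         isotope_abundance = isotope_abundance,
         control_mispick_k = control_mispick_k,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# all theoretical MS2 peaks of a (possibly modified) peptide:
# b/y ladder at charges 1-2 with site-containing fragments shifted,
# plus 4 precursor survivors from the true precursor neutral mass
.theoretical_ms2 <- function(pep, site, delta, precursor_neutral) {
  aa <- strsplit(pep$sequence, "")[[1]]
  rm <- unname(.residue_masses()[aa])
  n <- length(aa)
  idx <- seq_len(n - 1L)
  b_neut <- cumsum(rm)[idx] + as.numeric(idx >= site) * delta
  y_neut <- cumsum(rev(rm))[idx] + WATER_MASS +
    as.numeric(idx > n - site) * delta
  ladder_neut <- c(b_neut, y_neut)
  mz <- c(ladder_neut + PROTON_MASS, (ladder_neut + 2 * PROTON_MASS) / 2)
  surv <- .precursor_reporters(precursor_neutral)
  data.frame(
    mz = c(mz, surv$mz),
    kind = c(rep("ladder", length(mz)), rep("survivor", nrow(surv))),
    stringsAsFactors = FALSE
  )
}

.sim_ms2_spectrum <- function(cfg, pep, delta, rt, z, scan_id, mispick_k = 0L,
                              include_survivors = TRUE) {
  true_neutral <- peptide_mass(pep) + delta
  picked_neutral <- true_neutral + mispick_k * ISOTOPE_SPACING
  prec_mz <- mz_from_neutral(picked_neutral, z) *
    (1 + stats::rnorm(1, 0, cfg$precursor_ppm_sd) * 1e-6)
  theo <- .theoretical_ms2(pep, cfg$site, delta, picked_neutral)
  if (!include_survivors) theo <- theo[theo$kind != "survivor", , drop = FALSE]
  keep <- ifelse(theo$kind == "ladder",
                 stats::runif(nrow(theo)) <= cfg$ladder_completeness, TRUE)
  theo <- theo[keep, , drop = FALSE]
  frag_mz <- theo$mz * (1 + stats::rnorm(nrow(theo), 0,
                                         cfg$fragment_ppm_sd) * 1e-6)
  frag_int <- stats::rlnorm(nrow(theo), cfg$reporter_meanlog,
                            cfg$reporter_sdlog)
  noise_mz <- stats::runif(cfg$noise_peaks, 100, 2000)
  noise_int <- stats::runif(cfg$noise_peaks, cfg$noise_intensity[1],
                            cfg$noise_intensity[2])
  spectrum_record(
    scan_id = scan_id, ms_level = 2L, rt = rt,
    mz = c(frag_mz, noise_mz), intensity = c(frag_int, noise_int),
    precursor_mz = prec_mz, precursor_z = z,
    precursor_intensity = sum(frag_int)
  )
}

#' Simulate a synthetic LC-MS/MS run with a ground-truth manifest
#'
#' Deterministic under the configured seed: the same configuration produces
#' byte-identical runs. Every generated MS2 spectrum appears exactly once in
#' the manifest with its true class, planted delta-mass, charge and isotope
#' mis-pick.
#'
#' @param cfg A [simulation_config()].
#' @return List with `run` (an [ms_run()]) and `manifest` (`data.frame`
#'   with `scan_id`, `class`, `ligand`, `true_delta`, `charge`,
#'   `mispick_k`, `rt`; planted AUC ratios and the configuration echo are
#'   attached as attributes).
#' @export
simulate_run <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  pep <- peptide(cfg$peptide, site_index = cfg$site)
  pm <- peptide_mass(pep)
  n_lig <- if (is.null(cfg$ligands)) 0L else nrow(cfg$ligands)

  species <- data.frame(
    name = c("unmodified",
             if (n_lig) cfg$ligands$name else character()),
    delta = c(0, if (n_lig) cfg$ligands$mass - OXYGEN_MASS else numeric()),
    apex = c(cfg$apex_rt,
             if (n_lig) cfg$apex_rt + cfg$ligands$rt_offset else numeric()),
    ratio = c(1, if (n_lig) cfg$ligands$auc_ratio else numeric()),
    n_ms2 = c(cfg$n_unmodified_ms2,
              if (n_lig) cfg$ligands$n_ms2 else integer()),
    stringsAsFactors = FALSE
  )

  # --- MS1: Gaussian elution of 3-isotope envelopes ------------------------
  rt_lo <- min(species$apex) - cfg$ms1_halfwidth
  rt_hi <- max(species$apex) + cfg$ms1_halfwidth
  ms1_rts <- seq(rt_lo, rt_hi, by = cfg$ms1_interval)
  iso_ab <- cfg$isotope_abundance
  ms1 <- vector("list", length(ms1_rts))
  for (i in seq_along(ms1_rts)) {
    rt <- ms1_rts[i]
    mzs <- numeric(0); ints <- numeric(0)
    for (sp in seq_len(nrow(species))) {
      apex_int <- cfg$base_intensity * species$ratio[sp]
      g <- exp(-(rt - species$apex[sp])^2 / (2 * cfg$elution_sigma^2))
      tmz <- isotope_targets(pm + species$delta[sp], cfg$ms1_charge,
                             length(iso_ab))
      mzs <- c(mzs, tmz)
      ints <- c(ints, apex_int * g * iso_ab)
    }
    if (cfg$ms1_noise_cv > 0) {
      ints <- pmax(ints * (1 + stats::rnorm(length(ints), 0,
                                            cfg$ms1_noise_cv)), 0)
    }
    keep <- ints > 1e-3  # sub-count envelope tails are not recorded
    ms1[[i]] <- spectrum_record(
      scan_id = sprintf("sim_ms1_%05d", i), ms_level = 1L, rt = rt,
      mz = mzs[keep], intensity = ints[keep]
    )
  }

  # --- MS2: planted species, then decoys -----------------------------------
  ms2 <- list()
  manifest <- list()
  counter <- 0L
  for (sp in seq_len(nrow(species))) {
    is_unmod <- species$name[sp] == "unmodified"
    for (j in seq_len(species$n_ms2[sp])) {
      counter <- counter + 1L
      z <- sample(cfg$charges, 1, prob = cfg$charge_probs)
      rt <- species$apex[sp] + stats::runif(1, -cfg$elution_sigma,
                                            cfg$elution_sigma)
      mispick <- 0L
      if (is_unmod && !is.null(cfg$control_mispick_k)) {
        mispick <- as.integer(
          cfg$control_mispick_k[(j - 1L) %% length(cfg$control_mispick_k) + 1L])
      }
      scan_id <- sprintf("sim_ms2_%04d", counter)
      ms2[[length(ms2) + 1L]] <- .sim_ms2_spectrum(
        cfg, pep, species$delta[sp], rt, z, scan_id, mispick_k = mispick)
      manifest[[length(manifest) + 1L]] <- data.frame(
        scan_id = scan_id,
        class = if (is_unmod) "control" else "candidate",
        ligand = species$name[sp],
        true_delta = species$delta[sp],
        charge = z, mispick_k = mispick, rt = rt,
        stringsAsFactors = FALSE
      )
    }
  }
  for (j in seq_len(cfg$decoy_n)) {
    counter <- counter + 1L
    # decoys emulate unrelated background peptides: random sequences of the
    # same length, not permutations of the reporter peptide (a permutation
    # shares prefix/suffix residue multisets with the target, so several of
    # its ladder ions genuinely coincide with reporter masses -- those are
    # true ion matches, not false positives)
    decoy_seq <- paste(sample(names(.RESIDUE_FORMULA), nchar(cfg$peptide),
                              replace = TRUE), collapse = "")
    decoy_pep <- peptide(decoy_seq, site_index = cfg$site)
    z <- sample(cfg$charges, 1, prob = cfg$charge_probs)
    rt <- stats::runif(1, 0, cfg$gradient_length)
    decoy_delta <- stats::runif(1, 40, 400)
    scan_id <- sprintf("sim_ms2_%04d", counter)
    # bare ladders: no survivor ions, so reporter matches arise only by chance
    ms2[[length(ms2) + 1L]] <- .sim_ms2_spectrum(
      cfg, decoy_pep, decoy_delta, rt, z, scan_id,
      include_survivors = FALSE)
    manifest[[length(manifest) + 1L]] <- data.frame(
      scan_id = scan_id, class = "decoy", ligand = NA_character_,
      true_delta = decoy_delta, charge = z, mispick_k = 0L, rt = rt,
      stringsAsFactors = FALSE
    )
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(scan_id = character(), class = character(),
               ligand = character(), true_delta = numeric(),
               charge = integer(), mispick_k = integer(), rt = numeric(),
               stringsAsFactors = FALSE)
  attr(manifest, "auc_ratios") <- stats::setNames(species$ratio, species$name)
  attr(manifest, "config") <- cfg
  list(run = ms_run(ms1, ms2, cfg$gradient_length), manifest = manifest)
}

#' Write a run to MGF or mzML
#'
#' MGF output carries the MS2 spectra only (the format has no MS1 scans);
#' mzML output is written through mzR and carries both levels.
#'
#' @param run An [ms_run()].
#' @param path Output path.
#' @param format `"mgf"` or `"mzML"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, format = c("auto", "mgf", "mzML")) {
  stopifnot(inherits(run, "ms_run"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzML",
                     stop("cannot infer format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (format == "mgf") .write_mgf(run, path) else .write_mzml(run, path)
  invisible(path)
}
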