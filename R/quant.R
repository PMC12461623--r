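#' Extracted ion chromatogram over an isotope envelope
#'
#' For each MS1 scan in range, sums the intensities of peaks falling within
#' the m/z tolerance of any of the first `n_isotopes` isotope targets of the
#' species (default M, M+1, M+2 -- the three most abundant isotopes of a
#' peptide this size).
#'
#' @param run An [ms_run()] with MS1 scans (mzML input; MGF carries no MS1).
#' @param neutral Neutral monoisotopic mass of the species, Da.
#' @param z Charge of the extracted ion.
#' @param n_isotopes Number of isotopes summed (default 3).
#' @param mz_tol_ppm Extraction tolerance, ppm (default 10).
#' @param rt_range Optional length-2 retention-time window, minutes.
#' @return Object of class `xic_trace`: `data.frame` with `rt` and
#'   `intensity`, one row per MS1 scan in range; target description kept in
#'   attributes.
#' @export
extract_xic <- function(run, neutral, z, n_isotopes = 3L, mz_tol_ppm = 10,
                        rt_range = NULL) {
  stopifnot(inherits(run, "ms_run"))
  if (length(run$ms1) == 0L) {
    stop("run has no MS1 scans (MGF input?); XIC extraction needs mzML ",
         "with MS1 level data", call. = FALSE)
  }
  targets <- isotope_targets(neutral, z, n_isotopes)
  tol <- mz_tol_ppm * 1e-6 * targets
  scans <- run$ms1
  if (!is.null(rt_range)) {
    rts <- vapply(scans, function(s) s$rt, numeric(1))
    scans <- scans[rts >= rt_range[1] & rts <= rt_range[2]]
  }
  rt <- vapply(scans, function(s) s$rt, numeric(1))
  intensity <- vapply(scans, function(s) {
    tot <- 0
    for (i in seq_along(targets)) {
      lo <- findInterval(targets[i] - tol[i], s$mz) + 1L
      hi <- findInterval(targets[i] + tol[i], s$mz)
      if (hi >= lo) tot <- tot + sum(s$intensity[lo:hi])
    }
    tot
  }, numeric(1))
  trace <- data.frame(rt = rt, intensity = intensity)
  attr(trace, "neutral") <- neutral
  attr(trace, "z") <- z
  attr(trace, "n_isotopes") <- n_isotopes
  attr(trace, "mz_tol_ppm") <- mz_tol_ppm
  class(trace) <- c("xic_trace", "data.frame")
  trace
}

#' Chromatographic area under the curve
#'
#' Trapezoidal integral of an XIC over retention time (intensity x minutes).
#'
#' @param trace An [extract_xic()] trace (or any data frame with `rt` and
#'   `intensity`).
#' @return AUC; 0 with a warning when fewer than two points are available.
#' @export
xic_auc <- function(trace) {
  if (nrow(trace) < 2L) {
    warning("fewer than 2 trace points; AUC set to 0")
    return(0)
  }
  pracma::trapz(trace$rt, trace$intensity)
}

#' Cross-linking yield from modified / unmodified XIC ratio
#'
#' Extracts isotope-envelope XICs for the ligand-modified peptide (peptide
#' mass + delta-mass) and the unmodified peptide at the same charge,
#' integrates both, and reports `yield_percent = 100 * AUC(modified) /
#' AUC(unmodified)` -- the nominal cross-linking yield, with no
#' ionization-efficiency correction.
#'
#' @param run An [ms_run()] with MS1 scans.
#' @param p The carrier [peptide()].
#' @param adduct An [adduct_from_ligand()] adduct.
#' @param charge Charge of the extracted precursor (default 3, the dominant
#'   charge state of the 13-mer).
#' @param n_isotopes Isotopes summed per envelope (default 3: M, M+1, M+2).
#' @param mz_tol_ppm Extraction tolerance, ppm.
#' @param rt_range Optional retention-time window, minutes.
#' @return Object of class `yield_estimate`: list with `auc_modified`,
#'   `auc_unmodified`, `yield_percent` (NA, flagged `undefined`, when the
#'   unmodified AUC is zero) and the two traces.
#' @export
crosslink_yield <- function(run, p, adduct, charge = 3L, n_isotopes = 3L,
                            mz_tol_ppm = 10, rt_range = NULL) {
  stopifnot(inherits(adduct, "adduct_mass"))
  p <- .as_peptide(p)
  pm <- peptide_mass(p)
  unmod <- extract_xic(run, pm, charge, n_isotopes, mz_tol_ppm, rt_range)
  mod <- extract_xic(run, pm + adduct$delta_mass, charge, n_isotopes,
                     mz_tol_ppm, rt_range)
  auc_u <- xic_auc(unmod)
  auc_m <- xic_auc(mod)
  undefined <- auc_u <= 0
  structure(
    list(auc_modified = auc_m, auc_unmodified = auc_u,
         yield_percent = if (undefined) NA_real_ else 100 * auc_m / auc_u,
         undefined = undefined, trace_modified = mod,
         trace_unmodified = unmod),
    class = "yield_estimate"
  )
}

#' @export
print.yield_estimate <- function(x, ...) {
  if (x$undefined) {
    cat("<yield_estimate> undefined (unmodified AUC is zero)\n")
  } else {
    cat(sprintf(
      "<yield_estimate> %.3f%% (modified AUC %.4g / unmodified AUC %.4g)\n",
      x$yield_percent, x$auc_modified, x$auc_unmodified))
  }
  invisible(x)
}
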