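#' Build the reporter-ion set for a site-modified peptide
#'
#' Reporter ions are the backbone fragments that cannot contain the
#' cross-linked residue and are therefore identical between the free and any
#' ligand-bound form of the peptide: b-ions N-terminal of the site
#' (`b1..b(k-1)`) and y-ions C-terminal of it (`y1..y(n-k)`), each at charges
#' 1 and 2. Four precursor-survivor reporters (charges 2 and 3, with and
#' without NH3 loss) are derived per spectrum from that spectrum's own
#' observed precursor mass, since the ligand mass is unknown beforehand.
#'
#' For the 13-mer with the site at position 7 this gives 24 ladder reporters
#' plus 4 precursor reporters, 28 targets in total.
#'
#' @param p A [peptide()] with `site_index` set.
#' @return Object of class `reporter_set`: a list with the peptide, the
#'   ladder target table (`label`, `series`, `index`, `z`, `mz`) and the
#'   count of per-spectrum precursor reporters.
#' @examples
#' build_reporter_set(peptide("DSVTRQKEPRAPW", site_index = 7))
#' @export
build_reporter_set <- function(p) {
  p <- .as_peptide(p)
  if (is.null(p$site_index)) {
    stop("peptide has no site_index; reporter ions are defined relative ",
         "to the cross-linking site", call. = FALSE)
  }
  n <- nchar(p$sequence)
  k <- p$site_index
  rows <- list()
  add <- function(series, index, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = sprintf("%s%d_z%d", series, index, z),
      series = series, index = index, z = z,
      mz = fragment_mz(p, series, index, z),
      stringsAsFactors = FALSE
    )
  }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (z in 1:2) add("b", i, z)
  }
  if (n - k >= 1L) {
    for (j in seq_len(n - k)) for (z in 1:2) add("y", j, z)
  }
  ladder <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), series = character(), index = integer(),
               z = integer(), mz = numeric())
  structure(
    list(peptide = p, ladder = ladder, n_precursor = 4L),
    class = "reporter_set"
  )
}

#' @export
print.reporter_set <- function(x, ...) {
  cat(sprintf(
    "<reporter_set> %s (site %d): %d ladder + %d precursor reporters\n",
    x$peptide$sequence, x$peptide$site_index, nrow(x$ladder), x$n_precursor))
  invisible(x)
}

# Survivor-precursor reporter targets for one observed precursor neutral mass:
# charges 2 and 3, with and without NH3 loss.
.precursor_reporters <- function(observed_neutral) {
  z <- c(2L, 3L, 2L, 3L)
  loss <- c(0, 0, NH3_MASS, NH3_MASS)
  data.frame(
    label = c("p_z2", "p_z3", "p_z2_nh3", "p_z3_nh3"),
    series = "p", index = NA_integer_, z = z,
    mz = (observed_neutral - loss + z * PROTON_MASS) / z,
    stringsAsFactors = FALSE
  )
}

#' Match reporter ions against a spectrum
#'
#' Each reporter target is matched to at most one peak within the fragment
#' tolerance and each peak may satisfy at most one reporter. Assignment is
#' greedy by matched-peak intensity, ties broken by smaller absolute m/z
#' error. Precursor-survivor reporters are computed from the spectrum's own
#' observed precursor neutral mass.
#'
#' @param s A [spectrum_record()] (MS2).
#' @param rs A [reporter_set()].
#' @param frag_tol Fragment tolerance (default 0.03 Da absolute).
#' @param tol_unit `"Da"` or `"ppm"`.
#' @param precursor_z Charge to use when the spectrum's own assignment is
#'   absent.
#' @return List with `n_reporters` (integer) and `assignments`, a
#'   `data.frame` of every reporter target with matched peak m/z, intensity
#'   and signed error (NA where unmatched).
#' @export
match_reporters <- function(s, rs, frag_tol = 0.03,
                            tol_unit = c("Da", "ppm"), precursor_z = NULL) {
  stopifnot(inherits(s, "spectrum_record"), inherits(rs, "reporter_set"))
  tol_unit <- match.arg(tol_unit)
  z <- if (!is.null(precursor_z)) as.integer(precursor_z) else s$precursor_z
  targets <- rs$ladder
  if (!is.na(z) && !is.na(s$precursor_mz)) {
    obs_neutral <- neutral_mass(s$precursor_mz, z)
    targets <- rbind(targets, .precursor_reporters(obs_neutral))
  }
  nt <- nrow(targets)
  assignments <- cbind(
    targets,
    data.frame(peak_mz = NA_real_, peak_intensity = NA_real_,
               error = NA_real_)
  )
  if (length(s$mz) == 0L || nt == 0L) {
    return(list(n_reporters = 0L, assignments = assignments))
  }
  tol <- if (tol_unit == "Da") rep(frag_tol, nt) else
    frag_tol * 1e-6 * targets$mz
  # candidate (target, peak) pairs within tolerance; peaks sorted by m/z
  lo <- findInterval(targets$mz - tol, s$mz) + 1L
  hi <- findInterval(targets$mz + tol, s$mz)
  idx_t <- rep.int(seq_len(nt), pmax(hi - lo + 1L, 0L))
  idx_p <- unlist(lapply(seq_len(nt), function(i)
    if (hi[i] >= lo[i]) lo[i]:hi[i] else integer(0)), use.names = FALSE)
  if (length(idx_t) == 0L) {
    return(list(n_reporters = 0L, assignments = assignments))
  }
  err <- s$mz[idx_p] - targets$mz[idx_t]
  ord <- order(-s$intensity[idx_p], abs(err))
  used_t <- logical(nt); used_p <- logical(length(s$mz))
  for (q in ord) {
    ti <- idx_t[q]; pi <- idx_p[q]
    if (used_t[ti] || used_p[pi]) next
    used_t[ti] <- TRUE; used_p[pi] <- TRUE
    assignments$peak_mz[ti] <- s$mz[pi]
    assignments$peak_intensity[ti] <- s$intensity[pi]
    assignments$error[ti] <- err[q]
  }
  list(n_reporters = sum(used_t), assignments = assignments)
}

#' Delta-mass of a spectrum relative to the unmodified peptide
#'
#' `delta_mass = observed neutral precursor mass - theoretical peptide mass`.
#' The free-ligand mass adds back the oxygen lost during Schiff-base
#' formation plus reduction. An isotope-corrected delta is reported
#' alongside the raw value: the integer `k` in `0..4` minimizing
#' `|delta_mass - k * 1.003355 - anchor|` is subtracted, recovering the
#' monoisotopic delta when the instrument picked an M+k isotope as
#' precursor. The anchor is the delta-mass the hit is presumed to be a
#' mis-pick of (0 for the unmodified peptide).
#'
#' Spectra without a charge assignment are enumerated over `charges`, one
#' row per charge, flagged `charge_enumerated`.
#'
#' @param s A [spectrum_record()] (MS2).
#' @param p The carrier [peptide()].
#' @param charges Charges to enumerate when the precursor charge is unknown.
#' @param anchor Reference delta-mass for isotope correction (default 0).
#' @return `data.frame` with columns `precursor_z`, `charge_enumerated`,
#'   `observed_neutral`, `delta_mass`, `free_ligand_mass`,
#'   `isotope_corrected_delta`, `isotope_k`.
#' @export
compute_delta_mass <- function(s, p, charges = 2:5, anchor = 0) {
  stopifnot(inherits(s, "spectrum_record"))
  p <- .as_peptide(p)
  if (is.na(s$precursor_mz)) {
    stop("spectrum '", s$scan_id, "' has no precursor m/z", call. = FALSE)
  }
  zz <- if (!is.na(s$precursor_z)) s$precursor_z else as.integer(charges)
  pm <- peptide_mass(p)
  obs <- neutral_mass(s$precursor_mz, zz)
  delta <- obs - pm
  k <- vapply(delta, function(d) {
    ks <- 0:4
    ks[which.min(abs(d - ks * ISOTOPE_SPACING - anchor))]
  }, integer(1))
  data.frame(
    scan_id = s$scan_id,
    precursor_z = zz,
    charge_enumerated = is.na(s$precursor_z),
    observed_neutral = obs,
    delta_mass = delta,
    free_ligand_mass = delta + OXYGEN_MASS,
    isotope_corrected_delta = delta - k * ISOTOPE_SPACING,
    isotope_k = k,
    stringsAsFactors = FALSE
  )
}

# weighted median (type: lower interpolation at crossing of half total weight)
.weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- !is.na(x) & !is.na(w) & w >= 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  if (all(w == 0)) w <- rep(1, length(x))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  at <- which(cw >= 0.5)[1]
  if (cw[at] == 0.5 && at < length(x)) (x[at] + x[at + 1]) / 2 else x[at]
}

#' Reference retention time of the unmodified reporter peptide
#'
#' Intensity-weighted median retention time of the control-class hits
#' (spectra matching the unmodified peptide), used as the anchor for the
#' retention-time acceptance window of candidates.
#'
#' @param control_hits Control hit table from [screen_spectra()] (needs
#'   columns `rt` and `matched_intensity`).
#' @return Reference retention time, minutes.
#' @export
reference_rt <- function(control_hits) {
  if (is.null(control_hits) || nrow(control_hits) == 0L) {
    stop("no control hits found; supply a reference retention time via the ",
         "screen configuration (reference_rt)", call. = FALSE)
  }
  w <- control_hits$matched_intensity
  if (is.null(w)) w <- rep(1, nrow(control_hits))
  .weighted_median(control_hits$rt, w)
}

#' Screening configuration
#'
#' Defaults mirror the acquisition and filtering settings of the orbitrap
#' workflow the screen was designed for: +/-0.03 Da fragment tolerance,
#' 5 ppm precursor tolerance, 10 reporter ions required, +/-15 min
#' retention-time window at a 120 min gradient (scaled proportionally for
#' other gradients), a control delta-mass window of -0.05..4.05 Da covering
#' the M..M+4 isotope mis-picks of the unmodified peptide, and a candidate
#' threshold of delta-mass > 40 Da.
#'
#' @param frag_tol Fragment match tolerance.
#' @param frag_tol_unit `"Da"` or `"ppm"`.
#' @param min_reporters Minimum reporter-ion count to retain a spectrum
#'   (benchmarking mode uses 4).
#' @param rt_window Retention-time half-window in minutes at a 120-min
#'   gradient.
#' @param scale_rt_window Scale `rt_window` by `gradient_length / 120`.
#' @param control_window Delta-mass window (Da) classifying unmodified
#'   peptide spectra.
#' @param candidate_min_delta Minimum delta-mass (Da) for a ligand candidate.
#' @param precursor_ppm Instrument precursor accuracy, ppm.
#' @param charges Charges enumerated for spectra without an assignment.
#' @param reference_rt Optional fixed reference retention time (minutes);
#'   when `NULL` it is derived from control hits.
#' @param min_tic_fraction,min_continuity,min_similarity Report-time quality
#'   flags; hits falling below are annotated, never removed.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(frag_tol = 0.03, frag_tol_unit = "Da",
                          min_reporters = 10L, rt_window = 15,
                          scale_rt_window = TRUE,
                          control_window = c(-0.05, 4.05),
                          candidate_min_delta = 40,
                          precursor_ppm = 5, charges = 2:5,
                          reference_rt = NULL,
                          min_tic_fraction = 0.1, min_continuity = 3L,
                          min_similarity = 0.5) {
  structure(
    list(frag_tol = frag_tol, frag_tol_unit = frag_tol_unit,
         min_reporters = as.integer(min_reporters), rt_window = rt_window,
         scale_rt_window = isTRUE(scale_rt_window),
         control_window = control_window,
         candidate_min_delta = candidate_min_delta,
         precursor_ppm = precursor_ppm, charges = as.integer(charges),
         reference_rt = reference_rt,
         min_tic_fraction = min_tic_fraction,
         min_continuity = as.integer(min_continuity),
         min_similarity = min_similarity),
    class = "screen_config"
  )
}

# longest consecutive matched run within one fragment series (any charge)
.ladder_continuity <- function(assignments) {
  best <- 0L
  for (ser in c("b", "y")) {
    idx <- sort(unique(assignments$index[assignments$series == ser &
                                           !is.na(assignments$peak_mz)]))
    if (length(idx) == 0L) next
    if (length(idx) == 1L) { best <- max(best, 1L); next }
    runs <- rle(diff(idx) == 1L)
    cons <- runs$lengths[runs$values]
    best <- max(best, if (length(cons)) max(cons) + 1L else 1L)
  }
  best
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Quantitative spectral-quality scores
#'
#' Deterministic proxies for the visual shortlisting criteria: fraction of
#' the spectrum's total ion current carried by matched reporter peaks,
#' longest consecutive matched run within one fragment series, and cosine
#' similarity of the reporter-intensity vector to the consensus vector of
#' the unmodified-peptide (control) spectra.
#'
#' @param s A [spectrum_record()].
#' @param match Result of [match_reporters()] for `s`.
#' @param control_consensus Consensus reporter-intensity vector (ordered as
#'   the match assignments), or `NULL` for `NA` similarity.
#' @return List with `matched_tic_fraction`, `ladder_continuity`,
#'   `control_similarity`.
#' @export
quality_scores <- function(s, match, control_consensus = NULL) {
  tic <- sum(s$intensity)
  matched <- match$assignments$peak_intensity
  matched[is.na(matched)] <- 0
  list(
    matched_tic_fraction = if (tic > 0) sum(matched) / tic else 0,
    ladder_continuity = .ladder_continuity(match$assignments),
    control_similarity = if (is.null(control_consensus)) NA_real_
      else .cosine(matched, control_consensus)
  )
}

#' Screen a run for ligand-bound and free reporter-peptide spectra
#'
#' The central operation: every MS2 spectrum is matched against the
#' reporter-ion set, its delta-mass computed, and retained spectra are split
#' into a control class (delta-mass inside `control_window`, evidence of the
#' unmodified peptide including isotope mis-picks) and a candidate class
#' (delta-mass above `candidate_min_delta` and retention time within the
#' window around the control-derived reference). Every retained hit carries
#' at least `min_reporters` matched reporter ions and the three quality
#' scores; quality flags annotate but never remove hits.
#'
#' @param run An [ms_run()].
#' @param p The reporter [peptide()] with `site_index` set.
#' @param cfg A [screen_config()].
#' @return List of class `screen_result`: `candidates` and `controls`
#'   (data frames), `reference_rt`, `rt_window` (scaled), and `consensus`
#'   (control reporter-intensity consensus vector).
#' @export
screen_spectra <- function(run, p, cfg = screen_config()) {
  stopifnot(inherits(run, "ms_run"), inherits(cfg, "screen_config"))
  p <- .as_peptide(p)
  rs <- build_reporter_set(p)
  pm <- peptide_mass(p)
  rows <- list()
  vecs <- list()
  for (s in run$ms2) {
    zz <- if (!is.na(s$precursor_z)) s$precursor_z else cfg$charges
    for (z in zz) {
      m <- match_reporters(s, rs, frag_tol = cfg$frag_tol,
                           tol_unit = cfg$frag_tol_unit, precursor_z = z)
      if (m$n_reporters < cfg$min_reporters) next
      obs <- neutral_mass(s$precursor_mz, z)
      delta <- obs - pm
      tic <- sum(s$intensity)
      matched_int <- m$assignments$peak_intensity
      matched_int[is.na(matched_int)] <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = s$scan_id, rt = s$rt, precursor_z = z,
        charge_enumerated = is.na(s$precursor_z),
        precursor_mz = s$precursor_mz,
        observed_neutral = obs, delta_mass = delta,
        free_ligand_mass = delta + OXYGEN_MASS,
        n_reporters = m$n_reporters,
        matched_intensity = sum(matched_int),
        matched_tic_fraction = if (tic > 0) sum(matched_int) / tic else 0,
        ladder_continuity = .ladder_continuity(m$assignments),
        stringsAsFactors = FALSE
      )
      vecs[[length(rows)]] <- matched_int
    }
  }
  empty_hits <- data.frame(
    scan_id = character(), rt = numeric(), precursor_z = integer(),
    charge_enumerated = logical(), precursor_mz = numeric(),
    observed_neutral = numeric(), delta_mass = numeric(),
    free_ligand_mass = numeric(), n_reporters = integer(),
    matched_intensity = numeric(), matched_tic_fraction = numeric(),
    ladder_continuity = integer(), control_similarity = numeric(),
    isotope_corrected_delta = numeric(), isotope_k = integer(),
    flag_low_tic = logical(), flag_low_continuity = logical(),
    flag_low_similarity = logical(), stringsAsFactors = FALSE
  )
  if (length(rows) == 0L) {
    ref <- cfg$reference_rt
    return(structure(
      list(candidates = empty_hits, controls = empty_hits,
           reference_rt = if (is.null(ref)) NA_real_ else ref,
           rt_window = .scaled_rt_window(cfg, run), consensus = NULL),
      class = "screen_result"
    ))
  }
  hits <- do.call(rbind, rows)
  is_control <- hits$delta_mass >= cfg$control_window[1] &
    hits$delta_mass <= cfg$control_window[2]
  # consensus of control reporter-intensity vectors (each scaled to unit L2)
  consensus <- NULL
  if (any(is_control)) {
    mat <- do.call(rbind, vecs[which(is_control)])
    norms <- sqrt(rowSums(mat^2))
    norms[norms == 0] <- 1
    consensus <- colMeans(mat / norms)
  }
  hits$control_similarity <- vapply(seq_len(nrow(hits)), function(i) {
    if (is.null(consensus)) NA_real_ else .cosine(vecs[[i]], consensus)
  }, numeric(1))
  # isotope correction: controls anchored at delta 0; candidates keep their
  # raw value here and are re-anchored within clusters (see cluster_hits)
  k <- vapply(hits$delta_mass, function(d) {
    ks <- 0:4
    ks[which.min(abs(d - ks * ISOTOPE_SPACING))]
  }, integer(1))
  hits$isotope_corrected_delta <- ifelse(
    is_control, hits$delta_mass - k * ISOTOPE_SPACING, hits$delta_mass)
  hits$isotope_k <- ifelse(is_control, k, 0L)
  hits$flag_low_tic <- hits$matched_tic_fraction < cfg$min_tic_fraction
  hits$flag_low_continuity <- hits$ladder_continuity < cfg$min_continuity
  hits$flag_low_similarity <- !is.na(hits$control_similarity) &
    hits$control_similarity < cfg$min_similarity
  controls <- hits[is_control, , drop = FALSE]
  ref <- cfg$reference_rt
  if (is.null(ref)) {
    ref <- if (nrow(controls) > 0L) reference_rt(controls) else NA_real_
  }
  window <- .scaled_rt_window(cfg, run)
  is_cand <- hits$delta_mass > cfg$candidate_min_delta
  if (!is.na(ref)) {
    is_cand <- is_cand & !is.na(hits$rt) & abs(hits$rt - ref) <= window
  }
  candidates <- hits[is_cand & !is_control, , drop = FALSE]
  rownames(candidates) <- NULL
  rownames(controls) <- NULL
  structure(
    list(candidates = candidates, controls = controls, reference_rt = ref,
         rt_window = window, consensus = consensus),
    class = "screen_result"
  )
}

.scaled_rt_window <- function(cfg, run) {
  if (cfg$scale_rt_window) cfg$rt_window * run$gradient_length / 120
  else cfg$rt_window
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %d candidate / %d control hits; reference RT %.2f min (window +/-%.1f)\n",
    nrow(x$candidates), nrow(x$controls), x$reference_rt, x$rt_window))
  invisible(x)
}

#' Cluster candidate hits into putative ligand masses
#'
#' Single-linkage clustering of candidate delta-masses at a relative (ppm)
#' tolerance, so repeated sightings of one ligand collapse into one entry.
#' The default of 50 ppm reflects the error propagation of the precursor
#' measurement into the delta-mass (see [tolerance_model()]): a 5 ppm
#' instrument on the full cross-linked peptide leaves roughly 30-60 ppm of
#' relative accuracy on a small delta-mass, so sightings of one ligand
#' scatter far wider than the instrument ppm.
#' Each member is isotope-corrected against the smallest delta-mass in its
#' cluster; the representative delta-mass is the intensity-weighted mean of
#' the corrected values. Clusters are ordered by spectrum count, then summed
#' reporter count.
#'
#' @param candidates Candidate hit table from [screen_spectra()].
#' @param tol_ppm Clustering tolerance on delta-mass, ppm.
#' @return `data.frame` of clusters (`cluster_id`, `delta_mass`,
#'   `free_ligand_mass`, `n_spectra`, `sum_reporters`, `best_scan`,
#'   `best_n_reporters`); the per-hit membership table is attached as
#'   attribute `"members"`.
#' @export
cluster_hits <- function(candidates, tol_ppm = 50) {
  stopifnot(is.data.frame(candidates))
  empty <- data.frame(
    cluster_id = integer(), delta_mass = numeric(),
    free_ligand_mass = numeric(), n_spectra = integer(),
    sum_reporters = integer(), best_scan = character(),
    best_n_reporters = integer(), stringsAsFactors = FALSE
  )
  if (nrow(candidates) == 0L) {
    attr(empty, "members") <- candidates
    return(empty)
  }
  ord <- order(candidates$delta_mass)
  h <- candidates[ord, , drop = FALSE]
  d <- h$delta_mass
  gap_tol <- tol_ppm * 1e-6 * d[-length(d)]
  breaks <- if (length(d) > 1L) which(diff(d) > gap_tol) else integer(0)
  cl <- cumsum(c(1L, as.integer(seq_along(d)[-1] %in% (breaks + 1L))))
  # enforce that every member stays within tolerance of the representative
  cl <- .refine_clusters(d, cl, tol_ppm, h$matched_intensity)
  h$cluster_id <- cl
  # isotope-correct members toward the cluster minimum
  for (g in unique(cl)) {
    i <- which(cl == g)
    anchor <- min(h$delta_mass[i])
    k <- vapply(h$delta_mass[i], function(x) {
      ks <- 0:4
      ks[which.min(abs(x - ks * ISOTOPE_SPACING - anchor))]
    }, integer(1))
    h$isotope_k[i] <- k
    h$isotope_corrected_delta[i] <- h$delta_mass[i] - k * ISOTOPE_SPACING
  }
  groups <- split(seq_len(nrow(h)), h$cluster_id)
  agg <- lapply(groups, function(i) {
    w <- h$matched_intensity[i]
    if (all(w == 0)) w <- rep(1, length(i))
    rep_delta <- sum(h$isotope_corrected_delta[i] * w) / sum(w)
    best <- i[order(-h$n_reporters[i], -h$matched_tic_fraction[i])][1]
    data.frame(
      delta_mass = rep_delta,
      free_ligand_mass = rep_delta + OXYGEN_MASS,
      n_spectra = length(i),
      sum_reporters = sum(h$n_reporters[i]),
      best_scan = h$scan_id[best],
      best_n_reporters = h$n_reporters[best],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  ord2 <- order(-out$n_spectra, -out$sum_reporters)
  out <- out[ord2, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  # renumber members consistently with the sorted cluster table
  id_map <- stats::setNames(out$cluster_id, names(groups)[ord2])
  h$cluster_id <- unname(id_map[as.character(h$cluster_id)])
  out <- out[, c("cluster_id", "delta_mass", "free_ligand_mass", "n_spectra",
                 "sum_reporters", "best_scan", "best_n_reporters")]
  rownames(out) <- NULL
  attr(out, "members") <- h
  out
}

# split chains whose members drift beyond tol from the weighted mean
.refine_clusters <- function(d, cl, tol_ppm, w) {
  repeat {
    changed <- FALSE
    for (g in unique(cl)) {
      i <- which(cl == g)
      if (length(i) < 2L) next
      ww <- w[i]; if (all(ww == 0)) ww <- rep(1, length(i))
      rep_d <- sum(d[i] * ww) / sum(ww)
      if (all(abs(d[i] - rep_d) <= tol_ppm * 1e-6 * rep_d)) next
      gaps <- diff(d[i])
      split_at <- which.max(gaps)
      newg <- max(cl) + 1L
      cl[i[(split_at + 1L):length(i)]] <- newg
      changed <- TRUE
    }
    if (!changed) break
  }
  cl
}
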