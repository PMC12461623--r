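#' Error-propagation tolerance model for delta-mass values
#'
#' The precursor is measured at instrument accuracy (ppm of the full
#' cross-linked peptide mass), but the quantity of interest is the small
#' delta-mass left after subtracting the exactly known theoretical peptide
#' mass. The absolute precursor error therefore propagates undiminished into
#' the delta-mass, inflating its relative (ppm) uncertainty -- strongly for
#' small ligands, mildly for large ones.
#'
#' @param p The carrier [peptide()] (or sequence string).
#' @param precursor_ppm Instrument precursor accuracy, ppm (default 5; a
#'   20 ppm scenario is the common alternative).
#' @param denominator `"delta"` expresses the propagated error relative to
#'   the peptide delta-mass (ligand minus oxygen); `"ligand"` relative to
#'   the free-ligand mass.
#' @return Object of class `tolerance_model`.
#' @export
tolerance_model <- function(p, precursor_ppm = 5,
                            denominator = c("delta", "ligand")) {
  denominator <- match.arg(denominator)
  stopifnot(precursor_ppm > 0)
  p <- .as_peptide(p)
  structure(
    list(peptide = p, peptide_mass = peptide_mass(p),
         precursor_ppm = precursor_ppm, denominator = denominator),
    class = "tolerance_model"
  )
}

#' Propagated ppm tolerance for a given ligand mass
#'
#' Absolute precursor error = `precursor_ppm * 1e-6 * (peptide mass +
#' delta-mass)`; the returned tolerance expresses that absolute error in ppm
#' of the delta-mass (default) or of the free-ligand mass.
#'
#' @param tm A [tolerance_model()].
#' @param ligand_mass Free-ligand monoisotopic mass, Da.
#' @return Tolerance in ppm (vectorized over `ligand_mass`).
#' @examples
#' tm <- tolerance_model("DSVTRQKEPRAPW")
#' propagated_tolerance_ppm(tm, 233.0549)  # Ac-6-FP
#' @export
propagated_tolerance_ppm <- function(tm, ligand_mass) {
  stopifnot(inherits(tm, "tolerance_model"))
  if (any(ligand_mass <= OXYGEN_MASS)) {
    stop("ligand mass must exceed one oxygen", call. = FALSE)
  }
  delta <- ligand_mass - OXYGEN_MASS
  crosslinked <- tm$peptide_mass + delta
  abs_err <- tm$precursor_ppm * 1e-6 * crosslinked
  denom <- if (tm$denominator == "delta") delta else ligand_mass
  abs_err / denom * 1e6
}

#' Propagated tolerance over a grid of ligand masses
#'
#' @param tm A [tolerance_model()].
#' @param mass_grid Numeric vector of free-ligand masses, Da.
#' @return `data.frame` with `ligand_mass` and `tolerance_ppm` (strictly
#'   decreasing in ligand mass).
#' @export
tolerance_curve <- function(tm, mass_grid) {
  if (length(mass_grid) == 0L) stop("empty mass grid", call. = FALSE)
  data.frame(
    ligand_mass = mass_grid,
    tolerance_ppm = propagated_tolerance_ppm(tm, mass_grid)
  )
}

#' Read a compound table
#'
#' TSV with columns `name`, `formula`, `monoisotopic_mass` (either of the
#' last two may be blank; the mass is computed from the formula when
#' absent). When both are present they must agree to 1e-4 Da. A small
#' curated table of B-vitamin vitamers, pterins and riboflavin-pathway
#' compounds ships with the package (see the example).
#'
#' @param path TSV path.
#' @return `data.frame` with `name`, `formula`, `monoisotopic_mass`,
#'   `source`.
#' @examples
#' read_compound_table(system.file("extdata", "compounds_mr1.tsv",
#'                                 package = "xlscreen"))
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "formula")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("compound table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"monoisotopic_mass" %in% names(tab)) tab$monoisotopic_mass <- ""
  if (!"source" %in% names(tab)) tab$source <- ""
  mass <- suppressWarnings(as.numeric(tab$monoisotopic_mass))
  for (i in seq_len(nrow(tab))) {
    has_formula <- nzchar(trimws(tab$formula[i]))
    if (is.na(mass[i])) {
      if (!has_formula) {
        stop("compound '", tab$name[i],
             "' has neither formula nor mass", call. = FALSE)
      }
      mass[i] <- monoisotopic_mass(tab$formula[i])
    } else if (has_formula) {
      fm <- monoisotopic_mass(tab$formula[i])
      if (abs(fm - mass[i]) >= 1e-4) {
        stop("compound '", tab$name[i], "': stored mass ", mass[i],
             " disagrees with formula mass ", round(fm, 5), call. = FALSE)
      }
    }
    if (mass[i] <= 0) stop("non-positive compound mass for '", tab$name[i],
                           "'", call. = FALSE)
  }
  data.frame(name = tab$name, formula = tab$formula,
             monoisotopic_mass = mass, source = tab$source,
             stringsAsFactors = FALSE)
}

#' Match a free-ligand mass against a compound table
#'
#' All compounds within `max_ppm` (default 200 ppm, the widest error the
#' propagation can justify) are returned, ranked by absolute ppm error with
#' alphabetical tie-break. Each match is flagged
#' `within_propagated_tolerance` using the error-propagation model; the
#' applied tolerance is clamped to the practical 30-60 ppm band when the
#' computed value falls outside it.
#'
#' @param free_ligand_mass Observed free-ligand mass, Da.
#' @param compounds Table from [read_compound_table()].
#' @param tm A [tolerance_model()].
#' @param max_ppm Hard cap on emitted matches, ppm.
#' @param practical_band Length-2 clamp on the applied propagated tolerance,
#'   ppm.
#' @return `data.frame` with `name`, `formula`, `monoisotopic_mass`,
#'   `ppm_error` (signed), `applied_tolerance_ppm`,
#'   `within_propagated_tolerance`.
#' @export
match_compounds <- function(free_ligand_mass, compounds, tm,
                            max_ppm = 200, practical_band = c(30, 60)) {
  stopifnot(is.data.frame(compounds), inherits(tm, "tolerance_model"))
  empty <- data.frame(
    name = character(), formula = character(), monoisotopic_mass = numeric(),
    ppm_error = numeric(), applied_tolerance_ppm = numeric(),
    within_propagated_tolerance = logical(), stringsAsFactors = FALSE
  )
  if (nrow(compounds) == 0L) return(empty)
  ppm_err <- (free_ligand_mass - compounds$monoisotopic_mass) /
    compounds$monoisotopic_mass * 1e6
  keep <- abs(ppm_err) <= max_ppm
  if (!any(keep)) return(empty)
  out <- compounds[keep, c("name", "formula", "monoisotopic_mass"),
                   drop = FALSE]
  out$ppm_error <- ppm_err[keep]
  tol <- propagated_tolerance_ppm(tm, free_ligand_mass)
  tol <- min(max(tol, practical_band[1]), practical_band[2])
  out$applied_tolerance_ppm <- tol
  out$within_propagated_tolerance <- abs(out$ppm_error) <= tol
  out <- out[order(abs(out$ppm_error), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
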