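#' Parse a Hill-style elemental formula
#'
#' Turns a formula string such as `"C8H9NO3"` into a named integer vector of
#' element counts. Only element symbols present in the embedded monoisotopic
#' mass table are accepted.
#'
#' @param formula Character scalar, e.g. `"C8H9NO3"` or `"H2O"`.
#' @return Named integer vector of element counts (class
#'   `elemental_composition`). An empty string yields an empty composition.
#' @examples
#' parse_formula("C8H9NO3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (nchar(formula) == 0L) {
    out <- integer(0)
    class(out) <- "elemental_composition"
    return(out)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(tokens))[[1]]
  covered <- rep(FALSE, nchar(formula))
  if (tokens[1] != -1L) {
    for (i in seq_along(tokens)) {
      covered[tokens[i]:(tokens[i] + attr(tokens, "match.length")[i] - 1L)] <- TRUE
    }
  }
  if (!all(covered)) {
    bad <- substr(formula, which(!covered)[1], nchar(formula))
    stop("malformed formula '", formula, "': unparsable token '", bad, "'",
         call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  unknown <- setdiff(sym, names(.ELEMENT_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(cnt)) stop("malformed count in formula '", formula, "'",
                       call. = FALSE)
  out <- tapply(cnt, sym, sum)
  out <- stats::setNames(as.integer(out), names(out))
  class(out) <- "elemental_composition"
  out
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named count vector from [parse_formula()], or a formula string.
#' @return Mass in Da (sum of count x lightest-stable-isotope mass).
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (length(comp) == 0L) return(0)
  if (any(comp < 0)) stop("negative element count", call. = FALSE)
  sum(.ELEMENT_MASS[names(comp)] * as.numeric(comp))
}

#' Construct a carrier peptide
#'
#' A peptide over the 20 standard residues, optionally annotated with the
#' 1-based position of the cross-linked residue (`site_index`) and its
#' coordinates within the mature carrier protein.
#'
#' @param sequence One-letter amino-acid string.
#' @param site_index 1-based position of the cross-linking site within the
#'   peptide, or `NULL`.
#' @param protein_span Optional length-2 integer vector, 1-based inclusive
#'   start/end of the peptide in the mature protein.
#' @return Object of class `peptide`.
#' @examples
#' peptide("DSVTRQKEPRAPW", site_index = 7)
#' @export
peptide <- function(sequence, site_index = NULL, protein_span = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(trimws(sequence))
  if (nchar(sequence) == 0L) stop("empty peptide sequence", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.RESIDUE_FORMULA))
  if (length(bad) > 0L) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(site_index)) {
    site_index <- as.integer(site_index)
    if (site_index < 1L || site_index > nchar(sequence)) {
      stop("site_index out of range 1..", nchar(sequence), call. = FALSE)
    }
  }
  if (!is.null(protein_span)) {
    protein_span <- as.integer(protein_span)
    stopifnot(length(protein_span) == 2L)
    if (diff(protein_span) + 1L != nchar(sequence)) {
      stop("protein_span length does not match sequence length", call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, site_index = site_index,
         protein_span = protein_span),
    class = "peptide"
  )
}

.as_peptide <- function(p) {
  if (inherits(p, "peptide")) p else peptide(p)
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence, sep = "")
  if (!is.null(x$site_index)) cat("  site ", x$site_index, sep = "")
  if (!is.null(x$protein_span)) {
    cat("  span ", x$protein_span[1], "-", x$protein_span[2], sep = "")
  }
  cat("  mass ", format(peptide_mass(x), digits = 10), " Da\n", sep = "")
  invisible(x)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @param p A [peptide()] or sequence string.
#' @return Mass in Da.
#' @examples
#' peptide_mass("DSVTRQKEPRAPW")
#' @export
peptide_mass <- function(p) {
  p <- .as_peptide(p)
  aa <- strsplit(p$sequence, "")[[1]]
  sum(.residue_masses()[aa]) + WATER_MASS
}

#' Adduct mass bookkeeping for a Schiff-base / reductive-amination cross-link
#'
#' Conjugation of a carbonyl ligand to a lysine via Schiff-base formation
#' followed by reduction adds the ligand minus one oxygen to the peptide
#' (condensation loses water, reduction adds two hydrogens; net -O). The
#' free-ligand mass is therefore the peptide delta-mass plus one oxygen.
#'
#' @param ligand_mass Monoisotopic mass of the free ligand, Da.
#' @return Object of class `adduct_mass` with fields `delta_mass` and
#'   `free_ligand_mass`.
#' @examples
#' adduct_from_ligand(monoisotopic_mass("C8H9NO3"))  # pyridoxal
#' @export
adduct_from_ligand <- function(ligand_mass) {
  stopifnot(is.numeric(ligand_mass), length(ligand_mass) == 1L)
  if (ligand_mass - OXYGEN_MASS <= 1e-6) {
    stop("ligand mass must exceed the mass of one oxygen atom", call. = FALSE)
  }
  structure(
    list(delta_mass = ligand_mass - OXYGEN_MASS,
         free_ligand_mass = ligand_mass),
    class = "adduct_mass"
  )
}

#' @export
print.adduct_mass <- function(x, ...) {
  cat(sprintf("<adduct> delta %.4f Da, free ligand %.4f Da\n",
              x$delta_mass, x$free_ligand_mass))
  invisible(x)
}

#' Neutral mass from m/z and charge
#'
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral monoisotopic mass, Da.
#' @examples
#' neutral_mass(523.942589, 3)
#' @export
neutral_mass <- function(mz, z) {
  z <- as.integer(z)
  if (any(z <= 0L)) stop("charge must be a positive integer", call. = FALSE)
  z * mz - z * PROTON_MASS
}

#' m/z from neutral mass and charge
#'
#' @param neutral Neutral mass, Da.
#' @param z Positive integer charge.
#' @return m/z.
#' @export
mz_from_neutral <- function(neutral, z) {
  z <- as.integer(z)
  if (any(z <= 0L)) stop("charge must be a positive integer", call. = FALSE)
  (neutral + z * PROTON_MASS) / z
}

#' Theoretical b/y fragment ion m/z
#'
#' Standard monoisotopic b- and y-ion m/z for a peptide, optionally with an
#' ammonia neutral loss.
#'
#' @param p A [peptide()] or sequence string.
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1..length-1`.
#' @param z Fragment charge, 1 or 2.
#' @param neutral_loss `"none"` or `"NH3"`.
#' @return m/z.
#' @examples
#' fragment_mz("DSVTRQKEPRAPW", "y", 1)
#' @export
fragment_mz <- function(p, series = c("b", "y"), index, z = 1L,
                        neutral_loss = c("none", "NH3")) {
  p <- .as_peptide(p)
  series <- match.arg(series)
  neutral_loss <- match.arg(neutral_loss)
  n <- nchar(p$sequence)
  index <- as.integer(index)
  if (index < 1L || index > n - 1L) {
    stop("fragment index out of range 1..", n - 1L, call. = FALSE)
  }
  z <- as.integer(z)
  stopifnot(z %in% c(1L, 2L))
  aa <- strsplit(p$sequence, "")[[1]]
  rm <- .residue_masses()
  neutral <- if (series == "b") {
    sum(rm[aa[seq_len(index)]])
  } else {
    sum(rm[aa[(n - index + 1L):n]]) + WATER_MASS
  }
  if (neutral_loss == "NH3") neutral <- neutral - NH3_MASS
  (neutral + z * PROTON_MASS) / z
}

#' Isotope-envelope m/z targets
#'
#' m/z positions of the first `n_isotopes` isotopologues of a species of the
#' given neutral monoisotopic mass, at the given charge, using the average
#' peptide isotope spacing of 1.003355 Da.
#'
#' @param neutral Neutral monoisotopic mass, Da.
#' @param z Charge.
#' @param n_isotopes Number of isotopes (M, M+1, ...), `>= 1`.
#' @return Numeric vector of m/z of length `n_isotopes`.
#' @examples
#' isotope_targets(1568.8059, 3, 3)
#' @export
isotope_targets <- function(neutral, z, n_isotopes = 3L) {
  n_isotopes <- as.integer(n_isotopes)
  stopifnot(n_isotopes >= 1L)
  z <- as.integer(z)
  if (z <= 0L) stop("charge must be a positive integer", call. = FALSE)
  (neutral + (seq_len(n_isotopes) - 1L) * ISOTOPE_SPACING) / z + PROTON_MASS
}
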