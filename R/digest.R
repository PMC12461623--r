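#' Proteolytic enzyme rule
#'
#' Cleavage specificity for in silico digestion: cleave C-terminally of any
#' residue in `cleave_after`, unless the following residue is in
#' `blocked_by_next` (classically proline).
#'
#' @param name Enzyme name.
#' @param cleave_after Character vector of residues cleaved after.
#' @param blocked_by_next Residues that block cleavage when they follow the
#'   site.
#' @param missed_cleavages Maximum number of missed cleavages, `>= 0`.
#' @return Object of class `enzyme_rule`.
#' @seealso [chymotrypsin()]
#' @export
enzyme_rule <- function(name, cleave_after, blocked_by_next = character(),
                        missed_cleavages = 0L) {
  stopifnot(length(cleave_after) >= 1L)
  missed_cleavages <- as.integer(missed_cleavages)
  stopifnot(missed_cleavages >= 0L)
  structure(
    list(name = name,
         cleave_after = toupper(cleave_after),
         blocked_by_next = toupper(blocked_by_next),
         missed_cleavages = missed_cleavages),
    class = "enzyme_rule"
  )
}

#' Chymotrypsin cleavage rules
#'
#' Default specificity cleaves after F/W/Y/L/M (blocked by a following P);
#' the high-specificity variant cleaves after F/W/Y only. Both conventions
#' are in routine use and the choice is exposed to the caller.
#'
#' @param specificity `"default"` (F/W/Y/L/M) or `"high"` (F/W/Y).
#' @param missed_cleavages Maximum missed cleavages.
#' @return An [enzyme_rule()].
#' @export
chymotrypsin <- function(specificity = c("default", "high"),
                         missed_cleavages = 0L) {
  specificity <- match.arg(specificity)
  enzyme_rule(
    name = paste0("chymotrypsin", if (specificity == "high") "-high"),
    cleave_after = if (specificity == "high") c("F", "W", "Y")
                   else c("F", "W", "Y", "L", "M"),
    blocked_by_next = "P",
    missed_cleavages = missed_cleavages
  )
}

#' In silico digestion of a protein
#'
#' Enumerates every cleavage-consistent product with up to
#' `rule$missed_cleavages` missed cleavages. Protein termini always act as
#' cleavage boundaries; at 0 missed cleavages the products partition the
#' protein.
#'
#' @param protein Protein sequence string over the 20 standard residues.
#' @param rule An [enzyme_rule()].
#' @return `data.frame` with columns `peptide`, `start`, `end`, `n_missed`,
#'   `length`, ordered by `(start, end)`.
#' @examples
#' digest_protein("AYDSVTRQKEPRAPWGSH", chymotrypsin())
#' @export
digest_protein <- function(protein, rule) {
  stopifnot(inherits(rule, "enzyme_rule"))
  protein <- toupper(trimws(protein))
  if (nchar(protein) == 0L) stop("empty protein sequence", call. = FALSE)
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(.RESIDUE_FORMULA))
  if (length(bad) > 0L) {
    stop("non-standard residue(s) in protein: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  n <- length(aa)
  # cleavage points after position i (1..n-1); termini are boundaries 0 and n
  cut_after <- which(aa[-n] %in% rule$cleave_after &
                       !(aa[-1] %in% rule$blocked_by_next))
  bounds <- c(0L, cut_after, n)
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + rule$missed_cleavages)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein, start, end),
        start = start, end = end,
        n_missed = j - i - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out$length <- out$end - out$start + 1L
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file path.
#' @param id Optional record identifier; defaults to the first record.
#' @return Protein sequence string.
#' @export
read_protein_fasta <- function(path, id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (!is.null(id)) {
    hit <- which(vapply(names(seqs),
                        function(nm) grepl(id, nm, fixed = TRUE), logical(1)))
    if (length(hit) == 0L) {
      stop("identifier '", id, "' not found in ", path, call. = FALSE)
    }
    seqs <- seqs[hit[1]]
  }
  as.character(seqs[[1]])
}

#' Select and rank reporter peptides covering the cross-linking site
#'
#' From a digest, retains the products covering the given (1-based, mature
#' protein) site position and ranks them: peptides whose length falls inside
#' the ideal range first (then shorter distance to the range), ties broken by
#' fewer missed cleavages, then alphabetically. The top-ranked product is the
#' reporter-peptide candidate; its `site_index` records where the site falls
#' within the peptide.
#'
#' @param products Digest table from [digest_protein()].
#' @param site 1-based position of the cross-linked residue in the protein.
#' @param ideal_range Length-2 numeric, preferred peptide length range.
#' @return `data.frame` of covering products with added `site_index` and
#'   `rank` columns, best candidate first. Empty (with a warning) when no
#'   product covers the site.
#' @examples
#' prods <- digest_protein("AYDSVTRQKEPRAPWGSH", chymotrypsin())
#' select_reporter_peptide(prods, site = 9)
#' @export
select_reporter_peptide <- function(products, site, ideal_range = c(8, 20)) {
  stopifnot(is.data.frame(products), nrow(products) > 0L)
  site <- as.integer(site)
  protein_len <- max(products$end)
  if (site < 1L || site > protein_len) {
    stop("site position ", site, " outside protein (length ", protein_len,
         ")", call. = FALSE)
  }
  cover <- products[products$start <= site & products$end >= site, ,
                    drop = FALSE]
  if (nrow(cover) == 0L) {
    warning("no digest product covers site ", site)
    cover$site_index <- integer(0)
    cover$rank <- integer(0)
    return(cover)
  }
  cover$site_index <- site - cover$start + 1L
  dist <- ifelse(cover$length < ideal_range[1], ideal_range[1] - cover$length,
                 ifelse(cover$length > ideal_range[2],
                        cover$length - ideal_range[2], 0))
  ord <- order(dist, cover$n_missed, cover$peptide)
  cover <- cover[ord, , drop = FALSE]
  cover$rank <- seq_len(nrow(cover))
  rownames(cover) <- NULL
  cover
}
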