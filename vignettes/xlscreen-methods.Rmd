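---
title: "Reporter-ion delta-mass screening for covalent peptide-metabolite cross-links"
author: "xlscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter-ion delta-mass screening for covalent peptide-metabolite cross-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlscreen)
```

## The problem

Antigen-presenting molecules such as MR1 capture small metabolites through a
Schiff base: the primary amine of a binding-groove lysine condenses with an
aldehyde or ketone of the ligand. The bond is labile, which makes the bound
metabolome hard to survey. Reductive amination (e.g. with sodium
cyanoborohydride) converts the imine into a stable secondary amine, turning a
transient interaction into a covalent peptide-metabolite cross-link that
survives proteolysis and reversed-phase LC-MS/MS. After digestion, the
lysine of interest sits inside one predictable "reporter" peptide -- for the
mature MR1 alpha chain, the chymotryptic 13-mer `DSVTRQKEPRAPW` with the
modified lysine at position 7 -- and any cross-linked ligand reveals itself as
a mass shift on that peptide's precursor.

Conventional open-modification search engines handle this case poorly: they
search a proteome-wide space for small, enumerated modifications, whereas
here the question is the inverse -- one known peptide, one known site, an
*unknown and possibly large* mass shift. `xlscreen` implements the
site-centric alternative:

1. select the reporter peptide by in silico digestion;
2. scan every MS2 spectrum for *reporter ions* -- backbone fragments that
   cannot contain the modified residue and are therefore identical in the
   free and any ligand-bound form;
3. for spectra that carry enough reporter ions, compute the delta-mass
   `observed precursor neutral mass - theoretical peptide mass`;
4. convert delta-masses to free-ligand masses and annotate them against a
   compound table under an error-propagation-aware tolerance;
5. quantify cross-linking yields from MS1 extracted-ion chromatograms.

## The reporter-ion model

For a peptide of length $n$ with the cross-linked residue at position $k$,
the ions that can never contain the site are $b_1..b_{k-1}$ and
$y_1..y_{n-k}$. Both charge states 1 and 2 are used, matching how the
doubly charged short fragments appear on high-resolution instruments. For
the 13-mer with $k = 7$ this gives 24 ladder targets. Four
*precursor-survivor* reporters are added per spectrum: the surviving
precursor at charges 2 and 3, with and without ammonia loss. Because the
ligand mass is unknown before identification, these four targets are
computed from each spectrum's **own observed precursor mass** rather than
from the theoretical peptide -- the only self-consistent choice available
pre-identification. The reporter universe is therefore 28 targets.

```{r}
rs <- build_reporter_set(peptide("DSVTRQKEPRAPW", site_index = 7))
rs
```

Matching is greedy by matched-peak intensity with ties broken by smaller
absolute m/z error; a peak may satisfy at most one reporter and vice versa,
so the reporter count can never exceed 28 and never increases when the
tolerance is tightened.

## Screening criteria

Retained spectra must satisfy three criteria, mirrored in
`screen_config()`:

* **Reporter count** (`min_reporters`, default 10): the operating threshold
  for discovery runs; a permissive benchmarking mode uses 4.
* **Retention time** (`rt_window`, default +/-15 min at a 120-min gradient,
  scaled proportionally with `gradient_length`): a cross-linked peptide is
  chemically almost identical to the free peptide and must elute nearby.
* **Delta-mass windows**: hits with delta-mass inside
  `control_window = [-0.05, 4.05]` Da are *controls* -- the free peptide,
  including precursors mis-picked on the M+1..M+4 isotopes; hits with
  delta-mass above `candidate_min_delta = 40` Da are *ligand candidates*.
  The gap between the windows deliberately excludes small, ambiguous
  adducts (oxidation, alkali adducts) that are not interpretable as
  groove-bound metabolites.

The reference retention time is the intensity-weighted median of the
control hits; it can be fixed via configuration when a run contains no free
peptide. Fragment tolerance defaults to an absolute +/-0.03 Da (with a ppm
mode available) and the precursor accuracy to 5 ppm, the specifications of
the orbitrap acquisitions this screen targets.

The historical workflow's visual shortlisting is replaced by three
deterministic scores that annotate but never delete hits: the fraction of
total ion current carried by matched reporters (`matched_tic_fraction`,
flag below 0.1), the longest consecutive matched run in one fragment series
(`ladder_continuity`, flag below 3), and the cosine similarity of the
reporter-intensity vector to the control consensus (`control_similarity`,
flag below 0.5). The exact weighting a human reviewer applies is
irrecoverable, so these proxies are declared rather than inferred, and
thresholds live in the configuration.

### Isotope correction

A precursor picked on the M+k isotope inflates the delta-mass by
$k \cdot 1.003355$ Da. Every hit carries an `isotope_corrected_delta`
alongside the raw value: the integer $k \in \{0..4\}$ minimizing the
residual against an *anchor* is subtracted. The anchor is 0 for
control-window hits (they are presumed mis-picks of the free peptide) and
the smallest member delta-mass within a cluster for candidates. The raw
delta-mass is never replaced.

## Error propagation and annotation

The instrument measures the whole cross-linked precursor at ~5 ppm, but the
subtraction of the exactly known peptide mass leaves the entire *absolute*
error on the small delta-mass. The relative tolerance appropriate for
compound lookup is therefore

$$\mathrm{tol}(L) = \frac{p \cdot 10^{-6} \cdot (M_\mathrm{pep} + \Delta)}{\Delta} \cdot 10^{6}\ \mathrm{ppm},$$

with $p$ the precursor accuracy, $M_\mathrm{pep}$ the peptide mass and
$\Delta = L - m_O$ the delta-mass of a ligand of mass $L$. For an
Ac-6-FP-sized ligand on the 13-mer this evaluates to ~41 ppm at $p = 5$ --
an order of magnitude wider than the instrument accuracy, and strongly
decreasing with ligand size:

```{r}
tm <- tolerance_model("DSVTRQKEPRAPW", precursor_ppm = 5)
tolerance_curve(tm, c(100, 233.0549, 400))
```

Two conventions exist for the denominator (the delta-mass or the
free-ligand mass); the package defaults to the delta convention, which
reproduces the canonical 40-45 ppm figure, and exposes the other. Compound
matching is local against a user TSV -- a small curated table of B-vitamin
vitamers, pterins and riboflavin-pathway compounds ships with the package
-- with a hard 200 ppm cap on emitted matches and the applied propagated
tolerance clamped to the practical 30-60 ppm band. Candidate clustering
uses a 50 ppm default for the same reason: sightings of one ligand scatter
by the propagated, not the instrument, tolerance.

## Yield quantification

Cross-linking yield is the ratio of chromatographic areas,
`100 * AUC(modified) / AUC(unmodified)`, both extracted as MS1
isotope-envelope XICs summing the M, M+1 and M+2 ions (the three most
abundant isotopes at this peptide mass) within 10 ppm, integrated
trapezoidally over retention time. No ionization-efficiency correction is
applied -- the modified and free peptide are chemically similar, and the
number is understood as a nominal yield. For free small-molecule XICs only
the monoisotopic trace is used, as their M+1 abundance is low. The yield is
flagged undefined when the unmodified AUC is zero rather than silently
returning infinity.

## The synthetic-run generator

All end-to-end tests run on `simulate_run()`, which emulates the
acquisition the screen targets. Its defaults are the study conditions and
are not tuned per test:

* reporter peptide `DSVTRQKEPRAPW`, site 7; one planted Ac-6-FP-like
  ligand at an 8% AUC ratio eluting 0.5 min after the free peptide;
* precursor charges 2-5 with the triply charged state dominant
  (probabilities 0.2/0.55/0.15/0.1), Gaussian precursor error with
  sd 5/3 ppm so that ~99.7% of precursors respect the 5 ppm
  specification, fragment error sd 3 ppm;
* complete b/y ladders at charges 1-2 with site-containing fragments
  shifted by the adduct mass, four precursor survivors, log-normal
  fragment intensities, 30 uniform noise peaks per spectrum in m/z
  100-2000;
* Gaussian elution (sigma 0.15 min) of 3-isotope MS1 envelopes
  (relative abundances 1/0.85/0.45) sampled every 0.03 min across a
  +/-1.2 min window around the apexes, on a 120-min gradient;
* 100 decoy MS2 spectra per run.

Decoys are ladders of *random* peptide sequences of the reporter's length
at random precursor masses, emulating unrelated background peptides. A
composition-preserving shuffle of the reporter peptide would be the wrong
decoy here: any shuffle sharing a prefix or suffix residue multiset with
the target genuinely contains those reporter-ion masses, so retaining it is
correct reporter detection rather than a false positive. Decoy spectra also
carry no precursor-survivor ions -- survivors computed from a spectrum's own
precursor match by construction, which would make small reporter thresholds
vacuous for any decoy model.

What the generator does **not** emulate -- chromatographic tailing, dynamic
exclusion, co-isolation interference, correlated fragment intensities,
real isotope fine structure -- bounds what passing tests show: they
demonstrate the correctness of the arithmetic, the windows, the matching
and the recovery logic under idealized signals, not robustness to every
artifact of real acquisitions.

## Numerical choices

* One embedded table of monoisotopic atomic masses (lightest stable
  isotope, >= 6 decimals) is the single source for all arithmetic; residue
  masses derive from residue elemental compositions at load time. Proton
  1.00727646688 Da, average isotope spacing 1.003355 Da.
* Masses are carried at full double precision; rounding happens only at
  report time (delta-masses print at 2 decimals, table masses at 4, ppm at
  1, retention times at 2).
* Greedy reporter assignment ranks candidate pairs by peak intensity, then
  absolute error; this is deterministic and order-independent.
* Single-linkage delta-mass clustering splits chains whose members drift
  beyond the tolerance from the intensity-weighted representative,
  re-splitting at the largest gap until the invariant holds.
* Degenerate inputs fail loudly: empty peptides, unknown residues or
  elements, non-positive charges, ligands at or below one oxygen mass,
  MS2 spectra without precursors, XICs without MS1 scans, zero-width
  elution profiles.
* The weighted median used for the reference retention time takes the
  midpoint at an exact half-weight crossing.

## Problem sizes used in the shipped checks

The package's own verification runs 100 seeded screen simulations (one
planted ligand with mass drawn uniformly from 60-400 Da, 9 planted
spectra classes, 100 decoys each) plus 200 yield simulations (the four
studied AUC regimes 0.4%, 8%, 10% and 30%, with and without 5%
multiplicative MS1 noise), and checks full recall, zero decoy retention at
the 10-reporter threshold, sub-1% retention at the 4-reporter benchmark
threshold, and yield recovery within 2% (noiseless) or 10% (noisy)
relative error. These sizes were chosen to give stable empirical rates
while remaining quick to re-run.

## Known limitations

* Only Schiff-base/reductive-amination chemistry is modeled (net adduct =
  ligand minus one oxygen); other conjugation chemistries need a different
  adduct rule.
* One peptide, one site per screen; localization across multiple candidate
  sites and chimeric-spectrum deconvolution are out of scope.
* No FDR estimation: the screen is a thresholded shortlist with quality
  annotations, by design.
* MGF input carries no MS1 scans, so yields require mzML.
* The error-propagation model treats the theoretical peptide mass as
  exact; calibration drift of the instrument is not modeled.
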