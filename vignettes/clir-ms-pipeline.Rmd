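---
title: "Identifying protein-RNA cross-links from isotope-doublet mass spectrometry"
author: "CLIRpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying protein-RNA cross-links from isotope-doublet mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CLIRpipe)
```

## The measurement model

UV irradiation at 254 nm covalently joins amino-acid side chains to RNA
bases that stack against them. After digesting the protein with trypsin
and the RNA with nucleases (RNase T1 cuts 3' of G, RNase A 3' of
pyrimidines, benzonase nonspecifically), a cross-linked peptide carries a
short oligonucleotide remnant — the *adduct*. When the sample contains an
equimolar mixture of unlabeled and stable-isotope-labeled RNA, every
cross-linked species appears twice in the precursor (MS1) domain: a light
and a heavy form separated by a mass shift $\Delta m$ that depends only
on the adduct's nucleotide composition and the labeling scheme. For full
$^{13}$C/$^{15}$N body labeling,

$$\Delta m \;=\; \sum_{b \in \{A,C,G,U\}} n_b \left( C_b\,\delta_{13C} + N_b\,\delta_{15N} \right),$$

where $n_b$ counts nucleotides of base $b$ in the adduct, $C_b$ and $N_b$
are the carbon and nitrogen counts of the corresponding residue, and
$\delta_{13C} = 1.0033548$ Da, $\delta_{15N} = 0.9970349$ Da are the
isotope increments. A uridine contributes 11.0243 Da, a cytidine
12.0213 Da. For post-digestion labeling, an enzymatic reaction transfers
a heavy-oxygen phosphate onto the 5'-OH of the cross-linked
oligonucleotide, so $\Delta m = k\,\delta_{18O}$ with
$\delta_{18O} = 2.0042464$ Da, independent of adduct length; the default
$k = 3$ reflects the three nonbridging positions of the transferred
phosphate (the bridging oxygen comes from the 5'-OH), giving
$\Delta m \approx 6.0127$ Da. Both $k$ and a fixed cross-link mass offset
are configurable; the default offset of 0 assumes the covalent bond adds
no mass beyond pure additivity, which is the convention for this
chemistry, and any deviation (e.g. loss of H$_2$) can be expressed
through the offset.

MS2 fragmentation of the peptide backbone produces b- and y-ion ladders.
Fragments containing the cross-linked residue carry the full adduct
mass; fragments on the other side do not. The ladder therefore localizes
the cross-link to a residue and, together with the precursor mass,
determines the adduct's *composition* — its nucleotide multiset, never
its sequence. All downstream reporting is composition-based for this
reason, and mapping a composition back onto the RNA
(`mapCompositionToRNA`) returns *every* sequence window whose content
matches, which is genuinely ambiguous and is reported as such.

### Mass conventions

A ribonucleotide residue is defined as the nucleoside-3'-monophosphate
minus water. An oligonucleotide in the default 5'-OH / 3'-phosphate
terminal state — the product chemistry of RNase T1 and RNase A — then
weighs the residue sum plus one water, and a mononucleotide adduct equals
the free NMP (U: 324.0359 Da). A 5'-phosphate state adds one HPO$_3$
(79.96633 Da); a 2',3'-cyclic phosphate is the default state minus water
and is off by default, keeping the default mass model simple while
remaining expressible. All residue masses derive from NIST monoisotopic
atomic masses and agree with an independent elemental-composition
computation to better than $10^{-4}$ Da (see the test suite).

## The search

1. **Candidate space.** Tryptic peptides (cleavage after K/R, suppressed
   before P, configurable missed cleavages) are crossed with all
   nucleotide multisets up to a length cap and a neutral-loss set,
   yielding light/heavy precursor mass pairs. The cap defaults to 4
   nucleotides — mono- to tetranucleotide adducts are what exhaustive
   nuclease digestion leaves in practice — and the loss set defaults to
   {none, $-$H$_2$O, $-$HPO$_3$}, the water and 3'-phosphate losses
   expected for this adduct chemistry. Benzonase is modeled as "every
   substring up to the cap": the search operates on compositions, so
   completeness of the product set matters, not its kinetic
   distribution.
2. **Doublet detection.** Same-charge precursor pairs whose neutral-mass
   difference matches any candidate $\Delta m$ within the precursor
   tolerance (default 10 ppm) become doublet candidates. A spectrum may
   participate in several pairs; precursor matching disambiguates.
3. **Precursor matching.** A candidate is retained when both its light
   mass and its $\Delta m$ match the observed pair within tolerance.
4. **Localization and scoring.** Every residue of the candidate peptide
   is evaluated as the putative site. The score of a site is the sum of
   $\log_2(1 + I)$ over matched theoretical ions (fragment tolerance
   default 20 ppm), multiplied by the matched fraction of the
   theoretical ladder. The fraction factor keeps a long peptide from
   outscoring a short one through scattered coincidental matches — the
   situation that arises systematically for decoys, which share the
   precursor mass of their target. This surrogate score is deliberately
   simple and documented rather than a reimplementation of any published
   engine's scoring; it is pluggable in the sense that all downstream
   steps consume only the numeric score. Ties are resolved by reporting
   the lowest-position site as primary together with the full ambiguity
   set; a peptide of length one is always site 1 with no ambiguity, and
   a spectrum containing only short adduct-free ions yields a multi-site
   ambiguity set rather than a false localization. Only the light member
   of each doublet is scored; the heavy member's ladder is the same up
   to the label shift on adduct-bearing ions, so scoring one member
   keeps the engine deterministic without losing the contract being
   tested.
5. **FDR.** Decoys are target peptides reversed with the C-terminal
   residue fixed, preserving tryptic termini and the exact precursor
   mass, so every doublet that matches a target also confronts its
   decoy. Identifications are collapsed to the best score per unique
   (peptide, adduct mass, site) key; the estimated FDR at score $s$ is
   $\#\{\text{decoys} \ge s\} / \#\{\text{targets} \ge s\}$, q-values
   are monotonized from the bottom of the score list, and targets with
   $q \le 0.01$ (default) are reported. At tied scores decoys are
   counted before targets, so a threshold placed at a tie is
   conservative. Spectral counts — the number of passing identifications
   per residue and composition *before* uniqueness collapse — are
   reported separately, since they carry the semiquantitative abundance
   information.

## The simulator

`simulateDataset` emits, for each ground-truth cross-link, a light and a
heavy precursor as two separate centroided MS2 spectra (matching how
doublets appear in centroided peak lists, rather than modeling a merged
isotope envelope), with:

* precursor neutral masses differing by exactly the label shift, and
  intensities split so the heavy share equals the configured
  heavy fraction exactly (0.5 models equimolar heavy/light RNA mixing);
* the complete theoretical b/y ladder of the true site, the heavy member
  carrying the shifted adduct on adduct-bearing ions;
* optional uniform random noise peaks and multiplicative log-normal
  intensity jitter, under a mandatory seed — fixed seed, byte-identical
  output;
* precursor charges drawn from {2, 3} and singly charged fragments, the
  typical regime for peptide-oligonucleotide adducts of this size.

`simulateTwoPhase` builds a dispersed and a condensed dataset whose
ground-truth site sets intersect exactly in a chosen shared set, for
testing the phase-comparison contract.

What the simulator does *not* emulate: isotope envelope shapes,
retention time, co-isolation/chimeric spectra, variable cross-linking
and ionization efficiency, missing fragments, and charge-state
correlation with peptide length. Passing round-trip tests therefore
demonstrates that the engine's logic is self-consistent — that it
recovers what the generative model of doublets and ladders encodes — not
that it would achieve the same sensitivity on instrument data, where
incomplete ladders and co-eluting species dominate the difficulty.

## Phase comparison

`comparePhases` partitions site keys (protein, residue, composition)
into shared and phase-specific sets and pairs spectral counts only for
shared keys. The comparison is deliberately semiquantitative: because
cross-linking and ionization efficiencies differ between species, only
identical sites are comparable between samples, so the package computes
no cross-phase ratios for non-shared keys and no statistical test — it
reports qualitative presence/absence plus paired counts.

## Problem sizes and numerical choices

The test suite exercises a toy system: one 90-residue protein with a
realistic tryptic site distribution and the pyrimidine-tract RNA with
three UCUCU repeats. Unit round trips use 5-15 unique sites and 10-40
doublet pairs; the end-to-end FDR characterization uses 20 unique sites,
200 doublet pairs, 80 noise peaks per spectrum and log-normal intensity
jitter (sd 0.3), with adducts up to three nucleotides — sizes chosen so
the whole suite and the reproduction script each run in minutes on a
single core while keeping enough identifications for a stable decoy
estimate. Tolerances default to 10 ppm (precursor) and 20 ppm
(fragment), ordinary settings for high-resolution instruments and
configurable because acquisition settings are sample-dependent.
Degenerate inputs fail loudly rather than silently: empty sequences,
empty peak lists, compositions subtracted below zero, heavy fractions
outside (0, 1), FDR requests without decoys, and overlapping
phase-specific truth sets are all errors.

## Known limitations

* One cross-linked residue and one adduct per peptide; no chimeric
  spectra, no open modification search, no modified nucleotides or
  amino acids.
* The surrogate score is not calibrated across peptide lengths beyond
  the matched-fraction factor; absolute score values are not comparable
  between datasets, only the decoy-referenced q-values are.
* Localization uses the light doublet member only.
* Benzonase completeness is an over-approximation of real product
  distributions; it can only widen the candidate space, never miss a
  true composition shorter than the cap.
* The FDR estimate inherits the usual target-decoy assumptions
  (decoys sample the null score distribution; one decoy per target).
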