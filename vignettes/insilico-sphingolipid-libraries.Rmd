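---
title: "In silico MS/MS and retention-time libraries for sphingolipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico MS/MS and retention-time libraries for sphingolipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingolibr)
library(dplyr)
```

## The problem

Untargeted LC-ESI-MS/MS lipidomics identifies compounds by matching four
measurements against references: retention time (RT), precursor *m/z*,
isotopic pattern and the MS/MS spectrum. For sphingolipids, experimental
reference spectra are scarce, while the class itself is combinatorially
large: a sphingoid base (d = dihydroxy, t = trihydroxy; S sphingosine, DS
dihydrosphingosine, P phytosphingosine) is N-acylated by a fatty acid that
may be non-hydroxylated (N), alpha-hydroxylated (A), beta-hydroxylated (B)
or omega-hydroxylated and esterified with a second acid (EO), under a head
group that is a hydrogen (Cer), a hexose (HexCer) or phosphocholine (SM).

sphingolibr generates reference libraries *in silico* for 21 such classes:
it enumerates species from configured building-block ranges, derives their
diagnostic fragment ions from hydrogen-rearrangement (HR) rules, predicts
their RT from molecular descriptors with a segmented QSRR regression, and
matches query spectra against the result with dot-product similarity.

## Building blocks and formula arithmetic

Species formulas are pure block condensation: a base with `c` carbons,
`d` double bonds and `h` hydroxyls is `C_c H_(2c+3-2d) N O_h`; a fatty acid
is `C_k H_(2k-2j) O_2` plus one oxygen per hydroxylation; each bond formed
(amide, glycosidic, phosphodiester, ester) removes one water. All *m/z*
derive from one frozen table of IUPAC monoisotopic masses through

    m/z = (mass(M') + a * mass(H) - z * mass(e)) / |z|

where `M'` is the neutral (valence-satisfied) fragment and `a` the signed
count of rearranged hydrogens. The electron mass is included by default.
The literature rarely states whether printed values include it; at
quadrupole-TOF accuracy the difference (0.55 mDa) is invisible — the
convention is therefore a documented, switchable argument
(`include_electron`), default on.

## Hydrogen-rearrangement rules and fragment templates

Nine HR rules constrain the hydrogens gained or lost on bond cleavage in
low-energy CID: P1 (-1 H), P2 (+1 H), P3 (0), P4 (-2 H) in positive mode
and N1 (-1 H), N2 (-3 H), N3 (-2 H), N4 (0), N5 (-2 H) in negative mode,
with P3/P4/N4/N5 formulated from the already-ionized precursor. Two-step
cleavages combine rules by summing their deltas (e.g. N2+N5 = -5 H).

Per-class diagnostic ions live in a YAML template
(`inst/extdata/fragment-templates.yaml`), not in code: each entry maps the
species composition to a neutral substructure through a small formula
expression (`fa + NH3 - H2O`, `base - NH3`, `M - C6H10O5`, ...) plus the HR
rule(s) and a relative intensity. The engine only evaluates; the chemistry
stays auditable and extensible.

The template content is anchored where the record is public and
reconstructed where it is not:

* Ceramide N-family (negative mode): three fatty-acid ions (b, c, d) and
  two sphingoid ions (e, f), each with a dehydration satellite — 10
  diagnostic ions. The deprotonated molecule is precursor-related, not
  class-diagnostic, and is not part of the ten.
* Ceramide A-family: 14 diagnostic ions, including the
  nucleophilic-substitution product — the deprotonated alpha-hydroxy fatty
  acid (`C16H32O3` minus a proton, *m/z* 271.2279 for a C16:0 chain).
* Ceramide B-family: the base peak is the retro-aldol (alpha-elimination)
  N-acetyl sphingoid ion, `base + C2H2O` under rule N1 (theoretical
  340.2857 for d18:1 with the electron convention on; 340.2852 without).
* HexCer classes add the hexose-loss (Y0) pair; SM carries head-group
  diagnostics only, because sphingoid-base fragments of SM are rarely
  abundant enough for acyl assignment; positive mode is limited to the
  precursor dehydration series and the sphingoid `-2H2O` fragment.

The exact substructures of the non-anchored satellites were never published
as text, only as figures; the shipped formulas are this package's
chemically-reasoned reconstruction and are documented as such. Relative
intensities follow a rank convention (base peak 999, diagnostics 400,
satellites 150) described in the source material only as empirically
determined; they are arbitrary but fixed.

Numerical choices: product peaks closer than 0.001 Th merge keeping the
larger intensity; observed-peak annotation takes the nearest template ion
within 10 mDa (default), ties to the lower *m/z*; template expressions that
would drive an element count negative raise an error naming the entry and
species.

## Enumeration and the manifest

The published generation ranges are fatty-acid carbons 12–36, fatty-acid
double bonds 0–3, sphingoid carbons 14–30, sphingoid double bonds 0–7; one
representative structure per composition. These are the defaults of
`enumeration_config()`. For Cer[NS] they yield 25 x 4 x 17 x 8 = 13,600 raw
combinations, yet the distributed library reports 3,360 structures for that
class: the class-specific filters behind the published counts were never
stated. The package therefore treats all filters as configuration (parity,
per-class sub-ranges) and ships the published per-class counts as reference
data (`reference_manifest()`), which the manifest arithmetic tests check
(structures x adducts = spectra; 109,448 structures over 21 classes) —
they are a fixture, not a generation target.

EO species use a three-chain shorthand `CLASS dNN:M/KK:J/LL:I`
(base / omega-hydroxy acid / esterified acid), an artifact convention; the
esterified-chain range defaults to the fatty-acid range since no separate
range was published.

## Representative SMILES

`assemble_smiles()` concatenates block templates: sphingoid double bonds
are trans starting at position 4 (5 for trihydroxy bases) spaced by two
bonds; fatty-acid double bonds are cis, methylene-interrupted, placed
relative to the methyl end. For double-bond counts too large for the
standard scheme the bonds pack greedily without geometry markers. Strings
are not canonicalized and stereocenters are not annotated; the promise is
exact atom bookkeeping, which `smiles_element_counts()` (a small
standard-valence SMILES counter) verifies against the block-condensation
formula, and which the test suite cross-checks with OpenBabel via
ChemmineR.

## The segmented RT model

Reverse-phase RT correlates with hydrophobicity, but one linear model
cannot follow a step-formed gradient. The shipped model
(`rt_model_published()`) is two OLS equations routed on XLogP:

* XLogP <= 15.9: `RT = -14 + 0.55 XLogP + 0.17 SssCH2 + 0.048 C2SP3 +
  71 BIC0 - 0.0022 ATSC2m + 0.00081 ATSC2v`
* XLogP >= 16.6: `RT = 9.5 + 0.16 XLogP + 0.076 LipoaffinityIndex -
  0.14 SpMAD_Dzi + 0.085 C2SP3`
* in the open interval: the unweighted arithmetic mean of both (the
  documented blending rule — not linear interpolation), with no clamping.

Units are minutes; descriptors are PaDEL 2-D descriptors supplied as CSV
(the package does not compute them). Descriptor names are matched
case-insensitively with whitespace/underscores stripped, so the printed
spelling "ATSC2 m" and PaDEL's `ATSC2m` are one column.

The refitting pipeline mirrors the published procedure: drop constant and
duplicate columns, keep descriptors with |Pearson r| >= 0.85 against RT
(absolute value, because hydrophilicity descriptors anticorrelate with
reverse-phase RT), split into overlapping XLogP windows (5.0–16.6 and
15.9–32.1; rows in [15.9, 16.6] go to both segments by default — whether
the original training did this was not stated, so `split_by_segment()`
exposes both policies; the outer window bounds describe the training-data
extent and are not applied as gates), then forward stepwise selection
minimizing `AIC = n log(RSS/n) + 2k` from the intercept-only model, ties
broken by descriptor name, stopping when no addition lowers the AIC (an
RSS below 1e-16 n also stops: an exact fit cannot improve). The published
training SD (0.14 min) and validation SD (0.31 min) require the original
descriptor tables and are not reproducible at desk scale; the
parameter-recovery tests instead simulate from the published equation with
sigma = 0.14 min and assert recovery within three standard errors.

## Identification

`identify_feature()` gates candidates on polarity, precursor *m/z* (MS1
tolerance 0.01 Da), and RT (2 min) when both sides carry one — records
without an attached RT bypass that gate. Scoring pairs peaks greedily by
nearest *m/z* within the MS2 tolerance (0.05 Da), each peak used once,
ties to lower *m/z*, and computes 100 x cosine of the intensity vectors
over the union of positions (the dot product), its reverse variant over
library positions only, and the matched fraction of library diagnostic
ions. The exact blend behind the original software's total score is not
public; the package uses the equal-weight mean of the three and reports
each component so the 80% cutoff can equally be applied to the raw dot
product. No intensity or *m/z* weighting is applied inside the cosine.

## Synthetic data

The fixture generators emulate instrument noise, not chromatography:
Gaussian *m/z* jitter (default sigma 2 mDa, about QTOF accuracy),
multiplicative log-normal intensity noise (default CV 20%), Bernoulli peak
dropout, precursor jitter at sigma/2. Decoys keep the precursor and peak
count but redraw fragment *m/z* uniformly. What passing tests show is that
the matcher recovers the true record under mass/intensity noise; they say
nothing about isomer separation, co-elution, in-source fragmentation or
real false-discovery rates, all of which require instrument data.

## Problem sizes and determinism

The test suite builds a two-class library (Cer[NS]/Cer[AS], 36 species x 3
adducts) for the matcher tests, uses 200 seeded noisy queries for the
rank-1 recovery check, and n = 60–200 simulations for the regression
recovery checks; every stochastic test fixes its seed through `withr`. The
full published ranges (over 100k structures) are supported but not
exercised in tests; enumeration is vectorized per class and spectra
generation is linear in species x adducts.

## Known limitations

* Fragment identities outside the anchored ions are reconstructions; they
  are internally consistent (sub-formulas, chain-shift invariance, HR
  deltas) but not guaranteed to match the original figure-only tables.
* Positive-mode templates cover the dehydration series only.
* Table-2 structure counts cannot be regenerated because their filters
  were never published; they are shipped as reference data.
* SMILES are representative, not stereochemically annotated; InChIKey
  generation and canonicalization are out of scope.
* Quantum-chemical fragmentation energetics (heat-of-formation scoring of
  competing schemes) are out of scope.
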