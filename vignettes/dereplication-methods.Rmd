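---
title: "Methods: formula assignment, profile matching and scaffold analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: formula assignment, profile matching and scaffold analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massderep)
```

# Scope and model

`massderep` implements a dereplication workflow for complex polyphenolic
mixtures such as water-soluble lignin hydrolysates. The mixture is
characterised three ways — ultrahigh-resolution negative-mode mass
spectrometry, a broad radioligand binding panel, and a ChEMBL-style
bioactivity store — and the three views are joined on molecular formulas and
panel targets. The output is a ranking of known database compounds by how
well their assay-derived boolean activity fingerprint matches the mixture's
experimental activity profile, plus Murcko scaffold summaries of the
best-matching chemotypes.

The workflow makes three structural assumptions worth stating explicitly:

* **Deprotonation-only ionisation.** Negative-mode ESI of polyphenols is
  modelled as [M − zH]^z−, z ∈ {1, 2}; neutral mass is m/z·z + z·1.007276 Da.
  Adducts, multimers and isotopologues are out of scope. The electron mass
  is neglected (≤ 0.004 ppm at m/z 200, far below the 1 ppm window).
* **CHO-only composition.** Formula enumeration covers carbon, hydrogen and
  oxygen under the constraint box C ≤ 120, H ≤ 200, O ≤ 60, O/C ≤ 1,
  H/C ≤ 2. Within 200–800 Da this box contains no two formulas closer than
  about 2 ppm, so a sub-ppm instrument identifies formulas uniquely.
* **Formula-level identity.** Database matching is by exact C/H/O counts.
  Isomers are indistinguishable by construction; all isomers of a matched
  formula enter the candidate set, which is precisely why the bioactivity
  profile comparison (not the mass match) carries the identification weight.

# Stage by stage

## Formula assignment

`enumerateFormulas()` is exhaustive within the constraint box: for every
feasible (C, O) pair the hydrogen count is bounded exactly by the requested
ppm window, so no candidate can be missed (the test suite checks equivalence
against a brute-force materialisation of the whole box). `assignPeaklist()`
keeps the candidate with the smallest absolute ppm error; ties are broken by
fewer oxygens, then fewer hydrogens. The tie-break is a package convention —
proprietary assigners do not document theirs — and is irrelevant in practice
inside the 200–800 Da box, where 1 ppm windows contain at most one
candidate. A single tolerance (default 1 ppm) applies to both charge
states.

## Bulk descriptors

Atomic ratios from bulk mass fractions use *nominal* integer masses
(12/1/16): `nominalRatios(66.7, 4.82, 28.48)` gives H/C 0.87 and O/C 0.32.
This is a deliberate convention choice: exact atomic weights (12.011/1.008)
give 0.86/0.32 and do not reproduce the two-decimal values customarily
reported for elemental analyses of lignin preparations. Reported ratios are
rounded half away from zero to two decimals. Oxygen may be computed by
difference (100 − C − H on the ash-free basis, nitrogen treated as zero for
a CHO substance). The "number-averaged" composition of an assigned formula
set is the unweighted mean of the per-formula mass-fraction vectors — each
formula counts once, regardless of peak intensity; an intensity-weighted
variant is available through the `weights` argument.

## Van Krevelen classification

Only the three regions the workflow actually quantifies are implemented:
aliphatic (H/C > 1.2), condensed aromatic (H/C < 0.5) and lignin-like
(H/C ∈ [0.5, 1.0] and O/C ∈ [0.3, 0.5]). Boundary semantics follow the
printed inequalities: the aliphatic and condensed bounds are strict, the
lignin window is closed, and precedence is aliphatic → condensed → lignin →
unclassified, so every point gets exactly one label. The window rectangles
are arguments of `vkRegions()`; richer taxonomies (tannins, lipids,
carbohydrates) are deliberately not reproduced. The classifier is applied
uniformly to both charge states.

## Panel profile

Percent inhibition is 100 − (measured/control)·100; values above the
threshold (default 50 %, *strictly* greater) are active, interference-flagged
records are excluded, everything else — including negative values, i.e.
stimulation — is inactive. The packaged fixture holds the 24 significantly
bound panel rows of the motivating study; family rows (e.g. the 5-HT1
serotonin receptors) carry semicolon-separated member gene symbols under one
panel key. Note the source counts do not fully reconcile (a "22 targets"
narrative against 24 table rows, and an ideal-score universe of "56
receptors" that matches neither 71 binding assays − 13 interference = 58 nor
the table): the package keeps all 24 rows, leaves the scored-target universe
entirely to the panel file the user supplies, and surfaces counts rather
than resolving the discrepancy.

## Activity hashing and fingerprints

The boolean hashing thresholds are *not* stated in the motivating study; the
package adopts the common medicinal-chemistry defaults — potency endpoints
(Ki, Kd, IC50, EC50) active at ≤ 10 µM, percent-effect endpoints active at
≥ 50 % (mirroring the panel's own significance rule) — and exposes both as
arguments, because downstream compound counts depend on them. Censored
values that cannot decide the comparison (e.g. "> 50 nM" against a 10 µM
cutoff) are undetermined and ignored. Units are handled for nM/µM/mM and
percent; anything else is undetermined with a warning. Per compound–target
pair, multiple assay flags aggregate by *any-active* (a single active assay
makes the pair active); a majority-vote alternative is available. Both
choices are defensible; any-active was made the default because screening
databases over-represent inactive confirmations of known actives.

## Fit scoring

For each compound and each non-excluded panel target: +1 when the
fingerprint entry is defined and agrees with the experimental state, −1 when
it disagrees, 0 when no data exist; excluded (interference) targets always
contribute 0 and are not part of the scored universe T. The fit score is the
plain sum; compounds scoring ≥ 1 are well-fitted. Ranking ties are broken by
compound id so reports are reproducible. The score is deliberately unweighted
and unnormalised — it mirrors the published definition; a compound tested at
many targets can therefore outscore an equally consistent compound tested at
few, which is a known property of the statistic, not a defect of the
implementation.

## Murcko scaffolds

No cheminformatics toolkit is available as an R dependency, so the package
carries its own minimal machinery. The scaffold is computed as the 2-core of
the molecular graph (iteratively deleting terminal atoms leaves exactly the
ring systems plus their connecting linkers), augmented with atoms attached
to the framework by double or triple bonds (exocyclic carbonyls), i.e. the
classic *typed* Bemis–Murcko framework, not the carbon-skeleton variant.
Output is canonicalised by Morgan-style iterative ranking with deterministic
tie individualisation followed by a rank-ordered DFS writer, so identical
frameworks compare equal as strings. Three limitations are documented
rather than hidden:

* Canonicalisation is self-consistent within the package but does not
  reproduce any other toolkit's canonical strings; cross-toolkit comparisons
  must go through graph equality (the test suite re-parses frozen RDKit
  reference scaffolds and compares canonical forms).
* Aromaticity is taken from the SMILES notation as written (lowercase
  atoms), not re-perceived; a Kekulé rendering and an aromatic rendering of
  the same ring are treated as different graphs. Inputs should use one
  convention consistently — all packaged generators do.
* Stereochemistry is parsed and dropped, so stereoisomeric scaffolds merge.

Acyclic molecules report an explicit empty scaffold (`""`) and form their
own bucket in `scaffoldDistribution()`, whose percentages use the parsed
cohort as denominator.

# The synthetic-data generator

The generator exists so that every stage is testable without downloads, and
its defaults state a definite world: formulas are drawn uniformly from the
constraint box within 200–800 Da (the database generation window of the
motivating study); peaks carry a 43 % doubly-charged fraction (the observed
1602-of-3748 share), Gaussian m/z error with σ = 0.3 ppm, and log-normal
intensities; the panel truth covers the 24 packaged targets with a 60 %
active fraction plus two interference rows; the store plants a 50 % formula
match fraction, with per-compound boolean profiles over 2–6 targets realised
by potency values straddling the cutoffs and assay descriptions embedding
the packaged key substrings.

One numerical choice deserves emphasis: the ppm error is a *truncated*
Gaussian (redrawn beyond 3σ). A calibrated instrument's stated accuracy
window bounds its errors, while an unbounded Gaussian occasionally throws a
peak outside the 1 ppm assignment window (~0.09 % per peak), which would
make exact ground-truth recovery a coin flip over seeds instead of an
invariant. With truncation at 0.9 ppm and the box's ≥ 2 ppm formula spacing,
assignment of generated peaks is provably exact, and the end-to-end
recovery test (planted fit scores and well-fitted subset reproduced
compound-for-compound) is a real invariant rather than a high-probability
event.

What a green synthetic run does **not** establish: realistic assay-description
prose (the generator embeds key substrings verbatim, so the text search is
exercised but not stress-tested), realistic formula mass spectra (uniform
box sampling, no homologous series or intensity structure), database-scale
multiplicities, or any of the study's external-data figures (the
1316-compound extraction, maximum fit score 4, 354 well-fitted compounds and
the published scaffold percentages require genuine ChEMBL v23 plus
supplementary inputs that were never deposited). The pipeline emits all of
those statistics in the same shape, so they become checkable the moment a
user plugs in a real ChEMBL dump via the column-mapping loader.

# Degenerate inputs and determinism

Empty candidate lists are results, not errors; peaks without a candidate
stay in the report flagged unassigned. Duplicate panel targets are rejected;
duplicate peaks are processed independently. Unparseable formula strings and
SMILES are skipped with warnings and excluded from denominators. All
randomness flows through explicit integer seeds; `runAll()` itself is
deterministic (a pure function of inputs and config), which the suite checks
by byte-comparing re-run outputs. The store loader accepts CSV tables only —
an SQLite driver is not among the package's allowed dependencies — with
automatic recognition of genuine ChEMBL column names.
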