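---
title: "Ground-truth validation of crosslink identifications with xlfdr"
author: "xlfdr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-truth validation of crosslink identifications with xlfdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlfdr)
```

## The problem

Crosslinking mass spectrometry (XL-MS) identifies pairs of peptides
covalently joined by a crosslinker reagent. Search engines estimate
their own error rate by target–decoy competition, but on a real sample
there is no way to check that estimate: the true set of interactions is
unknown. A synthetic peptide library closes this gap. Peptides are
designed with exactly one crosslink-able residue each (other reactive
positions are protected during synthesis — an acetylated N-terminal tag
ending in arginine, an amide-protected C-terminal tag, and an azide in
place of the amine on C-terminal lysines; tryptic digestion and
reduction later strip all of these, which `digestConstruct()` models).
The peptides are crosslinked in small groups of 6–10 and pooled only
afterwards. Consequently a reported crosslink can be correct **only**
if both peptides belong to the same group, and the *experimentally
validated FDR* of any result list is directly countable:

$$\mathrm{FDR}_{\mathrm{validated}}
  = \frac{\#\ \text{target XLs across peptides not crosslinked within one group}}
         {\#\ \text{target XLs total}}$$

where the numerator covers both peptides allocated to different groups
and peptides never synthesized at all. Both failure categories are
false by construction; `validatedFdr()` reports them separately because
they have different causes (group leakage during pooling cannot occur —
cross-group links indicate search errors; non-library hits often come
from mass-coincident sequence permutations, e.g. a homeotypic MAKLTK
link explained by the library peptide MAKTIK of identical mass).

## The record model and engine dialects

Every analysis runs on one canonical record model (`CrosslinkSet`): one
row per crosslink-spectrum match (CSM) or unique residue pair, with both
peptide sequences, link sites, protein accessions, peptide start
positions, a normalized score, a decoy flag and a link type. Engine
exports differ in column layout, score polarity, decoy encoding and
position base; an `EngineDialect` (a YAML file the user can audit and
edit) declares those choices and `readResults()` applies them. Scores
are normalized so larger always means more confident: lower-is-better
scores are negated, which preserves order and is invertible; the
original value is kept. Positions are normalized to 1-based.
`filterTargets()` then drops decoys and everything that is not an
inter-peptide residue pair — dead-end (mono-)links, linear peptides,
and loop-links, which are likewise not pairs of two peptides.
`groupToUniqueLinks()` collapses CSMs onto unique residue pairs; a
unique link carries the *maximum* member score, so a score cutoff
applied at link level retains exactly the links that would survive at
CSM level.

## Theoretical crosslink space

For $n$ peptides in one reaction the enumerable space is all unordered
pairs including homeotypic self-pairs: $n(n+1)/2$. Grouped reactions
give $\sum_g n_g(n_g+1)/2$. For the 43-peptide carboxyl-reactive
library this is 946 combinations when pooled — the quantity
`scripts/acceptance.R` recomputes. Each combination is classified
homeotypic (identical sequences), intraprotein (homomeric) or
interprotein (heteromeric); identity is literal uppercase string
equality with I and L distinct, so isobaric permutations are *not*
equated — deliberately, since catching exactly those errors is what the
library is for. `nearIsobaricPairs()` flags such pairs for diagnostics.

```{r enumerate}
lib <- generateLibrary(simulationConfig(nPeptides = 43,
                                        chemistry = "acidic", seed = 1))
classCounts(enumerateTheoretical(lib, "pooled"))
```

## Score cutoffs to a target real FDR

Because engines' internal estimates are often optimistic, a post-hoc
score cutoff can correct a result list to a chosen real FDR.
`fdrScoreCurve()` evaluates FDR and retained count at every distinct
score; `applyScoreCutoff()` returns the least strict threshold whose
retained set (inclusive $\ge$, ties kept — deterministic, and matching
the "minimal accepted score" reading) meets the target, i.e. the
qualifying threshold retaining the most identifications. One subtlety
follows from that optimality: when more than $1/\alpha$ true links are
present, a budget of $\alpha$ admits up to
$\lfloor \alpha n \rfloor$ false links without violating the target, so
a perfectly clean retained list is only guaranteed for smaller result
sets; the tests exercise the zero-false guarantee in exactly that
regime. An infeasible target returns an empty set rather than an error.

## Overlap analysis

`makeLinkKey()` gives every link an identity invariant to side order,
engine, score and modification annotations: both sides are
`sequence|protein|position`, sorted and joined. Link *sites within* a
peptide are excluded by default because engines disagree on
site assignment inside a peptide; a strict mode includes them.
`computeOverlap()` partitions the union of two or more unique-link sets
into exact membership regions and computes the validated FDR per
region — commonly found links are reliably enriched for true positives,
exclusive regions concentrate the errors. Conflicting protein
assignments for the same sequence/position are warned about, never
silently merged. Region output has no arity limit; `plotVenn()` renders
at most three sets.

## Crosslink properties and motifs

For compatibility with linear-peptide parameter math, a crosslink is
linearized by concatenating its two sequences in lexicographic order
(all properties used are order-invariant). `computeProperties()`
reports: GRAVY (mean Kyte–Doolittle hydropathy), aromaticity (fraction
of F/W/Y), monoisotopic mass (residue masses + one water per peptide
chain + an optional crosslinker mass delta, default 0 since reagents
differ), and the isoelectric point. The pI uses Henderson–Hasselbalch
net charge with the EMBOSS pKa set (N-term 8.6, C-term 3.6, K 10.8,
R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1), bisected on pH 0–14 to
0.01 units; the linearized chain is treated as having one pair of
termini, consistent with its linear representation.
`distributionComparison()` compares observed amino-acid frequencies
against the expectation that every theoretical crosslink yields exactly
one CSM; both CSM-level and unique-link-level inputs are accepted and
the level is recorded on the result, since either can be of interest.
`ppmAroundSite()` builds a position probability matrix over offsets
−3…+3 around the linked residue of both peptides; offsets beyond a
terminus contribute nothing, columns are normalized over their own
support, and zero-support columns stay at zero rather than being
normalized. The site column itself is included by default (and flagged
on the object) — it usually shows the reactive residue and is a useful
sanity check.

## The simulator

`generateLibrary()` and `generateResults()` make the whole pipeline
testable with no experimental data. The defaults emulate the physical
libraries' structure: peptides of 6–20 residues with exactly one
internal reactive residue and a tryptic C-terminal K/R, groups of 6–10
(near-equal sizes around 8), and a peptide-to-protein allocation at the
ratio of 141 peptides to 38 proteins. Planted result files contain
configurable counts of within-group (true), cross-group and non-library
(false) links plus decoy rows; scores come from two normal
distributions on the normalized scale — correct N(200, 30), incorrect
N(60, 20), separable as engines show for true vs false hits, with the
correct location in the range of real engine score cutoffs (~120–214).
All randomness flows from the single config seed, and the same seed
reproduces every file byte-for-byte.

What the simulator does *not* emulate: spectra and their quality,
retention behaviour, intensity-dependent score correlations,
shared-peak score artefacts between isobaric sequences, or engine
specific score shapes. Passing tests therefore demonstrate the
correctness of the counting, filtering, thresholding and comparison
logic — not that any particular engine's real output will be clean.

```{r pipeline}
cfg <- simulationConfig(nPeptides = 100, nTrue = 423, nCrossGroup = 2,
                        seed = 11)
lib <- generateLibrary(cfg)
sim <- generateResults(lib, cfg)
links <- groupToUniqueLinks(filterTargets(sim$records))
validatedFdr(links, lib)
```

## Numerical and design choices

* Displayed percentages are rounded half-up to one decimal
  (2/425 = 0.47 % prints as "0.5 %"); stored values are unrounded.
* FDR of an empty set is defined as 0 with a warning, keeping batch
  reports total.
* Threshold ties are retained (inclusive $\ge$).
* Delimited files are read as character and converted explicitly, so
  decoy flags like "T" survive untouched.
* Validation truth is keyed on peptide sequence (group membership), not
  protein: groups are defined on peptides.
* Coordinates are 1-based inclusive throughout; dialects declare their
  engine's base and the reader converts.
* Test problem sizes: the property suites run 1000 random record sets
  of 5–60 records against brute-force oracles, and closed-form
  enumeration checks cover every library size 1–50; the full suite runs
  in about 2–3 minutes.

## Limitations

The package validates *result lists*, not spectra: it cannot say why an
engine failed, only that it did. The validated FDR is itself an
estimate conditioned on the library design — errors that pair two
peptides of the same group by chance are invisible to it, a
(group-size-dependent) blind spot inherent to the approach. Engine
dialects ship as examples and must be adapted to the actual export
version at hand.
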