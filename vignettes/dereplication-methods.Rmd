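---
title: "Methods: molecular networking and rule-based lipid dereplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular networking and rule-based lipid dereplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnet)
```

`lipidnet` dereplicates lipids from untargeted LC-MS² data of organic
extracts: it reads an MGF of MS² spectra plus a feature quantification
table, builds one modified-cosine molecular network per ionization mode,
classifies each spectrum with a diagnostic-ion rulebook, and maps
per-extract abundance proportions onto the annotated network. This
vignette describes the underlying models, the tunable parameters, the
synthetic-data generator used for validation, and the design decisions
taken where the methodology left room.

## Mass arithmetic

All m/z values are monoisotopic, computed from a hard-coded IUPAC/CODATA
isotope mass table (7 decimals) over integer element counts. Ion m/z
always applies the electron-mass correction (0.0005486 Da, subtracted
for cations, added for anions): at the low-hundreds m/z of headgroup
fragments the correction is worth ~3 ppm, and published
high-resolution values for ions such as the glycerophosphate anion
(m/z 171.0064) or the cyclic glycerophosphate anion (m/z 152.9958) agree
with the electron-corrected theory distinctly better than with the
uncorrected one. Published table m/z are treated as *measured* values:
the package's mass audit requires agreement within 5 ppm rather than
decimal equality, which also absorbs the ~2.4 ppm deviation of values
such as the LPG O-14:0 [M+H]⁺ ion. Isotopic envelopes, multiply charged
ions and average masses are out of scope.

Two entries of the published glycerophosphoinositol table carry formulas
inconsistent with both their own printed m/z and the homologous series
(`PI 20:1/6:1;O2` printed with O16 where the m/z matches O15, and
`PI 18:0/5:1;O2` printed with the formula of the neighboring
`PI O-18:0/6:1;O2` row). The species table therefore derives every
formula from the species' chain composition and audits it against the
printed m/z, which makes those two rows consistent again; the printed
formulas are treated as typographical slips.

## Modified cosine and network topology

Spectra are preprocessed by keeping the 6 most intense peaks per
non-overlapping 50 Da window and square-root-transforming intensities
(these two values are exposed as parameters; they are conventional
GNPS-style defaults, not values fixed by the source methodology). The
modified cosine allows a peak pair to match directly or shifted by the
precursor mass difference, and maximizes the summed product of
L2-normalized weights over one-to-one assignments. The assignment is
solved *exactly* by depth-first branch-and-bound over the candidate
pairs with an optimistic upper bound for pruning; at the fragment
tolerances in use, candidate sets are sparse and the exact solver is
cheap, so no greedy approximation is needed. The test suite pins the
solver against a brute-force enumeration oracle on hundreds of random
small spectrum pairs.

Networks are built per ionization mode — positive and negative spectra
are never mixed, mirroring the two separately preprocessed datasets the
workflow assumes — with the FBMN parameter set: precursor m/z tolerance
0.02 Da, fragment tolerance 0.05 Da, cosine ≥ 0.7, ≥ 4 matched peaks,
≤ 10 neighbors per node and ≤ 100 nodes per component. Topology is
enforced in a fixed order: first the mutual top-K neighbor rule (an edge
survives only if each endpoint ranks the other within its top 10 by
cosine, ties broken by partner id), then oversized components are split
by repeatedly deleting their lowest-cosine edge, ties broken by the
lexicographically smallest node pair. The neighbors-then-components
order and the deterministic tie-breaks are this package's own fixings of
details the FBMN description leaves open; they make runs byte-for-byte
reproducible.

Library matching uses the stricter thresholds (cosine > 0.7, ≥ 6 matched
peaks) and, in addition, a 2 Da precursor window for candidate library
entries. The window matters for lipids specifically: homologues within a
class share their entire headgroup fragment template, and the
precursor-shifted matching then aligns the chain-dependent peaks too, so
cosine alone cannot separate `LPC 16:0` from `LPC 18:0`. Restricting
candidates to the precursor neighborhood is the standard
library-search behavior and resolves the ambiguity.

## The lipid rulebook

Nine class/polarity rulesets cover glycerophosphoinositols (GPI),
-glycerols (GPG), -ethanolamines (GPE), -phosphates (GPA, with a separate
ruleset for cyclic GPA), -serines (GPS), -cholines (GPC), inositol
phosphorylceramides (IPC) and prostaglandin-type oxylipins (PG, named
`FA n:d;Ok` at the species level). Each ruleset lists *required* and
*supporting* items — fixed-m/z diagnostic ions (e.g. m/z 259.0224
[C6H12O9P]⁻, 184.0733 [C5H15NO4P]⁺, 247.0577 [C6H16O8P]⁺) and neutral
losses applied to the precursor (e.g. inositol phosphate C6H13O9P,
phosphoric acid H3PO4, serine C3H7NO3) — plus the chain-release losses
whose complements carry the fatty chain.

A class becomes a candidate when at least `min_required` required items
match; candidates are ranked by required matches, then supporting
matches, then summed matched intensity, with a fixed class-priority
tie-break. `min_required` is a calibration of this package (the source
methodology states no minimum): most classes need a single distinctive
required item, while cyclic GPA needs 2 (its 152.9958 anion is a common
monoglycerophospholipid peak) and IPC in negative mode needs all 3 of
{259.0224, 241.0119, anhydro-inositol loss} because GPI spectra share
the first two. The GPI-vs-IPC ambiguity is additionally resolved by the
precursor formula: the IPC template is nitrogen-bearing and the GPI
template nitrogen-free, so the annotation cascade (class → formula →
chain) discards the wrong one whenever the diagnostic overlap is
misleading.

Two printed loss formulas required interpretation. The positive-mode IPC
loss appears once as `C6H13O8P` and once as `C6H13O9P` in the same
description; the rulebook uses inositol monophosphate C6H13O9P
(consistent with the established ceramide rearrangement mechanism) and
treats the O8 variant as a slip. The negative-mode IPC inositol loss is
printed as `C6H11O5`, which violates hydrogen parity for a neutral
closed-shell loss; it is implemented as anhydro-inositol C6H10O5
(162.0528 Da).

## Precursor formulas and chain inference

For a candidate class, species formulas are enumerated over the class
template: total chain carbons 10–44, chain double bonds 0–8, extra
(oxidation) oxygens 0–4, and 0/1/2 ester bonds for the
glycerophospholipid classes (0 esters = monoalkyl ether species);
IPC uses the ceramide-phosphoinositol template C(n+6)H(2n−2d+12)NO(9+k)P
and PG the free fatty acid template CnH(2n−2d)O(2+k). Candidates within
5 ppm of the observed precursor are kept, nearest first; within one
template family the nearest distinct formulas are ≥ 30 mDa apart, so the
top candidate is effectively unique at 5 ppm.

Chain composition is then read off the residual formula (precursor minus
class backbone). The residual alone is ambiguous in two ways: a plain
acyl chain has the same elements as a once-oxidized ether chain, and a
two-chain oxidized species has the same elements as a longer
single-chain species. Both are resolved by chain evidence: in negative
mode a generic carboxylate-anion scan (CxH(2x−1−2y)O(2+z)⁻ over the
chain grid) finds the fatty acid anions, and a found carboxylate whose
complement is itself a valid chain pins a two-chain split such as
`PI 18:0/6:1;O2`; in positive mode the class's chain-release losses
(e.g. [M+H−C9H19O11P]⁺ for GPI, [M+H−183.0655]⁺ for GPC) and, for IPC,
the combined water + inositol phosphate + fatty-acyl-ketene loss play
the same role, the latter resolving the sphingoid/acyl split in names
like `IPC (d18:1/16:0)`. Without evidence the composition falls back to
arithmetic with a minimal-oxidation preference (fewest extra oxygens,
acyl over ether); if that fallback is ambiguous the annotation keeps the
class but drops its confidence to `class`. Negative-mode IPC spectra
carry no chain-split evidence, so those annotations are reported at sum
composition (`IPC 34:1;O2`), which is the species-level granularity the
nomenclature prescribes; structural isomers with identical precursor and
fragment masses (e.g. the E/D prostaglandin series) are deliberately not
distinguished.

The fragment match tolerance is max(0.005 Da, 10 ppm): wide enough for
the ~2 mDa deviations seen in published fragment values, narrow enough
to keep neighboring classes' diagnostics apart. The precursor tolerance
is 5 ppm.

## Synthetic data: what it emulates and what it does not

The generator inverts the annotator: for each of the 55 reference
species it places every diagnostic ion and neutral loss of the class
rulebook at theoretical m/z, with rank intensities in tiers
(100/60/30/10) that keep fragments described as dominant on top. Each
species is emitted in the polarities in which it was reported (68
spectra), with its published retention time, and joined to a
three-extract feature table whose abundance profiles qualitatively
encode the reported distribution — 0.70/0.20/0.10
(hexane/CHCl₃/MeOH) for phospholipids and IPCs, 0.15/0.70/0.15 for
prostaglandins. These profiles and the per-species total areas are
synthetic by construction and labeled as such.

Noise is seeded and configurable: Gaussian m/z jitter on fragments and
precursor, log-normal multiplicative intensity noise (s.d. 0.2 by
default), and uniform noise peaks capped at 5% of the base peak. Noise
peaks are rejected within 0.1 Da (twice the network fragment tolerance)
of any template peak, so robustness tests measure tolerance behavior,
not peak collisions. Identical seeds give byte-identical datasets.

What passing tests on this generator do *not* show: real spectra have
chemical noise correlated with the analyte, in-source fragmentation,
isotope envelopes, co-eluting isomers and intensity patterns that vary
with collision energy — none of which are simulated. Round-trip recovery
of all 68 synthetic spectra validates the internal consistency of the
rulebook, the mass arithmetic and the inference cascade, not the
annotator's sensitivity or specificity on an arbitrary instrument's
output. Absolute intensity realism is explicitly not a goal; only
presence, tolerance and rank structure are simulated.

## Pipeline, problem sizes and degenerate inputs

`run_pipeline()` splits input spectra by polarity, skips (with a
warning) a polarity with no spectra, retains unannotated nodes with
class `"unknown"`, excludes zero-total-area features from the extract
summary with a warning, and writes GraphML, node/edge/annotation CSVs,
a per-class extract summary and a JSON run report. Per-node and
per-class extract proportions each sum to 1 by construction. Spectra
with empty peak lists are retained on reading (flagged with a warning)
and simply receive no annotation.

The validation suite runs on the 68-spectrum reference fixture, 500
random small spectrum pairs for the assignment oracle, and 50 random
150-node graphs for the topology bounds — sizes chosen so the whole
suite completes in about a minute while still exercising every rule
entry of every class (an explicit coverage audit asserts this).
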