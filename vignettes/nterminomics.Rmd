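---
title: "Calling mitochondrial intermediate-peptidase substrates from differential N-terminomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial intermediate-peptidase substrates from differential N-terminomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nterminomics)
```

## The biological model

Most mitochondrial proteins are imported with a cleavable N-terminal
targeting presequence. Inside the matrix the presequence is removed by the
mitochondrial processing peptidase (MPP), which recognizes sites with an
arginine two or three residues upstream of the cut (the −2R and −3R
classes) or, less often, no arginine at all. MPP cleavage frequently leaves
a destabilizing residue (F, Y, L, I, ...) at the new N-terminus. Two
intermediate peptidases then trim the MPP product: ICP55 removes a single
residue (occasionally two), and OCT1 (also called MIP) removes a longer
segment — eight residues in the classical yeast substrates. Both convert a
destabilizing N-terminal residue into a stabilizing one, in line with the
N-end rule that links protein half-life to the identity of the N-terminal
residue.

A knockout of either peptidase freezes the cascade at the MPP intermediate.
Quantitative N-terminomics (ChaFRADIC-style enrichment of blocked
N-terminal peptides, with light dimethyl labels on the wild type and medium
labels on the mutant) therefore reveals substrates as N-terminal peptides
whose abundance shifts between genotypes: the intermediate terminus is
enriched in the knockout, the mature terminus is enriched in the wild type.
This package implements the downstream analysis of such an experiment:
curation of credible N-termini, substrate calling, cleavage-motif
statistics, and presequence property analytics, plus a forward simulator
that generates ground-truthed data of the same shape.

All coordinates are 1-based and inclusive; peptide ratios are oriented
mutant/wild-type throughout, so "enriched in the knockout" always means a
ratio above 1. One canonical orientation is enforced at ingest because
mixed verbal conventions ("60 times more abundant in the mutant", "50
times more abundant in the wild type") are a classic source of sign errors.

## Curating credible N-termini

Three criteria turn the raw identified-peptide list into per-protein
N-terminus assignments:

1. **Localization.** Only peptides from proteins with a consensus
   localization call of `mitochondrial` (SUBAcon-style annotations supplied
   as a two-column table) are kept. Accessions without any annotation are
   discarded with an explicit `no_localization` reason rather than treated
   as mitochondrial.
2. **Start position.** Peptides beginning after residue 120 of the
   full-length protein are discarded as probable degradation products. The
   boundary is inclusive-keep: a peptide starting exactly at 120 survives,
   one starting at 121 does not.
3. **Most-N-terminal selection.** Among the remaining peptides of a
   protein, the most N-terminal start defines the mature N-terminus.
   Downstream peptides are dropped as internal, with one exception: a
   downstream peptide whose ratio reaches the differential threshold in
   either direction is retained, because differential downstream termini
   are processing intermediates, not degradation. The exception reuses the
   global 3-fold threshold, since the curation rule itself carries no
   separate number.

A protein whose mature start is residue 1 or 2 (initiator methionine kept
or removed) is classified `no_presequence`; anything further in is
`processed` and the upstream residues are its presequence. Acetylated and
dimethylated N-termini are curated jointly; acetylated termini are,
however, excluded from substrate evidence by default because an in-vivo
acetylated terminus is blocked and cannot be a free processing
intermediate. Both choices are switchable.

Every filter returns its kept and discarded rows, so the stages satisfy a
conservation invariant (input = kept + discarded, checked in the tests),
are idempotent, and are insensitive to row order.

## Substrate calling

`call_icp55()` applies three rules per protein, in order:

* **paired** — two termini 1–2 residues apart where the upstream peptide is
  up in the knockout (ratio ≥ fold) *or* the downstream peptide is down
  (ratio ≤ 1/fold). The removed residues are read directly off the protein
  sequence between the two starts. The offset limit of 2 covers the
  observed two-residue removals (FC, FT, YN, FN).
* **single_up** — a lone upregulated peptide whose first residue is
  destabilizing: the knockout has exposed an unstable terminus that the
  peptidase would have removed.
* **single_down** — a lone downregulated peptide whose preceding protein
  residue is destabilizing: the wild-type mature terminus, depleted in the
  knockout. A peptide starting at residue 1 cannot use this rule and is
  skipped with a diagnostic.

Calls qualify from 1.5-fold (inclusive) and are tiered by the maximal
supporting fold change: `primary` at ≥ 3-fold ("at least 3-fold" is read as
inclusive), `secondary` in [1.5, 3). One call is kept per protein with
deduplication priority paired > single_down > single_up (paired evidence is
the strongest argument form; a depleted mature terminus pins the cleavage
site more precisely than an enriched intermediate), then larger fold, then
longer removal, then the more N-terminal intermediate. The brute-force
enumeration oracle in the test suite re-derives these rules literally and
agrees with the implementation on hundreds of randomized small peptide
sets.

The default N-end-rule stability table classifies
F, L, W, Y, I, R, K, H, D, E, N, Q as destabilizing and
A, S, T, G, V, C, M, P as stable — the classical destabilizing classes.
Met and Cys sit on the boundary of the rule in plants; they are stable by
default, and analyses where their removal is observed pass
`stability_table(extra_unstable = c("M", "C"))`, which is what the bundled
worked example uses (two of its single-terminus substrates lose M and C).

`call_oct1()` calls a protein when at least `min_lines` knockout lines show
a peptide at or beyond the threshold in either direction. The default of 1
admits single-line evidence, which the data demand (two of the seven
bundled substrates are supported by one line only); `min_lines = 2` gives a
strict mode. Removed segments are inferred from paired termini up to 20
residues apart when both directions are observed; otherwise the removal is
left undetermined rather than guessed, and nothing constrains the removed
segment to begin at an MPP intermediate — one substrate class (B13-like) is
matured by OCT1 without MPP acting at all.

`detect_ladders()` reports chains of ≥ 3 termini with start-to-start gaps
≤ 2 whose regulation is non-increasing downstream — the signature of
sequential single-residue cleavage, as seen for acyl carrier protein 3
(three termini: 100-fold up, 10-fold down, 100-fold down) and for the
RNA helicase PMH2 (a five-terminus chain).

## Cleavage-motif statistics

Windows span 20 residues upstream and 10 downstream of the mature
N-terminus, with −1 the last presequence residue and the cleavage between
−1 and +1; short presequences are padded with `-`, and pads are excluded
from both counts and the per-position n. The iceLogo-style differential
compares observed per-position frequencies with a position-independent
reference computed from the supplied proteome FASTA (never hardcoded, so
the reference always matches the organism and database at hand). Each cell
gets a two-sided one-sample proportion z-test with variance
f·(1−f)/n under the reference frequency f; cells at p ≥ 0.05 are flagged
non-significant. The choice of test follows the original differential-logo
approach; the threshold of 0.05 is an assumption (the source method leaves
it configurable) and no multiple-testing correction is applied across
cells, mirroring that tool's convention. The test suite checks the cells
against an independently coded binomial normal-approximation oracle.

`consensus_string()` renders positions −3..+2 (the span of all motifs of
interest): residues at observed frequency ≥ 0.20 that are significantly
over-represented, in decreasing frequency, with `X` where none qualifies.
On the bundled 88-substrate ICP55 window set this recovers an
R at −3, F/Y at −1 and S(S/T) after the cut — the −3R motif family with a
destabilizing residue immediately before the cleavage.

Small window sets deserve a caution. With only 7 OCT1 substrate windows, a
residue shared by 3 of 7 mature termini (frequency 0.43 against a
reference near 0.1) is flagged significant by the uncorrected proportion
z-test, so the OCT1 consensus reports the alanine at +1 and valine at +2
that the seven mature sequences happen to share (`XXX↓AV`) rather than a
fully empty motif. At n = 7 the normal approximation is at the edge of its
validity and a shared residue in 3 of 7 sequences is weak evidence; the
upstream positions, where a true recognition motif would live, show
nothing. We report the statistic as defined rather than special-casing
small n, and read the result as "no upstream motif" — consistent with the
absence of any −10R-like signal in these substrates.

## Presequence properties

`net_charge()` is a Henderson–Hasselbalch sum over ionizable side chains
(K, R, H positive; D, E, C, Y negative) with pKa defaults
D 3.65, E 4.25, C 8.3, Y 10.07, H 6.0, K 10.53, R 12.48, N-terminus 8.0,
C-terminus 3.1. Free termini are included by default because the quantity
of interest is the charge of the bare presequence peptide, which is how
such values are conventionally computed in peptide calculators; both the
pKa set and the termini flags are configurable, and charge comparisons
should carry a ±0.3 allowance for pKa-set variation between calculators.
The charge is monotonically non-increasing in pH and additive over
concatenation when termini are excluded (both are tested invariants).

Group summaries report n, mean/min/max length, mean net charge and pooled
residue frequencies. Group location comparisons use Welch's two-sided
t-test — the published group P-values for such data come from an
unspecified test, so Welch is an explicit assumption here, chosen for its
robustness to unequal variances; degenerate identical zero-variance groups
return p = 1 by convention. Cleavage-site prediction scoring counts a
prediction correct within ±1 residue; proteins in the truth set without a
prediction count as incorrect (so the denominator is the full truth set).
`compare_nterm_sets()` partitions shared accessions into identical and
differing termini and reports signed offsets, the form used when
reconciling N-termini across studies and methods.

## The synthetic-data generator

`generate_proteome()` forward-simulates the whole cascade with ground
truth attached to every protein. The defaults are the study conditions the
package is tested under, chosen once:

* **fraction_icp55_substrate = 0.5** — in plant mitochondria roughly half
  of the proteins with cleavable presequences are further trimmed by
  ICP55, far more than in yeast.
* **fraction_oct1_substrate = 0.05** — OCT1 substrates are rare (a handful
  among ~10² cleaved proteins).
* **presequence lengths** — truncated normal, mean 43.3, sd 20, range
  7–117 residues, the empirical range of plant mitochondrial presequences.
* **composition** — presequence positions draw from a fixed table with R,
  S, A, L enriched ≥ 1.5× over background and acidic residues depleted;
  this is a configuration default emulating known presequence composition,
  not a scientific claim.
* **ratio_noise_sd = 0.2** (log2 scale) — at this noise a 3-fold threshold
  sits ≈ 7.9 standard deviations out, so false differentials are
  vanishingly rare, matching the stringency of dimethyl-ratio data.
* **ratio_cap = 100** — reported fold changes are bounded; termini absent
  from one channel are reported at the cap rather than as missing, because
  bounded extreme fold changes are how such tables report
  presence/absence.
* **leak = 0.02** — residual intermediate abundance in the wild type. No
  abundance model for residual intermediates exists in the source data, so
  this is a free parameter of the simulator.
* ICP55 substrates receive a destabilizing residue (F/Y/L/I, weighted
  toward F) at the MPP site, a two-residue removal with probability 0.1,
  an arginine three residues upstream of the final mature start, and a
  small/hydroxylated mature start — the planted motif the motif module
  must recover. A 0.15 fraction of OCT1 substrates is MPP-independent
  (B13-like), matured from residue 2.
* Presequence-less proteins lose the initiator methionine with probability
  0.5 when residue 2 is small (A/S/T/G/V/C/P), populating the start ≤ 2
  class; a documented heuristic.

Digestion is semi-specific: any start (the enriched N-terminus), ArgC-like
at the C-terminal side cleaving after arginine only, because lysines are
dimethyl-blocked; reported peptides are 7–45 residues. Observed ratios are
(mutant abundance)/(wild-type abundance) × 2^ε with ε ~ N(0, sd), clipped
to [1/cap, cap]. Everything is deterministic given the seed, and every
emitted peptide start equals a simulated terminus (a tested round-trip).

What the simulator does **not** model: spectra, peaks, charge states,
retention times, fractionation, missed identifications, protein inference
ambiguity, or abundance-dependent detection. Passing recovery tests on
this generator therefore shows that the calling logic is correct under the
stated noise model — not that the pipeline is robust to every artifact of
real LC-MS data.

## Problem sizes, tolerances and numerical choices

The recovery benchmarks use 200-protein cohorts at log2 noise 0.2 (ICP55
sensitivity and precision ≥ 0.95; false-positive rate ≤ 1% with zero
planted substrates; exact recovery without noise), a 2000-protein draw for
the binomial check of substrate fractions, and 50 seeded runs of
50-protein proteomes for motif recovery (planted R at −3 and the F/Y/L/I
class at −1 recovered in ≥ 48 of 50 runs). These sizes are the package's
chosen benchmark conditions; the whole suite runs in well under a minute.
Frequency sums are checked to 1e−9; ladder monotonicity allows a 1e−9
ratio slack so exact ties count as non-increasing. Ties at the minimal
start all remain as evidence; ties in consensus rendering follow
decreasing frequency with alphabetical order as the stable fallback.

## Known limitations

* Peptides matching a protein more than once, or mapping to no supplied
  protein, are excluded with diagnostics; there is no protein-inference
  step for shared peptides.
* I and L are never collapsed during mapping (database-assigned proteins
  make the distinction meaningful); this is a deliberate convention.
* The curated call set is exactly what the rules produce. The raw
  differential peptide set and the deduplicated call set are both exposed,
  and no manual exclusions are emulated.
* Motif significance at very small n is reported as defined by the
  uncorrected proportion test; see the caution above.
* No graphical logo rendering; the matrices and consensus strings are the
  contract, and plotting can be layered on top.
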