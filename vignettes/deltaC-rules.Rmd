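---
title: "Delta-C rules: summarizing and imputing modification shifts in nanopore pore models"
author: "poreImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-C rules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreImpute)
```

## The model

A pore model maps each k-mer to the expected ionic current level (and its
spread) produced while that k-mer occupies the pore's sensing region. A
base modification — 5mC in CpG or GpC context, glucosylated cytosine, and
so on — changes those levels not only for the modified base but for every
k-mer overlapping it. Write v(x₀) for the canonical level of a k-mer x₀
and v̂(x) for the level of its modified form x (modification code, e.g.
`M`, substituted at the modified base). The quantity of interest is

ΔC(x) = v̂(x) − v(x₀),

the modification-induced current shift. The package's premise, which holds
to a good approximation in trained CpG tables, is that ΔC decomposes
additively into a **position effect** (where in the k-mer window the
modification sits) plus a small number of **context effects** (specific
bases at specific positions co-occurring with the modification):

ΔC(x) ≈ h_m + Σ_{(f,b): x[f]=b} h_{m,f,b}.

Each term is a *ΔC rule*. A rule set for a CpG 6-mer model typically has 5
position rules and a few dozen pattern rules — far fewer numbers than the
1280 modified 6-mers they reproduce — and each rule is directly
interpretable ("a T immediately left of the methylated CpG pulls the level
down by about 4 pA").

## Rule derivation

`deriveRules()` fits the decomposition by iterative median-residual
extraction, independently per modification position m:

1. The position rule is the median ΔC of all training k-mers modified at
   m; residuals are deltas minus that shift.
2. Every candidate pattern (f, b) — f outside the motif footprint, b one
   of ACGT, at least `minGroupSize` matching training k-mers — is scored
   by the median residual of its matching k-mers. The largest |median|
   wins (ties broken toward the smallest f, then alphabetically by b). If
   it exceeds the stopping threshold `r`, the rule is recorded, its shift
   is subtracted from the residuals of the *matching k-mers only*, and
   the scan repeats; otherwise derivation at m stops.

At termination every candidate median is at most `r`
(`ruleResidualScan()` re-checks this certificate). Derivation is a pure
function of the multiset of delta records: permuting the input leaves the
rule set unchanged, and adding a constant to one position's deltas moves
exactly that position rule.

Two semantic choices deserve a note, since the two obvious alternatives
disagree:

* **Sign convention.** ΔC is modified − canonical. Under this convention
  the worked 3-mer example is internally consistent: position rule −4,
  pattern rules −2 (A at 1) and +1 (T at 3) impute AMT from ACT = 11 as
  11 + (−4 − 2 + 1) = 6.
* **Residual-subtraction scope.** A pattern rule's shift is subtracted
  from the residuals of the k-mers that match it, not from the whole
  position group. Group-wide subtraction would push non-matching k-mers
  away from their own fit and corrupt their imputed values; under
  subgroup subtraction the per-position median example ((−1 + (−3))/2 =
  −2 for the A-at-1 group after a −4 position rule) comes out exactly.

Medians of even-sized groups average the two central values (the R
default), which the same example forces. A pattern may be re-selected in
later iterations if other extractions move its median back above `r`;
re-selections act additively, and an iteration cap
(`maxIterationsPerPosition`, default 1000) guards against floating-point
oscillation — in practice CpG-scale derivations use a few dozen
iterations.

## Identifiability: what "recovering the rules" can mean

Pattern groups overlap: a k-mer with an A at position 1 may also have a T
at position 3. When a ground-truth rule set places many rules on many
distinct pattern positions of the same modification position, the additive
decomposition of the resulting ΔC table is **not unique**, and median
extraction may legitimately return a different split — extra compensating
rules, shifts redistributed between patterns — while fitting every
training ΔC exactly. The package's tests therefore distinguish:

* **Function recovery** (always expected): on a noise-free, fully covered
  table the derived rules reproduce every k-mer's ΔC, and hence every
  imputed level, to within k·r per entry (each of the at most k applicable
  rules stops at a residual ≤ r).
* **Shift recovery** (expected in the identifiable regime): when each
  modification position carries pattern rules on at most two distinct
  pattern positions, one base each (`simulateRuleSet(distinctPositions =
  TRUE)`), every candidate group's median of the *other* rules'
  contributions is exactly zero under full coverage, so each shift is
  recovered exactly.

The identifiability threshold can be worked out from the group
arithmetic: within any candidate group, a quarter of the k-mers match a
rule on another pattern position, so with rules on q other positions the
zero-contribution mass is (3/4)^q of the group, and the group median stops
being the rule's own shift once that mass drops to one half. Two other
positions (mass 9/16) are safe; three are not.

## Imputation modes

`imputeModel()` applies a rule set to a complete canonical table:

* **full** — every modified k-mer gets the rule-based level, including
  those that were trained. Because each rule pools a median over many
  k-mers, this denoises the trained entries as well; it is the variant
  that behaves best in practice.
* **missing** — trained entries are copied verbatim from the trained
  table; only the untrained remainder is imputed. This preserves the raw
  training values (and their noise).

Pattern matching is against the k-mer *as written*: in a
multi-modification k-mer a position holding the modification code never
matches a canonical-base pattern. Multi-modification k-mers sum the rule
contributions of each modification position; because application is pure
addition, the order of positions is immaterial. Imputed entries keep the
canonical counterpart's `level_stdv` — the +1 inflation that marks
untrained placeholder entries in alphabet-expanded tables
(`expandAlphabet()`) is a bookkeeping convention, not a property of
trained values — while `mode = "missing"` keeps the trained entries'
spreads verbatim along with their levels.

K-mers whose motif runs off the window edge (e.g. `NNNNNM` for CpG, where
the partner G is outside the k-mer) are excluded by default everywhere:
they roughly double the nominal inventory (1280 → 2304 for CpG 6-mers)
without contributing callable information, which would flatter coverage
fractions. `includeIncomplete = TRUE` re-admits them for users who want
the padded inventory; no rules are ever derived from or applied to them,
so they impute to their canonical levels.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r` | 0.01 | model units (pA for typical tables) | stopping threshold on candidate medians; rescaled tables need a rescaled r (the CLI warns when r looks large against the table's level range) |
| `minGroupSize` | 1 | k-mers | smallest training group a pattern may be derived from; raising it trades completeness for robustness on sparse training sets |
| `maxIterationsPerPosition` | 1000 | iterations | oscillation guard; hitting it raises an error naming the oscillating pattern |
| `stdvIncrement` | 1 | model units | spread inflation marking untrained placeholder entries in expanded tables |
| `targetFraction` (T) | — | fraction | training coverage target for site selection; rule sets stabilize from T ≈ 0.25 in the simulated scenarios below |

## Training-site selection

`selectTrainingSites()` mirrors how one picks training loci on a real
reference: scan all motif sites (both strands by default — enzymatic
modification hits both, and while CG is its own reverse complement at
motif level, the flanks differ), visit them in a seeded random order, keep
a site only if it contributes at least one new modified k-mer (each site
contributes up to k − |motif| + 1 of them), and stop at the first
acceptance reaching the target fraction T. The overshoot is therefore at
most one site's contribution. Selection is deterministic given the seed,
and an unreachable target errors with the maximum achievable fraction. A
50 kb random genome at 50 % GC covers all 1280 CpG 6-mers, matching the
well-known suitability of genomes of that scale for CpG training.
Coordinates are held in `GRanges` (1-based, Bioconductor convention); BED
export is 0-based as the format requires.

## The synthetic-data generator

`simulateTruth()` emulates the data a training pipeline would produce:

* a canonical table with levels uniform on 60–130 and spreads on 1.5–4
  model units (the R9 pore-model scale);
* a ground-truth rule set with shift magnitudes 0.5–5 (the size of real
  CpG methylation shifts, whose largest rules are around ±4);
* the clean modified table by naive forward application
  (`forwardApply()`, an implementation of the additive model deliberately
  independent of `imputeModel()`, so the two can cross-check each other);
* Gaussian training noise (σ, on the *trained* modified levels only — the
  canonical table is treated as known, as it is when an existing
  canonical model serves as the basis);
* a trained inventory, either uniform over k-mers or via genome site
  selection.

What it does **not** emulate: real training noise is not i.i.d. Gaussian
(it depends on event segmentation, per-k-mer read depth and enzyme
conversion efficiency); real ΔC surfaces are only approximately additive,
so a perfect-recovery result here bounds algorithmic error, not model
misspecification; and no raw signal or read-level artifacts exist in the
simulation. Passing the synthetic round trips shows the estimator is
correct and stable under its own assumptions — transfer to real tables
rests on the additivity premise holding there.

## Problem sizes and numerical choices in the shipped checks

The test suite and acceptance script run at the scale the method is meant
for: k = 6 CpG tables (4096 canonical + 1280 modified entries), 50 kb
synthetic genomes, site-based holdouts at T = 0.25 with σ = 0.2 over five
seeds, and brute-force enumeration oracles at k ≤ 5–6. Expected-value
checks: the 3-mer walkthrough (AMT = 6) is exact; noise-free round trips
are held to k·r per entry (identifiable configurations to r per shift);
the noisy site-holdout scenario requires every ground-truth rule to be
re-established and the fully imputed table to sit below 2σ RMSE against
the clean truth. Model files are written with six-decimal formatting and
radix-sorted k-mers so byte-identical reruns are meaningful; rule TSVs
store shifts at full precision (`%.17g`) so a write/read round trip is
exact.

## Known limitations

* Additivity is an approximation; interactions between context bases
  (beyond one base at a time) are not modeled, and nothing corrects for
  them.
* Only `level_mean` is modeled. Modification-induced changes in
  `level_stdv` or event-duration noise (`sd_mean`/`sd_stdv`) are out of
  scope.
* Rule derivation uses single-modification, complete-motif training
  k-mers only; multi-modification k-mers are imputation targets, not
  evidence.
* With heavily overlapping ground-truth patterns the per-rule
  decomposition is not identifiable (see above); downstream users should
  compare imputed *tables*, not rule lists, across runs.
* The stopping threshold is scale-dependent; tables normalized to unit
  variance need a correspondingly smaller r.
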