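# poreImpute

Rule-based imputation of modified k-mer nanopore pore models.

## The problem

Nanopore sequencers read DNA by measuring the ionic current while a strand
moves through a pore; at any moment the k bases in the sensing region set
the expected current level. Table-based modification callers (Nanopolish,
f5c, Tombo) rely on *pore models*: tables mapping every k-mer to its
expected level, in both canonical and modified form. Training a modified
table normally requires observing every modified k-mer — 1280 distinct
6-mers for a single methylated CpG, 4^9-scale inventories for R10 9-mer
models — which is expensive or impossible for rare or exotic modifications
(GpC methylation, glucosylation, lesions, synthetic bases).

The empirical escape hatch: a base modification shifts the expected current
of similar k-mers by similar amounts. poreImpute exploits this by
compressing the shifts into a small ordered set of additive **ΔC rules**
and using them to fill in, or denoise, the modified half of a pore model
from a fraction of the k-mer inventory.

## The algorithm

For a modified k-mer x with modification at position m, let
ΔC(x) = v̂(x) − v(x₀): the trained modified level minus the canonical level
of its counterpart x₀ (modification code replaced by the canonical base).
Given a training set of ΔC values, per modification position m:

1. **Position rule** — shift h_m = median of ΔC over all training k-mers
   modified at m; residuals ρ = ΔC − h_m.
2. **Pattern rules** — over all candidate patterns (f, b) with position f
   outside the motif footprint and base b ∈ {A,C,G,T}, compute the median
   residual of the matching training k-mers; take the pattern with the
   largest |median| (ties: smallest f, then alphabetical b). If |median|
   exceeds the stopping threshold r (default 0.01 for pA-scale tables),
   record the rule, subtract its shift from the matching k-mers' residuals,
   and repeat; otherwise stop.

Imputation is then a lookup-and-sum: the imputed level of x is the
canonical level of x₀ plus the position rule for m plus every pattern rule
(m, f, b) with x[f] = b. `mode = "missing"` keeps trained entries verbatim
and imputes the rest; `mode = "full"` overwrites everything with the
rule-based values, which denoises the trained entries too. K-mers with
several modifications sum the contributions of each position.

## Worked example

A fully synthetic experiment: a 50 kb genome, a ground-truth rule set, a
noisy partially trained table covering 25 % of the 1280 modified 6-mers
(sampled by CpG-site coverage, the way one would pick training sites on a
real reference), then rule derivation and full imputation.

```r
library(poreImpute)
cpg    <- ModificationScheme("CG", 0, "M")
genome <- simulateGenome(50000, seed = 2024)
truth  <- simulateTruth(cpg, k = 6, nPatternRules = 10, noiseSd = 0.2,
                        trainedFraction = 0.25, holdoutMode = "site",
                        genome = genome, seed = 1)
delta  <- computeDelta(truthCanonical(truth),
                       truthModified(truth, noisy = TRUE),
                       cpg, trainedKmers(truth))
delta
#> DeltaTable: 322 trained k-mers (k = 6, motif CG)
#>   per-position medians: 1: -1.522 (n=65), 2: -0.543 (n=62),
#>   3: 1.179 (n=65), 4: 1.131 (n=66), 5: -2.797 (n=64)

rules <- deriveRules(delta, r = 0.01)
rules
#> RuleSet: 5 position rule(s), 97 pattern rule(s) (k = 6, motif CG)
#>     1  MGNNNN  -1.522
#>     2  MGNCNN  -0.144
#>     ...

full <- imputeModel(truthCanonical(truth), rules, mode = "full")
compareModels(full, truthModified(truth), subset = "imputed",
              trained = trainedKmers(truth))
#> ComparisonReport [imputed]: n = 958, pearson = 1.0000, rmse = 0.1235,
#>   max |diff| = 0.3304
```

Reading: from 322 noisy trained k-mers (σ = 0.2 pA) the derivation finds
the five per-position median shifts (the `MGNNNN`-style position rules)
plus pattern rules such as `MGNCNN` (a C two bases right of the motif);
applying them to the canonical table reproduces the 958 *never-trained*
modified k-mers with an RMSE well below the training noise. All 15
ground-truth rules are re-established (`ruleRecovery(truthRules(truth),
rules)`).

The same flows are scriptable through the installed CLI
(`exec/poreimpute`): `simulate`, `delta`, `derive`, `impute`, `expand`,
`select-sites`, `coverage`, `evaluate`, `summarize`. For real data, point
`derive` at a canonical and a partially trained Nanopolish/f5c model file
plus the trained k-mer list, then `impute` with the resulting rule TSV.

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/deltaC-rules.Rmd`) covers the model, its assumptions,
parameter choices, identifiability caveats and the synthetic-data design.
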