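---
title: "Paralog evidence for missense variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog evidence for missense variants: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogLR)
```

# The model

`paralogLR` treats "a pathogenic variant exists at the corresponding
position of a paralogous gene" as a diagnostic test for the pathogenicity
of a query missense variant, and calibrates that test as a positive
likelihood ratio.

## Coordinates

Everything pivots on one coordinate system. Each gene of a family
contributes a row to the family's multiple sequence alignment (aligned
FASTA, gap character `-`); residues are 1-based within the ungapped
protein, columns are 1-based within the alignment, and the two maps
(`col_of`, `res_of`) are materialized at construction and are mutually
inverse on non-gap positions. Residues of different genes in the same
column are *corresponding*.

## The evidence criteria

Two variants in different genes of one family are paralogous when

1. they occupy the same alignment column, and
2. the reference amino acid is the same in both genes.

A paralogous *pathogenic* variant with the same alternate amino acid as the
query is **para-SAME** evidence; with a different alternate, **para-DIFF**.
The two flags are evaluated independently — a query may satisfy both — and
an exclusive `para_diff_only` reading is exposed because analyses that
contrast the two criteria do not always state exclusivity. Condition (2) is
checked against the alignment row itself, not just the variant record: a
record whose reference amino acid disagrees with its own gene's sequence
indicates transcript-version drift (the dominant real-world failure mode)
and is quarantined with a warning rather than silently used or dropped.

## Calibration

With TP/FN the pathogenic variants with/without qualifying evidence and
FP/TN the same for population controls,

$$\mathrm{LR}^+ \;=\; \frac{\mathrm{sensitivity}}{1-\mathrm{specificity}}
  \;=\; \frac{\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})}
             {1-\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})}.$$

Counting is over *variants*, not residues. Pooled counts are sums of
per-gene counts (asserted by test); gene-wise LR+ is reported only for
genes with at least 10 mapped variants of each label, the conventional
floor below which a gene-wise ratio is too unstable to display.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_similarity` | 0.80 | family-inclusion threshold on mean pairwise identity |
| `min_pathogenic`, `min_control` | 10, 10 | gene-wise LR+ reporting floor |
| `zero_cell` | `"haldane"` | +0.5 on all four cells when any cell is 0, flagged; `"strict"` errors |
| `conf_level` / `ci_method` | 0.95 / `"log"` | CI level and method (`"bootstrap"` optional) |
| `threshold` | 12 Å | Cα–Cα neighbor distance for 3D profiles |
| `min_positions` | 6 | distinct projected positions required per phenotype ("more than five") |
| `alpha` | 0.05 | significance level on Bonferroni-adjusted p-values |
| `n_folds` | 4 | cross-validation folds (each fold tests exactly once) |

# Design choices made where the design was genuinely open

**Pairwise identity and the 80% filter.** "80% similarity on the full
protein sequence" does not pin down a denominator or a family statistic.
The default is the most conservative common reading — matches divided by
columns where at least one of the pair is non-gap, averaged over all
unordered pairs — with `alignment_length` and `min` available as options.
Neither option is claimed to be the historical definition.

**Confidence intervals.** Published LR+ values of this kind come with 95%
CIs whose method is rarely stated. The default is the standard log-method
interval, $\exp(\ln \mathrm{LR}^+ \pm z\sqrt{1/\mathrm{TP} -
1/(\mathrm{TP{+}FN})+1/\mathrm{FP}-1/(\mathrm{FP{+}TN})})$; a parametric
(binomial-margin) bootstrap is available for small cells. Zero cells take
the Haldane–Anscombe correction by default because pooled analyses of rare
evidence frequently produce empty FP cells; corrected results always carry
a flag.

**Conservation groups.** External per-column paralog-conservation scores
(Parazscore-style TSV) partition columns into MAX (family-wise maximum =
full conservation), POSITIVE_NONMAX and NEGATIVE (score < 0). A score of
exactly 0 below the maximum belongs to no published group; it is assigned
to POSITIVE_NONMAX (defined here as "non-negative, below maximum"), a
measure-zero case for the z-scaled stand-in. When no external score is
supplied, `default_conservation_score()` provides a transparently tagged
stand-in — the z-scaled modal-residue fraction per column. It is *not* a
reimplementation of any published conservation score; ingesting the real
score is the faithful path. Targets at unscored columns go to an explicit
`"unscored"` bucket rather than being dropped.

**Kendall correlation.** Patient tallies over residues are heavily tied,
so tau-b (tie-corrected) is used; whether published "Kendall correlation"
values are tau-a or tau-b is generally unstated. p-values use the
tie-corrected normal approximation of the S statistic, with exact
permutation enumeration for n ≤ 8 where the approximation is poorest. The
point estimate and large-sample p agree with `stats::cor.test` (asserted
in tests against that independent implementation and a brute-force pair
count).

**Neighbor threshold.** The Cα–Cα distance defining "spatially proximate"
is not a settled constant; 12 Å is a common contact-neighborhood radius
and every output records the threshold used so sensitivity sweeps are
one flag away.

**Cross-validation reading.** The 4-subset protocol ("each set of variants
used as part of the training set three times and once as the test set") is
implemented as 4 iterations — one per fold — since only that reading lets
every fold test exactly once. Folds split *distinct variants*, not
patients. The "correlated" evidence class requires a significantly
positive correlation at adjusted p < 0.05 recomputed per iteration from
training data only; "non-correlated" pools non-significant and
significantly negative phenotypes. Iterations without any correlated
phenotype contribute zero qualifying evidence (TP = FP = 0) and are
flagged. Using raw instead of adjusted p-values is available behind
`use_adjusted = FALSE`.

**Conflicting labels.** A substitution reported as both pathogenic and
control is refused with an error rather than resolved by precedence:
label conflicts signal upstream curation problems that no default should
paper over.

**PDB dialect.** Only ATOM/Cα records of one chain are parsed, first
alternate location wins, insertion codes are an error. Bit-exact behavior
on the supported dialect was preferred over permissive parsing of the full
format, for which no installed parser exists in this stack.

# What the synthetic generators emulate — and what they do not

`make_family()` realizes a mean pairwise identity *exactly*: `k =
round((1 − target) · L)` columns are made fully divergent (each gene gets a
distinct residue, so cross-gene reference matches are impossible there) and
every other column is identical across genes, giving every unordered pair
identity `(L − k)/L`, within `1/(2L)` of the target. Gaps, when enabled,
replace at most one gene's residue per column, which leaves the
union-denominator identity unchanged. This is a deliberately stylized
picture: real paralogs diverge gradually, with conservative substitutions
and indel blocks, so a green identity test establishes coordinate-system
correctness, not realism of the substitution process.

`plant_variants()` places pathogenic variants in two strata — with
probability `share_prob` into cross-paralog clusters at fully conserved
columns (same alternate with probability `same_alt_prob`), otherwise
uniformly — and controls uniformly over residues free of same-gene
pathogenic variants, with uniform alternate alleles. With `share_prob = 0`
pathogenic and control variants follow the same positional law, so the
para-SAME LR+ is 1 in expectation (the null-calibration test). The ground
truth travels with the data: sensitivities are computed by exhaustive
enumeration over the realized placements (an independent double loop inside
the generator, never the annotation code path), false-positive rates as
exact expectations over the uniform control placement, and
`expected_lr = sensitivity / E(FPR)`. `target_lr` solves `share_prob` from
a background-only pre-pass analytically, before any outcome is observed.
The defaults (3 genes, 20 + 20 variants per gene, identity 0.85) mirror a
small disease-gene family with a moderately curated variant load.

`make_helix_structure()` is an ideal α-helix (radius 2.3 Å, rise 1.5 Å,
100°/residue; consecutive Cα–Cα ≈ 3.83 Å) — a stand-in geometry, not a
channel fold. `make_phenotype_cohort()` draws each phenotype's distinct
variant positions from a hotspot window on the reference chain with 10%
background leakage, 40 distinct variants per phenotype (the conventional
minimum cohort size for the cross-validated analysis) and
`1 + Poisson(1)` patients per variant. The canonical two-hotspot world
(`make_cohort_world()`): focal and "correlated" phenotypes share a window
covering a quarter of a 200-residue chain from two different genes; a
"distal" phenotype occupies a disjoint window. Real cohorts differ in
every inconvenient way — uneven phenotype sizes, overlapping hotspots,
structure gaps — so the discrimination tests establish that the machinery
recovers a planted signal, not that any particular clinical correlation is
expected.

# Numerical notes

* Degenerate alignments (zero column variance) give all-zero z-scores and
  a single MAX stratum by definition.
* Constant tally vectors make tau undefined; such cells are flagged and
  excluded from significance calls instead of propagating NaN.
* `lr_plus` errors on empty margins (no pathogenic or no control variants
  in scope) — no number is invented for an undefined ratio.
* All generators save and restore the caller's RNG state; identical seeds
  replay byte-identical objects (asserted), and tabular outputs sort by
  (gene, position, alternate) so reruns diff cleanly.
* Bonferroni adjustment multiplies by the number of unordered phenotype
  pairs tested (diagonal excluded), capped at 1.

# Known limitations

* Protein-level only: no transcript mapping, genomic coordinates or
  nucleotide-level reasoning (at protein level, "irrespective of nucleotide
  change" is satisfied by construction).
* The stand-in conservation score is a placeholder; conclusions about
  conservation strata should rest on an externally computed score.
* Headline likelihood ratios published for real variant collections depend
  on licensed or very large databases and an unstated neighbor threshold;
  this package makes no attempt to reproduce them, and its tests assert
  only properties that the synthetic world can ground.
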