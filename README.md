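# paralogLR

Paralogous pathogenic variants as calibrated evidence for missense variant
interpretation.

## The problem

Most genes still have few classified pathogenic variants, so a newly
observed missense variant usually lands on a residue with no direct
precedent and ends up a variant of uncertain significance. Genes in the
same family, however, arose by duplication and retain high sequence and
structural similarity — a pathogenic variant at the *corresponding* residue
of a paralog carries real information about the query. `paralogLR`
implements this idea end to end for clinical-genetics and methods
researchers:

* **Annotation.** Two variants in different genes of one family are
  *paralogous* when (1) they sit in the same column of the family's
  multiple sequence alignment and (2) the reference amino acid is the same
  in both genes. A paralogous pathogenic variant with the same alternate
  amino acid as the query is **para-SAME** evidence (an alignment-aware
  extension of the ACMG PS1 criterion); with a different alternate it is
  **para-DIFF** (extending PM5).
* **Calibration.** The strength of the evidence is quantified as a positive
  likelihood ratio over pathogenic vs. population-control variants,

      LR+ = sensitivity / (1 − specificity)
          = (TP / (TP + FN)) / (1 − TN / (TN + FP)),

  where TP counts pathogenic variants with at least one qualifying
  paralogous pathogenic variant, FP counts control variants with one, and
  FN/TN their complements. LR+ is reported pooled across the family,
  gene-wise (for genes with ≥ 10 mapped variants of each label), stratified
  by paralog-conservation group, restricted to supplied regions, and by
  paralog-hit count. 95% CIs use the log method (parametric bootstrap
  optional); zero cells use the flagged Haldane–Anscombe +0.5 correction.
* **3D phenotype correlation.** Family variants are projected onto one
  reference chain through the alignment; per phenotype, patients are
  tallied over Cα-distance neighborhoods (default 12 Å, configurable) and
  phenotype pairs are compared by Kendall tau-b with Bonferroni-adjusted
  significance calls.
* **Phenotype-informed evidence.** A 4-fold cross-validation splits the
  focal phenotype's variants, learns 3D-correlated phenotypes on the
  training side only, and measures the LR+ of correlated- vs
  non-correlated-phenotype paralog evidence on the held-out folds
  (cells summed over iterations; leakage is asserted programmatically).
* **Synthetic data.** Seeded generators produce gene families with an exact
  pairwise-identity target, planted cross-paralog pathogenic sharing with
  an analytic expected LR+ sidecar, ideal-helix structures and
  hotspot-clustered phenotype cohorts — so the whole pipeline is testable
  with no external database.

## Worked example

```r
library(paralogLR)

fam     <- make_family(family_spec(n_genes = 3, length = 100,
                                   identity_target = 0.85, seed = 1))
planted <- plant_variants(fam, variant_spec(n_pathogenic = 20,
                                            n_control = 20,
                                            share_prob = 0.25, seed = 2))
fit <- paralog_lr(planted$variants, fam, criterion = "para_same")
fit
#> Paralog-evidence likelihood ratio (family 'SIMFAM', criterion para_same)
#>   60 pathogenic and 60 control variants
#> Pooled: LR+ = 14  [1.9, 103] (95% CI, log)
#>   sensitivity 0.233, specificity 0.983  (TP=14 FN=46 FP=1 TN=59)
#> Gene-wise LR+ reported for 3 gene(s): G1, G2, G3

planted$truth[, c("sens_same", "expected_fpr_same", "expected_lr_same")]
#>   sens_same expected_fpr_same expected_lr_same
#> 1 0.2333333        0.01666667               14
```

Reading this: 25% of the planted pathogenic variants were given an exact
paralogous copy in another gene, so 14 of 60 pathogenic variants carry
para-SAME evidence (sensitivity 0.233) against 1 of 60 controls, an
observed LR+ of 14 — matching the generator's analytic expectation carried
in the truth sidecar. The wide CI reflects the single false positive.

```r
cov <- residue_coverage(fam, subset(planted$variants, label == "pathogenic"))
cov[cov$gene == "total", ]
#>    gene n_residues n_same_gene n_paralog n_paralog_only n_union fold_increase
#> 4 total        300          60        97             70     130      2.166667
```

Mapping paralogous pathogenic variants across the family raises the number
of residues with applicable evidence from 60 to 130, a 2.17-fold gain over
same-gene evidence alone.

The same functions drive the command-line tool
(`inst/scripts/paralog-evidence.R`) with subcommands `annotate`, `lr`,
`residues`, `stratify`, `phenocorr`, `cv` and `simulate`; every run writes
deterministic TSV outputs plus its resolved configuration.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch under the given seed — planted
family calibration against the analytic sidecar, residue coverage,
conservation-stratified LR+, 3D phenotype correlation and the
cross-validated phenotype-informed evidence comparison — logging each stage
and writing the JSON report to `--out`.
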