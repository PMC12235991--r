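# Contingency counting, LR+ arithmetic and CIs, stratification, enrichment,
# region-restricted LR+ and the stand-in conservation score.

fake_evidence <- function(gene, label, para_same,
                          para_diff = FALSE, n_hits = NULL,
                          column = seq_along(gene)) {
  data.frame(gene = gene, label = label, para_same = para_same,
             para_diff = para_diff, para_diff_only = para_diff & !para_same,
             n_hits = n_hits %||%
               (as.integer(para_same) + as.integer(para_diff)),
             column = column, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("contingency counting is direct, additive and label-checked", {
  ev <- fake_evidence(gene = rep("G1", 7),
                      label = c(rep("pathogenic", 3), rep("control", 4)),
                      para_same = c(TRUE, TRUE, FALSE,
                                    TRUE, FALSE, FALSE, FALSE))
  cnt <- build_contingency(ev, "para_same")
  expect_equal(c(cnt$tp, cnt$fn, cnt$fp, cnt$tn), c(2L, 1L, 1L, 3L))

  empty <- build_contingency(ev[0, ], "para_same")
  expect_equal(c(empty$tp, empty$fn, empty$fp, empty$tn), rep(0L, 4))

  # pooled counts are the sum of per-gene counts
  ev2 <- rbind(fake_evidence("G1", c("pathogenic", "pathogenic",
                                     "control", "control"),
                             c(TRUE, FALSE, TRUE, FALSE)),
               fake_evidence("G2", c("pathogenic", "pathogenic",
                                     "control", "control"),
                             c(TRUE, TRUE, FALSE, FALSE)))
  pooled <- build_contingency(ev2, "para_same", "pooled")
  a <- build_contingency(ev2, "para_same", "G1")
  b <- build_contingency(ev2, "para_same", "G2")
  expect_equal(c(pooled$tp, pooled$fn, pooled$fp, pooled$tn),
               c(a$tp + b$tp, a$fn + b$fn, a$fp + b$fp, a$tn + b$tn))
  expect_equal(c(pooled$tp, pooled$fn, pooled$fp, pooled$tn),
               c(3L, 1L, 1L, 3L))

  ev$label[1] <- NA
  expect_error(build_contingency(ev, "para_same"), "label")
})

test_that("LR+ arithmetic, zero-cell policies and CI behavior", {
  r <- lr_plus(contingency(9, 1, 10, 90))
  expect_equal(r$sensitivity, 0.9)
  expect_equal(r$specificity, 0.9)
  expect_equal(r$lr_plus, 9.0)
  expect_false(r$corrected)
  expect_true(r$ci_low <= r$lr_plus && r$lr_plus <= r$ci_high)

  expect_equal(lr_plus(contingency(5, 5, 50, 50))$lr_plus, 1.0)

  rc <- lr_plus(contingency(10, 0, 0, 10))
  expect_true(rc$corrected)
  expect_equal(rc$lr_plus, (10.5 / 11) / (1 - 10.5 / 11))  # = 21
  expect_error(lr_plus(contingency(10, 0, 0, 10), zero_cell = "strict"),
               "zero cell")
  expect_error(lr_plus(contingency(0, 0, 5, 5)), "no pathogenic")
  expect_error(lr_plus(contingency(5, 5, 0, 0)), "no control")

  # CI widens monotonically as counts shrink at fixed cell ratios
  wide <- lr_plus(contingency(9, 1, 10, 90))
  narrow <- lr_plus(contingency(90, 10, 100, 900))
  expect_lt(log(narrow$ci_high / narrow$ci_low),
            log(wide$ci_high / wide$ci_low))
  expect_equal(narrow$lr_plus, wide$lr_plus)

  # bootstrap interval brackets the point estimate too
  b <- lr_plus(contingency(9, 1, 10, 90), ci_method = "bootstrap")
  expect_true(b$ci_low <= b$lr_plus && b$lr_plus <= b$ci_high)
})

test_that("gene-wise LR+ honors the mapping thresholds", {
  ev <- rbind(
    fake_evidence(rep("G1", 29),
                  c(rep("pathogenic", 9), rep("control", 20)),
                  c(rep(TRUE, 5), rep(FALSE, 24))),
    fake_evidence(rep("G2", 20),
                  c(rep("pathogenic", 10), rep("control", 10)),
                  rep(c(TRUE, FALSE), 10)))
  gw <- genewise_lr(ev)
  expect_named(gw$results, "G2")
  expect_equal(gw$skipped$gene, "G1")
  expect_equal(gw$skipped$n_pathogenic, 9L)
  gw0 <- genewise_lr(ev, min_pathogenic = 0, min_control = 0)
  expect_named(gw0$results, c("G1", "G2"))
})

test_that("conservation stratification partitions targets by column group", {
  trk <- conservation_track(column = 1:4, score = c(2, 2, 0.5, -1))
  expect_equal(trk$group, c("MAX", "MAX", "POSITIVE_NONMAX", "NEGATIVE"))

  ev <- fake_evidence(gene = rep("G1", 8),
                      label = rep(c("pathogenic", "control"), 4),
                      para_same = c(TRUE, FALSE, TRUE, FALSE,
                                    TRUE, TRUE, FALSE, FALSE),
                      column = c(1, 1, 1, 1, 1, 1, 1, 1))
  res <- stratified_lr(ev, trk)
  expect_named(res, "MAX")  # all targets sit in MAX columns

  ev$column <- c(1, 1, 4, 4, 4, 4, 9, 9)  # column 9 has no score
  res2 <- stratified_lr(ev, trk)
  expect_setequal(names(res2), c("MAX", "NEGATIVE", "unscored"))

  # planted enrichment only at low-conservation columns shows up as a
  # higher LR+ in the NEGATIVE stratum than in POSITIVE_NONMAX
  set.seed(5)
  n <- 200
  col <- rep(c(3, 4), each = n / 2)    # 3: POSITIVE_NONMAX, 4: NEGATIVE
  lab <- rep(rep(c("pathogenic", "control"), each = n / 4), 2)
  hit <- ifelse(col == 4 & lab == "pathogenic", runif(n) < 0.6,
                runif(n) < 0.1)
  ev3 <- fake_evidence(gene = "G1", label = lab, para_same = hit,
                       column = col)
  res3 <- stratified_lr(ev3, trk)
  expect_gt(res3$NEGATIVE$lr_plus, res3$POSITIVE_NONMAX$lr_plus)
})

test_that("hit-count enrichment matches hand counts", {
  ev <- fake_evidence(gene = rep("G1", 6),
                      label = c(rep("pathogenic", 3), rep("control", 3)),
                      para_same = FALSE,
                      n_hits = c(0L, 1L, 2L, 0L, 0L, 1L))
  tab <- enrichment_by_hit_count(ev)
  expect_equal(tab$fold_enrichment[tab$k == 1], (2 / 3) / (1 / 3))
  # numerator and denominator fractions never increase with k
  expect_true(all(diff(tab$frac_pathogenic) <= 0))
  expect_true(all(diff(tab$frac_control) <= 0))

  same <- fake_evidence(gene = rep("G1", 4),
                        label = c("pathogenic", "pathogenic",
                                  "control", "control"),
                        para_same = FALSE, n_hits = c(0L, 1L, 0L, 1L))
  expect_equal(enrichment_by_hit_count(same)$fold_enrichment, 1.0)

  none <- fake_evidence(gene = rep("G1", 4),
                        label = c("pathogenic", "pathogenic",
                                  "control", "control"),
                        para_same = FALSE, n_hits = c(1L, 1L, 0L, 0L))
  tabn <- enrichment_by_hit_count(none)
  expect_true(tabn$corrected[tabn$k == 1])
  expect_true(is.finite(tabn$fold_enrichment[tabn$k == 1]))
})

test_that("region-restricted LR+ uses in-region membership as the test", {
  regions <- region_set(data.frame(gene = "G1", start = 10, end = 20))
  v <- protein_variants(gene = rep("G1", 4),
                        position = c(15, 25, 16, 30),
                        ref_aa = "A", alt_aa = "T",
                        label = c("pathogenic", "pathogenic",
                                  "control", "control"))
  r <- region_lr(regions, v)
  expect_equal(c(r$counts$tp, r$counts$fn, r$counts$fp, r$counts$tn),
               c(1L, 1L, 1L, 1L))
  expect_equal(r$lr_plus, 1.0)

  r0 <- region_lr(region_set(data.frame(gene = character(0),
                                        start = integer(0),
                                        end = integer(0))), v)
  expect_true(r0$corrected)           # sensitivity 0 forces the correction
  expect_equal(r0$counts$tp, 0L)

  rall <- region_lr(region_set(data.frame(gene = "G1", start = 1,
                                          end = 1000)), v)
  expect_true(rall$corrected)         # specificity 0, corrected path
  expect_equal(rall$counts$tn, 0L)
})

test_that("stand-in conservation score groups columns sensibly", {
  aln <- family_alignment(c(G1 = "AADA", G2 = "AATA", G3 = "AATA",
                            G4 = "AADA"))
  trk <- default_conservation_score(aln)
  expect_true(attr(trk, "standin"))
  # fully conserved columns attain the maximum and land in MAX
  expect_equal(trk$group[trk$column %in% c(1, 2, 4)], rep("MAX", 3))
  # the {D,T,T,D} column has modal fraction 0.5 and scores below the rest
  expect_lt(trk$score[trk$column == 3], min(trk$score[trk$column != 3]))

  flat <- default_conservation_score(
    family_alignment(c(G1 = "ACDE", G2 = "ACDE")))
  expect_equal(flat$score, rep(0, 4))      # degenerate variance: all z = 0
  expect_equal(flat$group, rep("MAX", 4))
})
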