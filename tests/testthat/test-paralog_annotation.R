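# para-SAME / para-DIFF criteria and residue-coverage accounting.

toy2 <- function() family_alignment(c(G1 = "ACDE", G2 = "ACDE"))

test_that("find_paralog_hits applies the two paralogous-variant conditions", {
  ref <- protein_variants("G1", 1, "A", "T", "pathogenic")
  hit <- find_paralog_hits(list(gene = "G2", position = 1, ref_aa = "A",
                                alt_aa = "T"), ref, toy2())
  expect_equal(nrow(hit), 1L)
  expect_true(hit$same_substitution)
  expect_equal(hit$source_gene, "G1")

  # same column and reference, different alternate: para-DIFF material
  hit2 <- find_paralog_hits(list(gene = "G2", position = 1, ref_aa = "A",
                                 alt_aa = "G"), ref, toy2())
  expect_equal(nrow(hit2), 1L)
  expect_false(hit2$same_substitution)

  # mismatched reference amino acid across genes: condition (2) fails
  diverged <- family_alignment(c(G1 = "ACDE", G2 = "GCDE"))
  hit3 <- find_paralog_hits(list(gene = "G2", position = 1, ref_aa = "G",
                                 alt_aa = "T"), ref, diverged)
  expect_equal(nrow(hit3), 0L)

  expect_error(
    find_paralog_hits(list(gene = "G2", position = 9, ref_aa = "A",
                           alt_aa = "T"), ref, toy2()),
    "beyond the ungapped length")
})

test_that("annotate_set sets the evidence flags independently", {
  targets <- protein_variants("G2", 1, "A", "T", "pathogenic")
  empty <- protein_variants(data.frame(gene = character(0),
                                       position = integer(0),
                                       ref_aa = character(0),
                                       alt_aa = character(0),
                                       label = character(0)))
  ev0 <- annotate_set(targets, empty, toy2())
  expect_equal(ev0$n_hits, 0L)
  expect_false(ev0$para_same)
  expect_false(ev0$para_diff)

  one_same <- annotate_set(targets,
                           protein_variants("G1", 1, "A", "T", "pathogenic"),
                           toy2())
  expect_true(one_same$para_same)
  expect_false(one_same$para_diff)

  both <- annotate_set(
    targets,
    protein_variants(gene = c("G1", "G1"), position = c(1, 1),
                     ref_aa = c("A", "A"), alt_aa = c("T", "W"),
                     label = "pathogenic"),
    toy2())
  expect_true(both$para_same)
  expect_true(both$para_diff)
  expect_false(both$para_diff_only)
  expect_equal(both$n_hits, 2L)
})

test_that("variants disagreeing with their own alignment row are quarantined", {
  ref <- protein_variants(gene = c("G1", "G1"), position = c(1, 2),
                          ref_aa = c("A", "A"),  # row has C at position 2
                          alt_aa = c("T", "T"), label = "pathogenic")
  expect_warning(
    ev <- annotate_set(protein_variants("G2", 1, "A", "G", "pathogenic"),
                       ref, toy2()),
    "quarantined")
  expect_equal(ev$n_hits, 1L)  # only the consistent reference row is used
  expect_equal(nrow(attr(ev, "quarantined")), 1L)
})

test_that("hits match the brute-force oracle and are symmetric", {
  set.seed(77)
  for (rep in 1:40) {
    rows <- random_rows(sample(2:4, 1), sample(8:30, 1))
    aln <- family_alignment(rows)
    v <- random_variants(rows, sample(10:40, 1))
    if (is.null(v)) next
    patho <- v[v$label == "pathogenic", , drop = FALSE]
    if (nrow(patho) == 0) next
    ev <- annotate_set(v, patho, aln)
    for (i in seq_len(nrow(ev))) {
      o <- oracle_hits(ev[i, ], patho, rows)
      expect_equal(ev$n_hits[i], o$n)
      expect_equal(ev$para_same[i], o$same)
      expect_equal(ev$para_diff[i], o$diff)
    }
    # symmetry: a pathogenic hit for a pathogenic target reciprocates
    pe <- ev[ev$label == "pathogenic", , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      h <- attr(ev, "hits")[[which(ev$gene == pe$gene[i] &
                                     ev$position == pe$position[i] &
                                     ev$alt_aa == pe$alt_aa[i])[1]]]
      for (j in seq_len(nrow(h))) {
        back <- oracle_hits(
          list(gene = h$source_gene[j], position = h$source_position[j],
               ref_aa = h$source_ref[j], alt_aa = h$source_alt[j]),
          pe, rows)
        expect_gte(back$n, 1L)
      }
    }
  }
})

test_that("removing same-substitution references flips para_same only", {
  aln <- family_alignment(c(G1 = "ACDEFG", G2 = "ACDEFG", G3 = "ACDEFG"))
  ref <- protein_variants(gene = c("G1", "G3"), position = c(2, 2),
                          ref_aa = "C", alt_aa = c("Y", "W"),
                          label = "pathogenic")
  target <- protein_variants("G2", 2, "C", "Y", "pathogenic")
  ev <- annotate_set(target, ref, aln)
  expect_true(ev$para_same)
  expect_true(ev$para_diff)
  ev2 <- annotate_set(target, ref[ref$alt_aa != "Y", ], aln)
  expect_false(ev2$para_same)
  expect_equal(ev2$para_diff, ev$para_diff)
})

test_that("residue coverage reproduces the hand-counted examples", {
  aln <- family_alignment(c(G1 = "AA", G2 = "AA"))
  p1 <- protein_variants("G1", 1, "A", "T", "pathogenic")
  c1 <- residue_coverage(aln, p1)
  g2 <- c1[c1$gene == "G2", ]
  expect_equal(g2$n_same_gene, 0L)
  expect_equal(g2$n_paralog, 1L)
  expect_equal(g2$n_paralog_only, 1L)

  p2 <- protein_variants(gene = c("G1", "G2"), position = c(1, 1),
                         ref_aa = "A", alt_aa = c("T", "G"),
                         label = "pathogenic")
  g2 <- residue_coverage(aln, p2)
  g2 <- g2[g2$gene == "G2", ]
  expect_equal(g2$n_same_gene, 1L)
  expect_equal(g2$n_paralog, 1L)
  expect_equal(g2$n_paralog_only, 0L)
  expect_equal(g2$fold_increase, 1.0)

  p3 <- protein_variants(gene = c("G1", "G1", "G2"), position = c(1, 2, 1),
                         ref_aa = "A", alt_aa = c("T", "V", "G"),
                         label = "pathogenic")
  g2 <- residue_coverage(aln, p3)
  g2 <- g2[g2$gene == "G2", ]
  expect_equal(g2$n_same_gene, 1L)
  expect_equal(g2$n_union, 2L)
  expect_equal(g2$fold_increase, 2.0)
})

test_that("coverage identities hold on random fixtures", {
  set.seed(99)
  for (rep in 1:15) {
    rows <- random_rows(sample(2:4, 1), sample(10:25, 1))
    aln <- family_alignment(rows)
    v <- random_variants(rows, 25, labels = "pathogenic")
    if (is.null(v) || nrow(v) == 0) next
    cov <- residue_coverage(aln, v)
    per_gene <- cov[cov$gene != "total", ]
    expect_equal(per_gene$n_union,
                 per_gene$n_same_gene + per_gene$n_paralog_only)
    expect_true(all(per_gene$n_paralog_only <= per_gene$n_paralog))
    # conservation: same-gene residue totals equal distinct (gene, residue)
    expect_equal(sum(per_gene$n_same_gene),
                 nrow(unique(v[, c("gene", "position")])))
    pos <- per_gene$n_same_gene > 0
    expect_true(all(per_gene$fold_increase[pos] >= 1))
  }
})
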