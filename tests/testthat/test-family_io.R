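# Variant tables, aligned FASTA coordinate maps, identity filtering, PDB.

test_that("variant tables validate, collapse duplicates and refuse conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tposition\tref_aa\talt_aa\tlabel\tn_patients",
               "SCN1A\t226\tA\tT\tpathogenic\t2",
               "SCN1A\t226\tA\tT\tpathogenic\t3",
               "SCN2A\t10\tG\tR\tcontrol\t1"), path)
  v <- read_variant_table(path)
  expect_equal(nrow(v), 2L)
  expect_equal(v$n_patients[v$gene == "SCN1A"], 5L)
  expect_equal(v$n_patients[v$gene == "SCN2A"], 1L)

  # single row maps directly with default patient count
  one <- protein_variants("SCN1A", 226, "A", "T", "pathogenic")
  expect_equal(one$n_patients, 1L)

  expect_error(protein_variants("G1", 5, "A", "A", "pathogenic"),
               "ref_aa equals alt_aa.*row")
  expect_error(protein_variants("G1", 5, "B", "T", "pathogenic"),
               "canonical")
  expect_error(protein_variants("G1", 0, "A", "T", "pathogenic"),
               "position")
  expect_error(
    protein_variants(gene = c("G1", "G1"), position = c(5, 5),
                     ref_aa = c("A", "A"), alt_aa = c("T", "T"),
                     label = c("pathogenic", "control")),
    "conflicting")
})

test_that("missing required columns are reported by name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tposition\tref_aa\talt_aa", "G1\t1\tA\tT"), path)
  expect_error(read_variant_table(path), "label")
})

test_that("variant table IO round-trips the collapsed set", {
  v <- protein_variants(
    gene = c("G2", "G1", "G1"), position = c(3, 7, 7),
    ref_aa = c("C", "K", "K"), alt_aa = c("W", "E", "E"),
    label = c("control", "pathogenic", "pathogenic"),
    phenotype = c(NA, "DEE", "DEE"), n_patients = c(1, 2, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  v2 <- read_variant_table(path)
  expect_equal(v2, v)
  write_variant_table(v2, path)
  expect_equal(read_variant_table(path), v2)
})

test_that("aligned FASTA reading builds the residue/column maps", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">G1", "AC-GT", ">G2", "ACQGT"), path)
  aln <- read_aligned_fasta(path, family_id = "FAM")
  expect_equal(aln$n_columns, 5L)
  expect_equal(unname(aln$col_of$G1[3]), 4L)      # the G after the gap
  expect_true(is.na(aln$res_of$G1[3]))            # column 3 is a gap in G1
  expect_equal(unname(aln$res_of$G2[3]), 3L)

  gapfree <- family_alignment(c(G1 = "ACDE", G2 = "ACDE"))
  expect_equal(gapfree$n_columns, 4L)
  expect_equal(unname(gapfree$col_of$G2[3]), 3L)

  writeLines(c(">G1", "ACDE", ">G2", "ACDEF"), path)
  expect_error(read_aligned_fasta(path), "unequal")
  writeLines(c(">G1", "ACDE", ">G1", "ACDE"), path)
  expect_error(read_aligned_fasta(path), "duplicate")
})

test_that("coordinate maps are mutually inverse on random families", {
  set.seed(41)
  for (rep in 1:20) {
    rows <- random_rows(sample(2:4, 1), sample(10:30, 1))
    aln <- family_alignment(rows)
    for (g in aln$genes) {
      len <- nchar(gsub("-", "", rows[[g]]))
      expect_equal(length(aln$col_of[[g]]), len)
      # round trip residue -> column -> residue
      expect_equal(unname(aln$res_of[[g]][aln$col_of[[g]]]), seq_len(len))
      # columns strictly increase with residue index
      expect_true(all(diff(aln$col_of[[g]]) > 0))
    }
  }
})

test_that("pairwise identity follows the union denominator and is symmetric", {
  a <- family_alignment(c(G1 = "ACDE", G2 = "ACDE"))
  expect_equal(pairwise_identity(a, "G1", "G2"), 1.0)
  b <- family_alignment(c(G1 = "ACDE", G2 = "ACDF"))
  expect_equal(pairwise_identity(b, "G1", "G2"), 0.75)
  d <- family_alignment(c(G1 = "A---", G2 = "AAAA"))
  expect_equal(pairwise_identity(d, "G1", "G2"), 0.25)
  expect_equal(pairwise_identity(d, "G2", "G1"),
               pairwise_identity(d, "G1", "G2"))
  # under the alignment-length denominator the same pair scores identically
  # here (no doubly-gapped columns), but the option is honored
  expect_equal(pairwise_identity(d, "G1", "G2",
                                 denominator = "alignment_length"), 0.25)
  expect_error(pairwise_identity(d, "G1", "G9"), "not a member")
})

test_that("family filtering applies the mean-pairwise threshold", {
  ident <- family_alignment(c(G1 = "AAAAAAAAAA", G2 = "AAAAAAAAAA"),
                            family_id = "ident")
  # pairwise identities {1.0, 0.6, 0.6}: mean 0.733, dropped at 0.80
  mixed <- family_alignment(c(G1 = "AAAAAAAAAA", G2 = "AAAAAAAAAA",
                              G3 = "AAAAAACCCC"), family_id = "mixed")
  expect_equal(family_similarity(mixed), mean(c(1, 0.6, 0.6)))
  res <- filter_families(list(ident, mixed), min_similarity = 0.80)
  expect_equal(vapply(res$kept, function(a) a$family_id, ""), "ident")
  expect_equal(res$dropped$family_id, "mixed")
  expect_equal(res$dropped$similarity, mean(c(1, 0.6, 0.6)))
  res0 <- filter_families(list(ident, mixed), min_similarity = 0)
  expect_length(res0$kept, 2L)
  # min statistic is stricter than the mean
  expect_lt(family_similarity(mixed, statistic = "min"),
            family_similarity(mixed, statistic = "mean"))
})

test_that("PDB Calpha parsing handles chains, altlocs and HETATM", {
  coords <- rbind(`1` = c(0, 0, 0), `2` = c(3.8, 0, 0), `3` = c(7.6, 0, 0))
  model <- structure_model(coords, chain_id = "A")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(model, path)
  back <- read_ca_coordinates(path, chain = "A")
  expect_equal(back$residues, 1:3)
  expect_equal(unname(back$coords), unname(coords), tolerance = 1e-9)
  expect_error(read_ca_coordinates(path, chain = "B"), "no Calpha")

  # altloc A and B for residue 5: first occurrence wins; HETATM is ignored
  atom <- function(serial, altloc, chain, resseq, x, y, z, icode = " ") {
    sprintf("ATOM  %5d  CA %1sALA %1s%4d%1s   %8.3f%8.3f%8.3f",
            serial, altloc, chain, resseq, icode, x, y, z)
  }
  lines <- c("HETATM    1 CA    CA A   1      9.000   9.000   9.000",
             atom(2, "A", "A", 5, 1, 2, 3),
             atom(3, "B", "A", 5, 8, 8, 8),
             "END")
  writeLines(lines, path)
  m <- read_ca_coordinates(path, chain = "A")
  expect_equal(m$residues, 5L)
  expect_equal(unname(m$coords[1, ]), c(1, 2, 3))

  # insertion codes are outside the supported dialect
  writeLines(atom(2, " ", "A", 5, 1, 2, 3, icode = "A"), path)
  expect_error(read_ca_coordinates(path, chain = "A"), "insertion")
})
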