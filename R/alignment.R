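# Gap-aware family alignments and the residue <-> column coordinate system.
#
# The whole framework pivots on one coordinate system: each gene's 1-based
# residue index maps to a 1-based alignment column, and residues from
# different genes in the same column are "corresponding". Both directions of
# the map are materialized once at construction.

#' Construct a family alignment
#'
#' Builds the coordinate system of a gene family from aligned sequences:
#' for every gene, `col_of` maps residue index to alignment column and
#' `res_of` maps column to residue index (NA at gaps). All rows must have
#' equal length and use `-` as the gap character.
#'
#' @param rows named character vector of aligned sequences; names are gene
#'   symbols.
#' @param family_id family identifier string.
#' @return an object of class `family_alignment` with elements `family_id`,
#'   `rows`, `n_columns`, `genes`, `mat` (character matrix, genes x columns),
#'   `col_of` and `res_of` (named lists of integer vectors).
#' @examples
#' aln <- family_alignment(c(G1 = "AC-GT", G2 = "ACQGT"))
#' aln$col_of$G1[3]   # residue 3 of G1 sits in column 4
#' @export
family_alignment <- function(rows, family_id = "family") {
  if (is.null(names(rows)) || any(names(rows) == "")) {
    pev_stop("alignment rows must be named by gene symbol")
  }
  if (anyDuplicated(names(rows))) {
    pev_stop("duplicate gene symbols in alignment: %s",
             paste(unique(names(rows)[duplicated(names(rows))]),
                   collapse = ", "))
  }
  if (length(rows) < 2L) pev_stop("an alignment needs at least 2 sequences")
  rows <- stats::setNames(toupper(as.character(rows)), names(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    pev_stop("aligned sequences have unequal lengths (%s)",
             paste(widths, collapse = ", "))
  }
  n_columns <- widths[[1L]]
  if (n_columns == 0L) pev_stop("alignment has zero columns")
  mat <- do.call(rbind, lapply(rows, chars))
  rownames(mat) <- names(rows)
  ok <- mat %in% c(AA20, GAP)
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    pev_stop("alignment contains non-canonical characters: %s",
             paste(bad, collapse = ", "))
  }
  col_of <- list()
  res_of <- list()
  for (g in names(rows)) {
    non_gap <- mat[g, ] != GAP
    col_of[[g]] <- which(non_gap)                  # residue index -> column
    r <- rep(NA_integer_, n_columns)
    r[non_gap] <- seq_len(sum(non_gap))            # column -> residue index
    res_of[[g]] <- r
  }
  structure(list(family_id = family_id,
                 rows = rows,
                 genes = names(rows),
                 n_columns = n_columns,
                 mat = mat,
                 col_of = col_of,
                 res_of = res_of),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("Family alignment '%s': %d genes, %d columns\n",
              x$family_id, length(x$genes), x$n_columns))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Ungapped sequences of a family alignment
#'
#' @param alignment a `family_alignment`.
#' @return named character vector of ungapped protein sequences.
#' @export
ungapped_sequences <- function(alignment) {
  vapply(alignment$rows, function(s) gsub(GAP, "", s, fixed = TRUE), "")
}

check_gene <- function(alignment, gene) {
  if (!gene %in% alignment$genes) {
    pev_stop("gene '%s' is not a member of family '%s'",
             gene, alignment$family_id)
  }
}

# column of (gene, residue); errors past the ungapped length
column_of <- function(alignment, gene, position) {
  check_gene(alignment, gene)
  cols <- alignment$col_of[[gene]]
  if (any(position < 1L | position > length(cols))) {
    pev_stop("position %s is outside gene %s (length %d)",
             paste(position[position < 1L | position > length(cols)],
                   collapse = ","), gene, length(cols))
  }
  cols[position]
}

#' Read a family alignment from aligned FASTA
#'
#' Reads an aligned FASTA file (gap character `-`) whose record ids are gene
#' symbols, and builds the residue/column coordinate maps by scanning each
#' row left to right. Unequal sequence lengths or duplicated ids are errors.
#'
#' @param path path to an aligned FASTA file.
#' @param family_id family identifier attached to the alignment.
#' @return a `family_alignment`.
#' @export
read_aligned_fasta <- function(path, family_id = basename(path)) {
  if (!file.exists(path)) pev_stop("alignment file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2L) pev_stop("%s: need at least 2 aligned records", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  rows <- stats::setNames(as.character(aa), ids)
  family_alignment(rows, family_id = family_id)
}

#' Write a family alignment to aligned FASTA
#'
#' @param alignment a `family_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in alignment$genes) {
    writeLines(c(paste0(">", g), alignment$rows[[g]]), con)
  }
  invisible(path)
}

#' Pairwise sequence identity between two genes of a family
#'
#' Fraction of alignment columns where both rows carry the same amino acid.
#' The denominator is configurable: `"union"` (default) counts columns where
#' at least one of the two rows is non-gap; `"alignment_length"` counts all
#' columns. Symmetric in its arguments.
#'
#' @param alignment a `family_alignment`.
#' @param gene_a,gene_b gene symbols, members of the alignment.
#' @param denominator `"union"` or `"alignment_length"`.
#' @return a fraction in \[0, 1\].
#' @export
pairwise_identity <- function(alignment, gene_a, gene_b,
                              denominator = c("union", "alignment_length")) {
  denominator <- match.arg(denominator)
  check_gene(alignment, gene_a)
  check_gene(alignment, gene_b)
  a <- alignment$mat[gene_a, ]
  b <- alignment$mat[gene_b, ]
  matches <- sum(a != GAP & b != GAP & a == b)
  denom <- switch(denominator,
                  union = sum(a != GAP | b != GAP),
                  alignment_length = alignment$n_columns)
  if (denom == 0L) return(NaN)
  matches / denom
}

#' Family-level similarity statistic
#'
#' Aggregates [pairwise_identity()] over all unordered member pairs, by the
#' mean (default) or the minimum.
#'
#' @inheritParams pairwise_identity
#' @param statistic `"mean"` or `"min"` over unordered pairs.
#' @return a fraction in \[0, 1\].
#' @export
family_similarity <- function(alignment, statistic = c("mean", "min"),
                              denominator = c("union", "alignment_length")) {
  statistic <- match.arg(statistic)
  denominator <- match.arg(denominator)
  genes <- alignment$genes
  pairs <- utils::combn(genes, 2L)
  ids <- apply(pairs, 2L, function(p) {
    pairwise_identity(alignment, p[1L], p[2L], denominator = denominator)
  })
  switch(statistic, mean = mean(ids), min = min(ids))
}

#' Filter gene families by sequence similarity
#'
#' Keeps the families whose family-level similarity statistic reaches
#' `min_similarity` (default 0.80, the conventional cutoff against aligning
#' highly diverged paralogs) and reports the dropped ones.
#'
#' @param alignments list of `family_alignment` objects.
#' @param min_similarity minimum similarity fraction (default 0.80).
#' @inheritParams family_similarity
#' @return list with elements `kept` (list of alignments) and `dropped`
#'   (`data.frame` with family_id and similarity).
#' @export
filter_families <- function(alignments, min_similarity = 0.80,
                            statistic = c("mean", "min"),
                            denominator = c("union", "alignment_length")) {
  statistic <- match.arg(statistic)
  denominator <- match.arg(denominator)
  sims <- vapply(alignments, family_similarity, 0,
                 statistic = statistic, denominator = denominator)
  ids <- vapply(alignments, function(a) a$family_id, "")
  keep <- sims >= min_similarity
  list(kept = alignments[keep],
       dropped = data.frame(family_id = ids[!keep],
                            similarity = sims[!keep],
                            stringsAsFactors = FALSE))
}
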