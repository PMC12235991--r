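# Paralogous-variant annotation: the para-SAME / para-DIFF criteria.
#
# Two variants in different genes of one family are paralogous when
#   (1) they occupy the same alignment column, and
#   (2) the reference amino acid is the same in both genes.
# A paralogous pathogenic variant with the same alternate amino acid as the
# query is para-SAME evidence; with a different alternate, para-DIFF.
# Condition (2) is checked against the alignment row itself, so variant
# records that disagree with their own gene's sequence (transcript-version
# drift) are quarantined with a warning rather than silently used.

# Attach alignment columns and row residues to a variant table. Rows whose
# ref_aa disagrees with the alignment are split off into 'quarantined'.
map_variants_to_columns <- function(variants, alignment,
                                    what = "variant") {
  variants <- validate_variants(variants)
  for (g in unique(variants$gene)) check_gene(alignment, g)
  n <- nrow(variants)
  column <- integer(n)
  row_aa <- character(n)
  for (g in unique(variants$gene)) {
    idx <- which(variants$gene == g)
    cols <- alignment$col_of[[g]]
    pos <- variants$position[idx]
    over <- pos > length(cols)
    if (any(over)) {
      pev_stop("%s position %d is beyond the ungapped length (%d) of gene %s",
               what, pos[over][1L], length(cols), g)
    }
    column[idx] <- cols[pos]
    row_aa[idx] <- alignment$mat[g, cols[pos]]
  }
  variants$column <- column
  mismatch <- row_aa != variants$ref_aa
  quarantined <- variants[mismatch, , drop = FALSE]
  if (nrow(quarantined) > 0L) {
    pev_warn(paste0("%d %s(s) disagree with the alignment row of their own ",
                    "gene and were quarantined (e.g. %s:%d %s, row has %s)"),
             nrow(quarantined), what, quarantined$gene[1L],
             quarantined$position[1L], quarantined$ref_aa[1L],
             row_aa[mismatch][1L])
  }
  list(mapped = variants[!mismatch, , drop = FALSE],
       quarantined = quarantined)
}

#' Find paralogous pathogenic variants for one target variant
#'
#' Returns the reference-set variants in other genes of the family that
#' satisfy the two paralogous-variant conditions for the target: same
#' alignment column and same reference amino acid (verified against the
#' alignment rows). `same_substitution` is `TRUE` when the hit carries the
#' same alternate amino acid as the target (para-SAME), `FALSE` otherwise
#' (para-DIFF).
#'
#' @param target a single variant: one-row data.frame or list with fields
#'   `gene`, `position`, `ref_aa`, `alt_aa`.
#' @param reference_set variant table of pathogenic variants to search.
#' @param alignment a `family_alignment` covering the target and reference
#'   genes.
#' @return `data.frame` with one row per hit: `source_gene`,
#'   `source_position`, `source_ref`, `source_alt`, `column`,
#'   `same_substitution`.
#' @export
find_paralog_hits <- function(target, reference_set, alignment) {
  tgt <- protein_variants(gene = target$gene, position = target$position,
                          ref_aa = target$ref_aa, alt_aa = target$alt_aa,
                          label = target$label %||% "pathogenic")
  ev <- suppressWarnings(annotate_set(tgt, reference_set, alignment))
  if (nrow(ev) == 0L) {
    pev_stop("target %s:%d ref_aa %s disagrees with the alignment row",
             tgt$gene, tgt$position, tgt$ref_aa)
  }
  hits <- attr(ev, "hits")[[1L]]
  rownames(hits) <- NULL
  hits
}

#' Annotate variants with para-SAME / para-DIFF paralog evidence
#'
#' Batch application of the paralogous-variant criteria: every target is
#' compared against the pathogenic reference variants in *other* genes of
#' the family (the cross-gene restriction makes self-hits impossible). The
#' two flags are evaluated independently: a target may satisfy both
#' para-SAME and para-DIFF; `para_diff_only` exposes the exclusive reading.
#'
#' @param targets variant table to annotate (any label).
#' @param reference_set variant table of pathogenic variants providing the
#'   evidence; non-pathogenic rows are refused.
#' @param alignment a `family_alignment`.
#' @return `data.frame` of class `paralog_evidence`: the target columns plus
#'   `column`, `para_same`, `para_diff`, `para_diff_only`, `n_hits` and
#'   `hit_list` (semicolon-joined `gene:pos:ref>alt`). Attributes:
#'   `hits` (per-target hit data.frames), `quarantined` (targets or
#'   reference rows dropped for row/record disagreement).
#' @export
annotate_set <- function(targets, reference_set, alignment) {
  reference_set <- validate_variants(reference_set)
  if (nrow(reference_set) > 0L &&
      any(reference_set$label != "pathogenic")) {
    pev_stop("the reference set must contain pathogenic variants only")
  }
  tmap <- map_variants_to_columns(targets, alignment, what = "target")
  rmap <- if (nrow(reference_set) > 0L) {
    map_variants_to_columns(reference_set, alignment, what = "reference")
  } else {
    list(mapped = reference_set, quarantined = reference_set)
  }
  tv <- tmap$mapped
  rv <- rmap$mapped

  n <- nrow(tv)
  hit_rows <- vector("list", n)
  empty_hits <- data.frame(source_gene = character(0),
                           source_position = integer(0),
                           source_ref = character(0),
                           source_alt = character(0),
                           column = integer(0),
                           same_substitution = logical(0),
                           stringsAsFactors = FALSE)
  if (nrow(rv) > 0L && n > 0L) {
    rkey <- paste(rv$column, rv$ref_aa)
    ref_by_key <- split(seq_len(nrow(rv)), rkey)
    tkey <- paste(tv$column, tv$ref_aa)
    for (i in seq_len(n)) {
      idx <- ref_by_key[[tkey[i]]]
      if (!is.null(idx)) idx <- idx[rv$gene[idx] != tv$gene[i]]
      if (is.null(idx) || length(idx) == 0L) {
        hit_rows[[i]] <- empty_hits
      } else {
        hit_rows[[i]] <- data.frame(
          source_gene = rv$gene[idx],
          source_position = rv$position[idx],
          source_ref = rv$ref_aa[idx],
          source_alt = rv$alt_aa[idx],
          column = rv$column[idx],
          same_substitution = rv$alt_aa[idx] == tv$alt_aa[i],
          stringsAsFactors = FALSE)
      }
    }
  } else {
    hit_rows <- rep(list(empty_hits), n)
  }

  tv$para_same <- vapply(hit_rows, function(h) any(h$same_substitution), NA)
  tv$para_diff <- vapply(hit_rows, function(h) any(!h$same_substitution), NA)
  tv$para_diff_only <- tv$para_diff & !tv$para_same
  tv$n_hits <- vapply(hit_rows, nrow, 0L)
  tv$hit_list <- vapply(hit_rows, function(h) {
    if (nrow(h) == 0L) return("")
    paste(sprintf("%s:%d:%s>%s", h$source_gene, h$source_position,
                  h$source_ref, h$source_alt), collapse = ";")
  }, "")
  rownames(tv) <- NULL
  attr(tv, "hits") <- hit_rows
  attr(tv, "quarantined") <- rbind(tmap$quarantined, rmap$quarantined)
  class(tv) <- c("paralog_evidence", "data.frame")
  tv
}

#' Residue-coverage gain from paralogous pathogenic variants
#'
#' Per gene, over distinct residues (not variants): `n_same_gene` residues
#' carry a pathogenic variant of the gene itself; `n_paralog` residues
#' correspond (same column, same reference amino acid) to a pathogenic
#' variant in another family member; `n_paralog_only` are paralog-covered
#' residues without a same-gene pathogenic variant. The union quantifies how
#' many residues gain classifiable evidence, and
#' `fold_increase = n_union / n_same_gene` the gain over gene-specific data
#' alone.
#'
#' @param alignment a `family_alignment`.
#' @param pathogenic variant table of pathogenic variants of the family.
#' @return `data.frame` of class `residue_coverage` with one row per gene
#'   plus a `"total"` row.
#' @export
residue_coverage <- function(alignment, pathogenic) {
  pathogenic <- validate_variants(pathogenic)
  if (nrow(pathogenic) > 0L && any(pathogenic$label != "pathogenic")) {
    pev_stop("residue_coverage expects pathogenic variants only")
  }
  pmap <- map_variants_to_columns(pathogenic, alignment, what = "pathogenic")
  pv <- pmap$mapped
  genes <- alignment$genes
  rows <- lapply(genes, function(g) {
    own <- pv[pv$gene == g, , drop = FALSE]
    own_res <- unique(own$position)
    other <- pv[pv$gene != g, , drop = FALSE]
    cols <- alignment$col_of[[g]]          # residue -> column
    res_aa <- alignment$mat[g, cols]       # residue -> amino acid
    cov_key <- unique(paste(other$column, other$ref_aa))
    covered <- which(paste(cols, res_aa) %in% cov_key)
    n_same <- length(own_res)
    n_par <- length(covered)
    n_par_only <- length(setdiff(covered, own_res))
    data.frame(gene = g,
               n_residues = length(cols),
               n_same_gene = n_same,
               n_paralog = n_par,
               n_paralog_only = n_par_only,
               n_union = n_same + n_par_only,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(gene = "total",
                      n_residues = sum(out$n_residues),
                      n_same_gene = sum(out$n_same_gene),
                      n_paralog = sum(out$n_paralog),
                      n_paralog_only = sum(out$n_paralog_only),
                      n_union = sum(out$n_union),
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out$fold_increase <- out$n_union / out$n_same_gene
  rownames(out) <- NULL
  class(out) <- c("residue_coverage", "data.frame")
  out
}
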