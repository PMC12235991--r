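# Protein-level variant tables: construction, validation, TSV IO.
#
# A variant table is a plain data.frame with columns
#   gene, position, ref_aa, alt_aa, label, phenotype, n_patients, source
# where label is "pathogenic" or "control". Tables are validated on entry
# and exact duplicates are collapsed with patient counts summed.

VARIANT_REQUIRED <- c("gene", "position", "ref_aa", "alt_aa", "label")
VARIANT_COLS <- c(VARIANT_REQUIRED, "phenotype", "n_patients", "source")
VARIANT_LABELS <- c("pathogenic", "control")

#' Construct a validated protein variant table
#'
#' Builds the package's canonical variant table: one row per amino-acid
#' substitution with a pathogenic/control label, an optional phenotype and a
#' patient tally. Exact duplicates (same gene, position, reference and
#' alternate amino acid, label and phenotype) are collapsed into one row with
#' `n_patients` summed. A substitution reported with conflicting labels is an
#' error: such conflicts signal upstream curation problems and are never
#' resolved silently.
#'
#' @param gene character vector of gene symbols, or a data.frame already
#'   holding the variant columns (then all other arguments are ignored).
#' @param position integer vector of 1-based residue positions.
#' @param ref_aa,alt_aa one-letter amino acids (20 canonical letters only);
#'   `alt_aa` must differ from `ref_aa` row-wise.
#' @param label `"pathogenic"` or `"control"`.
#' @param phenotype optional phenotype annotation (NA allowed).
#' @param n_patients optional positive integer patient counts (default 1).
#' @param source optional free-text provenance.
#' @param collapse collapse exact duplicates, summing `n_patients`
#'   (default `TRUE`).
#' @return a `data.frame` with columns gene, position, ref_aa, alt_aa, label,
#'   phenotype, n_patients, source, sorted by gene, position, alt_aa.
#' @examples
#' protein_variants("SCN1A", 226, "A", "T", "pathogenic")
#' @export
protein_variants <- function(gene, position = NULL, ref_aa = NULL,
                             alt_aa = NULL, label = NULL, phenotype = NA,
                             n_patients = 1L, source = NA,
                             collapse = TRUE) {
  if (is.data.frame(gene)) {
    df <- gene
  } else {
    df <- data.frame(gene = as.character(gene),
                     position = position,
                     ref_aa = as.character(ref_aa),
                     alt_aa = as.character(alt_aa),
                     label = as.character(label),
                     phenotype = phenotype,
                     n_patients = n_patients,
                     source = source,
                     stringsAsFactors = FALSE)
  }
  validate_variants(df, collapse = collapse)
}

# Core validator. Returns the normalized, optionally collapsed table.
validate_variants <- function(df, collapse = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(VARIANT_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    pev_stop("variant table is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"phenotype" %in% names(df)) df$phenotype <- rep(NA_character_, nrow(df))
  if (!"n_patients" %in% names(df)) df$n_patients <- rep(1L, nrow(df))
  if (!"source" %in% names(df)) df$source <- rep(NA_character_, nrow(df))
  df$gene <- trimws(as.character(df$gene))
  df$ref_aa <- toupper(trimws(as.character(df$ref_aa)))
  df$alt_aa <- toupper(trimws(as.character(df$alt_aa)))
  df$label <- trimws(as.character(df$label))
  df$phenotype <- as.character(df$phenotype)
  df$source <- as.character(df$source)
  df$n_patients[is.na(df$n_patients)] <- 1L

  pos <- suppressWarnings(as.numeric(df$position))
  npat <- suppressWarnings(as.numeric(df$n_patients))
  n <- nrow(df)
  bad <- function(cond) which(cond)
  problems <- list(
    "gene symbol is empty" = bad(is.na(df$gene) | df$gene == ""),
    "position is not an integer >= 1" =
      bad(is.na(pos) | pos < 1 | pos != round(pos)),
    "ref_aa is not one of the 20 canonical amino acids" =
      bad(!(df$ref_aa %in% AA20)),
    "alt_aa is not one of the 20 canonical amino acids" =
      bad(!(df$alt_aa %in% AA20)),
    "ref_aa equals alt_aa" =
      bad(!is.na(df$ref_aa) & df$ref_aa == df$alt_aa &
            df$ref_aa %in% AA20),
    "label is not 'pathogenic' or 'control'" =
      bad(!(df$label %in% VARIANT_LABELS)),
    "n_patients is not an integer >= 1" =
      bad(is.na(npat) | npat < 1 | npat != round(npat))
  )
  problems <- problems[vapply(problems, length, 1L) > 0L]
  if (length(problems) > 0L) {
    msgs <- vapply(names(problems), function(what) {
      sprintf("%s (row%s %s)", what,
              if (length(problems[[what]]) > 1L) "s" else "",
              paste(problems[[what]], collapse = ", "))
    }, "")
    pev_stop("invalid variant row(s): %s", paste(msgs, collapse = "; "))
  }
  df$position <- as.integer(pos)
  df$n_patients <- as.integer(npat)

  # conflicting labels for the same substitution are refused
  sub_key <- paste(df$gene, df$position, df$ref_aa, df$alt_aa, sep = ":")
  lab_by_sub <- tapply(df$label, sub_key, function(x) length(unique(x)))
  conflicts <- names(lab_by_sub)[lab_by_sub > 1L]
  if (length(conflicts) > 0L) {
    pev_stop("conflicting pathogenic/control labels for substitution(s): %s",
             paste(conflicts, collapse = ", "))
  }

  if (collapse && n > 0L) {
    key <- paste(sub_key, df$label, ifelse(is.na(df$phenotype), "<NA>",
                                           df$phenotype), sep = ":")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      npat_sum <- tapply(df$n_patients, key, sum)
      out <- df[first, , drop = FALSE]
      out$n_patients <- as.integer(npat_sum[key[first]])
      df <- out
    }
  }
  out <- order_variants(df[, VARIANT_COLS, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Read a protein variant table from TSV
#'
#' Reads a tab-separated table with a header and validates it into the
#' canonical variant table (see [protein_variants()]). Column names can be
#' remapped through `dialect`, e.g. `c(gene = "symbol")` when the file calls
#' its gene column "symbol". Malformed rows abort with their row numbers;
#' exact duplicates are collapsed with `n_patients` summed.
#'
#' @param path path to a TSV file with header.
#' @param dialect named character vector mapping canonical column names
#'   (names) to the file's column names (values).
#' @return a validated variant `data.frame`.
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) pev_stop("variant table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(VARIANT_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    pev_stop("%s: missing required column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  if ("phenotype" %in% names(df)) df$phenotype[df$phenotype == ""] <- NA
  if ("source" %in% names(df)) df$source[df$source == ""] <- NA
  validate_variants(df)
}

#' Write a protein variant table to TSV
#'
#' @param variants a validated variant table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  variants <- validate_variants(variants)
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene-family definitions from TSV
#'
#' Expects columns `family_id` and `gene`; one row per family member.
#' Families with fewer than two members or duplicated symbols are rejected.
#'
#' @param path path to a TSV file with header.
#' @return named list: family_id -> character vector of member gene symbols.
#' @export
read_family_definitions <- function(path) {
  if (!file.exists(path)) pev_stop("family definition file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "gene") %in% names(df))) {
    pev_stop("%s: need columns 'family_id' and 'gene'", path)
  }
  fams <- split(as.character(df$gene), as.character(df$family_id))
  for (fid in names(fams)) {
    if (anyDuplicated(fams[[fid]])) {
      pev_stop("family %s lists duplicate gene symbols", fid)
    }
    if (length(fams[[fid]]) < 2L) {
      pev_stop("family %s has fewer than 2 members", fid)
    }
  }
  fams
}
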