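# Per-column paralog-conservation tracks and the three-group stratification
# (maximum score / positive non-maximum / negative). External scores such as
# Parazscore are ingested from TSV; a clearly tagged stand-in score is
# available when no external track exists.

CONSERVATION_GROUPS <- c("MAX", "POSITIVE_NONMAX", "NEGATIVE")

#' Construct a conservation track
#'
#' Assigns every scored alignment column to exactly one of three paralog
#' conservation groups: `MAX` (columns attaining the family-wise maximum
#' score, i.e. full paralog conservation), `POSITIVE_NONMAX` (score >= 0
#' below the maximum) and `NEGATIVE` (score < 0, low conservation).
#'
#' @param column integer vector of 1-based alignment columns.
#' @param score numeric conservation scores (one per column).
#' @param family_id family identifier.
#' @param standin logical; `TRUE` marks the track as a package-internal
#'   stand-in rather than an externally computed score.
#' @return a `data.frame` of class `conservation_track` with columns
#'   `column`, `score`, `group`.
#' @export
conservation_track <- function(column, score, family_id = "family",
                               standin = FALSE) {
  column <- as.integer(column)
  score <- as.numeric(score)
  stopifnot(length(column) == length(score))
  if (anyDuplicated(column)) pev_stop("duplicate columns in conservation track")
  if (anyNA(score)) pev_stop("conservation scores must not be NA")
  max_score <- max(score)
  group <- ifelse(score == max_score, "MAX",
                  ifelse(score < 0, "NEGATIVE", "POSITIVE_NONMAX"))
  out <- data.frame(column = column, score = score, group = group,
                    stringsAsFactors = FALSE)
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family_id") <- family_id
  attr(out, "standin") <- standin
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Read a per-column conservation score from TSV
#'
#' Expects columns `family_id`, `column`, `score` (Parazscore-style). Only
#' rows of the requested family are used; groups are assigned by the
#' three-bucket rule of [conservation_track()].
#'
#' @param path path to a TSV file with header.
#' @param family_id family to extract.
#' @return a `conservation_track`.
#' @export
read_conservation <- function(path, family_id) {
  if (!file.exists(path)) pev_stop("conservation file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "column", "score")
  if (!all(need %in% names(df))) {
    pev_stop("%s: need columns %s", path, paste(need, collapse = ", "))
  }
  df <- df[df$family_id == family_id, , drop = FALSE]
  if (nrow(df) == 0L) pev_stop("no conservation rows for family '%s'", family_id)
  conservation_track(df$column, df$score, family_id = family_id,
                     standin = FALSE)
}

#' Stand-in paralog conservation score from an alignment
#'
#' A transparent substitute for an external paralog-conservation score when
#' none is supplied: per column, the fraction of non-gap rows sharing the
#' column's modal residue, z-scaled across columns (a degenerate, zero
#' variance alignment scores 0 everywhere, putting every column in `MAX`).
#' The result is tagged `standin = TRUE` and is not a reimplementation of any
#' published score.
#'
#' @param alignment a `family_alignment`.
#' @return a `conservation_track` over all columns with at least one non-gap
#'   row.
#' @export
default_conservation_score <- function(alignment) {
  stopifnot(inherits(alignment, "family_alignment"))
  frac <- apply(alignment$mat, 2L, function(col) {
    col <- col[col != GAP]
    if (length(col) == 0L) return(NA_real_)
    max(table(col)) / length(col)
  })
  scored <- which(!is.na(frac))
  x <- frac[scored]
  s <- stats::sd(x)
  z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  conservation_track(scored, z, family_id = alignment$family_id,
                     standin = TRUE)
}

#' Read a region table (pathogenic-enriched-region style)
#'
#' Expects columns `gene`, `start`, `end` (1-based, inclusive residue
#' coordinates, start <= end). Overlapping entries per gene are allowed; the
#' membership test normalizes them to a residue set.
#'
#' @param path path to a TSV file with header.
#' @return a validated `data.frame` of class `region_set`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) pev_stop("region file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  region_set(df)
}

#' Construct a region set
#'
#' @param df data.frame with columns `gene`, `start`, `end`.
#' @return the validated `data.frame` with class `region_set`.
#' @export
region_set <- function(df) {
  need <- c("gene", "start", "end")
  if (!all(need %in% names(df))) {
    pev_stop("region table needs columns %s", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) pev_stop("non-integer region bounds")
  if (any(df$start < 1L)) pev_stop("region start must be >= 1")
  if (any(df$start > df$end)) pev_stop("region start must be <= end")
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

# membership of (gene, position) pairs in any region of their gene
in_region <- function(regions, gene, position) {
  stopifnot(length(gene) == length(position))
  out <- logical(length(gene))
  for (i in seq_len(nrow(regions))) {
    out <- out | (gene == regions$gene[i] &
                    position >= regions$start[i] &
                    position <= regions$end[i])
  }
  out
}
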