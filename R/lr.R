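# The evidence calculus: contingency counts and the positive likelihood
# ratio LR+ = sensitivity / (1 - specificity), with
#   TP = pathogenic variants with qualifying paralog evidence
#   FN = pathogenic variants without
#   FP = control variants with
#   TN = control variants without.
# Counting is over variants, not residues. The 95% CI uses the standard log
# method for likelihood ratios; a parametric bootstrap is available for
# small cells. Zero cells are handled by the Haldane-Anscombe +0.5
# correction (flagged) or rejected under the strict policy.

CRITERIA <- c("para_same", "para_diff", "para_diff_only", "any")

qualifies_by <- function(evidence, criterion) {
  switch(criterion,
         para_same = evidence$para_same,
         para_diff = evidence$para_diff,
         para_diff_only = evidence$para_diff_only,
         any = evidence$n_hits >= 1L,
         pev_stop("unknown criterion '%s'", criterion))
}

#' Build a 2x2 contingency table from paralog evidence
#'
#' Counts pathogenic and control variants with and without qualifying
#' paralog evidence under the chosen criterion. Pooled scope sums the counts
#' across all genes of the family; a gene symbol restricts counting to that
#' gene.
#'
#' @param evidence a `paralog_evidence` table containing both pathogenic and
#'   control targets (see [annotate_set()]), or any data.frame with the flag
#'   columns and a `label`.
#' @param criterion one of `"para_same"`, `"para_diff"`, `"para_diff_only"`,
#'   `"any"`.
#' @param scope `"pooled"` or a gene symbol.
#' @return object of class `contingency`: list with `tp`, `fn`, `fp`, `tn`,
#'   `scope`, `criterion`.
#' @export
build_contingency <- function(evidence, criterion = "para_same",
                              scope = "pooled") {
  criterion <- match.arg(criterion, CRITERIA)
  if (!"label" %in% names(evidence) || anyNA(evidence$label)) {
    pev_stop("every target must carry a pathogenic/control label")
  }
  if (!all(evidence$label %in% VARIANT_LABELS)) {
    pev_stop("unknown label(s): %s",
             paste(setdiff(unique(evidence$label), VARIANT_LABELS),
                   collapse = ", "))
  }
  if (!identical(scope, "pooled")) {
    evidence <- evidence[evidence$gene == scope, , drop = FALSE]
  }
  q <- qualifies_by(evidence, criterion)
  patho <- evidence$label == "pathogenic"
  contingency(tp = sum(patho & q), fn = sum(patho & !q),
              fp = sum(!patho & q), tn = sum(!patho & !q),
              scope = scope, criterion = criterion)
}

#' @rdname build_contingency
#' @param tp,fn,fp,tn non-negative integer cell counts.
#' @export
contingency <- function(tp, fn, fp, tn, scope = "pooled",
                        criterion = "custom") {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    pev_stop("contingency cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 scope = scope, criterion = criterion),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("Contingency (%s, %s): TP=%d FN=%d FP=%d TN=%d\n",
              x$scope, x$criterion, x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

# sum a list of contingency objects cell-wise
pool_contingency <- function(counts, scope = "pooled",
                             criterion = counts[[1L]]$criterion) {
  contingency(tp = sum(vapply(counts, `[[`, 0L, "tp")),
              fn = sum(vapply(counts, `[[`, 0L, "fn")),
              fp = sum(vapply(counts, `[[`, 0L, "fp")),
              tn = sum(vapply(counts, `[[`, 0L, "tn")),
              scope = scope, criterion = criterion)
}

#' Positive likelihood ratio with confidence interval
#'
#' Computes sensitivity, specificity and
#' `LR+ = sensitivity / (1 - specificity)` from a 2x2 contingency table.
#' The default confidence interval is the log method,
#' `exp(log LR+ +/- z * sqrt(1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)))`;
#' `ci_method = "bootstrap"` draws parametric binomial resamples of both
#' margins instead. If any cell is zero, the Haldane-Anscombe policy adds
#' 0.5 to all four cells before computing (and flags `corrected`); the
#' strict policy raises an error naming the cell.
#'
#' @param counts a `contingency` object (or anything coercible via
#'   `contingency()` fields `tp`, `fn`, `fp`, `tn`).
#' @param zero_cell `"haldane"` (default) or `"strict"`.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"log"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `ci_method = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resamples.
#' @return object of class `lr_result`: list with `sensitivity`,
#'   `specificity`, `lr_plus`, `lr_minus`, `ci_low`, `ci_high`, `corrected`,
#'   `conf_level`, `ci_method`, `counts`.
#' @examples
#' lr_plus(contingency(tp = 9, fn = 1, fp = 10, tn = 90))
#' @export
lr_plus <- function(counts, zero_cell = c("haldane", "strict"),
                    conf_level = 0.95, ci_method = c("log", "bootstrap"),
                    n_boot = 2000L, boot_seed = 1L) {
  zero_cell <- match.arg(zero_cell)
  ci_method <- match.arg(ci_method)
  if (!inherits(counts, "contingency")) {
    counts <- contingency(counts$tp, counts$fn, counts$fp, counts$tn)
  }
  raw <- c(tp = counts$tp, fn = counts$fn, fp = counts$fp, tn = counts$tn)
  if (raw["tp"] + raw["fn"] == 0L) {
    pev_stop("no pathogenic variants in scope '%s': LR+ undefined",
             counts$scope)
  }
  if (raw["fp"] + raw["tn"] == 0L) {
    pev_stop("no control variants in scope '%s': LR+ undefined",
             counts$scope)
  }
  corrected <- any(raw == 0L)
  if (corrected && zero_cell == "strict") {
    pev_stop("zero cell (%s) under strict zero-cell policy",
             paste(names(raw)[raw == 0L], collapse = ", "))
  }
  cells <- raw + (if (corrected) 0.5 else 0)
  sens <- cells["tp"] / (cells["tp"] + cells["fn"])
  spec <- cells["tn"] / (cells["tn"] + cells["fp"])
  lr <- sens / (1 - spec)
  lrm <- (1 - sens) / spec
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "log") {
    se_log <- sqrt(1 / cells["tp"] - 1 / (cells["tp"] + cells["fn"]) +
                     1 / cells["fp"] - 1 / (cells["fp"] + cells["tn"]))
    ci <- exp(log(lr) + c(-1, 1) * z * se_log)
  } else {
    n1 <- cells["tp"] + cells["fn"]
    n0 <- cells["fp"] + cells["tn"]
    ci <- with_seed(boot_seed, {
      tp_b <- stats::rbinom(n_boot, size = round(n1), prob = sens)
      fp_b <- stats::rbinom(n_boot, size = round(n0), prob = 1 - spec)
      lr_b <- ((tp_b + 0.5) / (n1 + 1)) / ((fp_b + 0.5) / (n0 + 1))
      stats::quantile(lr_b, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                      names = FALSE)
    })
    ci <- range(c(ci, lr))  # guarantee the point estimate lies inside
  }
  structure(list(sensitivity = unname(sens),
                 specificity = unname(spec),
                 lr_plus = unname(lr),
                 lr_minus = unname(lrm),
                 ci_low = unname(ci[1L]),
                 ci_high = unname(ci[2L]),
                 corrected = corrected,
                 conf_level = conf_level,
                 ci_method = ci_method,
                 counts = counts),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, digits = 3L, ...) {
  cat(sprintf("LR+ = %.*g  [%.*g, %.*g] (%d%% CI, %s%s)\n",
              digits, x$lr_plus, digits, x$ci_low, digits, x$ci_high,
              round(100 * x$conf_level), x$ci_method,
              if (x$corrected) ", zero-cell corrected" else ""))
  cat(sprintf("  sensitivity %.*g, specificity %.*g  (TP=%d FN=%d FP=%d TN=%d)\n",
              digits, x$sensitivity, digits, x$specificity,
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn))
  invisible(x)
}

# one-row data.frame view of an lr_result, used by TSV emitters
lr_row <- function(x) {
  data.frame(scope = x$counts$scope, criterion = x$counts$criterion,
             tp = x$counts$tp, fn = x$counts$fn,
             fp = x$counts$fp, tn = x$counts$tn,
             sensitivity = x$sensitivity, specificity = x$specificity,
             lr_plus = x$lr_plus, ci_low = x$ci_low, ci_high = x$ci_high,
             corrected = x$corrected, stringsAsFactors = FALSE)
}

#' Gene-wise likelihood ratios
#'
#' Computes one LR+ per gene, restricted to genes where at least
#' `min_pathogenic` pathogenic and `min_control` control variants could be
#' mapped (default 10 and 10, the conventional floor below which a gene-wise
#' LR+ is too unstable to report). Skipped genes are listed with their
#' counts.
#'
#' @inheritParams build_contingency
#' @param min_pathogenic,min_control minimum mapped variants per gene.
#' @param ... passed to [lr_plus()].
#' @return list with `results` (named list of `lr_result`) and `skipped`
#'   (`data.frame` gene / n_pathogenic / n_control).
#' @export
genewise_lr <- function(evidence, criterion = "para_same",
                        min_pathogenic = 10L, min_control = 10L, ...) {
  criterion <- match.arg(criterion, CRITERIA)
  genes <- sort(unique(evidence$gene))
  results <- list()
  skipped <- list()
  for (g in genes) {
    sub <- evidence[evidence$gene == g, , drop = FALSE]
    n_p <- sum(sub$label == "pathogenic")
    n_c <- sum(sub$label == "control")
    if (n_p >= min_pathogenic && n_c >= min_control) {
      results[[g]] <- lr_plus(build_contingency(sub, criterion, scope = g), ...)
    } else {
      skipped[[g]] <- data.frame(gene = g, n_pathogenic = n_p,
                                 n_control = n_c, stringsAsFactors = FALSE)
    }
  }
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(gene = character(0), n_pathogenic = integer(0),
                    n_control = integer(0)))
}

#' Conservation-stratified likelihood ratios
#'
#' Assigns each target to the paralog-conservation group of its alignment
#' column (`MAX`, `POSITIVE_NONMAX`, `NEGATIVE`; see
#' [conservation_track()]) and computes the LR+ within each group. Targets
#' at columns without a score fall into an explicit `"unscored"` bucket
#' rather than being dropped.
#'
#' @inheritParams build_contingency
#' @param conservation a `conservation_track` for the family.
#' @param ... passed to [lr_plus()].
#' @return named list of `lr_result`, one per group present in the data.
#' @export
stratified_lr <- function(evidence, conservation, criterion = "para_same",
                          ...) {
  criterion <- match.arg(criterion, CRITERIA)
  stopifnot(inherits(conservation, "conservation_track"))
  group_of <- stats::setNames(conservation$group, conservation$column)
  grp <- group_of[as.character(evidence$column)]
  grp[is.na(grp)] <- "unscored"
  out <- list()
  for (g in intersect(c(CONSERVATION_GROUPS, "unscored"), unique(grp))) {
    sub <- evidence[grp == g, , drop = FALSE]
    cnt <- build_contingency(sub, criterion, scope = "pooled")
    cnt$scope <- g
    out[[g]] <- lr_plus(cnt, ...)
  }
  out
}

#' Enrichment of pathogenic variants by paralog-hit count
#'
#' For each k from 1 to the largest observed hit count, compares the
#' fraction of pathogenic variants carrying at least k paralogous pathogenic
#' hits with the same fraction among control variants. A zero cell in the
#' implied 2x2 table triggers the Haldane-Anscombe +0.5 correction, flagged
#' per row.
#'
#' @param evidence a `paralog_evidence` table with pathogenic and control
#'   targets.
#' @return `data.frame` with columns `k`, `n_pathogenic_ge_k`,
#'   `n_control_ge_k`, `frac_pathogenic`, `frac_control`, `fold_enrichment`,
#'   `corrected`.
#' @export
enrichment_by_hit_count <- function(evidence) {
  patho <- evidence$label == "pathogenic"
  n_p <- sum(patho)
  n_c <- sum(!patho)
  if (n_p == 0L || n_c == 0L) {
    pev_stop("need both pathogenic and control targets for enrichment")
  }
  k_max <- max(evidence$n_hits, 1L)
  rows <- lapply(seq_len(k_max), function(k) {
    a <- sum(patho & evidence$n_hits >= k)
    c_ <- sum(!patho & evidence$n_hits >= k)
    corrected <- any(c(a, n_p - a, c_, n_c - c_) == 0L)
    if (corrected) {
      fold <- ((a + 0.5) / (n_p + 1)) / ((c_ + 0.5) / (n_c + 1))
    } else {
      fold <- (a / n_p) / (c_ / n_c)
    }
    data.frame(k = k, n_pathogenic_ge_k = a, n_control_ge_k = c_,
               frac_pathogenic = a / n_p, frac_control = c_ / n_c,
               fold_enrichment = fold, corrected = corrected)
  })
  do.call(rbind, rows)
}

#' Region-restricted likelihood ratio
#'
#' Uses membership in any supplied region of the variant's gene as the
#' qualifying test instead of paralog evidence, with the contingency and
#' LR+ contract otherwise unchanged. This is the comparison surface for
#' region-based approaches such as pathogenic-variant-enriched regions.
#'
#' @param regions a `region_set`.
#' @param variants variant table with pathogenic and control labels.
#' @param ... passed to [lr_plus()].
#' @return an `lr_result` (criterion `"region"`).
#' @export
region_lr <- function(regions, variants, ...) {
  variants <- validate_variants(variants)
  q <- in_region(regions, variants$gene, variants$position)
  patho <- variants$label == "pathogenic"
  cnt <- contingency(tp = sum(patho & q), fn = sum(patho & !q),
                     fp = sum(!patho & q), tn = sum(!patho & !q),
                     scope = "pooled", criterion = "region")
  lr_plus(cnt, ...)
}
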