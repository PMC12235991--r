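# The central estimator: calibrate paralog evidence as a positive
# likelihood ratio on a labeled variant set.

#' Fit the paralog-evidence likelihood-ratio model
#'
#' The package's main entry point: annotates a labeled variant set
#' (pathogenic and control) with paralogous pathogenic variants through the
#' family alignment, then calibrates the chosen evidence criterion as a
#' positive likelihood ratio, pooled across the family and gene-wise.
#'
#' The evidence reference defaults to the pathogenic variants of `variants`
#' themselves: each target is compared only against reference variants in
#' *other* genes, so a variant never supports itself.
#'
#' @param variants variant table with both labels (see
#'   [protein_variants()]).
#' @param alignment a `family_alignment` covering all genes involved.
#' @param criterion evidence criterion: `"para_same"` (default),
#'   `"para_diff"`, `"para_diff_only"` or `"any"`.
#' @param reference optional pathogenic variant table to use as the evidence
#'   source instead of the pathogenic subset of `variants`.
#' @param min_pathogenic,min_control gene-wise reporting thresholds (see
#'   [genewise_lr()]).
#' @param zero_cell,conf_level,ci_method passed to [lr_plus()].
#' @return an object of class `paralog_lr` with elements `call`,
#'   `criterion`, `evidence` (the annotated targets), `pooled`
#'   (an `lr_result`), `genewise`, `skipped`, `n_pathogenic`, `n_control`,
#'   `family_id`. Methods: `print`, `summary`, `coef`, `confint`.
#' @examples
#' aln <- family_alignment(c(G1 = "ACDEFGHIKL", G2 = "ACDEFGHIKL"))
#' v <- protein_variants(
#'   gene = c("G1", "G2", "G1", "G2"),
#'   position = c(1, 1, 5, 7),
#'   ref_aa = c("A", "A", "F", "H"),
#'   alt_aa = c("T", "T", "S", "R"),
#'   label = c("pathogenic", "pathogenic", "control", "control"))
#' fit <- paralog_lr(v, aln, min_pathogenic = 1, min_control = 1)
#' fit
#' @export
paralog_lr <- function(variants, alignment,
                       criterion = c("para_same", "para_diff",
                                     "para_diff_only", "any"),
                       reference = NULL,
                       min_pathogenic = 10L, min_control = 10L,
                       zero_cell = "haldane", conf_level = 0.95,
                       ci_method = "log") {
  criterion <- match.arg(criterion)
  variants <- validate_variants(variants)
  if (is.null(reference)) {
    reference <- variants[variants$label == "pathogenic", , drop = FALSE]
  }
  evidence <- annotate_set(variants, reference, alignment)
  pooled <- lr_plus(build_contingency(evidence, criterion, "pooled"),
                    zero_cell = zero_cell, conf_level = conf_level,
                    ci_method = ci_method)
  gw <- genewise_lr(evidence, criterion = criterion,
                    min_pathogenic = min_pathogenic,
                    min_control = min_control,
                    zero_cell = zero_cell, conf_level = conf_level,
                    ci_method = ci_method)
  structure(list(call = match.call(),
                 criterion = criterion,
                 evidence = evidence,
                 pooled = pooled,
                 genewise = gw$results,
                 skipped = gw$skipped,
                 n_pathogenic = sum(evidence$label == "pathogenic"),
                 n_control = sum(evidence$label == "control"),
                 family_id = alignment$family_id),
            class = "paralog_lr")
}

#' @export
print.paralog_lr <- function(x, digits = 3L, ...) {
  cat(sprintf("Paralog-evidence likelihood ratio (family '%s', criterion %s)\n",
              x$family_id, x$criterion))
  cat(sprintf("  %d pathogenic and %d control variants\n",
              x$n_pathogenic, x$n_control))
  cat("Pooled: ")
  print(x$pooled, digits = digits)
  if (length(x$genewise) > 0L) {
    cat(sprintf("Gene-wise LR+ reported for %d gene(s): %s\n",
                length(x$genewise),
                paste(names(x$genewise), collapse = ", ")))
  }
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("Skipped %d gene(s) below the reporting thresholds\n",
                nrow(x$skipped)))
  }
  invisible(x)
}

#' Summarize a fitted paralog-evidence model
#'
#' @param object a `paralog_lr` fit.
#' @param ... unused.
#' @return a `summary.paralog_lr`: the fit plus a `table` data.frame with
#'   one row per scope (pooled and each reported gene).
#' @export
summary.paralog_lr <- function(object, ...) {
  rows <- c(list(lr_row(object$pooled)),
            lapply(object$genewise, lr_row))
  object$table <- do.call(rbind, rows)
  rownames(object$table) <- NULL
  class(object) <- c("summary.paralog_lr", class(object))
  object
}

#' @export
print.summary.paralog_lr <- function(x, digits = 4L, ...) {
  cat(sprintf("Paralog-evidence likelihood ratio (family '%s', criterion %s)\n\n",
              x$family_id, x$criterion))
  print(format(x$table, digits = digits), row.names = FALSE)
  if (nrow(x$skipped) > 0L) {
    cat("\nSkipped genes (below thresholds):\n")
    print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.paralog_lr <- function(object, ...) {
  c(lr_plus = object$pooled$lr_plus,
    sensitivity = object$pooled$sensitivity,
    specificity = object$pooled$specificity)
}

#' @export
confint.paralog_lr <- function(object, parm = "lr_plus", level = NULL, ...) {
  if (!is.null(level) && level != object$pooled$conf_level) {
    pev_stop("refit with conf_level = %s to change the interval level", level)
  }
  matrix(c(object$pooled$ci_low, object$pooled$ci_high), nrow = 1L,
         dimnames = list("lr_plus",
                         sprintf("%g %%", 100 * c(
                           (1 - object$pooled$conf_level) / 2,
                           1 - (1 - object$pooled$conf_level) / 2))))
}
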