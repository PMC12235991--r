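# Phenotype-informed evidence, cross-validated: split the focal phenotype's
# variants into four folds, learn 3D-correlated phenotypes on the training
# side only, and measure the LR+ of correlated- vs non-correlated-phenotype
# paralog evidence on the held-out fold. Four iterations, one per fold;
# cells are summed across iterations before the LR+ is taken.

#' Split a phenotype's variants into four folds
#'
#' Seeded shuffle of the distinct variants followed by round-robin
#' assignment, so fold sizes differ by at most one and the plan is
#' deterministic given the seed.
#'
#' @param variants variant table of the focal phenotype (distinct
#'   substitutions are the unit of splitting; duplicates collapse first).
#' @param seed integer seed.
#' @param n_folds number of folds (default 4).
#' @return object of class `fold_plan`: list with `variants` (the distinct
#'   table), `fold` (integer assignment), `seed`, `n_folds`.
#' @export
make_folds <- function(variants, seed, n_folds = 4L) {
  variants <- validate_variants(variants)
  if (nrow(variants) < n_folds) {
    pev_stop("need at least %d distinct variants to build %d folds (got %d)",
             n_folds, n_folds, nrow(variants))
  }
  ord <- with_seed(seed, sample.int(nrow(variants)))
  fold <- integer(nrow(variants))
  fold[ord] <- rep_len(seq_len(n_folds), nrow(variants))
  structure(list(variants = variants, fold = fold, seed = seed,
                 n_folds = n_folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d variants in %d folds (sizes %s), seed %d\n",
              nrow(x$variants), x$n_folds,
              paste(tabulate(x$fold, x$n_folds), collapse = "/"), x$seed))
  invisible(x)
}

# substitution identity key
variant_key <- function(v) paste(v$gene, v$position, v$ref_aa, v$alt_aa,
                                 sep = ":")

#' Cross-validated phenotype-informed paralog evidence
#'
#' For each of four iterations, three folds of the focal phenotype's
#' variants are combined with all variants of the other phenotypes; the 3D
#' phenotype-correlation matrix is recomputed on that training set only, and
#' the held-out fold is scored against three evidence classes drawn from the
#' training side: variants of significantly positively correlated
#' phenotypes (`correlated`), variants of non-significant or negatively
#' correlated phenotypes (`non_correlated`), and control variants
#' (`control_paralog`). Contingency cells are summed across iterations and
#' the pooled LR+ is reported per class.
#'
#' No held-out variant ever enters its iteration's correlation matrix or
#' reference sets; the disjointness assertion is instrumented and recorded
#' in the result (`leakage_ok`).
#'
#' @param focal_phenotype name of the focal phenotype.
#' @param variants phenotype cohort: variant table with `phenotype` and
#'   `n_patients` for all phenotypes, all labeled pathogenic.
#' @param controls control variant table (label `control`), used both as
#'   comparison targets and as the `control_paralog` reference.
#' @param alignment a `family_alignment`.
#' @param structure reference `structure_model`.
#' @param reference_gene gene whose chain `structure` represents.
#' @param threshold neighbor distance threshold in Angstrom (default 12).
#' @param seed integer seed for the fold split.
#' @param min_variants minimum number of distinct focal variants (default 4;
#'   large real cohorts conventionally require more than 40).
#' @param min_positions position threshold for phenotype profiles.
#' @param alpha significance level for the correlation calls.
#' @param use_adjusted use Bonferroni-adjusted p-values for the correlated
#'   class (default `TRUE`; `FALSE` uses raw p-values).
#' @param criterion qualifying evidence, passed to [build_contingency()]
#'   (default `"any"`: any paralogous variant from the class's reference
#'   set).
#' @return object of class `paralog_cv`: list with `focal_phenotype`,
#'   `classes` (per class: pooled `contingency` and `lr_result`),
#'   `per_iteration` (data.frame of cells), `correlated` (list of phenotype
#'   sets per iteration), `fold_plan`, `leakage_ok`, `threshold`, `seed`.
#' @export
run_cv <- function(focal_phenotype, variants, controls, alignment,
                   structure, reference_gene, threshold = 12, seed = 1L,
                   min_variants = 4L, min_positions = 6L, alpha = 0.05,
                   use_adjusted = TRUE, criterion = "any") {
  variants <- validate_variants(variants)
  controls <- validate_variants(controls)
  if (any(variants$label != "pathogenic")) {
    pev_stop("the phenotype cohort must be labeled pathogenic")
  }
  if (any(controls$label != "control")) {
    pev_stop("the control set must be labeled control")
  }
  focal <- variants[!is.na(variants$phenotype) &
                      variants$phenotype == focal_phenotype, , drop = FALSE]
  others <- variants[is.na(variants$phenotype) |
                       variants$phenotype != focal_phenotype, , drop = FALSE]
  if (nrow(focal) < max(4L, min_variants)) {
    pev_stop("focal phenotype '%s' has %d distinct variants; need >= %d",
             focal_phenotype, nrow(focal), max(4L, min_variants))
  }
  plan <- make_folds(focal, seed = seed)
  graph <- build_neighbor_graph(structure, threshold = threshold)

  classes <- c("correlated", "non_correlated", "control_paralog")
  iter_rows <- list()
  correlated_sets <- list()
  leakage_ok <- TRUE
  for (it in seq_len(plan$n_folds)) {
    test <- plan$variants[plan$fold == it, , drop = FALSE]
    train_focal <- plan$variants[plan$fold != it, , drop = FALSE]
    training <- rbind(train_focal, others)

    # leakage assertion: held-out substitutions must be absent from training
    disjoint <- length(intersect(variant_key(test), variant_key(training))) == 0L
    leakage_ok <- leakage_ok && disjoint

    proj <- suppressWarnings(
      project_to_reference(alignment, reference_gene, training))
    prof <- phenotype_profiles(proj, graph, min_positions = min_positions)
    corr_set <- character(0)
    if (ncol(prof$tally) >= 2L && focal_phenotype %in% colnames(prof$tally)) {
      cm <- correlate_phenotypes(prof, alpha = alpha)
      pvals <- if (use_adjusted) cm$p_adj else cm$p
      sig_pos <- !is.na(pvals) & pvals < alpha &
        !is.na(cm$tau) & cm$tau > 0
      corr_set <- setdiff(
        cm$phenotypes[sig_pos[focal_phenotype, ]], focal_phenotype)
    }
    correlated_sets[[it]] <- corr_set

    other_phen <- unique(others$phenotype[!is.na(others$phenotype)])
    refs <- list(
      correlated = training[!is.na(training$phenotype) &
                              training$phenotype %in% corr_set, , drop = FALSE],
      non_correlated = training[!is.na(training$phenotype) &
                                  training$phenotype %in%
                                  setdiff(other_phen, corr_set), , drop = FALSE],
      control_paralog = controls)

    targets <- rbind(test, controls)
    for (cl in classes) {
      ref <- refs[[cl]]
      if (cl == "control_paralog") {
        ref$label <- "pathogenic"  # evidence role, not a clinical claim
      }
      if (nrow(ref) == 0L) {
        cnt <- contingency(0L, nrow(test), 0L, nrow(controls),
                           scope = focal_phenotype, criterion = criterion)
      } else {
        ev <- suppressWarnings(annotate_set(targets, ref, alignment))
        cnt <- build_contingency(ev, criterion = criterion, scope = "pooled")
      }
      iter_rows[[length(iter_rows) + 1L]] <- data.frame(
        iteration = it, class = cl, tp = cnt$tp, fn = cnt$fn,
        fp = cnt$fp, tn = cnt$tn,
        n_correlated_phenotypes = length(corr_set),
        empty_reference = nrow(refs[[cl]]) == 0L,
        stringsAsFactors = FALSE)
    }
  }
  per_iteration <- do.call(rbind, iter_rows)

  class_results <- lapply(classes, function(cl) {
    sub <- per_iteration[per_iteration$class == cl, , drop = FALSE]
    cnt <- contingency(sum(sub$tp), sum(sub$fn), sum(sub$fp), sum(sub$tn),
                       scope = focal_phenotype, criterion = cl)
    list(counts = cnt, lr = lr_plus(cnt))
  })
  names(class_results) <- classes

  structure(list(focal_phenotype = focal_phenotype,
                 classes = class_results,
                 per_iteration = per_iteration,
                 correlated = correlated_sets,
                 fold_plan = plan,
                 leakage_ok = leakage_ok,
                 threshold = threshold,
                 seed = seed),
            class = "paralog_cv")
}

#' @export
print.paralog_cv <- function(x, digits = 3L, ...) {
  cat(sprintf("Phenotype-informed paralog evidence, %d-fold CV (focal: %s)\n",
              x$fold_plan$n_folds, x$focal_phenotype))
  for (cl in names(x$classes)) {
    r <- x$classes[[cl]]
    cat(sprintf("  %-16s LR+ = %6.*g [%.*g, %.*g]  (TP=%d FN=%d FP=%d TN=%d)\n",
                cl, digits, r$lr$lr_plus, digits, r$lr$ci_low,
                digits, r$lr$ci_high, r$counts$tp, r$counts$fn,
                r$counts$fp, r$counts$tn))
  }
  cat(sprintf("  leakage check: %s; threshold %g A; seed %d\n",
              if (x$leakage_ok) "passed" else "FAILED",
              x$threshold, x$seed))
  invisible(x)
}
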