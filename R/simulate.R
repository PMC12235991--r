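# Seeded generators for families, variant sets, structures and phenotype
# cohorts, with the statistical structure the rest of the package assumes.
# All generators are pure functions of (spec, seed): identical seeds replay
# byte-identical outputs, and every planted dataset travels with a ground
# truth computed independently of the annotation code path.

#' Specify a synthetic gene family
#'
#' @param n_genes number of paralogs (2..10).
#' @param length ungapped-protein / alignment length (columns).
#' @param conserved_columns columns forced identical across all genes
#'   (never diverged, never gapped).
#' @param identity_target mean pairwise identity to realize (default 0.85,
#'   comfortably above the 0.80 family-inclusion cutoff).
#' @param gap_prob probability that a divergent column carries a gap in one
#'   (never more than one) gene (default 0).
#' @param seed integer seed.
#' @param family_id family identifier.
#' @return a list of class `family_spec`.
#' @export
family_spec <- function(n_genes = 3L, length = 100L,
                        conserved_columns = integer(0),
                        identity_target = 0.85, gap_prob = 0,
                        seed = 1L, family_id = "SIMFAM") {
  stopifnot(n_genes >= 2L, n_genes <= 10L, length >= 10L,
            identity_target > 0, identity_target <= 1,
            gap_prob >= 0, gap_prob <= 1)
  conserved_columns <- as.integer(conserved_columns)
  if (length(conserved_columns) > 0 &&
      (min(conserved_columns) < 1L || max(conserved_columns) > length)) {
    pev_stop("conserved_columns must lie in 1..length")
  }
  structure(list(n_genes = as.integer(n_genes), length = as.integer(length),
                 conserved_columns = conserved_columns,
                 identity_target = identity_target, gap_prob = gap_prob,
                 seed = as.integer(seed), family_id = family_id),
            class = "family_spec")
}

#' Generate a synthetic gene family alignment
#'
#' Realizes the identity target exactly: `k = round((1 - target) * length)`
#' columns are made fully divergent (every gene carries a distinct residue),
#' all remaining columns are identical across genes, so every unordered pair
#' has identity `(length - k) / length` — within `1/(2*length)` of the
#' target. Gaps, when enabled, replace the residue of at most one gene per
#' divergent column, which leaves the union-denominator identity unchanged.
#'
#' @param spec a `family_spec`.
#' @return a `family_alignment` with genes `G1..Gn`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    k <- round((1 - spec$identity_target) * L)
    divergible <- setdiff(seq_len(L), spec$conserved_columns)
    if (k > length(divergible)) {
      pev_stop(paste0("identity target %.2f is infeasible: it requires %d ",
                      "divergent columns but only %d are not conserved"),
               spec$identity_target, k, length(divergible))
    }
    consensus <- sample(AA20, L, replace = TRUE)
    mat <- matrix(rep(consensus, each = spec$n_genes), nrow = spec$n_genes)
    divergent <- sort(sample(divergible, k))
    for (col in divergent) {
      mat[, col] <- sample(AA20, spec$n_genes)  # distinct residues per gene
      if (spec$gap_prob > 0 && stats::runif(1) < spec$gap_prob) {
        mat[sample.int(spec$n_genes, 1L), col] <- GAP
      }
    }
    rows <- apply(mat, 1L, paste, collapse = "")
    names(rows) <- paste0("G", seq_len(spec$n_genes))
    family_alignment(rows, family_id = spec$family_id)
  })
}

#' Specify a planted variant set
#'
#' @param n_pathogenic,n_control variants per gene.
#' @param share_prob probability that a pathogenic variant is planted at an
#'   alignment column already carrying a pathogenic variant of another gene
#'   (with matching reference amino acid); the remainder, and all controls,
#'   are placed uniformly over residues.
#' @param same_alt_prob probability that a planted shared copy uses the same
#'   alternate amino acid as its cluster (para-SAME); otherwise a different
#'   one (para-DIFF) (default 1).
#' @param target_lr optional target pooled para-SAME LR+; when given,
#'   `share_prob` is derived analytically from a background-only pre-pass
#'   (see [plant_variants()]) and the supplied `share_prob` is ignored.
#' @param seed integer seed.
#' @return a list of class `variant_spec`.
#' @export
variant_spec <- function(n_pathogenic = 20L, n_control = 20L,
                         share_prob = 0.2, same_alt_prob = 1,
                         target_lr = NULL, seed = 1L) {
  stopifnot(share_prob >= 0, share_prob <= 1,
            same_alt_prob >= 0, same_alt_prob <= 1,
            n_pathogenic >= 1L, n_control >= 1L)
  structure(list(n_pathogenic = as.integer(n_pathogenic),
                 n_control = as.integer(n_control),
                 share_prob = share_prob, same_alt_prob = same_alt_prob,
                 target_lr = target_lr, seed = as.integer(seed)),
            class = "variant_spec")
}

# Exact expected para-SAME / any-hit firing probability for a uniformly
# placed variant with uniform alternate allele, per gene, given a realized
# pathogenic set. Used for both the truth sidecar and target_lr calibration.
uniform_hit_probs <- function(family, pathogenic, exclude = NULL) {
  sapply(family$genes, function(g) {
    cols <- family$col_of[[g]]
    res_aa <- family$mat[g, cols]
    elig <- seq_along(cols)
    if (!is.null(exclude)) {
      elig <- setdiff(elig, exclude[[g]] %||% integer(0))
    }
    if (length(elig) == 0L) return(c(same = 0, any = 0))
    other <- pathogenic[pathogenic$gene != g, , drop = FALSE]
    p_same <- p_any <- numeric(length(elig))
    if (nrow(other) > 0L) {
      key <- paste(other$column, other$ref_aa)
      alts_by_key <- tapply(other$alt_aa, key, function(a) unique(a))
      rkey <- paste(cols[elig], res_aa[elig])
      hit <- rkey %in% names(alts_by_key)
      p_any[hit] <- 1
      # random alt is uniform over the 19 non-reference residues; qualifying
      # alternates never equal the reference at ref-matching columns
      p_same[hit] <- vapply(rkey[hit],
                            function(kk) length(alts_by_key[[kk]]) / 19, 0)
    }
    c(same = mean(p_same), any = mean(p_any))
  })
}

#' Plant pathogenic and control variants on a synthetic family
#'
#' Pathogenic variants are planted in two strata: with probability
#' `share_prob` a variant joins a cross-paralog cluster at a fully conserved
#' column (same reference amino acid by construction; same alternate with
#' probability `same_alt_prob`), otherwise it is placed uniformly over the
#' gene's residues. Controls are placed uniformly over residues not carrying
#' a pathogenic variant of the same gene, with a uniform alternate amino
#' acid. With `share_prob = 0` pathogenic and control variants follow the
#' same positional distribution, so the para-SAME LR+ is 1 in expectation.
#'
#' The returned ground truth is computed independently of the annotation
#' code path: sensitivities by exhaustive enumeration over the realized
#' placements, false-positive rates as exact expectations over the uniform
#' control placement, and `expected_lr_same = sensitivity / E(FPR)`.
#'
#' @param family a `family_alignment` (typically from [make_family()]).
#' @param spec a `variant_spec`.
#' @return list of class `planted_variants`: `variants` (pathogenic +
#'   control table), `truth` (one-row data.frame sidecar with realized
#'   sensitivities, expected FPRs, expected LR+ and the share probability
#'   used), `share_prob_used`.
#' @export
plant_variants <- function(family, spec) {
  stopifnot(inherits(family, "family_alignment"),
            inherits(spec, "variant_spec"))
  with_seed(spec$seed, {
    genes <- family$genes
    n_res <- lengths(family$col_of)
    if (any(spec$n_pathogenic + spec$n_control > n_res)) {
      pev_stop("requested %d variants per gene but the shortest gene has %d residues",
               spec$n_pathogenic + spec$n_control, min(n_res))
    }
    share_prob <- spec$share_prob
    if (!is.null(spec$target_lr)) {
      # background-only pre-pass: analytic firing probabilities under the
      # null placement give the baseline rate f0, from which the share
      # probability reaching the target LR+ is solved before any outcome of
      # the final draw is observed
      pre <- plant_variants(family, variant_spec(
        n_pathogenic = spec$n_pathogenic, n_control = spec$n_control,
        share_prob = 0, same_alt_prob = spec$same_alt_prob,
        seed = spec$seed + 104729L))
      f0 <- pre$truth$expected_fpr_same
      share_prob <- if (!is.finite(f0) || f0 <= 0) 1 else
        max(0, min(1, (spec$target_lr * f0 - f0) / (1 - f0)))
    }

    # fully conserved (identical, gap-free) columns are eligible for shared
    # clusters
    identical_cols <- which(apply(family$mat, 2L, function(col) {
      all(col != GAP) && length(unique(col)) == 1L
    }))

    n_shared <- stats::rbinom(length(genes), spec$n_pathogenic, share_prob)
    names(n_shared) <- genes

    # build cross-gene clusters: repeatedly pair the two genes with the
    # largest remaining shared quota at a fresh conserved column
    free_cols <- sample(identical_cols)
    placements <- list()  # per planted variant: gene, position, column, alt
    add <- function(gene, column, alt, stratum) {
      pos <- family$res_of[[gene]][column]
      placements[[length(placements) + 1L]] <<- data.frame(
        gene = gene, position = pos, column = column,
        ref_aa = family$mat[gene, column], alt_aa = alt,
        stratum = stratum, stringsAsFactors = FALSE)
    }
    clusters <- list()  # per cluster: column, alt, genes
    quota <- n_shared
    while (sum(quota > 0L) >= 2L) {
      if (length(free_cols) == 0L) break
      top2 <- names(sort(quota, decreasing = TRUE))[1:2]
      col <- free_cols[1L]
      free_cols <- free_cols[-1L]
      ref <- family$mat[top2[1L], col]
      alt <- sample(setdiff(AA20, ref), 1L)
      for (g in top2) {
        use_alt <- if (stats::runif(1) < spec$same_alt_prob) alt else
          sample(setdiff(AA20, c(ref, alt)), 1L)
        add(g, col, use_alt, "shared")
        quota[g] <- quota[g] - 1L
      }
      clusters[[length(clusters) + 1L]] <- list(column = col, alt = alt,
                                                genes = top2)
    }
    # leftover quota of a single gene attaches to existing clusters of other
    # genes; with none available it is demoted to background placement
    for (g in names(quota)[quota > 0L]) {
      while (quota[g] > 0L) {
        open <- Filter(function(cl) !(g %in% cl$genes), clusters)
        if (length(open) == 0L) break
        cl <- open[[sample.int(length(open), 1L)]]
        ref <- family$mat[g, cl$column]
        use_alt <- if (stats::runif(1) < spec$same_alt_prob) cl$alt else
          sample(setdiff(AA20, c(ref, cl$alt)), 1L)
        add(g, cl$column, use_alt, "shared")
        for (i in seq_along(clusters)) {
          if (clusters[[i]]$column == cl$column) {
            clusters[[i]]$genes <- c(clusters[[i]]$genes, g)
          }
        }
        quota[g] <- quota[g] - 1L
      }
    }

    planted <- if (length(placements)) do.call(rbind, placements) else NULL
    # background pathogenic: uniform over residues not already used by the
    # same gene
    for (g in genes) {
      used <- if (is.null(planted)) integer(0) else
        planted$position[planted$gene == g]
      n_bg <- spec$n_pathogenic - length(used)
      if (n_bg > 0L) {
        pos <- sample(setdiff(seq_len(n_res[[g]]), used), n_bg)
        for (p in pos) {
          col <- family$col_of[[g]][p]
          ref <- family$mat[g, col]
          add(g, col, sample(setdiff(AA20, ref), 1L), "background")
        }
      }
    }
    planted <- do.call(rbind, placements)
    pathogenic <- protein_variants(
      gene = planted$gene, position = planted$position,
      ref_aa = planted$ref_aa, alt_aa = planted$alt_aa,
      label = "pathogenic", source = planted$stratum, collapse = FALSE)

    # controls: uniform over residues without a same-gene pathogenic variant
    ctrl <- list()
    patho_res <- split(planted$position, planted$gene)
    for (g in genes) {
      elig <- setdiff(seq_len(n_res[[g]]), patho_res[[g]] %||% integer(0))
      if (length(elig) < spec$n_control) {
        pev_stop("gene %s has too few free residues for %d controls",
                 g, spec$n_control)
      }
      pos <- sample(elig, spec$n_control)
      col <- family$col_of[[g]][pos]
      ref <- family$mat[g, col]
      alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L), "")
      ctrl[[g]] <- data.frame(gene = g, position = pos, ref_aa = ref,
                              alt_aa = unname(alt), stringsAsFactors = FALSE)
    }
    ctrl <- do.call(rbind, ctrl)
    controls <- protein_variants(gene = ctrl$gene, position = ctrl$position,
                                 ref_aa = ctrl$ref_aa, alt_aa = ctrl$alt_aa,
                                 label = "control", source = "control",
                                 collapse = FALSE)

    truth <- planted_truth(family, planted, patho_res, spec, share_prob)
    structure(list(variants = rbind(pathogenic, controls),
                   truth = truth,
                   share_prob_used = share_prob),
              class = "planted_variants")
  })
}

# Ground truth sidecar, independent of the annotation code path:
# sensitivities by brute-force enumeration over realized pathogenic
# placements, false-positive rates as exact expectations over the uniform
# control placement.
planted_truth <- function(family, planted, patho_res, spec, share_prob) {
  n <- nrow(planted)
  has_same <- logical(n)
  has_any <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (planted$gene[j] != planted$gene[i] &&
          planted$column[j] == planted$column[i] &&
          planted$ref_aa[j] == planted$ref_aa[i]) {
        has_any[i] <- TRUE
        if (planted$alt_aa[j] == planted$alt_aa[i]) has_same[i] <- TRUE
      }
    }
  }
  sens_same <- mean(has_same)
  sens_any <- mean(has_any)

  probs <- uniform_hit_probs(family, planted, exclude = patho_res)
  # every gene contributes the same number of controls: plain mean
  fpr_same <- mean(probs["same", ])
  fpr_any <- mean(probs["any", ])
  data.frame(
    n_pathogenic = n,
    n_control = spec$n_control * length(family$genes),
    share_prob_used = share_prob,
    sens_same = sens_same,
    sens_any = sens_any,
    expected_fpr_same = fpr_same,
    expected_fpr_any = fpr_any,
    expected_lr_same = if (fpr_same > 0) sens_same / fpr_same else NA_real_,
    expected_lr_any = if (fpr_any > 0) sens_any / fpr_any else NA_real_)
}

#' Ideal alpha-helix toy structure
#'
#' Calpha trace of an ideal alpha helix: radius 2.3 A, rise 1.5 A per
#' residue, 100 degrees rotation per residue, giving consecutive
#' Calpha-Calpha distances of about 3.8 A.
#'
#' @param n_residues number of residues (>= 2).
#' @param chain_id chain identifier.
#' @return a `structure_model`.
#' @export
make_helix_structure <- function(n_residues, chain_id = "A") {
  stopifnot(n_residues >= 2L)
  i <- seq_len(n_residues)
  theta <- (i - 1) * 100 * pi / 180
  coords <- cbind(x = 2.3 * cos(theta),
                  y = 2.3 * sin(theta),
                  z = 1.5 * (i - 1))
  rownames(coords) <- i
  structure_model(coords, chain_id = chain_id)
}

#' Generate a phenotype cohort clustered in spatial hotspots
#'
#' For each phenotype, distinct variant positions are drawn from its hotspot
#' residue set (given in reference-gene coordinates) with probability
#' `1 - leakage`, and from the whole mappable background otherwise; each
#' variant carries `1 + Poisson(patient_rate)` patients. Positions are
#' translated to the phenotype's gene through the family alignment; columns
#' that are gapped in either gene are never drawn.
#'
#' @param family a `family_alignment`.
#' @param structure reference `structure_model`.
#' @param reference_gene gene whose chain `structure` represents.
#' @param hotspots named list: phenotype -> list(gene = symbol,
#'   residues = integer vector of reference residues).
#' @param n_variants distinct variants per phenotype (default 40, the
#'   conventional minimum cohort size for the cross-validated analysis).
#' @param leakage background leakage probability (default 0.1).
#' @param patient_rate Poisson rate of extra patients per variant
#'   (default 1).
#' @param seed integer seed.
#' @return a pathogenic variant table with phenotype and `n_patients`.
#' @export
make_phenotype_cohort <- function(family, structure, reference_gene,
                                  hotspots, n_variants = 40L, leakage = 0.1,
                                  patient_rate = 1, seed = 1L) {
  stopifnot(inherits(family, "family_alignment"),
            inherits(structure, "structure_model"),
            leakage >= 0, leakage <= 1)
  check_gene(family, reference_gene)
  with_seed(seed, {
    ref_cols <- family$col_of[[reference_gene]]
    out <- list()
    for (ph in names(hotspots)) {
      hs <- hotspots[[ph]]
      check_gene(family, hs$gene)
      # reference residues that exist in the structure and map to a non-gap
      # residue of the phenotype's gene
      mappable <- which(seq_along(ref_cols) %in% structure$residues &
                          !is.na(family$res_of[[hs$gene]][ref_cols]))
      hot <- intersect(as.integer(hs$residues), mappable)
      if (length(hot) == 0L) {
        pev_stop("hotspot of phenotype '%s' has no mappable residues", ph)
      }
      if (n_variants > length(mappable)) {
        pev_stop("phenotype '%s': %d variants requested but only %d mappable residues",
                 ph, n_variants, length(mappable))
      }
      picked <- integer(0)
      while (length(picked) < n_variants) {
        pool <- if (stats::runif(1) < leakage) mappable else hot
        pool <- setdiff(pool, picked)
        if (length(pool) == 0L) pool <- setdiff(mappable, picked)
        picked <- c(picked, pool[sample.int(length(pool), 1L)])
      }
      gene_pos <- family$res_of[[hs$gene]][ref_cols[picked]]
      ref <- unname(family$mat[hs$gene, ref_cols[picked]])
      alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L), "")
      out[[ph]] <- data.frame(
        gene = hs$gene, position = gene_pos, ref_aa = ref,
        alt_aa = unname(alt), label = "pathogenic", phenotype = ph,
        n_patients = 1L + stats::rpois(n_variants, patient_rate),
        source = "cohort", stringsAsFactors = FALSE)
    }
    validate_variants(do.call(rbind, out), collapse = FALSE)
  })
}

#' Canonical two-hotspot phenotype world
#'
#' Builds the package's reference synthetic cohort scenario in one call: a
#' gene family, an ideal-helix reference structure on gene `G1`, a phenotype
#' cohort in which the focal phenotype (gene `G1`) and a `correlated`
#' phenotype (gene `G2`) draw their variants from the same spatial window of
#' the reference chain while a `distal` phenotype (gene `G3`, or `G2` for
#' two-gene families) occupies a disjoint window, plus uniform family-wide
#' controls. The windows span a quarter of the chain each, so the default 40
#' distinct variant positions per phenotype fit inside their hotspot.
#'
#' @param seed integer seed; sub-seeds for family, cohort and controls are
#'   derived from it.
#' @param n_genes,length family dimensions (defaults 3 genes x 200
#'   residues).
#' @param n_variants distinct variants per phenotype (default 40).
#' @param leakage background leakage (default 0.1).
#' @param identity_target mean pairwise identity (default 0.9).
#' @param n_controls controls per gene (default 40).
#' @return list with `family`, `structure`, `cohort`, `controls`,
#'   `hotspots`, `reference_gene`.
#' @export
make_cohort_world <- function(seed, n_genes = 3L, length = 200L,
                              n_variants = 40L, leakage = 0.1,
                              identity_target = 0.9, n_controls = 40L) {
  fam <- make_family(family_spec(n_genes = n_genes, length = length,
                                 identity_target = identity_target,
                                 seed = seed))
  helix <- make_helix_structure(length)
  quarter <- floor(length / 4)
  hot_a <- seq(11L, 10L + quarter)
  hot_b <- seq(length - 9L - quarter, length - 10L)
  hotspots <- list(
    focal = list(gene = "G1", residues = hot_a),
    correlated = list(gene = "G2", residues = hot_a),
    distal = list(gene = if (n_genes >= 3L) "G3" else "G2",
                  residues = hot_b))
  cohort <- make_phenotype_cohort(fam, helix, "G1", hotspots,
                                  n_variants = n_variants, leakage = leakage,
                                  seed = seed + 1L)
  controls <- make_uniform_controls(fam, n_controls, avoid = cohort,
                                    seed = seed + 2L)
  list(family = fam, structure = helix, cohort = cohort,
       controls = controls, hotspots = hotspots, reference_gene = "G1")
}

#' Uniform control variants over a family
#'
#' Places `n_per_gene` control variants per gene uniformly over residues not
#' listed in `avoid` (e.g. an existing pathogenic set, to rule out label
#' conflicts), with uniform alternate amino acids.
#'
#' @param family a `family_alignment`.
#' @param n_per_gene controls per gene.
#' @param avoid optional variant table whose same-gene residues are excluded.
#' @param seed integer seed.
#' @param genes subset of family genes to cover (default all).
#' @return a control variant table.
#' @export
make_uniform_controls <- function(family, n_per_gene, avoid = NULL,
                                  seed = 1L, genes = family$genes) {
  with_seed(seed, {
    out <- list()
    for (g in genes) {
      check_gene(family, g)
      elig <- seq_along(family$col_of[[g]])
      if (!is.null(avoid)) elig <- setdiff(elig, avoid$position[avoid$gene == g])
      if (length(elig) < n_per_gene) {
        pev_stop("gene %s has only %d free residues for %d controls",
                 g, length(elig), n_per_gene)
      }
      pos <- sample(elig, n_per_gene)
      col <- family$col_of[[g]][pos]
      ref <- unname(family$mat[g, col])
      alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L), "")
      out[[g]] <- data.frame(gene = g, position = pos, ref_aa = ref,
                             alt_aa = unname(alt), label = "control",
                             source = "control", stringsAsFactors = FALSE)
    }
    validate_variants(do.call(rbind, out), collapse = FALSE)
  })
}
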