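# 3D phenotype correlation: project family variants onto one reference
# chain, build Calpha proximity neighborhoods, tally patients per residue
# per phenotype, and correlate the phenotype-specific distributions with
# Kendall's tau-b.

#' Project family variants onto a reference gene
#'
#' Translates each variant's position to the corresponding residue of the
#' reference gene through the family alignment (same column). Variants whose
#' column is a gap in the reference are flagged `unmapped` and reported, not
#' dropped silently.
#'
#' @param alignment a `family_alignment`.
#' @param reference_gene gene symbol of the reference chain (alignment
#'   member).
#' @param variants variant table (any label; phenotype and patient counts
#'   are carried through).
#' @return the variant table with added columns `column`, `ref_residue`
#'   (NA when unmapped) and `unmapped`; attribute `unmapped` holds the
#'   unmapped subset.
#' @export
project_to_reference <- function(alignment, reference_gene, variants) {
  check_gene(alignment, reference_gene)
  vmap <- map_variants_to_columns(variants, alignment, what = "variant")
  v <- vmap$mapped
  v$ref_residue <- alignment$res_of[[reference_gene]][v$column]
  v$unmapped <- is.na(v$ref_residue)
  attr(v, "unmapped") <- v[v$unmapped, , drop = FALSE]
  attr(v, "quarantined") <- vmap$quarantined
  v
}

#' Build a Calpha proximity neighbor graph
#'
#' Computes all pairwise Euclidean distances between Calpha atoms and links
#' residues at distance `<= threshold` (inclusive). Every residue is its own
#' neighbor.
#'
#' @param structure a `structure_model`.
#' @param threshold distance threshold in Angstrom (default 12, a common
#'   contact-neighborhood radius; the value is recorded on the result and
#'   should be swept when it matters).
#' @return object of class `neighbor_graph`: list with `threshold`,
#'   `residues` and `neighbors` (named list residue -> integer vector of
#'   neighbor residues, self included).
#' @export
build_neighbor_graph <- function(structure, threshold = 12) {
  stopifnot(inherits(structure, "structure_model"), threshold > 0)
  d <- as.matrix(stats::dist(structure$coords))
  adj <- d <= threshold
  res <- structure$residues
  neighbors <- lapply(seq_along(res), function(i) res[adj[i, ]])
  names(neighbors) <- res
  structure(list(threshold = threshold,
                 residues = res,
                 neighbors = neighbors),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("Neighbor graph: %d residues, threshold %g A, mean degree %.1f\n",
              length(x$residues), x$threshold, mean(deg)))
  invisible(x)
}

#' Phenotype-specific 3D patient tallies
#'
#' For each phenotype with variants at `min_positions` or more distinct
#' projected positions, tallies for every structure residue the number of
#' patients carrying a variant at the residue itself or any of its spatial
#' neighbors. Phenotypes below the position threshold are excluded and
#' reported.
#'
#' @param projected variants projected onto the reference gene
#'   (see [project_to_reference()]); unmapped rows are ignored.
#' @param graph a `neighbor_graph` on the reference structure.
#' @param min_positions minimum number of distinct projected positions for a
#'   phenotype to be considered (default 6, i.e. more than five).
#' @return object of class `phenotype_profiles`: list with `tally` (matrix,
#'   structure residues x phenotypes), `threshold`, `n_positions` (named
#'   vector) and `excluded` (character vector of excluded phenotypes).
#' @export
phenotype_profiles <- function(projected, graph, min_positions = 6L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  v <- projected[!is.na(projected$ref_residue), , drop = FALSE]
  v <- v[!is.na(v$phenotype), , drop = FALSE]
  v <- v[v$ref_residue %in% graph$residues, , drop = FALSE]
  n_pos <- tapply(v$ref_residue, v$phenotype,
                  function(p) length(unique(p)))
  keep <- names(n_pos)[n_pos >= min_positions]
  excluded <- setdiff(names(n_pos), keep)
  res <- graph$residues
  tally <- matrix(0L, nrow = length(res), ncol = length(keep),
                  dimnames = list(res, sort(keep)))
  for (ph in colnames(tally)) {
    sub <- v[v$phenotype == ph, , drop = FALSE]
    counts <- numeric(length(res))
    names(counts) <- res
    # a variant at residue r contributes its patients to every residue whose
    # neighborhood contains r; by symmetry these are exactly N(r)
    for (i in seq_len(nrow(sub))) {
      nb <- graph$neighbors[[as.character(sub$ref_residue[i])]]
      counts[as.character(nb)] <- counts[as.character(nb)] + sub$n_patients[i]
    }
    tally[, ph] <- as.integer(counts)
  }
  structure(list(tally = tally,
                 threshold = graph$threshold,
                 n_positions = n_pos[colnames(tally)],
                 excluded = excluded),
            class = "phenotype_profiles")
}

# ---- Kendall tau-b ---------------------------------------------------------

# Kendall S statistic (sum over pairs of sign products); x, y numeric
kendall_S <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  sum(dx * dy * upper.tri(dx))
}

#' Kendall tau-b with a two-sided p-value
#'
#' Tie-corrected Kendall rank correlation. The p-value uses exact
#' enumeration over all permutations of `y` for `n <= exact_max` and
#' otherwise the tie-corrected normal approximation of the S statistic.
#' Returns `tau = NA` when either vector is constant.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_max largest n for which the permutation-exact p-value is
#'   computed (default 8).
#' @return list with `tau`, `p_value`, `S`, `method`.
#' @export
kendall_tau <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) return(list(tau = NA_real_, p_value = NA_real_,
                          S = NA_real_, method = "undefined"))
  tx <- table(x)
  ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  if (n1 == n0 || n2 == n0) {
    return(list(tau = NA_real_, p_value = NA_real_, S = NA_real_,
                method = "constant"))
  }
  S <- kendall_S(x, y)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  if (n <= exact_max) {
    perms <- permutations_of(n)
    s_obs <- abs(S)
    hits <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(kendall_S(x, y[perms[i, ]])) >= s_obs - 1e-9) hits <- hits + 1L
    }
    p <- hits / nrow(perms)
    method <- "exact_permutation"
  } else {
    # tie-corrected variance of S (normal approximation)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_S <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_S)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(tau = tau, p_value = min(1, p), S = S, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n is small by construction
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Correlate phenotype-specific 3D variant distributions
#'
#' Computes Kendall tau-b between all pairs of phenotype tallies over the
#' common residue universe of the structure, with two-sided p-values,
#' Bonferroni adjustment over the unordered pairs tested, and significance
#' calls at adjusted p < `alpha`. Constant tally vectors yield undefined
#' correlations; such cells are flagged and excluded from significance
#' calls.
#'
#' @param profiles a `phenotype_profiles` object (or a numeric matrix
#'   residues x phenotypes).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return object of class `phenotype_correlation`: list with `phenotypes`,
#'   `tau`, `p`, `p_adj`, `sig_positive`, `sig_negative` (matrices),
#'   `n_tests`, `alpha`, `threshold`, `undefined`.
#' @export
correlate_phenotypes <- function(profiles, alpha = 0.05) {
  tally <- if (inherits(profiles, "phenotype_profiles")) profiles$tally
  else as.matrix(profiles)
  phen <- colnames(tally)
  k <- length(phen)
  if (k < 2L) pev_stop("need at least 2 phenotype profiles to correlate")
  tau <- matrix(NA_real_, k, k, dimnames = list(phen, phen))
  p <- tau
  diag(tau) <- 1
  m <- k * (k - 1) / 2
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      kt <- kendall_tau(tally[, i], tally[, j])
      tau[i, j] <- tau[j, i] <- kt$tau
      p[i, j] <- p[j, i] <- kt$p_value
    }
  }
  p_adj <- pmin(p * m, 1)  # matrix first so dimensions survive pmin
  undefined <- is.na(tau) & row(tau) != col(tau)
  sig_pos <- !is.na(p_adj) & p_adj < alpha & !is.na(tau) & tau > 0
  sig_neg <- !is.na(p_adj) & p_adj < alpha & !is.na(tau) & tau < 0
  diag(sig_pos) <- diag(sig_neg) <- FALSE
  structure(list(phenotypes = phen, tau = tau, p = p, p_adj = p_adj,
                 sig_positive = sig_pos, sig_negative = sig_neg,
                 n_tests = m, alpha = alpha,
                 threshold = if (inherits(profiles, "phenotype_profiles"))
                   profiles$threshold else NA_real_,
                 undefined = undefined),
            class = "phenotype_correlation")
}

#' @export
print.phenotype_correlation <- function(x, digits = 2L, ...) {
  cat(sprintf("Phenotype 3D-correlation matrix: %d phenotypes, %d pairs",
              length(x$phenotypes), x$n_tests))
  if (!is.na(x$threshold)) cat(sprintf(", threshold %g A", x$threshold))
  cat("\n")
  print(round(x$tau, digits))
  np <- sum(x$sig_positive) / 2
  nn <- sum(x$sig_negative) / 2
  cat(sprintf("%d significantly positive and %d significantly negative pair(s) at adjusted p < %g\n",
              np, nn, x$alpha))
  invisible(x)
}

#' Long-format view of a phenotype correlation matrix
#'
#' @param x a `phenotype_correlation`.
#' @return `data.frame` with one row per unordered phenotype pair:
#'   `pheno_a`, `pheno_b`, `tau`, `p`, `p_adj`, `sig` in
#'   `{positive, negative, ns, undefined}`.
#' @export
correlation_table <- function(x) {
  stopifnot(inherits(x, "phenotype_correlation"))
  k <- length(x$phenotypes)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      sig <- if (x$undefined[i, j]) "undefined"
      else if (x$sig_positive[i, j]) "positive"
      else if (x$sig_negative[i, j]) "negative"
      else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        pheno_a = x$phenotypes[i], pheno_b = x$phenotypes[j],
        tau = x$tau[i, j], p = x$p[i, j], p_adj = x$p_adj[i, j],
        sig = sig, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
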