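# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive everything from first principles (string
# scans, pair loops) instead of reusing the package's coordinate maps.

# residue index -> alignment column by scanning the raw aligned string
oracle_column_of <- function(row, position) {
  cc <- strsplit(row, "")[[1]]
  which(cc != "-")[position]
}

# Brute-force paralogous-hit oracle: tests every reference variant against
# the two written conditions (same alignment column, same reference amino
# acid) plus the cross-gene requirement, straight from the aligned strings.
oracle_hits <- function(target, reference, rows) {
  t_col <- oracle_column_of(rows[[target$gene]], target$position)
  hit <- logical(nrow(reference))
  same <- logical(nrow(reference))
  for (j in seq_len(nrow(reference))) {
    if (reference$gene[j] == target$gene) next
    r_col <- oracle_column_of(rows[[reference$gene[j]]], reference$position[j])
    if (r_col == t_col && reference$ref_aa[j] == target$ref_aa) {
      hit[j] <- TRUE
      same[j] <- reference$alt_aa[j] == target$alt_aa
    }
  }
  list(n = sum(hit), same = any(same & hit), diff = any(hit & !same))
}

# Family-level brute force: annotates every target against every reference
# variant by applying the two written conditions directly to the aligned
# strings (columns recomputed here by string scan, never via the package).
oracle_annotate <- function(rows, targets, reference) {
  t_col <- mapply(function(g, p) oracle_column_of(rows[[g]], p),
                  targets$gene, targets$position)
  r_col <- mapply(function(g, p) oracle_column_of(rows[[g]], p),
                  reference$gene, reference$position)
  n <- nrow(targets)
  out <- data.frame(n_hits = integer(n), para_same = logical(n),
                    para_diff = logical(n))
  for (i in seq_len(n)) {
    hit <- reference$gene != targets$gene[i] &
      r_col == t_col[i] &
      reference$ref_aa == targets$ref_aa[i]
    out$n_hits[i] <- sum(hit)
    out$para_same[i] <- any(hit & reference$alt_aa == targets$alt_aa[i])
    out$para_diff[i] <- any(hit & reference$alt_aa != targets$alt_aa[i])
  }
  out
}

# Brute-force Kendall tau-b: concordant/discordant pair counts with tie
# corrections, all via an explicit double loop.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  if (n1 == n0 || n2 == n0) return(NA_real_)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Random small family with gaps and a biased-to-consensus composition so
# that cross-gene reference matches actually occur; returns aligned rows.
random_rows <- function(n_genes, n_cols) {
  consensus <- sample(paralogLR:::AA20, n_cols, replace = TRUE)
  repeat {
    rows <- vapply(seq_len(n_genes), function(g) {
      cc <- consensus
      u <- runif(n_cols)
      cc[u > 0.60 & u <= 0.85] <-
        sample(paralogLR:::AA20, sum(u > 0.60 & u <= 0.85), replace = TRUE)
      cc[u > 0.85] <- "-"
      paste(cc, collapse = "")
    }, "")
    if (all(nchar(gsub("-", "", rows)) >= 2)) break
  }
  names(rows) <- paste0("G", seq_len(n_genes))
  rows
}

# Random labeled variants consistent with the rows (ref taken from the row);
# substitution keys are kept unique so labels never conflict.
random_variants <- function(rows, n, labels = c("pathogenic", "control")) {
  genes <- names(rows)
  out <- list()
  seen <- character(0)
  tries <- 0
  while (length(out) < n && tries < n * 20) {
    tries <- tries + 1
    g <- sample(genes, 1)
    len <- nchar(gsub("-", "", rows[[g]]))
    pos <- sample.int(len, 1)
    ref <- substr(gsub("-", "", rows[[g]]), pos, pos)
    alt <- sample(setdiff(paralogLR:::AA20, ref), 1)
    key <- paste(g, pos, ref, alt)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- data.frame(
      gene = g, position = pos, ref_aa = ref, alt_aa = alt,
      label = sample(labels, 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# delta-method standard error of log LR+ from pooled cells
se_log_lr <- function(tp, fn, fp, tn) {
  sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
}
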