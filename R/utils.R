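# Internal helpers shared across modules.

# The 20 canonical amino acids, one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators are pure
#' functions of their seed and never disturb the caller's RNG stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting; keeps call out of the message
pev_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

pev_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split an aligned string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# deterministic sort order used by all tabular outputs: gene, position, alt
order_variants <- function(df) {
  df[order(df$gene, df$position, df$alt_aa), , drop = FALSE]
}
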