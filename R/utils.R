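# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Round half away from zero (commercial rounding); base round() rounds half
# to even, which would bias small synthetic counts.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic child seeds derived from one user seed, kept < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# All subsets of a vector with sizes from `sizes`, in deterministic order
# (increasing size, lexicographic within size). Returns list of vectors.
subsets_of <- function(x, sizes) {
  out <- list()
  for (k in sizes) {
    if (k > length(x)) next
    if (k == 0L) {
      out[[length(out) + 1L]] <- x[0]
    } else {
      cmb <- utils::combn(seq_along(x), k)
      for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- x[cmb[, j]]
    }
  }
  out
}

is_superset_of_any <- function(s, sets) {
  for (m in sets) if (all(m %in% s)) return(TRUE)
  FALSE
}
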