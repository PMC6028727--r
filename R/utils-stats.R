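# Fast row-wise medians / MADs for matrices with missing values.
#
# Both use a single radix order() over (row, value) with NAs last, then
# pick the middle element(s) per row from the row-sorted layout. This
# keeps the pooled-MAD assessment of thousands of chain outputs cheap
# without compiled code.

row_medians <- function(m) {
  p <- nrow(m)
  s <- ncol(m)
  if (p == 0L || s == 0L) return(rep(NA_real_, p))
  o <- order(rep(seq_len(p), times = s), m, na.last = TRUE, method = "radix")
  sm <- matrix(m[o], nrow = s)
  n <- s - colSums(is.na(sm))
  lo <- pmax((n + 1L) %/% 2L, 1L)
  hi <- pmax((n + 2L) %/% 2L, 1L)
  base <- (seq_len(p) - 1L) * s
  res <- (sm[base + lo] + sm[base + hi]) / 2
  res[n == 0L] <- NA_real_
  res
}

# Raw (unscaled) row MADs: median of |x - row median|; no 1.4826 factor.
row_mads <- function(m) {
  row_medians(abs(m - row_medians(m)))
}

col_medians <- function(m) row_medians(t(m))

# Observed (non-missing) count per row.
row_n_obs <- function(m) rowSums(!is.na(m))
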