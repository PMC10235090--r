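# Half-open time intervals [begin, end), stored as a two-column matrix.
# The half-open convention means a point exactly at an interval's end is
# outside it; all schedule and overlap computations share it.

.iv <- function(begin, end) {
  stopifnot(length(begin) == length(end))
  if (length(begin) && any(end <= begin)) stop("interval end must exceed begin")
  cbind(begin = as.numeric(begin), end = as.numeric(end))
}

.iv_empty <- function() .iv(numeric(0), numeric(0))

# sort by begin and merge overlapping or touching intervals
.iv_merge <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  b <- iv[1L, 1L]; e <- iv[1L, 2L]
  ob <- numeric(0); oe <- numeric(0)
  for (k in seq_len(nrow(iv))[-1L]) {
    if (iv[k, 1L] <= e) e <- max(e, iv[k, 2L])
    else { ob <- c(ob, b); oe <- c(oe, e); b <- iv[k, 1L]; e <- iv[k, 2L] }
  }
  .iv(c(ob, b), c(oe, e))
}

# clip all intervals to [lo, hi), dropping empties
.iv_clip <- function(iv, lo, hi) {
  if (!nrow(iv)) return(iv)
  b <- pmax(iv[, 1L], lo); e <- pmin(iv[, 2L], hi)
  keep <- e > b
  .iv(b[keep], e[keep])
}

.iv_total <- function(iv) if (nrow(iv)) sum(iv[, 2L] - iv[, 1L]) else 0

# total overlap duration between one interval [b, e) and a merged set
.iv_overlap1 <- function(b, e, iv) {
  if (!nrow(iv)) return(0)
  lo <- pmax(iv[, 1L], b); hi <- pmin(iv[, 2L], e)
  sum(pmax(0, hi - lo))
}

# membership of points in a merged interval set (half-open)
.iv_contains <- function(iv, t) {
  if (!nrow(iv)) return(rep(FALSE, length(t)))
  vapply(t, function(ti) any(ti >= iv[, 1L] & ti < iv[, 2L]), logical(1))
}
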