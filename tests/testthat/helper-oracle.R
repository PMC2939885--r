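# Independent brute-force repeat oracle: per-diagonal two-pointer formulation
# (minimal window start per end position from cumulative mismatch counts),
# distinct from the package's sentinel-window enumeration. Used to verify
# the repeat finder exhaustively on small sequences.

oracle_windows <- function(neq, max_mm, min_len) {
  len <- length(neq)
  if (len < min_len) return(NULL)
  cum <- cumsum(neq)
  mpos <- which(neq)
  # minimal window start l(r) such that [l(r), r] holds <= max_mm mismatches
  l <- ifelse(cum <= max_mm, 1L, mpos[pmax(1L, cum - max_mm)] + 1L)
  # maximal windows: end r where the next end forces a larger start
  keep_r <- c(l[-1] > l[-len], TRUE)
  starts <- l[keep_r]; ends <- which(keep_r)
  # trim terminal mismatches
  mat <- which(!neq)
  if (!length(mat)) return(NULL)
  si <- findInterval(starts - 1L, mat) + 1L
  ei <- findInterval(ends, mat)
  ok <- si <= length(mat) & ei >= 1L & si <= ei
  starts <- mat[si[ok]]; ends <- mat[ei[ok]]
  keep <- (ends - starts + 1L) >= min_len
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(NULL)
  o <- order(starts, -ends)
  starts <- starts[o]; ends <- ends[o]
  drop <- logical(length(starts)); max_end <- -1L
  for (i in seq_along(starts)) {
    if (ends[i] <= max_end) drop[i] <- TRUE else max_end <- ends[i]
  }
  starts <- starts[!drop]; ends <- ends[!drop]
  mm <- vapply(seq_along(starts),
               function(i) sum(neq[starts[i]:ends[i]]), integer(1))
  data.frame(start = starts, end = ends, mm = mm)
}

oracle_repeats <- function(s, min_len, max_mm) {
  ai <- utf8ToInt(s)
  n <- length(ai)
  rows <- list()
  # forward: every positive diagonal
  for (d in seq_len(n - min_len)) {
    neq <- ai[1:(n - d)] != ai[(1 + d):n]
    w <- oracle_windows(neq, max_mm, min_len)
    if (is.null(w)) next
    rows[[length(rows) + 1L]] <-
      data.frame(unit_len = w$end - w$start + 1L, start1 = w$start,
                 start2 = w$start + d, type = "F", mismatches = w$mm)
  }
  # inverted: every diagonal of s against its reverse complement
  ti <- utf8ToInt(plastidkit::revcomp(s))
  for (d in seq(-(n - min_len), n - min_len)) {
    i1 <- max(1L, 1L - d); i2 <- min(n, n - d)
    if (i2 - i1 + 1L < min_len) next
    neq <- ai[i1:i2] != ti[(i1 + d):(i2 + d)]
    w <- oracle_windows(neq, max_mm, min_len)
    if (is.null(w)) next
    ia <- w$start + i1 - 1L
    ib <- w$start + i1 - 1L + d
    len <- w$end - w$start + 1L
    s2 <- n - (ib + len - 1L) + 1L
    a <- pmin(ia, s2); b <- pmax(ia, s2)
    keep <- b >= a + len
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(unit_len = len[keep], start1 = a[keep], start2 = b[keep],
                 type = "I", mismatches = w$mm[keep])
  }
  if (!length(rows))
    return(data.frame(unit_len = integer(0), start1 = integer(0),
                      start2 = integer(0), type = character(0),
                      mismatches = integer(0)))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$type, out$start1, out$start2), ]
  rownames(out) <- NULL
  out
}

# random DNA convenience for tests (AT-rich like a plastid genome)
rand_dna <- function(n, at = 0.63) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
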