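# Interval algebra on two-column matrices of half-open [start, end)
# intervals in bp. Coordinates are continuous (fork positions are fractional
# bp), which is why these helpers operate on plain numeric matrices.

## sort by start and merge overlapping/abutting intervals
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(), ncol = 2))
  m <- m[m[, 1] < m[, 2], , drop = FALSE]
  if (nrow(m) == 0) return(matrix(numeric(), ncol = 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  s <- m[, 1]; e <- m[, 2]
  out_s <- s[1]; out_e <- e[1]; k <- 1L
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L
      out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  cbind(out_s, out_e, deparse.level = 0)
}

## set difference a \ b, both merged interval matrices
diff_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(a)
  out <- matrix(numeric(), ncol = 2)
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    ov <- b[b[, 2] > s & b[, 1] < e, , drop = FALSE]
    cur <- s
    for (j in seq_len(nrow(ov))) {
      if (ov[j, 1] > cur) out <- rbind(out, c(cur, ov[j, 1]))
      cur <- max(cur, ov[j, 2])
    }
    if (cur < e) out <- rbind(out, c(cur, e))
  }
  out
}

## total length of merged intervals
total_length <- function(m) if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])

## add, into per-bin coverage vector `cov` (bp units), the overlap of each
## interval with each bin of width `bin`; bins beyond n are clipped away
add_interval_coverage <- function(cov, m, bin) {
  n <- length(cov)
  for (i in seq_len(nrow(m))) {
    s <- max(m[i, 1], 0); e <- min(m[i, 2], n * bin)
    if (e <= s) next
    i0 <- floor(s / bin) + 1L
    i1 <- ceiling(e / bin)
    idx <- i0:i1
    lo <- pmax(s, (idx - 1L) * bin)
    hi <- pmin(e, idx * bin)
    cov[idx] <- cov[idx] + (hi - lo)
  }
  cov
}
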