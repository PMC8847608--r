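# Independent brute-force oracles shared by unit and acceptance tests.
# These deliberately re-derive each rule from its definition with plain
# scans, separate from the run-table machinery inside the package.

oracle_runs <- function(v) {
  r <- rle(v)
  data.frame(cls = r$values, len = r$lengths,
             end = cumsum(r$lengths), start = cumsum(r$lengths) - r$lengths)
}

oracle_sporadic <- function(v, maxlen = 4L) {
  r <- oracle_runs(v)
  for (i in seq_len(nrow(r))) {
    if (r$cls[i] == 0L || r$len[i] > maxlen) next
    l0 <- i == 1L || r$cls[i - 1L] == 0L
    r0 <- i == nrow(r) || r$cls[i + 1L] == 0L
    if (l0 && r0) v[(r$start[i] + 1L):r$end[i]] <- 0L
  }
  v
}

no_sporadic <- function(v, maxlen = 4L) identical(v, oracle_sporadic(v, maxlen))

no_interruption <- function(v, maxgap = 6L) {
  r <- oracle_runs(v)
  for (i in seq_len(nrow(r)))
    if (r$cls[i] == 0L && r$len[i] <= maxgap && i > 1L && i < nrow(r) &&
        r$cls[i - 1L] != 0L && r$cls[i + 1L] != 0L) return(FALSE)
  TRUE
}

no_transition <- function(v, maxlen = 4L) {
  r <- oracle_runs(v)
  for (i in seq_len(nrow(r))) {
    if (r$cls[i] == 0L || r$len[i] > maxlen) next
    if (i == 1L || i == nrow(r)) next # boundary-truncated: exempt
    other <- 3L - r$cls[i]
    if (r$cls[i - 1L] == other || r$cls[i + 1L] == other) return(FALSE)
  }
  TRUE
}
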