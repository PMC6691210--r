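# Independent per-cohort forward simulation: given daily entries and a
# constant stream-life L, track each cohort explicitly and sum survivors.
# This is deliberately naive bookkeeping, independent of the accounting
# recursion it cross-checks.
cohort_live_oracle <- function(entries, L) {
  n <- length(entries)
  live <- numeric(n + L)
  for (d in seq_len(n)) {
    if (entries[d] == 0) next
    for (t in d:(d + L - 1L)) live[t] <- live[t] + entries[d]
  }
  live
}

# small helper: empirical mean day of a daily_series
series_mean_day <- function(x) {
  v <- as.numeric(x)
  sum(days(x) * v) / sum(v)
}
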