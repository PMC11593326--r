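# Small in-code fixtures and brute-force oracles shared across test files.

# A count series with given vertical counts and zero horizontal axes
# (so vm == vertical).
make_series <- function(vertical, epoch_len_s = 5,
                        start = as.POSIXct("2024-01-01", tz = "UTC"),
                        child_id = "t") {
  z <- integer(length(vertical))
  count_series(child_id, start, epoch_len_s, vertical, z, z)
}

# Random vertical-only series: bursts of zero runs and active counts.
random_series <- function(n_epochs, epoch_len_s = 5, max_count = 400,
                          zero_prob = 0.5) {
  v <- integer(0)
  while (length(v) < n_epochs) {
    len <- sample(1:400, 1)
    v <- c(v, if (runif(1) < zero_prob) integer(len)
           else sample(0:max_count, len, replace = TRUE))
  }
  make_series(v[seq_len(n_epochs)], epoch_len_s)
}

# Brute-force non-wear oracle: scan every epoch's zero run within its
# calendar day and mark epochs belonging to a long-enough run.
bf_nonwear_mask <- function(series, min_zero_run_minutes = 20) {
  thr <- ceiling(min_zero_run_minutes * 60 / series$epoch_len_s)
  zero <- series$counts[, 1L] == 0L
  dates <- epoch_dates(series)
  nonworn <- logical(length(zero))
  for (idx in split(seq_along(zero), dates)) {
    i <- 1L
    while (i <= length(idx)) {
      if (zero[idx[i]]) {
        j <- i
        while (j < length(idx) && zero[idx[j + 1L]]) j <- j + 1L
        if (j - i + 1L >= thr) nonworn[idx[i:j]] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  nonworn
}

# Hand-rolled per-epoch classification oracle on the cpm scale.
bf_classify <- function(counts, set, epoch_len_s) {
  cpm <- counts * 60 / epoch_len_s
  ifelse(cpm < set$sb_upper_cpm, "sedentary",
         ifelse(cpm >= set$mvpa_lower_cpm, "mvpa", "light"))
}

# Write a tiny epoch CSV from vectors; returns the path.
write_epoch_fixture <- function(path, timestamps, a1, a2 = 0 * a1,
                                a3 = 0 * a1) {
  writeLines(c("timestamp,axis1,axis2,axis3",
               sprintf("%s,%d,%d,%d", timestamps, a1, a2, a3)), path)
  path
}

iso <- function(t0, stride_s, n)
  format(as.POSIXct(t0, tz = "UTC") + (seq_len(n) - 1) * stride_s,
         "%Y-%m-%dT%H:%M:%S")
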