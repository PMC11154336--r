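# Independent brute-force transfer entropy (l = k = 1): literal evaluation of
# the triple sum over all (x_t, x_{t-1}, y_{t-1}) cells with plug-in
# probabilities. Deliberately naive and separate from the package's
# entropy-difference path.
te_oracle <- function(src, tgt) {
  n <- length(tgt)
  N <- n - 1
  tot <- 0
  for (a in sort(unique(tgt))) for (b in sort(unique(tgt))) for (cc in sort(unique(src))) {
    pabc <- sum(tgt[2:n] == a & tgt[1:N] == b & src[1:N] == cc) / N
    if (pabc == 0) next
    pbc <- sum(tgt[1:N] == b & src[1:N] == cc) / N
    pb  <- sum(tgt[1:N] == b) / N
    pab <- sum(tgt[2:n] == a & tgt[1:N] == b) / N
    tot <- tot + pabc * log2((pabc / pbc) / (pab / pb))
  }
  tot
}

# Independent conditional entropy H(now | past) from raw transition counts.
cond_entropy_oracle <- function(series) {
  n <- length(series)
  tab <- table(past = series[1:(n - 1)], now = series[2:n])
  p <- tab / sum(tab)
  h_joint <- -sum(p[p > 0] * log2(p[p > 0]))
  pm <- rowSums(p)
  h_past <- -sum(pm[pm > 0] * log2(pm[pm > 0]))
  h_joint - h_past
}

# A small well-formed trial file for IO tests; returns its path.
write_demo_trial <- function(path, n = 270, with_speed = TRUE, seed = 42,
                             na_rows = integer(0)) {
  set.seed(seed)
  ts <- (seq_len(n) - 1) / 90
  df <- data.frame(
    time_s = ts,
    eye_yaw_deg = round(10 * sin(ts) + rnorm(n, sd = 0.5), 6),
    eye_pitch_deg = round(3 * cos(ts) + rnorm(n, sd = 0.3), 6),
    head_yaw_deg = round(8 * sin(ts - 0.1) + rnorm(n, sd = 0.4), 6),
    head_pitch_deg = round(2 * cos(ts - 0.1) + rnorm(n, sd = 0.2), 6)
  )
  if (with_speed) df$speed_kmh <- round(40 + rnorm(n, sd = 1), 6)
  df_chr <- as.data.frame(lapply(df, as.character))
  if (length(na_rows)) df_chr$eye_yaw_deg[na_rows] <- "NA"
  write.table(df_chr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_symbols <- function(n, B) symbol_series(sample(0:(B - 1), n, replace = TRUE), B)
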