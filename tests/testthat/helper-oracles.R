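# Independent brute-force oracles used to freeze and cross-check expected
# values. These deliberately avoid the code paths they validate.

# Upper-tail binomial probability by direct term-by-term summation in
# log space.
oracle_binom_tail <- function(K, n, p) {
  if (K <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- K:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Unique subsequence count (lengths 2-4) by explicit window enumeration.
oracle_unique_count <- function(sample) {
  m <- length(sample)
  total <- 0L
  for (L in 2:4) {
    seen <- character(0)
    for (i in 1:(m - L + 1)) {
      seen <- c(seen, paste(sample[i:(i + L - 1)], collapse = "|"))
    }
    total <- total + length(unique(seen))
  }
  total
}

# Greedy maximal-window fixation enumeration with full dispersion
# recomputation at every candidate window (quadratic, small inputs only).
oracle_fixation_onsets <- function(raw, disp, mindur) {
  n <- nrow(raw)
  onsets <- numeric(0)
  i <- 1
  while (i <= n) {
    j_max <- i
    for (j in i:n) {
      d <- (max(raw$x[i:j]) - min(raw$x[i:j])) +
        (max(raw$y[i:j]) - min(raw$y[i:j]))
      if (d > disp) break
      j_max <- j
    }
    if (raw$t_ms[j_max] - raw$t_ms[i] >= mindur) {
      onsets <- c(onsets, raw$t_ms[i])
      i <- j_max + 1
    } else {
      i <- i + 1
    }
  }
  onsets
}

# Textbook one-way ANOVA F from between/within sums of squares.
oracle_oneway_F <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ss_b <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(g) - 1
  df_w <- length(x) - nlevels(g)
  list(F = (ss_b / df_b) / (ss_w / df_w), df_b = df_b, df_w = df_w,
       eta_p = ss_b / (ss_b + ss_w))
}

# Build a minimal single-game annotated tibble from parallel vectors.
make_game <- function(types, latencies, in_chunk = NULL, first = NULL) {
  n <- length(types)
  tibble::tibble(
    game_id = "g1",
    t_ms = cumsum(ifelse(is.na(latencies), 0, latencies)),
    action_type = types,
    latency_ms = latencies,
    in_chunk = if (is.null(in_chunk)) rep(FALSE, n) else in_chunk,
    is_first_action = if (is.null(first)) rep(FALSE, n) else first
  )
}
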