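# Independent brute-force oracles used to cross-check package operations.
# These deliberately use naive algorithms, not the implementation paths.

# naive scan run-length encoder
naive_rle <- function(states) {
  out <- data.frame(state = integer(0), start = integer(0),
                    length = integer(0))
  i <- 1L
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1L] == states[i]) j <- j + 1L
    out <- rbind(out, data.frame(state = states[i], start = i - 1L,
                                 length = j - i + 1L))
    i <- j + 1L
  }
  out
}

# double-loop transition counter over 4-state factor sequences
brute_transition_counts <- function(seqs) {
  counts <- matrix(0L, 4L, 4L,
                   dimnames = list(from = DYAD_STATES, to = DYAD_STATES))
  for (s in seqs) {
    st <- as.integer(s$states)
    if (length(st) < 2L) next
    for (t in 2:length(st)) {
      counts[st[t - 1L], st[t]] <- counts[st[t - 1L], st[t]] + 1L
    }
  }
  counts
}

# covariance-over-sigmas Pearson correlation
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# closed-form 2x2 Pearson chi-square: N (ad - bc)^2 / (r1 r2 c1 c2)
brute_chi2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact two-sided rank-sum p by enumerating all group assignments
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# random dyad-night fixtures
random_night <- function(T_, p_h = 0.2, p_d = 0.3, dyad = "dyadA",
                         night = "night1") {
  dyad_night(stats::rbinom(T_, 1, p_h), stats::rbinom(T_, 1, p_d),
             dyad_id = dyad, night_id = night)
}

# reference four-state transition-probability rows (from-state order
# Both, HumanOnly, DogOnly, Neither) used for the in-table arithmetic
# checks, with their per-row observation counts
reference_transition_table <- function() {
  probs <- rbind(
    c(0.399, 0.090, 0.247, 0.262),
    c(0.086, 0.239, 0.043, 0.631),
    c(0.053, 0.021, 0.457, 0.467),
    c(0.006, 0.015, 0.057, 0.921)
  )
  as_transition_table(probs = probs, row_n = c(1198, 1226, 5512, 46473))
}

# tiny epoch CSV written from explicit rows
write_epoch_fixture <- function(path, dyad = "d1", night = "n1",
                                subject = "H01", species = "human",
                                idx = 0:2, activity = c(0, 120, 50)) {
  df <- data.frame(dyad_id = dyad, night_id = night, subject_id = subject,
                   species = species, epoch_index = idx,
                   activity = activity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

small_params <- function(...) {
  sim_params(n_dyads = 2L, nights_per_dyad = 3L, epochs_per_night = 120L,
             ...)
}
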