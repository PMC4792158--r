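# Independent oracles and shared fixtures, built in code.

# The eight-location worked cycle and its hand-computed statistics.
worked_cycle <- "ababcdcd"
worked_counts <- c(ab = 2L, ba = 1L, bc = 1L, cd = 2L, da = 1L, dc = 1L)
worked_jp <- c(ab = 2, ba = 1, bc = 1, cd = 2, da = 1, dc = 1) / 8
worked_cp <- c(ab = 1, ba = .5, bc = .5, cd = 1, da = .5, dc = .5)
worked_je <- 2.5   # -(2 * 1/4 * log2(1/4) + 4 * 1/8 * log2(1/8))
worked_ce <- 0.5   # -(4 * 1/8 * log2(1/2))

# Naive windowing loop: counts every (n_prev+1)-gram one position at a time.
naive_gram_counts <- function(symbols, n_prev, circular = TRUE) {
  n <- length(symbols)
  grams <- character(0)
  if (circular) {
    for (i in seq_len(n)) {
      idx <- ((i - 1 + 0:n_prev) %% n) + 1
      grams <- c(grams, paste(symbols[idx], collapse = ""))
    }
  } else {
    for (i in seq_len(n - n_prev)) {
      grams <- c(grams, paste(symbols[i + 0:n_prev], collapse = ""))
    }
  }
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))[order(names(tab))]
}

# Entropy of the prefix marginal, aggregated from a joint table: the
# independent route for the chain-rule check.
prefix_entropy <- function(jp, n_prev) {
  pref <- substr(names(jp), 1, n_prev)
  mass <- tapply(jp, pref, sum)
  -sum(mass * log2(mass))
}

random_symbols <- function(n, alphabet) {
  sample(alphabet, n, replace = TRUE)
}

# One flat-tuning multi-session experiment plus its unit table and grid;
# shared by the heavier acceptance checks.
exp2_replicate <- function(family, specs, seed) {
  trials <- simulate_experiment2(n_sessions = nrow(family), family = family,
                                 seed = seed)
  units <- unit_entropy_table(trials, specs, spec_col = "label",
                              unit_col = "session")
  list(trials = trials, units = units)
}
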