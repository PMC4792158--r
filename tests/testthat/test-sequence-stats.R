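test_that("the worked eight-location cycle reproduces its hand statistics", {
  seq <- location_sequence("a-b-a-b-c-d-c-d")
  ts <- build_transition_set(seq, n_prev = 1)
  expect_identical(ts$counts, worked_counts)
  expect_identical(ts$total, 8L)

  jp <- joint_probability(ts)
  cp <- conditional_probability(ts)
  expect_equal(jp, worked_jp)
  expect_equal(cp, worked_cp)
  # p(a|b): the "ba" transition against the mass of prefix "b"
  expect_equal(sum(jp[c("ba", "bc")]), 1 / 4)
  expect_equal(unname(jp[["ba"]] / sum(jp[c("ba", "bc")])), 1 / 2)
  expect_equal(joint_entropy(jp), worked_je)
  expect_equal(conditional_entropy(jp, cp), worked_ce)
})

test_that("degenerate and derived transition sets count correctly", {
  # single-symbol cycle
  aa <- build_transition_set(location_sequence("aaaa"), 1)
  expect_identical(aa$counts, c(aa = 4L))
  expect_equal(joint_probability(aa), c(aa = 1))
  expect_equal(joint_entropy(joint_probability(aa)), 0)

  # long two-symbol alternation at two previous locations
  ab200 <- location_sequence(rep(c("a", "b"), 100))
  ts <- build_transition_set(ab200, 2)
  expect_identical(ts$counts, c(aba = 100L, bab = 100L))

  # non-circular window count
  ts_open <- build_transition_set(location_sequence("ababcdcd"), 1,
                                  circular = FALSE)
  expect_identical(ts_open$total, 7L)
})

test_that("invalid sequences and empty sets are rejected", {
  expect_error(location_sequence("abxe"), "outside the declared alphabet")
  expect_error(build_transition_set(location_sequence("ab"), 2),
               "too short")
  expect_error(joint_entropy(c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(conditional_entropy(c(ab = 1), c(ba = 1)), "same gram set")
})

test_that("transition counting matches a naive windowing oracle exhaustively", {
  alphabet <- c("a", "b", "c")
  for (len in 2:7) {
    combos <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      symbols <- as.character(combos[i, ])
      for (k in seq_len(min(2, len - 1))) {
        ts <- build_transition_set(
          location_sequence(symbols, alphabet = alphabet), k)
        expect_identical(ts$counts, naive_gram_counts(symbols, k),
                         info = paste(paste(symbols, collapse = ""), k))
      }
    }
  }
})

test_that("probabilities normalise and entropies obey the chain rule", {
  withr::local_seed(2024)
  for (rep in 1:100) {
    alphabet <- letters[1:sample(3:4, 1)]
    symbols <- random_symbols(sample(30:100, 1), alphabet)
    k <- sample(1:3, 1)
    pt <- predictor_table(location_sequence(symbols, alphabet = alphabet), k)
    jp <- stats::setNames(pt$jp, pt$gram)
    cp <- stats::setNames(pt$cp, pt$gram)
    expect_equal(sum(jp), 1, tolerance = 1e-12)
    pref <- substr(pt$gram, 1, k)
    expect_true(all(abs(tapply(cp, pref, sum) - 1) < 1e-12))
    # CE = JE - entropy of the prefix marginal
    expect_equal(conditional_entropy(jp, cp),
                 joint_entropy(jp) - prefix_entropy(jp, k),
                 tolerance = 1e-9)
    # JE bounded by log2 of the distinct-gram count, equality iff uniform
    expect_lte(joint_entropy(jp), log2(length(jp)) + 1e-12)
    ce <- conditional_entropy(jp, cp)
    expect_true(ce >= -1e-12 && ce <= joint_entropy(jp) + 1e-12)
  }
  expect_equal(joint_entropy(rep(1 / 12, 12)), log2(12))
})

test_that("identical inputs give bit-identical predictor tables", {
  seq <- location_sequence("abacdbdcabcd")
  expect_identical(predictor_table(seq, 2), predictor_table(seq, 2))
})

test_that("per-trial predictors look up the nominal table with empirical fallback", {
  nominal <- predictor_table(location_sequence(worked_cycle), 1)
  stream <- strsplit("ababcdcd", "")[[1]]
  ptp <- per_trial_predictors(stream, 1, nominal = nominal)
  expect_true(is.na(ptp$jp[1]))          # no history yet
  # trial 3 is the second "a", reached from prefix "b": gram "ba"
  expect_identical(ptp$gram[3], "ba")
  expect_equal(ptp$jp[3], 1 / 8)
  expect_equal(ptp$cp[3], 1 / 2)
  expect_true(all(ptp$source[-1] == "nominal"))

  # deterministic cycle: every complete-history trial has CP 1
  cyc <- predictor_table(location_sequence("abcd"), 1)
  ptp2 <- per_trial_predictors(rep(c("a", "b", "c", "d"), 5), 1,
                               nominal = cyc)
  expect_true(all(ptp2$cp[-1] == 1))

  # grams absent from the nominal table fall back to the realized stream
  ptp3 <- per_trial_predictors(c("a", "b", "a", "c", "a", "b"), 1,
                               nominal = cyc)
  expect_identical(ptp3$source[4], "empirical")
  expect_false(anyNA(ptp3$jp[-1]))
})

test_that("realized per-trial conditional probabilities converge to the generating matrix", {
  P <- matrix(c(0, .9, .05, .05,
                .9, 0, .05, .05,
                .05, .05, 0, .9,
                .05, .05, .9, 0), 4, 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  seq <- gen_probabilistic(P, 50000, seed = 5)
  pt <- predictor_table(seq, 1)
  for (i in seq_len(nrow(pt))) {
    expect_lt(abs(pt$cp[i] -
                    P[substr(pt$gram[i], 1, 1), substr(pt$gram[i], 2, 2)]),
              0.01)
  }
})

test_that("predictor tables round-trip through CSV with a JSON sidecar", {
  pt <- predictor_table(location_sequence(worked_cycle), 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  paths <- write_predictor_table(pt, csv)
  back <- readr::read_csv(paths[["csv"]], show_col_types = FALSE)
  expect_equal(back$jp, pt$jp)
  side <- jsonlite::read_json(paths[["json"]])
  expect_equal(side$je, worked_je)
  expect_equal(side$ce, worked_ce)
  expect_identical(side$n_transitions, 8L)
})
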