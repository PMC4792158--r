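test_that("the sigmoid RT function hits its midpoint, asymptotes and values", {
  p <- sigmoid_params(2, 500, 250, 1)
  expect_equal(sigmoid_rt(2, p, "increasing"), 375)          # midpoint
  expect_equal(sigmoid_rt(-50, p, "increasing"), 250)        # low asymptote
  expect_equal(sigmoid_rt(50, p, "increasing"), 500)
  expect_equal(sigmoid_rt(3, p, "increasing"),
               250 + 250 / (1 + exp(-1)))                    # 432.7646 ms
  # decreasing orientation mirrors around Xhalf
  expect_equal(sigmoid_rt(2 + 0.7, p, "decreasing"),
               sigmoid_rt(2 - 0.7, p, "increasing"))
  expect_error(sigmoid_rt(NaN, p), "finite")
  expect_error(sigmoid_params(300, 500, 0), "Ymax > Ymin > 0")
})

test_that("the learning trajectory interpolates monotonically between its endpoints", {
  st <- sigmoid_params(2, 480, 350, 1)
  en <- sigmoid_params(5, 470, 230, 1)
  expect_equal(learning_trajectory(5, st, en), st)
  expect_equal(learning_trajectory(6, st, en, rate = Inf), en)
  traj <- learning_trajectory(5:22, st, en)
  xh <- vapply(traj, `[[`, 0, "xhalf")
  ym <- vapply(traj, `[[`, 0, "ymin")
  expect_false(is.unsorted(xh))
  expect_false(is.unsorted(rev(ym)))
  mid <- learning_trajectory(13, st, en)
  expect_true(mid$xhalf > st$xhalf && mid$xhalf < en$xhalf)
  expect_true(mid$ymin < st$ymin && mid$ymin > en$ymin)
})

test_that("a simulated session has the exact design shape", {
  tr <- simulate_session(session_design(sequence_presets()$simple_repetitive),
                         seed = 6)
  expect_identical(nrow(tr), 1225L)
  expect_identical(as.integer(table(tr$block)), rep(49L, 25L))
  expect_identical(length(unique(tr$block)), 25L)
  expect_true(all(tr$rt_ms > 0 & tr$rt_ms <= 3000))
  expect_true(all(tr$location %in% letters[1:4]))
})

test_that("with noise off the simulation equals the generating sigmoid", {
  spec <- sequence_presets()$very_simple_repetitive
  p <- sigmoid_params(4, 480, 260, 1)
  tr <- simulate_session(session_design(spec), params_start = p,
                         params_end = p,
                         noise = noise_model(sigma = 0, p_error = 0),
                         predictor = "je", seed = 1)
  je <- attr(nominal_predictor_table(spec, 3), "je")
  trained <- tr$rt_ms[tr$block %in% 5:22]
  expect_equal(trained, rep(sigmoid_rt(je, p, "increasing"), length(trained)),
               tolerance = 1e-9)
  expect_true(all(tr$correct))
})

test_that("simulation is deterministic under a fixed seed", {
  d <- session_design(sequence_presets()$complex_probabilistic)
  expect_identical(simulate_session(d, seed = 99), simulate_session(d, seed = 99))
})

test_that("the six-group experiment has its design shape and RT ordering", {
  tr <- simulate_experiment1(n_per_group = 8, seed = 11)
  expect_identical(nrow(tr), 6L * 8L * 1225L)
  expect_identical(length(unique(tr$subject_id)), 48L)
  med <- median_rt(dplyr::filter(tr, block %in% 15:22),
                   c("group", "subject_id"))
  g <- tapply(med$median_rt, med$group, mean)
  # orderings the six-group design distinguishes: the two probabilistic /
  # repetitive middle pairs are equivalent classes
  expect_lt(g[["very_simple_repetitive"]], g[["simple_repetitive"]])
  expect_lt(g[["simple_repetitive"]],
            min(g[["complex_repetitive"]], g[["simple_probabilistic"]]))
  expect_lt(max(g[["complex_repetitive"]], g[["simple_probabilistic"]]),
            max(g[["complex_probabilistic"]], g[["random"]]))
})

test_that("the multi-session experiment spans its entropy family", {
  fam <- gen_entropy_graded_family(6, je_range = c(2, 6), n_prev = 3)
  tr <- simulate_experiment2(n_sessions = 6, family = fam, seed = 12)
  expect_identical(nrow(tr), 6L * 1225L)
  expect_identical(sort(unique(tr$session)), 1:6)
  expect_identical(sort(unique(tr$family_index)), 1:6)
  expect_identical(attr(tr, "family"), fam)
  # every family sequence is used exactly once
  expect_identical(length(unique(tr$label)), 6L)
})

test_that("a noiseless single-unit run is a deterministic pipeline fixture", {
  tr1 <- simulate_experiment1(n_per_group = 1,
                              noise = noise_model(sigma = 0, p_error = 0),
                              between_sd = 0, seed = 5)
  tr2 <- simulate_experiment1(n_per_group = 1,
                              noise = noise_model(sigma = 0, p_error = 0),
                              between_sd = 0, seed = 5)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$correct))
})
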