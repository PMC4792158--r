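test_that("linear fits recover exact and orthogonal relationships", {
  x <- seq(-3, 3, length.out = 20)
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$params$slope, 2)
  expect_equal(f$params$intercept, 1)
  expect_equal(f$r_squared, 1)

  # zero covariance: flat slope, zero explained variance
  x0 <- c(-1, -1, 1, 1)
  y0 <- c(0, 2, 0, 2)
  f0 <- fit_linear(x0, y0)
  expect_equal(f0$params$slope, 0)
  expect_equal(f0$r_squared, 0)

  expect_error(fit_linear(rep(1, 5), rnorm(5)), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("linear fits agree with the closed-form normal equations", {
  withr::local_seed(31)
  for (rep in 1:20) {
    x <- rnorm(50)
    y <- 1.7 - 0.8 * x + rnorm(50, 0, 0.5)
    f <- fit_linear(x, y)
    X <- cbind(1, x)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(f$params$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$params$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("noisy linear estimates fall within three standard errors", {
  withr::local_seed(7)
  x <- rnorm(1000)
  y <- 3 + 2 * x + rnorm(1000, 0, 1)
  f <- fit_linear(x, y)
  expect_lt(abs(f$params$slope - 2), 3 * f$param_se[["slope"]])
  expect_lt(abs(f$params$intercept - 3), 3 * f$param_se[["intercept"]])
})

test_that("noise-free sigmoid samples are recovered exactly", {
  p <- sigmoid_params(3, 480, 240, 0.8)
  x <- seq(0.5, 6, length.out = 40)
  for (orient in c("increasing", "decreasing")) {
    y <- sigmoid_rt(x, p, orient)
    f <- fit_sigmoid(x, y, orientation = orient)
    expect_true(f$converged)
    expect_equal(f$params$xhalf, 3, tolerance = 1e-6)
    expect_equal(f$params$ymax, 480, tolerance = 1e-6)
    expect_equal(f$params$ymin, 240, tolerance = 1e-6)
    expect_equal(f$params$slope, 0.8, tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("slope-fixed fits honor the constraint and recover the rest", {
  withr::local_seed(17)
  p <- sigmoid_params(3.5, 470, 230, 1)
  x <- runif(200, 1, 6.5)
  y <- sigmoid_rt(x, p, "increasing") * exp(rnorm(200, 0, 0.1))
  f <- fit_sigmoid(x, y, orientation = "increasing", fixed = list(slope = 1))
  expect_true(f$converged)
  expect_identical(f$fixed, "slope")
  expect_identical(f$params$slope, 1)
  expect_true(is.na(f$param_se[["slope"]]))
  expect_lt(abs(f$params$xhalf - 3.5), 3 * f$param_se[["xhalf"]])
  expect_lt(abs(f$params$ymax - 470), 3 * f$param_se[["ymax"]])
  expect_lt(abs(f$params$ymin - 230), 3 * f$param_se[["ymin"]])
})

test_that("degenerate sigmoid inputs are flagged, not reported", {
  f <- fit_sigmoid(1:10, rep(300, 10))
  expect_false(f$converged)
  f2 <- fit_sigmoid(rep(2, 10), rnorm(10, 300, 10))
  expect_false(f2$converged)
  expect_error(fit_sigmoid(1:2, c(1, 2)), "at least")
})

test_that("sigmoid fits are deterministic", {
  withr::local_seed(23)
  x <- runif(80, 0, 6)
  y <- sigmoid_rt(x, sigmoid_params(3, 450, 250, 1), "increasing") +
    rnorm(80, 0, 20)
  expect_identical(fit_sigmoid(x, y)[c("params", "rss", "r_squared")],
                   fit_sigmoid(x, y)[c("params", "rss", "r_squared")])
})

test_that("on sigmoid-generated data the sigmoid beats the line on average", {
  withr::local_seed(41)
  p <- sigmoid_params(3, 460, 250, 0.7)
  r2 <- replicate(50, {
    x <- runif(60, 0.5, 6)
    y <- sigmoid_rt(x, p, "increasing") * exp(rnorm(60, 0, 0.12))
    c(fit_sigmoid(x, y, "increasing")$r_squared, fit_linear(x, y)$r_squared)
  })
  expect_gt(mean(r2[1, ]), mean(r2[2, ]))
})

test_that("median summaries match a sort-based oracle and resist outliers", {
  expect_equal(stats::median(c(5, 1, 9)), sort(c(5, 1, 9))[2])
  withr::local_seed(53)
  tabs <- lapply(1:1000, function(i) {
    n <- sample(c(3, 5, 7, 9, 20), 1)
    tibble::tibble(grp = sprintf("g%04d", i), correct = TRUE,
                   rt_ms = stats::rlnorm(n, log(350), 0.3))
  })
  trials <- dplyr::bind_rows(tabs)
  med <- median_rt(trials, "grp")
  oracle <- vapply(split(trials$rt_ms, trials$grp), function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
  }, numeric(1))
  expect_equal(med$median_rt, unname(oracle[med$grp]))

  # a wild but order-preserving tail value leaves the median unchanged
  v <- c(300, 310, 320, 330, 3000)
  expect_equal(stats::median(v), stats::median(c(v[-5], 1e6)))

  expect_warning(median_rt(tibble::tibble(grp = character(), correct = logical(),
                                          rt_ms = numeric()), "grp"),
                 "no correct trials")
})

test_that("trial-wise grids find the generating probability-sigmoid relation", {
  tr <- simulate_experiment1(n_per_group = 2, seed = 77)
  wp <- attach_predictors(tr, sequence_presets(), spec_col = "group",
                          n_prev_range = 1:2)
  grid <- compare_predictors_trialwise(wp, n_prev_range = 1:2)
  expect_identical(nrow(grid), 8L)
  expect_true(all(grid$converged))
  top <- best_cell(grid)
  expect_identical(top$fn, "sigmoid")
  # JP attains the maximum (CP may tie exactly at one previous location,
  # where uniform location usage makes CP a rescaled copy of JP)
  jp_sig <- grid$r_squared[grid$predictor == "jp" & grid$fn == "sigmoid" &
                             grid$n_prev == top$n_prev]
  expect_equal(jp_sig, top$r_squared, tolerance = 1e-6)
  # recomputation is deterministic
  expect_identical(grid, compare_predictors_trialwise(wp, n_prev_range = 1:2))
  expect_error(compare_predictors_trialwise(wp, window = c(2000, 3000)),
               "empty analysis window")
})

test_that("constant reaction times explain nothing in any cell", {
  tr <- simulate_experiment1(n_per_group = 1,
                             noise = noise_model(sigma = 0, p_error = 0),
                             between_sd = 0, seed = 5)
  tr$rt_ms <- 400
  wp <- attach_predictors(tr, sequence_presets(), spec_col = "group",
                          n_prev_range = 1)
  grid <- compare_predictors_trialwise(wp, n_prev_range = 1)
  lin <- grid[grid$fn == "linear", ]
  expect_true(all(lin$r_squared == 0))
  expect_true(all(!grid$converged[grid$fn == "sigmoid"]))
})

test_that("session-wise grids need enough units and flag degenerate columns", {
  units <- tibble::tibble(median_rt = c(300, 350, 390),
                          je_1 = 1:3, ce_1 = c(0, 0, 0))
  expect_error(compare_predictors_sessionwise(units, 1), "at least 4 units")
  units4 <- tibble::tibble(median_rt = c(300, 350, 390, 410),
                           je_1 = 1:4, ce_1 = rep(0, 4))
  grid <- compare_predictors_sessionwise(units4, 1)
  expect_true(all(!grid$converged[grid$predictor == "ce"]))
  expect_true(all(grid$converged[grid$predictor == "je"]))
})

test_that("block-wise fits recover drifting parameters and flag thin blocks", {
  fam <- gen_entropy_graded_family(24, je_range = c(1.5, 6.6), n_prev = 3)
  specs <- stats::setNames(fam$spec, vapply(fam$spec, `[[`, "", "name"))
  tr <- simulate_experiment2(24, family = fam, seed = 19, rate = 0.15)
  units <- unit_entropy_table(tr, specs, spec_col = "label",
                              unit_col = "session", n_prev_range = 3)
  je <- units[, c("session", "je_3")]
  names(je)[2] <- "je"
  traj <- blockwise_sigmoid(tr, je, unit_col = "session")
  expect_identical(traj$block, 5:22)
  expect_true(all(traj$converged))
  expect_gt(cor(traj$block, traj$xhalf, method = "spearman"), 0.7)
  expect_lt(cor(traj$block, traj$ymin, method = "spearman"), -0.7)
  expect_true(all(is.finite(traj$xhalf_se)))

  # fewer than four distinct entropies: flagged, excluded from trajectories
  je_thin <- je
  je_thin$je <- rep(c(2, 3), length.out = nrow(je_thin))
  traj_thin <- blockwise_sigmoid(tr, je_thin, unit_col = "session")
  expect_true(all(!traj_thin$converged))

  # flat generating parameters: recovered series flat within its error bands
  tr_flat <- simulate_experiment2(24, family = fam, seed = 20)  # rate = Inf
  traj_flat <- blockwise_sigmoid(tr_flat, je, unit_col = "session")
  expect_lt(max(traj_flat$xhalf) - min(traj_flat$xhalf),
            6 * stats::median(traj_flat$xhalf_se))
})
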