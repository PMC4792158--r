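#' Sigmoid tuning parameters
#'
#' The four-parameter logistic relating a predictor (probability or entropy)
#' to mean reaction time: `Xhalf` is the predictor value at the middle of
#' the transition, `Ymax` and `Ymin` the high and low RT asymptotes in ms,
#' and `slope` the transition width in predictor units.
#'
#' @param xhalf Predictor value at mid-transition.
#' @param ymax High-asymptote RT, ms.
#' @param ymin Low-asymptote RT, ms.
#' @param slope Transition width (> 0), predictor units.
#' @return A named list of class `sigmoid_params`.
#' @export
sigmoid_params <- function(xhalf, ymax, ymin, slope = 1) {
  if (!(ymax > ymin) || ymin <= 0) {
    stop("need Ymax > Ymin > 0", call. = FALSE)
  }
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  structure(list(xhalf = xhalf, ymax = ymax, ymin = ymin, slope = slope),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("<sigmoid_params> Xhalf = %.3g, Ymax = %.4g ms, Ymin = %.4g ms, slope = %.3g\n",
              x$xhalf, x$ymax, x$ymin, x$slope))
  invisible(x)
}

#' Sigmoid reaction-time function
#'
#' Mean RT as a logistic function of a predictor. Entropy predictors use the
#' increasing orientation (more uncertainty, slower responses):
#' `RT = Ymin + (Ymax - Ymin) / (1 + exp(-(x - Xhalf)/slope))`.
#' Probability predictors use the decreasing mirror (likelier transitions,
#' faster responses), with `+(x - Xhalf)` inside the exponential.
#'
#' @param x Predictor value(s); must be finite.
#' @param params A [sigmoid_params()].
#' @param orientation `"increasing"` (entropy) or `"decreasing"`
#'   (probability).
#' @return Mean RT in ms, same length as `x`.
#' @examples
#' sigmoid_rt(2, sigmoid_params(2, 500, 250), "increasing")  # midpoint: 375
#' @export
sigmoid_rt <- function(x, params, orientation = c("increasing", "decreasing")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  s <- if (orientation == "increasing") -1 else 1
  params$ymin + (params$ymax - params$ymin) /
    (1 + exp(s * (x - params$xhalf) / params$slope))
}

#' Block-wise learning trajectory of the sigmoid parameters
#'
#' Exponential relaxation of the tuning parameters across the training
#' blocks: at the first trained block the parameters equal `start`, and they
#' approach `end` at rate `rate` per block. The defaults express the two
#' signatures of sequence learning: `Xhalf` drifts up (more of the
#' uncertainty range becomes well predicted), `Ymin` drifts down (simple
#' sequences become automatic) and `Ymax` stays put (the stimulus-response
#' mapping itself is already learned).
#'
#' @param block Block number(s).
#' @param start,end [sigmoid_params()] at the first trained block and in the
#'   fully-trained limit.
#' @param rate Relaxation rate per block (> 0); `Inf` jumps to `end` from
#'   the second trained block on. The default 0.15 gives a progressive,
#'   largely unsaturated drift across an 18-block training phase.
#' @param trained_blocks Blocks over which training runs.
#' @return For a single block, a [sigmoid_params()]; for several, a list of
#'   them.
#' @export
learning_trajectory <- function(block, start, end, rate = 0.15,
                                trained_blocks = 5:22) {
  stopifnot(inherits(start, "sigmoid_params"), inherits(end, "sigmoid_params"))
  one <- function(b) {
    b <- min(max(b, min(trained_blocks)), max(trained_blocks))
    d <- b - min(trained_blocks)
    w <- if (is.finite(rate)) exp(-rate * d) else as.numeric(d == 0)
    sigmoid_params(
      xhalf = end$xhalf + (start$xhalf - end$xhalf) * w,
      ymax = end$ymax + (start$ymax - end$ymax) * w,
      ymin = end$ymin + (start$ymin - end$ymin) * w,
      slope = end$slope + (start$slope - end$slope) * w)
  }
  if (length(block) == 1L) one(block) else lapply(block, one)
}

#' Session design
#'
#' The canonical session layout: 25 blocks of 49 trials (1225 trials).
#' Bookend blocks (1-4 and 23-25) run the random no-repeat sequence; the
#' trained blocks (5-22) run the session's own sequence spec.
#'
#' @param trained_spec A [seq_spec()] for the trained blocks.
#' @param n_blocks,trials_per_block Session shape.
#' @param random_blocks Blocks carrying the random sequence.
#' @return An object of class `session_design`.
#' @export
session_design <- function(trained_spec,
                           n_blocks = 25L, trials_per_block = 49L,
                           random_blocks = c(1:4, 23:25)) {
  stopifnot(inherits(trained_spec, "seq_spec"))
  trained_blocks <- setdiff(seq_len(n_blocks), random_blocks)
  structure(list(trained_spec = trained_spec,
                 random_spec = seq_spec("random_norepeat",
                                        alphabet = trained_spec$alphabet),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 random_blocks = sort(as.integer(random_blocks)),
                 trained_blocks = trained_blocks),
            class = "session_design")
}

#' Noise and error model for simulated trials
#'
#' Reaction times get multiplicative lognormal noise (RT distributions are
#' right-skewed and the analyses summarise by medians, which the
#' median-one lognormal leaves unbiased); errors are independent Bernoulli
#' lapses; responses are capped at the response deadline.
#'
#' @param sigma Lognormal sigma of the multiplicative noise.
#' @param p_error Per-trial error probability.
#' @param deadline_ms Response deadline, ms.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.25, p_error = 0.03, deadline_ms = 3000) {
  stopifnot(sigma >= 0, p_error >= 0, p_error < 1, deadline_ms > 0)
  structure(list(sigma = sigma, p_error = p_error, deadline_ms = deadline_ms),
            class = "noise_model")
}

#' Per-subject random effects
#'
#' @param baseline Multiplicative speed factor on mean RT.
#' @param noise_scale Multiplier on the lognormal sigma.
#' @return A list of class `subject_effects`.
#' @export
subject_effects <- function(baseline = 1, noise_scale = 1) {
  structure(list(baseline = baseline, noise_scale = noise_scale),
            class = "subject_effects")
}

# Entropy predictors are used at three previous locations, where the joint
# entropy of the sequence pool spans roughly 1 to 6.75 bits: a slope-1
# sigmoid then has both asymptotes inside the data range. Xhalf drifts up
# and Ymin down with training; Ymax stays near-flat.
default_params_entropy <- function() {
  list(start = sigmoid_params(xhalf = 2.2, ymax = 480, ymin = 350, slope = 1),
       end = sigmoid_params(xhalf = 5.2, ymax = 470, ymin = 225, slope = 1))
}

default_params_probability <- function() {
  list(start = sigmoid_params(xhalf = 0.12, ymax = 480, ymin = 330,
                              slope = 0.05),
       end = sigmoid_params(xhalf = 0.22, ymax = 470, ymin = 230,
                            slope = 0.05))
}

#' Simulate one SRT session
#'
#' Generates the stimulus stream of a full session from its design and draws
#' a reaction time for every trial: the trial's mean RT is the sigmoid of a
#' predictor under that block's tuning parameters, multiplied by lognormal
#' noise and capped at the deadline. Two generating predictors are
#' supported, mirroring the two levels at which performance is analysed:
#'
#' * `"je"` — the sequence's joint entropy drives the whole session
#'   (increasing orientation); all trials of a block share a mean.
#' * `"jp"` — each trial's own nominal joint probability drives it
#'   (decreasing orientation), producing trial-level dispersion.
#'
#' @param design A [session_design()].
#' @param params_start,params_end [sigmoid_params()] at the start and end of
#'   training; defaults depend on `predictor`.
#' @param rate Learning rate per block, passed to [learning_trajectory()].
#' @param predictor `"je"` or `"jp"`.
#' @param n_prev History length used by the generating predictor; defaults
#'   to 3 for entropy (matching where the slope-1 sigmoid is well covered)
#'   and 1 for probability.
#' @param noise A [noise_model()].
#' @param subject A [subject_effects()].
#' @param seed Optional RNG seed (global RNG state untouched when given).
#' @param subject_id,label Identifiers copied into the output.
#'
#' @return A tibble of trial records: `subject_id`, `label`, `block`,
#'   `trial` (session-global 1..1225), `location`, `correct`, `rt_ms`.
#' @export
simulate_session <- function(design,
                             params_start = NULL, params_end = NULL,
                             rate = 0.15,
                             predictor = c("je", "jp"), n_prev = NULL,
                             noise = noise_model(),
                             subject = subject_effects(),
                             seed = NULL,
                             subject_id = "s01", label = NULL) {
  predictor <- match.arg(predictor)
  n_prev <- n_prev %||% (if (predictor == "je") 3L else 1L)
  defaults <- if (predictor == "je") default_params_entropy() else
    default_params_probability()
  params_start <- params_start %||% defaults$start
  params_end <- params_end %||% defaults$end
  run <- function() {
    tpb <- design$trials_per_block
    nb <- design$n_blocks
    n_total <- tpb * nb
    block_of <- rep(seq_len(nb), each = tpb)
    is_trained <- block_of %in% design$trained_blocks
    symbols <- character(n_total)
    symbols[is_trained] <- realize_sequence(design$trained_spec,
                                            sum(is_trained))
    symbols[!is_trained] <- realize_sequence(design$random_spec,
                                             sum(!is_trained))
    orientation <- if (predictor == "je") "increasing" else "decreasing"
    x <- numeric(n_total)
    if (predictor == "je") {
      je_trained <- attr(nominal_predictor_table(design$trained_spec, n_prev),
                         "je")
      je_random <- attr(nominal_predictor_table(design$random_spec, n_prev),
                        "je")
      x[is_trained] <- je_trained
      x[!is_trained] <- je_random
    } else {
      nominal <- nominal_predictor_table(design$trained_spec, n_prev)
      ptp <- per_trial_predictors(
        symbols, n_prev = n_prev, nominal = nominal,
        empirical_symbols = symbols[is_trained])
      x <- ptp$jp
      # early trials without a complete history: use the table's mean JP
      x[is.na(x)] <- mean(nominal$jp)
    }
    params <- learning_trajectory(seq_len(nb), params_start, params_end,
                                  rate = rate,
                                  trained_blocks = design$trained_blocks)
    mu <- numeric(n_total)
    for (b in seq_len(nb)) {
      in_b <- block_of == b
      mu[in_b] <- sigmoid_rt(x[in_b], params[[b]], orientation)
    }
    mu <- mu * subject$baseline
    rt <- mu * exp(stats::rnorm(n_total, 0, noise$sigma * subject$noise_scale))
    rt <- pmin(rt, noise$deadline_ms)
    correct <- stats::runif(n_total) >= noise$p_error
    tibble::tibble(subject_id = subject_id,
                   label = label %||% design$trained_spec$name,
                   block = block_of, trial = seq_len(n_total),
                   location = symbols, correct = correct, rt_ms = rt)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the six-group between-subjects experiment
#'
#' `n_per_group` subjects per sequence preset, each performing one full
#' session whose trained blocks carry the group's sequence. Subjects get
#' lognormal baseline-speed random effects. Trial-level dispersion is the
#' point of this design, so the generating predictor defaults to per-trial
#' joint probability.
#'
#' @param n_per_group Subjects per group.
#' @param presets Named list of [seq_spec()]s, one group each.
#' @param seed RNG seed for the whole experiment.
#' @param predictor,n_prev,noise,rate Passed to [simulate_session()].
#' @param between_sd Lognormal sd of the per-subject baseline factor.
#' @param ... Further arguments to [simulate_session()].
#' @return A tibble of trial records with a `group` column.
#' @export
simulate_experiment1 <- function(n_per_group = 8L,
                                 presets = sequence_presets(),
                                 seed = NULL, predictor = "jp",
                                 n_prev = 1L, noise = noise_model(),
                                 rate = 0.15, between_sd = 0.06, ...) {
  run <- function() {
    out <- vector("list", length(presets) * n_per_group)
    k <- 0L
    for (g in names(presets)) {
      design <- session_design(presets[[g]])
      for (s in seq_len(n_per_group)) {
        k <- k + 1L
        subj <- subject_effects(baseline = exp(stats::rnorm(1, 0, between_sd)))
        out[[k]] <- simulate_session(
          design, predictor = predictor, n_prev = n_prev, noise = noise,
          rate = rate, subject = subj,
          subject_id = sprintf("%s_%02d", g, s), label = g, ...)
      }
    }
    dplyr::bind_rows(out) |>
      dplyr::rename(group = "label")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate the multi-session single-subject experiment
#'
#' One (virtual) over-trained subject performs `n_sessions` sessions, each
#' training a different sequence drawn from an entropy-graded family, so the
#' sessions span a wide range of joint entropy. Session-level performance is
#' the point of this design, so the generating predictor defaults to the
#' sequence's joint entropy and the tuning parameters default to the
#' fully-trained limit with no further drift (`rate = Inf`), reflecting a
#' subject whose stimulus-response mapping is already optimised.
#'
#' @param n_sessions Number of sessions.
#' @param family Output of [gen_entropy_graded_family()]; when `NULL`, a
#'   48-step family graded in three-previous-location joint entropy from
#'   1.5 to 6.6 bits.
#' @param seed RNG seed for the whole experiment.
#' @param params_start,params_end Tuning parameters; default to the
#'   fully-trained entropy defaults for both ends.
#' @param rate Learning rate; `Inf` (flat) by default.
#' @param n_prev,noise,... Passed to [simulate_session()].
#' @return A tibble of trial records with a `session` column, plus the
#'   family table as attribute `"family"`.
#' @export
simulate_experiment2 <- function(n_sessions = 48L, family = NULL,
                                 seed = NULL,
                                 params_start = NULL, params_end = NULL,
                                 rate = Inf, n_prev = 3L,
                                 noise = noise_model(), ...) {
  if (is.null(family)) {
    family <- gen_entropy_graded_family(n_sequences = n_sessions,
                                        je_range = c(1.5, 6.6), n_prev = 3L)
  }
  stopifnot(nrow(family) == n_sessions)
  defaults <- default_params_entropy()
  params_end <- params_end %||% defaults$end
  params_start <- params_start %||% (if (is.infinite(rate)) params_end else
    defaults$start)
  run <- function() {
    session_order <- sample.int(n_sessions)
    out <- lapply(seq_len(n_sessions), function(i) {
      spec <- family$spec[[session_order[i]]]
      simulate_session(session_design(spec),
                       params_start = params_start, params_end = params_end,
                       rate = rate, predictor = "je", n_prev = n_prev,
                       noise = noise, subject_id = "s01",
                       label = spec$name, ...) |>
        dplyr::mutate(session = i, family_index = session_order[i],
                      .after = "subject_id")
    })
    dplyr::bind_rows(out)
  }
  trials <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(trials, "family") <- family
  trials
}
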