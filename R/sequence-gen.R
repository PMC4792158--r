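#' Sequence specifications
#'
#' A `seq_spec` describes how a stimulus sequence is produced: purely random
#' with the no-immediate-repeat restriction, a deterministic repeating cycle,
#' or a first-order Markov chain over the location alphabet. Specs are what
#' session designs and the simulator carry around; [realize_sequence()] turns
#' one into an actual [location_sequence()].
#'
#' @param kind One of `"random_norepeat"`, `"repetitive"`, `"probabilistic"`.
#' @param pattern Cycle string, required for the repetitive kind.
#' @param transition_matrix Row-stochastic matrix over the alphabet with zero
#'   diagonal, required for the probabilistic kind.
#' @param alphabet Location alphabet.
#' @param name Optional label carried into outputs.
#' @return An object of class `seq_spec`.
#' @export
seq_spec <- function(kind = c("random_norepeat", "repetitive", "probabilistic"),
                     pattern = NULL, transition_matrix = NULL,
                     alphabet = c("a", "b", "c", "d"), name = NULL) {
  kind <- match.arg(kind)
  if (kind == "repetitive") {
    if (is.null(pattern) || nchar(pattern) == 0L) {
      stop("repetitive specs need a non-empty `pattern`", call. = FALSE)
    }
    syms <- strsplit(pattern, "")[[1]]
    if (!all(syms %in% alphabet)) {
      stop("pattern symbols outside the alphabet", call. = FALSE)
    }
  }
  if (kind == "probabilistic") {
    transition_matrix <- validate_transition_matrix(transition_matrix, alphabet)
  }
  if (kind == "random_norepeat") {
    transition_matrix <- uniform_norepeat_matrix(alphabet)
  }
  structure(list(kind = kind, pattern = pattern,
                 transition_matrix = transition_matrix,
                 alphabet = alphabet,
                 name = name %||% kind),
            class = "seq_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_transition_matrix <- function(P, alphabet, tol = 1e-9,
                                       require_norepeat = TRUE) {
  m <- length(alphabet)
  if (is.null(P) || !is.matrix(P) || any(dim(P) != m)) {
    stop("`transition_matrix` must be a ", m, "x", m, " matrix", call. = FALSE)
  }
  if (is.null(rownames(P))) dimnames(P) <- list(alphabet, alphabet)
  P <- P[alphabet, alphabet]
  if (any(P < -tol)) stop("transition probabilities must be >= 0", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  if (require_norepeat && any(abs(diag(P)) > tol)) {
    stop("no-immediate-repeat requires a zero diagonal", call. = FALSE)
  }
  P
}

#' Uniform no-repeat transition matrix
#'
#' The transition matrix of the maximally unpredictable sequence under the
#' task's one restriction: each of the other `m - 1` locations is equally
#' likely, the current one impossible.
#'
#' @param alphabet Location alphabet.
#' @return An `m x m` row-stochastic matrix with zero diagonal.
#' @export
uniform_norepeat_matrix <- function(alphabet = c("a", "b", "c", "d")) {
  m <- length(alphabet)
  P <- matrix(1 / (m - 1), m, m, dimnames = list(alphabet, alphabet))
  diag(P) <- 0
  P
}

#' Generate a random no-repeat sequence
#'
#' Draws each location uniformly among the alternatives to its predecessor,
#' so no location ever repeats on the next trial.
#'
#' @param length Number of trials.
#' @param n_locations Alphabet size (>= 2).
#' @param seed Optional RNG seed; when given the global RNG state is left
#'   untouched.
#' @param alphabet Alphabet (defaults to the first `n_locations` letters).
#' @return A [location_sequence()] (non-circular).
#' @export
gen_random_norepeat <- function(length, n_locations = 4L, seed = NULL,
                                alphabet = letters[seq_len(n_locations)]) {
  if (n_locations < 2L) stop("need at least 2 locations", call. = FALSE)
  gen_probabilistic(uniform_norepeat_matrix(alphabet), length, seed = seed,
                    alphabet = alphabet)
}

#' Generate a repetitive (deterministic cycle) sequence
#'
#' @param pattern Cycle string, e.g. `"ababcdcd"`.
#' @param length Total trial count; the cycle is repeated and truncated.
#' @param alphabet Location alphabet.
#' @return A [location_sequence()] (non-circular realization of the cycle).
#' @export
gen_repetitive <- function(pattern, length,
                           alphabet = c("a", "b", "c", "d")) {
  if (is.null(pattern) || nchar(pattern) == 0L) {
    stop("`pattern` must be non-empty", call. = FALSE)
  }
  syms <- strsplit(pattern, "")[[1]]
  location_sequence(rep_len(syms, length), alphabet = alphabet,
                    circular = FALSE)
}

#' Generate a first-order Markov sequence
#'
#' Realizes a Markov chain over the location alphabet. The initial state is
#' drawn uniformly unless `initial` is given.
#'
#' @param transition_matrix Row-stochastic matrix (rows: current location;
#'   columns: next location).
#' @param length Number of trials.
#' @param seed Optional RNG seed (global RNG state untouched when given).
#' @param initial Optional starting location.
#' @param alphabet Location alphabet.
#' @param require_norepeat Insist on a zero diagonal (default `TRUE`).
#' @return A [location_sequence()] (non-circular).
#' @export
gen_probabilistic <- function(transition_matrix, length, seed = NULL,
                              initial = NULL,
                              alphabet = c("a", "b", "c", "d"),
                              require_norepeat = TRUE) {
  P <- validate_transition_matrix(transition_matrix, alphabet,
                                  require_norepeat = require_norepeat)
  draw <- function() {
    m <- length(alphabet)
    cum <- t(apply(P, 1, cumsum))
    out <- integer(length)
    u <- stats::runif(length)
    out[1] <- if (is.null(initial)) sample.int(m, 1L) else
      match(initial, alphabet)
    if (length > 1L) {
      for (i in 2:length) {
        out[i] <- sum(u[i] > cum[out[i - 1L], ]) + 1L
      }
    }
    location_sequence(alphabet[out], alphabet = alphabet, circular = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Realize a sequence spec
#'
#' @param spec A [seq_spec()].
#' @param length Trial count.
#' @param seed Optional RNG seed.
#' @return A [location_sequence()].
#' @export
realize_sequence <- function(spec, length, seed = NULL) {
  stopifnot(inherits(spec, "seq_spec"))
  switch(spec$kind,
    repetitive = gen_repetitive(spec$pattern, length, spec$alphabet),
    random_norepeat = ,
    probabilistic = gen_probabilistic(spec$transition_matrix, length,
                                      seed = seed, alphabet = spec$alphabet))
}

# ---- Markov-chain entropy calculus -----------------------------------------

#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of the chain, normalised to a probability
#' vector. Unique for the irreducible chains produced by this package;
#' transient states (locations a cycle never visits) get mass zero.
#'
#' @param P Row-stochastic matrix.
#' @return Named probability vector over the states.
#' @export
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- pmax(v / sum(v), 0)
  stats::setNames(v / sum(v), rownames(P))
}

#' Exact transition-gram predictor table of a Markov chain
#'
#' Enumerates every positive-probability `(n_prev + 1)`-gram of the chain at
#' stationarity: the gram's joint probability is the stationary mass of its
#' first symbol times the product of stepwise transition probabilities, and
#' its conditional probability is the last transition step given the prefix.
#' This is the nominal predictor table of probabilistic and random sequence
#' specs, playing the same role the circular table plays for repetitive ones.
#'
#' @param P Row-stochastic transition matrix (named dimnames = alphabet).
#' @param n_prev Number of previous locations.
#' @return A [predictor_table()] (`count` is `NA`: probabilities are exact,
#'   not tallied).
#' @export
markov_predictor_table <- function(P, n_prev = 1L) {
  alphabet <- rownames(P)
  pi0 <- markov_stationary(P)
  grams <- expand.grid(rep(list(alphabet), n_prev + 1L),
                       stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder so column 1 is the
  # leading symbol and the gram string reads left to right in time
  p <- pi0[grams[[1]]]
  cp_last <- rep(1, nrow(grams))
  for (k in seq_len(n_prev)) {
    step <- P[cbind(grams[[k]], grams[[k + 1L]])]
    p <- p * step
    cp_last <- step
  }
  keep <- p > 1e-15
  gram_str <- do.call(paste0, grams)[keep]
  ord <- order(gram_str)
  tbl <- tibble::tibble(gram = gram_str[ord], count = NA_integer_,
                        jp = p[keep][ord] / sum(p[keep]),
                        cp = cp_last[keep][ord])
  new_predictor_table(tbl, n_prev = n_prev, n_transitions = NA_integer_)
}

#' Nominal predictor table of a sequence spec
#'
#' Repetitive specs use the circular transition set of the cycle; random and
#' probabilistic specs use the exact Markov table.
#'
#' @param spec A [seq_spec()].
#' @param n_prev Number of previous locations.
#' @return A [predictor_table()].
#' @export
nominal_predictor_table <- function(spec, n_prev = 1L) {
  stopifnot(inherits(spec, "seq_spec"))
  if (spec$kind == "repetitive") {
    syms <- strsplit(spec$pattern, "")[[1]]
    # tile whole cycles so grams longer than the cycle stay well defined;
    # circular probabilities are invariant under tiling
    reps <- max(1L, ceiling((n_prev + 1L) / length(syms)))
    pt <- predictor_table(location_sequence(rep(syms, reps),
                                            alphabet = spec$alphabet,
                                            circular = TRUE),
                          n_prev = n_prev)
    pt$count <- pt$count %/% reps
    attr(pt, "n_transitions") <- attr(pt, "n_transitions") %/% reps
    pt
  } else {
    markov_predictor_table(spec$transition_matrix, n_prev = n_prev)
  }
}

#' First-order Markov reduction of a repeating cycle
#'
#' The conditional-probability rows of the cycle's circular transition set,
#' assembled into a transition matrix. For no-repeat cycles this preserves
#' the cycle's one-step transition statistics exactly. Locations absent from
#' the cycle get uniform no-repeat rows so that noise-mixed chains remain
#' well defined on the full alphabet.
#'
#' @param pattern Cycle string.
#' @param alphabet Location alphabet.
#' @return Row-stochastic matrix.
#' @export
cycle_transition_matrix <- function(pattern, alphabet = c("a", "b", "c", "d")) {
  pt <- predictor_table(location_sequence(pattern, alphabet = alphabet,
                                          circular = TRUE), n_prev = 1L)
  P <- uniform_norepeat_matrix(alphabet)
  used <- unique(substr(pt$gram, 1, 1))
  P[used, ] <- 0
  P[cbind(substr(pt$gram, 1, 1), substr(pt$gram, 2, 2))] <- pt$cp
  P
}

#' Entropies of a Markov chain's transition grams
#'
#' Closed-form joint and conditional entropy of the `(n_prev + 1)`-gram
#' distribution at stationarity: with `H(pi)` the entropy of the stationary
#' distribution and `Hc` the conditional entropy rate
#' `-sum_i pi_i sum_j P_ij log2 P_ij`, the gram joint entropy is
#' `H(pi) + n_prev * Hc` and the gram conditional entropy is `Hc`.
#'
#' @param P Row-stochastic matrix.
#' @param n_prev Number of previous locations.
#' @return Named vector `c(je = , ce = )` in bits.
#' @export
markov_entropies <- function(P, n_prev = 1L) {
  pi0 <- markov_stationary(P)
  h_pi <- -sum(pi0[pi0 > 0] * log2(pi0[pi0 > 0]))
  rows <- apply(P, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
  hc <- sum(pi0 * rows)
  c(je = h_pi + n_prev * hc, ce = hc)
}

#' Mix a transition matrix toward the uniform no-repeat chain
#'
#' `(1 - epsilon) * P + epsilon * U`: with probability `epsilon` the
#' deterministic (or structured) successor is replaced by a uniform draw
#' among the alternatives. The knob behind the entropy-graded family.
#'
#' @param P Row-stochastic matrix.
#' @param epsilon Mixing weight in `[0, 1]`.
#' @return Row-stochastic matrix.
#' @export
mix_toward_uniform <- function(P, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  (1 - epsilon) * P + epsilon * uniform_norepeat_matrix(rownames(P))
}

default_base_patterns <- function() {
  c("ab", "abc", "abcd", "ababcd", "ababcdcd", "abacdbdc")
}

#' Build a family of sequences spanning a joint-entropy range
#'
#' Emulates a multi-session design in which every session trains a different
#' sequence, from near-deterministic to fully random. Each target joint
#' entropy is met by taking the base cycle whose Markov reduction has the
#' largest entropy not exceeding the target and mixing it toward the uniform
#' no-repeat chain; the mixing weight is solved by bisection on the exact
#' chain entropy, so achieved values are deterministic and monotone in the
#' target. Using several base cycles of different lengths and alphabet
#' coverage keeps the conditional entropy from being a mere shifted copy of
#' the joint entropy across the family.
#'
#' @param n_sequences Number of sequences (sessions).
#' @param je_range Target joint-entropy range in bits, spanned evenly.
#' @param n_prev History length at which targets are defined.
#' @param base_patterns Pool of deterministic base cycles.
#' @param alphabet Location alphabet.
#' @param tol Bisection tolerance on achieved entropy, bits.
#'
#' @return A tibble with columns `index`, `target_je`, `base`, `epsilon`,
#'   `achieved_je`, `achieved_ce`, `attained` (achieved within 0.15 bits of
#'   target) and a list-column `spec` of [seq_spec()] objects.
#' @export
gen_entropy_graded_family <- function(n_sequences = 48L,
                                      je_range = c(1, log2(12)),
                                      n_prev = 1L,
                                      base_patterns = default_base_patterns(),
                                      alphabet = c("a", "b", "c", "d"),
                                      tol = 1e-4) {
  targets <- seq(je_range[1], je_range[2], length.out = n_sequences)
  bases <- lapply(base_patterns, cycle_transition_matrix, alphabet = alphabet)
  base_je <- vapply(bases, function(P) markov_entropies(P, n_prev)[["je"]],
                    numeric(1))
  ord <- order(base_je)
  bases <- bases[ord]; base_je <- base_je[ord]
  base_patterns <- base_patterns[ord]
  max_je <- markov_entropies(uniform_norepeat_matrix(alphabet),
                             n_prev)[["je"]]
  rows <- lapply(seq_along(targets), function(i) {
    tgt <- targets[i]
    j <- max(c(1L, which(base_je <= tgt + 1e-12)))
    P0 <- bases[[j]]
    je_at <- function(eps) markov_entropies(mix_toward_uniform(P0, eps),
                                            n_prev)[["je"]]
    if (tgt <= base_je[j]) {
      eps <- 0
    } else if (tgt >= max_je) {
      eps <- 1
    } else {
      lo <- 0; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (je_at(mid) < tgt) lo <- mid else hi <- mid
        if (hi - lo < 1e-12) break
      }
      eps <- (lo + hi) / 2
    }
    P <- mix_toward_uniform(P0, eps)
    ent <- markov_entropies(P, n_prev)
    spec <- seq_spec("probabilistic", transition_matrix = P,
                     alphabet = alphabet,
                     name = sprintf("graded_%02d_%s", i, base_patterns[j]))
    tibble::tibble(index = i, target_je = tgt, base = base_patterns[j],
                   epsilon = eps, achieved_je = ent[["je"]],
                   achieved_ce = ent[["ce"]],
                   attained = abs(ent[["je"]] - tgt) <= 0.15,
                   spec = list(spec))
  })
  dplyr::bind_rows(rows)
}

#' The six named sequence presets
#'
#' One preset per training group of the six-group design: a fully random
#' no-repeat sequence, two probabilistic (Markov) sequences of graded
#' structure, and three deterministic cycles of graded complexity. Their
#' one-step joint entropies are strictly ordered
#' (very simple repetitive < simple repetitive < complex repetitive <
#' simple probabilistic < complex probabilistic < random), mirroring the
#' ordering of asymptotic reaction times across groups.
#'
#' @param alphabet Location alphabet.
#' @return Named list of [seq_spec()] objects.
#' @export
sequence_presets <- function(alphabet = c("a", "b", "c", "d")) {
  prob_preset <- function(p_follow, name) {
    P <- mix_toward_uniform(cycle_transition_matrix("abcd", alphabet),
                            epsilon = (1 - p_follow) * 3 / 2)
    seq_spec("probabilistic", transition_matrix = P, alphabet = alphabet,
             name = name)
  }
  list(
    random = seq_spec("random_norepeat", alphabet = alphabet,
                      name = "random"),
    complex_probabilistic = prob_preset(0.55, "complex_probabilistic"),
    simple_probabilistic = prob_preset(0.70, "simple_probabilistic"),
    complex_repetitive = seq_spec("repetitive", pattern = "abacdbdc",
                                  alphabet = alphabet,
                                  name = "complex_repetitive"),
    simple_repetitive = seq_spec("repetitive", pattern = "ababcdcd",
                                 alphabet = alphabet,
                                 name = "simple_repetitive"),
    very_simple_repetitive = seq_spec("repetitive", pattern = "abcd",
                                      alphabet = alphabet,
                                      name = "very_simple_repetitive")
  )
}
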