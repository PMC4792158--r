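#' Stimulus-location sequences
#'
#' A `location_sequence` is an ordered run of stimulus locations over a small
#' finite alphabet (four horizontal screen positions, `"a"` to `"d"`, in the
#' standard serial reaction time task). Sequences may be declared *circular*:
#' the nominal training sequence repeats block after block, so its transition
#' structure wraps around from the last location back to the first.
#'
#' @param x A character vector of single-letter locations, or a single string
#'   such as `"ababcdcd"` which is split into characters. Separators (`"-"`,
#'   whitespace) are dropped, so `"a-b-a-b-c-d-c-d"` also works.
#' @param alphabet Character vector of allowed locations. Defaults to the
#'   four-location alphabet `c("a","b","c","d")`.
#' @param circular Logical; treat the sequence as a repeating cycle when
#'   building transitions. Default `TRUE`.
#'
#' @return An object of class `location_sequence`: a character vector of
#'   symbols with `alphabet` and `circular` attributes.
#' @examples
#' location_sequence("ababcdcd")
#' @export
location_sequence <- function(x, alphabet = c("a", "b", "c", "d"),
                              circular = TRUE) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(gsub("[-[:space:]]", "", x), "")[[1]]
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), alphabet)
  if (length(bad) > 0L) {
    stop("symbols outside the declared alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(x, alphabet = alphabet, circular = isTRUE(circular),
            class = "location_sequence")
}

#' @export
print.location_sequence <- function(x, ...) {
  cat("<location_sequence> ", length(x), " symbols over {",
      paste(attr(x, "alphabet"), collapse = ","), "}",
      if (attr(x, "circular")) ", circular" else "", "\n", sep = "")
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

as_location_sequence <- function(x, ...) {
  if (inherits(x, "location_sequence")) x else location_sequence(x, ...)
}

#' Build the transition set of a sequence
#'
#' Slides a window of `n_prev + 1` consecutive locations along the sequence
#' and counts each resulting transition (gram). For a circular sequence every
#' position starts one transition, the window wrapping from the end back to
#' the start, so an L-symbol cycle yields exactly L transitions; the
#' non-circular variant yields `L - n_prev`.
#'
#' @param seq A [location_sequence()] (or anything coercible to one).
#' @param n_prev Number of previous locations in each transition (>= 1).
#' @param circular Override the sequence's circular flag.
#'
#' @return An object of class `transition_set`: a list with `counts` (named
#'   integer vector in lexicographic gram order), `total`, `n_prev` and
#'   `alphabet`.
#' @examples
#' build_transition_set(location_sequence("ababcdcd"), n_prev = 1)
#' @export
build_transition_set <- function(seq, n_prev = 1L,
                                 circular = NULL) {
  seq <- as_location_sequence(seq)
  n_prev <- as.integer(n_prev)
  if (n_prev < 1L) stop("`n_prev` must be >= 1", call. = FALSE)
  circular <- if (is.null(circular)) attr(seq, "circular") else isTRUE(circular)
  n <- length(seq)
  if (n < n_prev + 1L) {
    stop("sequence of length ", n, " is too short for transitions of ",
         n_prev + 1L, " locations", call. = FALSE)
  }
  grams <- sequence_grams(unclass(seq), n_prev, circular)
  counts <- table(grams)
  counts <- counts[order(names(counts))]
  structure(
    list(counts = stats::setNames(as.integer(counts), names(counts)),
         total = length(grams), n_prev = n_prev,
         alphabet = attr(seq, "alphabet"), circular = circular),
    class = "transition_set"
  )
}

# All (n_prev+1)-grams of a symbol vector, one string per window position.
sequence_grams <- function(symbols, n_prev, circular) {
  n <- length(symbols)
  if (circular) {
    ext <- c(symbols, symbols[seq_len(n_prev)])
    starts <- seq_len(n)
  } else {
    ext <- symbols
    starts <- seq_len(n - n_prev)
  }
  cols <- lapply(0:n_prev, function(k) ext[starts + k])
  do.call(paste0, cols)
}

#' @export
print.transition_set <- function(x, ...) {
  cat("<transition_set> n_prev = ", x$n_prev, ", ", length(x$counts),
      " distinct / ", x$total, " total transitions\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Joint probabilities of a transition set
#'
#' The joint probability (JP) of a transition is its count divided by the
#' total number of transitions in the set.
#'
#' @param ts A [build_transition_set()] result.
#' @return Named numeric vector of joint probabilities, summing to 1, in
#'   lexicographic gram order.
#' @examples
#' joint_probability(build_transition_set(location_sequence("ababcdcd"), 1))
#' @export
joint_probability <- function(ts) {
  stopifnot(inherits(ts, "transition_set"))
  if (ts$total < 1L || length(ts$counts) == 0L) {
    stop("empty transition set", call. = FALSE)
  }
  ts$counts / ts$total
}

#' Conditional probabilities of a transition set
#'
#' The conditional probability (CP) of a transition is its joint probability
#' divided by the summed joint probability of all transitions sharing its
#' previous-location prefix: the probability of the present location given
#' the `n_prev` preceding ones.
#'
#' @inheritParams joint_probability
#' @return Named numeric vector of conditional probabilities; within each
#'   prefix the values sum to 1.
#' @examples
#' conditional_probability(build_transition_set(location_sequence("ababcdcd"), 1))
#' @export
conditional_probability <- function(ts) {
  jp <- joint_probability(ts)
  prefixes <- substr(names(jp), 1L, ts$n_prev)
  prefix_mass <- tapply(jp, prefixes, sum)
  as.numeric(jp / prefix_mass[prefixes]) |> stats::setNames(names(jp))
}

#' Joint entropy of a transition distribution
#'
#' `JE = -sum(JP * log2(JP))` over the distinct transitions, in bits: the
#' uncertainty of the whole transition set. Zero-probability grams never
#' appear in the tables, so `0 * log 0` does not arise.
#'
#' @param jp Named numeric vector of joint probabilities summing to 1.
#' @param tol Tolerance on the normalisation check.
#' @return Joint entropy in bits (non-negative scalar).
#' @examples
#' joint_entropy(c(ab = .25, ba = .125, bc = .125, cd = .25, da = .125, dc = .125))
#' @export
joint_entropy <- function(jp, tol = 1e-9) {
  jp <- jp[jp > 0]
  if (length(jp) == 0L || abs(sum(jp) - 1) > tol) {
    stop("joint probabilities must sum to 1", call. = FALSE)
  }
  -sum(jp * log2(jp))
}

#' Conditional entropy of a transition distribution
#'
#' `CE = -sum(JP * log2(CP))`, in bits: the uncertainty of the present
#' location once the previous locations are known. By the chain rule this
#' equals the joint entropy minus the entropy of the previous-location
#' (prefix) marginal.
#'
#' @param jp,cp Named numeric vectors over the same gram set: joint and
#'   conditional probabilities as returned by [joint_probability()] and
#'   [conditional_probability()].
#' @return Conditional entropy in bits, with `0 <= CE <= JE`.
#' @examples
#' ts <- build_transition_set(location_sequence("ababcdcd"), 1)
#' conditional_entropy(joint_probability(ts), conditional_probability(ts))
#' @export
conditional_entropy <- function(jp, cp) {
  if (!setequal(names(jp), names(cp))) {
    stop("`jp` and `cp` must be defined on the same gram set", call. = FALSE)
  }
  cp <- cp[names(jp)]
  keep <- jp > 0
  -sum(jp[keep] * log2(cp[keep]))
}

#' Full predictor table of a sequence
#'
#' Computes, for one history length, the per-transition joint and conditional
#' probabilities together with the sequence-level joint and conditional
#' entropies.
#'
#' @param x A [location_sequence()] or an already-built `transition_set`.
#' @param n_prev Number of previous locations (ignored when `x` is a
#'   `transition_set`).
#' @param ... Passed on to [build_transition_set()].
#'
#' @return A tibble of class `predictor_table` with columns `gram`, `count`,
#'   `jp`, `cp` in lexicographic gram order, and attributes `n_prev`, `je`,
#'   `ce`, `n_transitions`.
#' @examples
#' predictor_table(location_sequence("ababcdcd"), n_prev = 1)
#' @export
predictor_table <- function(x, n_prev = 1L, ...) {
  ts <- if (inherits(x, "transition_set")) x else
    build_transition_set(x, n_prev = n_prev, ...)
  jp <- joint_probability(ts)
  cp <- conditional_probability(ts)
  new_predictor_table(
    tibble::tibble(gram = names(jp), count = unname(ts$counts),
                   jp = unname(jp), cp = unname(cp)),
    n_prev = ts$n_prev, n_transitions = ts$total
  )
}

new_predictor_table <- function(tbl, n_prev, n_transitions) {
  jp <- stats::setNames(tbl$jp, tbl$gram)
  cp <- stats::setNames(tbl$cp, tbl$gram)
  structure(tbl,
            n_prev = n_prev,
            je = joint_entropy(jp),
            ce = conditional_entropy(jp, cp),
            n_transitions = n_transitions,
            class = c("predictor_table", class(tbl)))
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("# predictor table: n_prev = %d, JE = %.4f bits, CE = %.4f bits\n",
              attr(x, "n_prev"), attr(x, "je"), attr(x, "ce")))
  NextMethod()
}

#' Sequence-level entropies
#'
#' Convenience accessors for the joint and conditional entropy stored on a
#' [predictor_table()].
#'
#' @param pt A `predictor_table`.
#' @return A named numeric vector `c(je = , ce = )`, in bits.
#' @export
sequence_entropies <- function(pt) {
  stopifnot(inherits(pt, "predictor_table"))
  c(je = attr(pt, "je"), ce = attr(pt, "ce"))
}

#' Attach per-trial predictor values to a realized trial stream
#'
#' Each trial `i > n_prev` in a realized stream is described by the gram that
#' ends at it (the present location plus its `n_prev` predecessors). The
#' trial inherits the JP and CP of that gram, looked up in the *nominal*
#' predictor table of the generating sequence; grams absent from the nominal
#' table (which happens for random or probabilistic streams) fall back to
#' the empirical table computed from the realized stream itself. The first
#' `n_prev` trials have no complete history and get `NA`.
#'
#' @param symbols Character vector: the realized stimulus stream in trial
#'   order.
#' @param n_prev Number of previous locations.
#' @param nominal Optional `predictor_table` of the nominal generating
#'   sequence. When `NULL`, only the empirical table is used.
#' @param empirical_symbols Symbols from which the empirical fallback table
#'   is computed (non-circular). Defaults to `symbols`; in a full session
#'   pass the trained-block stream here.
#'
#' @return A tibble with columns `trial`, `gram`, `jp`, `cp` and a `source`
#'   column marking `"nominal"`, `"empirical"` or `NA`.
#' @export
per_trial_predictors <- function(symbols, n_prev = 1L, nominal = NULL,
                                 empirical_symbols = symbols) {
  n_prev <- as.integer(n_prev)
  n <- length(symbols)
  grams <- rep(NA_character_, n)
  if (n > n_prev) {
    idx <- (n_prev + 1L):n
    cols <- lapply(n_prev:0, function(k) symbols[idx - k])
    grams[idx] <- do.call(paste0, cols)
  }
  emp <- NULL
  lookup <- function(tbl, g) {
    m <- match(g, tbl$gram)
    list(jp = tbl$jp[m], cp = tbl$cp[m])
  }
  out <- tibble::tibble(trial = seq_len(n), gram = grams,
                        jp = NA_real_, cp = NA_real_,
                        source = NA_character_)
  if (!is.null(nominal)) {
    hit <- lookup(nominal, grams)
    found <- !is.na(hit$jp)
    out$jp[found] <- hit$jp[found]
    out$cp[found] <- hit$cp[found]
    out$source[found] <- "nominal"
  }
  missing <- !is.na(grams) & is.na(out$jp)
  if (any(missing)) {
    if (length(empirical_symbols) >= n_prev + 1L) {
      emp <- predictor_table(
        location_sequence(empirical_symbols,
                          alphabet = sort(unique(empirical_symbols)),
                          circular = FALSE),
        n_prev = n_prev)
      hit <- lookup(emp, grams)
      fill <- missing & !is.na(hit$jp)
      out$jp[fill] <- hit$jp[fill]
      out$cp[fill] <- hit$cp[fill]
      out$source[fill] <- "empirical"
    }
  }
  out
}

#' Write a predictor table to CSV with a JSON sidecar
#'
#' The CSV holds the per-gram columns (`gram`, `count`, `jp`, `cp`); the
#' sidecar records the scalar summary `{n_prev, je, ce, n_transitions}`.
#'
#' @param pt A [predictor_table()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path; defaults to the CSV path with a
#'   `.json` extension.
#' @return Invisibly, the two paths.
#' @export
write_predictor_table <- function(pt, csv_path,
                                  json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(pt, "predictor_table"))
  readr::write_csv(tibble::as_tibble(pt), csv_path)
  jsonlite::write_json(
    list(n_prev = attr(pt, "n_prev"), je = attr(pt, "je"),
         ce = attr(pt, "ce"), n_transitions = attr(pt, "n_transitions")),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
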