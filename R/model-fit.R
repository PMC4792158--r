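#' Fit results
#'
#' Both fitting routines return a `fit_result`: the fitted parameters, which
#' of them were held fixed, the residual sum of squares, the explained
#' variance `R^2 = 1 - RSS/TSS` (computed the same way for linear and
#' nonlinear fits, so it can go negative for a fit worse than the mean), the
#' number of points, parameter standard errors from the Jacobian, and a
#' convergence flag. Results with `converged = FALSE` must not be reported.
#'
#' @name fit_result
NULL

new_fit_result <- function(function_kind, params, fixed, rss, tss, n,
                           converged, se = NULL, fit = NULL) {
  # constant y: a fit can at best reproduce the mean, explaining nothing
  structure(list(function_kind = function_kind, params = params,
                 fixed = fixed,
                 r_squared = if (tss > 0) 1 - rss / tss else 0,
                 rss = rss, tss = tss, n_points = n,
                 converged = converged, param_se = se, fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit on %d points: R^2 = %s, RSS = %.4g%s\n",
              x$function_kind, x$n_points,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$rss,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(unlist(x$params))
  invisible(x)
}

#' Ordinary least-squares linear fit
#'
#' @param x,y Numeric vectors of equal length (>= 3 points); `x` must not be
#'   constant.
#' @return A [fit_result] with `params$intercept` and `params$slope`.
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate fit: `x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # vcov warns on an exactly collinear response; the SEs are still valid
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  new_fit_result("linear",
                 params = list(intercept = unname(co[1]),
                               slope = unname(co[2])),
                 fixed = character(0), rss = rss, tss = tss,
                 n = length(x), converged = TRUE,
                 se = c(intercept = unname(se[1]), slope = unname(se[2])),
                 fit = fit)
}

# Deterministic multi-start grid: multiplicative jitter on slope and
# additive jitter (in x-sd units) on xhalf, first entry unjittered.
sigmoid_starts <- function(x, y, fixed_slope = NULL) {
  ymax0 <- unname(stats::quantile(y, 0.95))
  ymin0 <- unname(stats::quantile(y, 0.05))
  if (ymax0 <= ymin0) ymax0 <- ymin0 + max(1e-6, abs(ymin0) * 1e-3)
  xhalf0 <- stats::median(x)
  slope0 <- fixed_slope %||% (diff(range(x)) / 6)
  sx <- stats::sd(x)
  slope_mult <- c(1, 0.5, 2, 1, 1)
  xhalf_shift <- c(0, 0, 0, -0.75, 0.75) * sx
  lapply(1:5, function(i) {
    list(xhalf = xhalf0 + xhalf_shift[i], ymax = ymax0, ymin = ymin0,
         slope = slope0 * slope_mult[i])
  })
}

#' Sigmoid (four-parameter logistic) least-squares fit
#'
#' Fits the logistic of [sigmoid_rt()] by Levenberg-Marquardt nonlinear
#' least squares. Starting values come from the data (asymptotes from the
#' 5th/95th RT percentiles, mid-point from the x median, width from a sixth
#' of the x range) and are refined from five deterministic jittered starts;
#' the best residual sum of squares wins, ties going to the first found.
#' Any parameter can be held fixed — fixing `slope = 1` is the standard move
#' for stable block-wise entropy fits. Standard errors come from the
#' Jacobian at the optimum. Non-convergence from every start is flagged,
#' never silently reported.
#'
#' @param x,y Numeric vectors; at least 4 points (3 when the slope is
#'   fixed), `x` spanning a nonzero range.
#' @param orientation `"increasing"` (entropy predictors) or `"decreasing"`
#'   (probability predictors).
#' @param fixed Named list of parameters to hold, e.g. `list(slope = 1)`.
#' @param start Optional named list overriding the automatic starts.
#' @return A [fit_result] with `params` = `xhalf`, `ymax`, `ymin`, `slope`.
#' @export
fit_sigmoid <- function(x, y, orientation = c("increasing", "decreasing"),
                        fixed = list(), start = NULL) {
  orientation <- match.arg(orientation)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  free <- setdiff(c("xhalf", "ymax", "ymin", "slope"), names(fixed))
  if (length(x) < length(free)) {
    stop("need at least ", length(free), " points", call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  degenerate <- diff(range(x)) == 0 || tss == 0
  sgn <- if (orientation == "increasing") -1 else 1
  model <- function(p, xx) {
    p$ymin + (p$ymax - p$ymin) / (1 + exp(sgn * (xx - p$xhalf) / p$slope))
  }
  fail <- function() {
    new_fit_result("sigmoid",
                   params = stats::setNames(
                     as.list(rep(NA_real_, 4)),
                     c("xhalf", "ymax", "ymin", "slope")),
                   fixed = names(fixed), rss = NA_real_, tss = tss,
                   n = length(x), converged = FALSE)
  }
  if (degenerate) return(fail())
  starts <- if (is.null(start)) sigmoid_starts(x, y, fixed$slope) else
    list(utils::modifyList(sigmoid_starts(x, y, fixed$slope)[[1]], start))
  lower <- c(xhalf = -Inf, ymax = -Inf, ymin = -Inf, slope = 1e-8)
  # fixed parameters and the orientation sign enter the formula as literals
  term <- function(nm) {
    if (!is.null(fixed[[nm]])) deparse(fixed[[nm]]) else nm
  }
  fml <- stats::as.formula(sprintf(
    "y ~ sigmoid_model(x, %s, %s, %s, %s, %s)",
    term("xhalf"), term("ymax"), term("ymin"), term("slope"), sgn))
  best <- NULL
  for (s0 in starts) {
    s0[names(fixed)] <- NULL
    res <- tryCatch(
      minpack.lm::nlsLM(
        fml, start = s0,
        lower = lower[names(s0)],
        data = data.frame(x = x, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(res)) {
      rss <- sum(stats::residuals(res)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = res, rss = rss)
      }
    }
  }
  if (is.null(best)) return(fail())
  co <- as.list(stats::coef(best$fit))
  params <- utils::modifyList(co, fixed)
  params <- params[c("xhalf", "ymax", "ymin", "slope")]
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) NULL)
  se_full <- c(xhalf = NA_real_, ymax = NA_real_, ymin = NA_real_,
               slope = NA_real_)
  if (!is.null(se)) se_full[names(se)] <- se
  new_fit_result("sigmoid", params = params, fixed = names(fixed),
                 rss = best$rss, tss = tss, n = length(x),
                 converged = TRUE, se = se_full, fit = best$fit)
}

# Logistic kernel referenced from nlsLM's model formula.
sigmoid_model <- function(x, xhalf, ymax, ymin, slope, sgn) {
  ymin + (ymax - ymin) / (1 + exp(sgn * (x - xhalf) / slope))
}

#' Median reaction time by group
#'
#' Median RT of correct trials within each grouping unit; with
#' `mean_of_medians = TRUE`, additionally the mean of those medians (and its
#' standard error) across the first grouping variable's sibling units — the
#' standard block-curve summary.
#'
#' @param trials Trial tibble with `rt_ms` and `correct` columns.
#' @param group_by Character vector of grouping columns.
#' @param mean_of_medians Summarise the per-unit medians by their mean +- SE
#'   across the last grouping column.
#' @return A tibble of medians (or of mean-of-medians summaries).
#' @export
median_rt <- function(trials, group_by, mean_of_medians = FALSE) {
  med <- trials |>
    dplyr::filter(.data$correct) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     median_rt = stats::median(.data$rt_ms),
                     .groups = "drop")
  empty <- nrow(med) == 0L
  if (empty) warning("no correct trials in any group")
  if (!mean_of_medians) return(med)
  outer <- utils::head(group_by, -1L)
  med |>
    dplyr::group_by(dplyr::across(dplyr::all_of(outer))) |>
    dplyr::summarise(n_units = dplyr::n(),
                     mean_median_rt = mean(.data$median_rt),
                     se = stats::sd(.data$median_rt) / sqrt(dplyr::n()),
                     .groups = "drop")
}

#' Attach nominal per-trial predictors across history lengths
#'
#' For every unit (subject or session) and every history length in
#' `n_prev_range`, looks up each trial's joint and conditional probability
#' in the nominal predictor table of the unit's generating sequence, with
#' empirical fallback from the unit's realized trained-block stream (see
#' [per_trial_predictors()]). Adds columns `jp_k` / `cp_k` per history
#' length `k`.
#'
#' @param trials Trial tibble with `location`, `block`, `trial` columns.
#' @param specs Named list of [seq_spec()]s keyed by the values of
#'   `spec_col`.
#' @param spec_col Column naming each trial's generating sequence
#'   (`"group"` for the between-subjects design, `"label"` otherwise).
#' @param unit_col Column identifying a contiguous realized stream.
#' @param n_prev_range History lengths.
#' @param trained_blocks Blocks whose realized stream feeds the empirical
#'   fallback table.
#' @return `trials` with `2 * length(n_prev_range)` predictor columns added.
#' @export
attach_predictors <- function(trials, specs, spec_col = "group",
                              unit_col = "subject_id",
                              n_prev_range = 1:4,
                              trained_blocks = 5:22) {
  nominal_tables <- lapply(specs, function(sp) {
    lapply(n_prev_range, function(k) nominal_predictor_table(sp, k))
  })
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit_col))) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$trial)
      sp_name <- df[[spec_col]][1]
      tabs <- nominal_tables[[sp_name]]
      trained <- df$location[df$block %in% trained_blocks]
      for (j in seq_along(n_prev_range)) {
        k <- n_prev_range[j]
        ptp <- per_trial_predictors(df$location, n_prev = k,
                                    nominal = tabs[[j]],
                                    empirical_symbols = trained)
        df[[paste0("jp_", k)]] <- ptp$jp
        df[[paste0("cp_", k)]] <- ptp$cp
      }
      df
    }) |>
    dplyr::ungroup()
}

#' Trial-wise predictor-by-function comparison grid
#'
#' Fits single-trial RT against joint and conditional probability with both
#' a linear and a sigmoid function, for each history length, on correct
#' trials pooled across units inside the analysis window — 16 fits on
#' identical point sets per history length. Probability predictors use the
#' decreasing sigmoid orientation.
#'
#' @param trials Trial tibble carrying `jp_k` / `cp_k` columns from
#'   [attach_predictors()].
#' @param n_prev_range History lengths (columns must exist for each).
#' @param window Session-global trial window `c(first, last)`; the default
#'   spans training blocks 10-22, past the fast-changing early blocks.
#' @return A `comparison_grid` tibble: `predictor`, `fn`, `n_prev`,
#'   `r_squared`, `converged`, `n_points`.
#' @export
compare_predictors_trialwise <- function(trials, n_prev_range = 1:4,
                                         window = c(442, 1078)) {
  dat <- trials |>
    dplyr::filter(.data$correct,
                  .data$trial >= window[1], .data$trial <= window[2])
  if (nrow(dat) == 0L) stop("empty analysis window", call. = FALSE)
  grid_fit(dat, y = dat$rt_ms,
           predictors = c(jp = "jp_", cp = "cp_"),
           n_prev_range = n_prev_range, orientation = "decreasing")
}

#' Session-wise predictor-by-function comparison grid
#'
#' Fits one median RT per unit (subject or session) against the unit's
#' sequence-level joint and conditional entropy, linear and sigmoid, per
#' history length. Entropy predictors use the increasing orientation.
#'
#' @param units Tibble with one row per unit: a `median_rt` column plus
#'   `je_k` / `ce_k` columns per history length.
#' @param n_prev_range History lengths.
#' @return A `comparison_grid` tibble as in
#'   [compare_predictors_trialwise()].
#' @export
compare_predictors_sessionwise <- function(units, n_prev_range = 1:4) {
  if (nrow(units) < 4L) {
    stop("degenerate fit: need at least 4 units", call. = FALSE)
  }
  grid_fit(units, y = units$median_rt,
           predictors = c(je = "je_", ce = "ce_"),
           n_prev_range = n_prev_range, orientation = "increasing")
}

grid_fit <- function(dat, y, predictors, n_prev_range, orientation) {
  rows <- list()
  for (p in names(predictors)) {
    for (k in n_prev_range) {
      x <- dat[[paste0(predictors[[p]], k)]]
      keep <- is.finite(x) & is.finite(y)
      for (fn in c("linear", "sigmoid")) {
        fit <- tryCatch({
          if (fn == "linear") fit_linear(x[keep], y[keep]) else
            fit_sigmoid(x[keep], y[keep], orientation = orientation)
        }, error = function(e) NULL)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          predictor = p, fn = fn, n_prev = k,
          r_squared = if (is.null(fit) || !fit$converged) NA_real_ else
            fit$r_squared,
          converged = !is.null(fit) && fit$converged,
          n_points = sum(keep))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_grid", class(out))
  out
}

#' Best cell of a comparison grid
#'
#' @param grid A comparison grid.
#' @return One-row tibble: the converged cell with the highest `r_squared`.
#' @export
best_cell <- function(grid) {
  grid |>
    dplyr::filter(.data$converged) |>
    dplyr::slice_max(.data$r_squared, n = 1, with_ties = FALSE)
}

#' Per-unit entropy table for session-wise analysis
#'
#' Builds the unit table consumed by [compare_predictors_sessionwise()]:
#' one median RT per unit (correct trials inside the analysis window) plus
#' the nominal joint and conditional entropy of the unit's sequence at each
#' history length.
#'
#' @param trials Trial tibble.
#' @param specs Named list of [seq_spec()]s keyed by `spec_col` values.
#' @param spec_col,unit_col Columns naming each trial's sequence and unit.
#' @param n_prev_range History lengths.
#' @param window Trial window for the median.
#' @return A tibble with `median_rt` and `je_k` / `ce_k` columns.
#' @export
unit_entropy_table <- function(trials, specs, spec_col = "label",
                               unit_col = "session",
                               n_prev_range = 1:4,
                               window = c(442, 1078)) {
  med <- trials |>
    dplyr::filter(.data$trial >= window[1], .data$trial <= window[2]) |>
    median_rt(group_by = c(unit_col, spec_col))
  for (k in n_prev_range) {
    ent <- vapply(med[[spec_col]], function(nm) {
      pt <- nominal_predictor_table(specs[[nm]], k)
      c(attr(pt, "je"), attr(pt, "ce"))
    }, numeric(2))
    med[[paste0("je_", k)]] <- ent[1, ]
    med[[paste0("ce_", k)]] <- ent[2, ]
  }
  med
}

#' Block-wise sigmoid parameter trajectories
#'
#' For each training block, takes the median RT of every unit in that block,
#' fits the increasing sigmoid of RT on the unit's joint entropy with the
#' slope fixed (default 1, the standard stabilisation), and returns the
#' `Xhalf`, `Ymax`, `Ymin` series with standard errors. Blocks whose fit
#' does not converge are flagged and carry `NA` parameters.
#'
#' @param trials Trial tibble.
#' @param je_per_unit Tibble with the unit column and a `je` column.
#' @param unit_col Unit (subject/session) column name.
#' @param blocks Training blocks to fit.
#' @param fixed_slope Value the slope is held at.
#' @return A tibble with one row per block: parameter estimates, standard
#'   errors, `r_squared` and `converged`.
#' @export
blockwise_sigmoid <- function(trials, je_per_unit, unit_col = "session",
                              blocks = 5:22, fixed_slope = 1) {
  rows <- lapply(blocks, function(b) {
    med <- trials |>
      dplyr::filter(.data$block == b) |>
      median_rt(group_by = unit_col) |>
      dplyr::inner_join(je_per_unit, by = unit_col)
    base <- tibble::tibble(block = b, xhalf = NA_real_, ymax = NA_real_,
                           ymin = NA_real_,
                           xhalf_se = NA_real_, ymax_se = NA_real_,
                           ymin_se = NA_real_,
                           r_squared = NA_real_, converged = FALSE)
    if (length(unique(med$je)) < 4L) return(base)
    fit <- fit_sigmoid(med$je, med$median_rt, orientation = "increasing",
                       fixed = list(slope = fixed_slope))
    if (!fit$converged) return(base)
    tibble::tibble(block = b,
                   xhalf = fit$params$xhalf, ymax = fit$params$ymax,
                   ymin = fit$params$ymin,
                   xhalf_se = fit$param_se[["xhalf"]],
                   ymax_se = fit$param_se[["ymax"]],
                   ymin_se = fit$param_se[["ymin"]],
                   r_squared = fit$r_squared, converged = TRUE)
  })
  dplyr::bind_rows(rows)
}
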