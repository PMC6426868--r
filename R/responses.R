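# Deconvolution-based estimation of per-condition responses, baseline
# correction, and the 2-18 s window magnitude.

#' FIR least-squares deconvolution of condition responses
#'
#' Builds a finite-impulse-response design: one lagged onset indicator per
#' condition and lag over `lag_range_s` (block-train onsets only, one event
#' per block), and solves ordinary least squares per channel. Samples under
#' the artifact mask are dropped as rows from the fit. With non-overlapping
#' epochs and no noise this reduces exactly to the trigger-locked epoch
#' average.
#'
#' @param rec A preprocessed `dot_recording` on a uniform base.
#' @param triggers Tibble `onset_s`, `condition` (typically the retained
#'   triggers from [exclude_triggers()]). Default: the recording's own.
#' @param lag_range_s Lag window (s) relative to onset, default [-5, 30].
#' @param mask Optional logical per-sample artifact mask (TRUE = drop).
#' @return A `dot_responses` object: `coef` array (lags x channels x
#'   conditions), `lags_s`, `conditions`, `n_reps`, `channels`,
#'   `baseline_corrected` flag.
#' @export
deconvolve_responses <- function(rec, triggers = rec$triggers,
                                 lag_range_s = c(-5, 30), mask = NULL) {
  dtv <- diff(rec$times_s)
  if (diff(range(dtv)) > 1e-6 * mean(dtv)) {
    rlang::abort("deconvolution requires a uniform time base")
  }
  dt <- mean(dtv)
  nt <- length(rec$times_s)
  lags <- seq(lag_range_s[1], lag_range_s[2], by = dt)
  nlag <- length(lags)
  conds <- sort(unique(triggers$condition))
  ncond <- length(conds)
  if (ncond == 0) rlang::abort("no triggers to deconvolve")

  # design matrix: column (condition, lag) has 1 at sample index onset + lag
  ii <- integer(0); jj <- integer(0)
  for (ci in seq_along(conds)) {
    on <- triggers$onset_s[triggers$condition == conds[ci]]
    oidx <- round((on - rec$times_s[1]) / dt) + 1
    for (li in seq_len(nlag)) {
      ridx <- oidx + round(lags[li] / dt)
      ridx <- ridx[ridx >= 1 & ridx <= nt]
      ii <- c(ii, ridx)
      jj <- c(jj, rep((ci - 1) * nlag + li, length(ridx)))
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nt, ncond * nlag))
  keep <- if (is.null(mask)) rep(TRUE, nt) else !mask
  Xk <- X[keep, , drop = FALSE]
  Y <- t(rec$amplitudes[, keep, drop = FALSE])
  XtX <- as.matrix(Matrix::crossprod(Xk))
  XtY <- as.matrix(Matrix::crossprod(Xk, Y))
  beta <- tryCatch(
    solve(XtX, XtY),
    error = function(e) {
      zero <- which(colSums(abs(XtX)) == 0 | diag(XtX) == 0)
      bad <- unique(conds[ceiling(zero / nlag)])
      rlang::abort(paste0(
        "rank-deficient deconvolution design",
        if (length(bad)) paste0(" (conditions: ", paste(bad, collapse = ", "), ")"),
        ": ", conditionMessage(e)
      ))
    }
  )
  coef <- array(beta, dim = c(nlag, ncond, nrow(rec$amplitudes)))
  coef <- aperm(coef, c(1, 3, 2)) # lags x channels x conditions
  dimnames(coef) <- list(NULL, NULL, conds)
  n_reps <- vapply(conds, function(cc) sum(triggers$condition == cc), numeric(1))
  structure(list(
    coef = coef, lags_s = lags, conditions = conds,
    n_reps = stats::setNames(n_reps, conds),
    channels = rec$channels,
    baseline_window_s = c(-1, 0), magnitude_window_s = c(2, 18),
    baseline_corrected = FALSE
  ), class = "dot_responses")
}

#' @export
print.dot_responses <- function(x, ...) {
  cat("<dot_responses> ", dim(x$coef)[2], " channels, ",
      length(x$conditions), " conditions, lags [",
      min(x$lags_s), ", ", max(x$lags_s), "] s",
      if (x$baseline_corrected) ", baseline-corrected", "\n", sep = "")
  invisible(x)
}

#' Subtract the pre-stimulus baseline from response courses
#'
#' For every channel and condition, the mean over the baseline window
#' (default [-1, 0] s) is subtracted, establishing a common pre-stimulus
#' baseline of zero. Idempotent.
#'
#' @param resp A `dot_responses`.
#' @param window_s Baseline window (s), default the object's [-1, 0].
#' @return Baseline-corrected `dot_responses`.
#' @export
baseline_correct <- function(resp, window_s = resp$baseline_window_s) {
  sel <- resp$lags_s >= window_s[1] & resp$lags_s <= window_s[2]
  if (!any(sel)) rlang::abort("lag range does not cover the baseline window")
  bl <- apply(resp$coef[sel, , , drop = FALSE], c(2, 3), mean)
  resp$coef <- sweep(resp$coef, c(2, 3), bl, "-")
  resp$baseline_window_s <- window_s
  resp$baseline_corrected <- TRUE
  resp
}

#' Response magnitude over the post-stimulus window
#'
#' Arithmetic mean of the (baseline-corrected) response over lags in the
#' magnitude window, default [2, 18] s inclusive — the scalar measure of the
#' hemodynamic response used in all statistics.
#'
#' @param resp A `dot_responses`.
#' @param window_s Magnitude window (s), default [2, 18].
#' @return Tibble `channel`, `condition`, `magnitude`.
#' @export
window_magnitude <- function(resp, window_s = c(2, 18)) {
  sel <- resp$lags_s >= window_s[1] & resp$lags_s <= window_s[2]
  if (!any(sel) || window_s[1] < min(resp$lags_s) || window_s[2] > max(resp$lags_s)) {
    rlang::abort("magnitude window outside the lag range")
  }
  mag <- apply(resp$coef[sel, , , drop = FALSE], c(2, 3), mean)
  nch <- dim(resp$coef)[2]
  tibble::tibble(
    channel = rep(seq_len(nch), times = length(resp$conditions)),
    condition = rep(resp$conditions, each = nch),
    magnitude = as.vector(mag)
  )
}

#' Long-format view of response courses
#' @param x A `dot_responses`.
#' @param ... Unused.
#' @method as_tibble dot_responses
#' @export
as_tibble.dot_responses <- function(x, ...) {
  d <- dim(x$coef)
  tibble::tibble(
    lag_s = rep(x$lags_s, times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    condition = rep(x$conditions, each = d[1] * d[2]),
    value = as.vector(x$coef)
  )
}

#' Plot condition-wise response time courses
#'
#' Mean over channels per condition with a per-lag standard-error ribbon.
#' @param object A `dot_responses`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dot_responses
#' @export
autoplot.dot_responses <- function(object, ...) {
  df <- as_tibble.dot_responses(object) |>
    dplyr::group_by(.data$lag_s, .data$condition) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_s, .data$mean,
                                   color = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "lag (s)", y = "response", color = "condition",
                  fill = "condition") +
    ggplot2::theme_minimal()
}
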