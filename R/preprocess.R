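# Signal preprocessing: resampling to a common time base, zero-phase
# bandpass, superficial signal regression, artifact detection and trigger
# exclusion.

#' Preprocessing configuration
#'
#' Houses the preprocessing constants: 1 Hz common time base, 0.007-0.2 Hz
#' passband (-3 dB), 12 mm short-channel cutoff for superficial signal
#' regression, artifact threshold 3.5-7 x SD (or automatic L-curve knee),
#' and the minimum of 5 artifact-free repetitions per condition for subject
#' inclusion.
#'
#' @param target_rate_hz Common sampling rate (Hz).
#' @param band_lo_hz,band_hi_hz -3 dB passband edges (Hz).
#' @param ssr_sds_mm Channels with SDS below this form the superficial
#'   regressor (mm).
#' @param artifact_k Threshold multiplier in [3.5, 7], or `"auto"`.
#' @param min_reps_per_condition Inclusion threshold on clean repetitions.
#' @param epoch_span_s Window around each trigger checked for mask overlap
#'   (s, relative to onset).
#' @return A `dot_preprocess_config` list.
#' @export
preprocess_config <- function(target_rate_hz = 1,
                              band_lo_hz = 0.007, band_hi_hz = 0.2,
                              ssr_sds_mm = 12,
                              artifact_k = "auto",
                              min_reps_per_condition = 5,
                              epoch_span_s = c(-1, 18)) {
  stopifnot(band_lo_hz > 0, band_lo_hz < band_hi_hz,
            band_hi_hz < target_rate_hz / 2)
  if (is.numeric(artifact_k) && (artifact_k < 3.5 || artifact_k > 7)) {
    rlang::abort("artifact_k must lie in [3.5, 7] (or be \"auto\")")
  }
  structure(list(
    target_rate_hz = target_rate_hz, band_lo_hz = band_lo_hz,
    band_hi_hz = band_hi_hz, ssr_sds_mm = ssr_sds_mm,
    artifact_k = artifact_k, min_reps_per_condition = min_reps_per_condition,
    epoch_span_s = epoch_span_s
  ), class = "dot_preprocess_config")
}

#' Resample a recording to a common uniform time base
#'
#' Linear interpolation of every channel (honoring its per-source scan
#' offset) onto a shared uniform grid at `target_rate_hz`. Triggers and
#' annotations are unchanged.
#'
#' @param rec A `dot_recording`.
#' @param target_rate_hz Target rate (Hz), default 1.
#' @return The resampled `dot_recording` (offsets cleared).
#' @export
resample_to_common_base <- function(rec, target_rate_hz = 1) {
  if (ncol(rec$amplitudes) < 2) rlang::abort("need >= 2 samples per channel")
  native_rate <- 1 / stats::median(diff(rec$times_s))
  if (target_rate_hz > native_rate * 10) {
    rlang::abort("refusing to upsample by more than 10x the native rate")
  }
  dt <- 1 / target_rate_hz
  lo <- ceiling((min(rec$times_s) + max(rec$channels$time_offset_s)) / dt) * dt
  hi <- floor((max(rec$times_s) + min(rec$channels$time_offset_s)) / dt) * dt
  new_t <- seq(lo, hi, by = dt)
  out <- matrix(0, nrow(rec$amplitudes), length(new_t))
  for (k in seq_len(nrow(out))) {
    out[k, ] <- stats::approx(rec$times_s + rec$channels$time_offset_s[k],
                              rec$amplitudes[k, ], xout = new_t, rule = 2)$y
  }
  rec$amplitudes <- out
  rec$times_s <- new_t
  rec$channels$time_offset_s <- 0
  rec$meta$target_rate_hz <- target_rate_hz
  # triggers may now sit inside the trimmed span edge; keep them but warn
  validate_recording(rec)
}

# two-pass (forward-backward) amplitude gain of a digital filter at f
two_pass_gain <- function(flt, f, rate_hz) {
  w <- 2 * pi * f / rate_hz
  num <- sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1)))
  den <- sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1)))
  Mod(num / den)^2
}

# choose a Butterworth design cutoff so the measured two-pass gain at the
# target edge frequency is exactly -3 dB (bilinear warping makes the analog
# adjustment formula inexact, so solve numerically)
calibrate_cutoff <- function(target_hz, rate_hz, order, type) {
  ny <- rate_hz / 2
  obj <- function(fc) {
    flt <- signal::butter(order, fc / ny, type = type)
    two_pass_gain(flt, target_hz, rate_hz) - 1 / sqrt(2)
  }
  lo <- target_hz / 4
  hi <- min(target_hz * 4, ny * 0.99)
  stats::uniroot(obj, c(lo, hi), tol = 1e-12)$root
}

# zero-phase Butterworth bandpass with cutoffs calibrated so the measured
# two-pass (filtfilt) gain at lo/hi is -3 dB
bandpass_matrix <- function(x, rate_hz, lo_hz, hi_hz, order = 2) {
  ny <- rate_hz / 2
  hp <- signal::butter(order, calibrate_cutoff(lo_hz, rate_hz, order, "high") / ny,
                       type = "high")
  lp <- signal::butter(order, calibrate_cutoff(hi_hz, rate_hz, order, "low") / ny,
                       type = "low")
  t(apply(x, 1, function(v) {
    v <- v - mean(v)
    signal::filtfilt(lp, signal::filtfilt(hp, v))
  }))
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering with cutoffs adjusted
#' so the measured two-pass gain at `lo_hz` and `hi_hz` is -3 dB; mid-band
#' gain is 1 within 5%. DC is removed. The passband 0.007-0.2 Hz suppresses
#' drift and contact variation below and pulse/noise above the hemodynamic
#' band.
#'
#' @param rec A `dot_recording` on a uniform time base.
#' @param lo_hz,hi_hz -3 dB cutoff frequencies (Hz).
#' @param order Butterworth section order (per pass) for each edge.
#' @return Filtered `dot_recording`.
#' @export
bandpass <- function(rec, lo_hz = 0.007, hi_hz = 0.2, order = 2) {
  dt <- diff(rec$times_s)
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    rlang::abort("bandpass requires uniform sampling; resample first")
  }
  rate <- 1 / mean(dt)
  if (diff(range(rec$times_s)) < 3 / lo_hz) {
    rlang::warn("recording shorter than ~3 periods of the low cutoff; filter applied anyway")
  }
  if (rec$signal == "intensity") {
    rlang::warn("bandpass applied to raw intensities; consider optical_density() first")
  }
  rec$amplitudes <- bandpass_matrix(rec$amplitudes, rate, lo_hz, hi_hz, order)
  rec$meta$band_hz <- c(lo_hz, hi_hz)
  rec
}

#' Superficial signal regression (SSR)
#'
#' Forms a regressor by averaging all channels with source-detector
#' separation below `sds_mm` (default 12 mm; short channels sample mainly
#' scalp and systemic physiology) and subtracts each channel's least-squares
#' projection onto (intercept, regressor). Residuals are exactly
#' uncorrelated with the regressor.
#'
#' @param rec A `dot_recording` (typically bandpassed optical density).
#' @param sds_mm Short-channel separation cutoff (mm).
#' @param on_missing `"error"` (default) or `"passthrough"` when no short
#'   channel exists.
#' @return The recording with the superficial signal regressed out;
#'   `meta$ssr_regressor` keeps the regressor.
#' @export
superficial_signal_regression <- function(rec, sds_mm = 12,
                                          on_missing = c("error", "passthrough")) {
  on_missing <- match.arg(on_missing)
  short <- which(rec$channels$sds_mm < sds_mm)
  if (length(short) == 0) {
    if (on_missing == "error") {
      rlang::abort("no channels with SDS below the short-channel cutoff")
    }
    rlang::warn("no short channels; SSR skipped")
    return(rec)
  }
  g <- colMeans(rec$amplitudes[short, , drop = FALSE])
  gc <- g - mean(g)
  denom <- sum(gc^2)
  x <- rec$amplitudes
  mu <- rowMeans(x)
  xc <- x - mu
  if (denom <= .Machine$double.eps * length(gc)) {
    rec$amplitudes <- xc # degenerate regressor: mean-center only
  } else {
    beta <- as.numeric(xc %*% gc) / denom
    rec$amplitudes <- xc - outer(beta, gc)
  }
  rec$meta$ssr_regressor <- g
  rec$meta$ssr_sds_mm <- sds_mm
  rec
}

# L-curve knee: point of maximum distance from the chord of the normalized
# (k, n_flagged) curve
lcurve_knee <- function(k, n) {
  ks <- (k - min(k)) / max(diff(range(k)), 1e-12)
  ns <- (n - min(n)) / max(diff(range(n)), 1e-12)
  a <- c(ks[1], ns[1])
  b <- c(ks[length(ks)], ns[length(ns)])
  ab <- b - a
  d <- abs(ab[2] * (ks - a[1]) - ab[1] * (ns - a[2])) / max(sqrt(sum(ab^2)), 1e-12)
  k[which.max(d)]
}

#' Detect movement/noise artifacts
#'
#' High-pass filters each channel (reusing the band low cutoff), then flags
#' every sample where any channel's absolute filtered value exceeds
#' `k` times that channel's standard deviation. The mask is united with
#' externally annotated bad intervals (the synthetic stand-in for video
#' coding). `k = "auto"` scans 3.5-7 and takes the L-curve knee of the
#' (k, flagged-count) curve.
#'
#' @param rec A `dot_recording` on a uniform base.
#' @param k Numeric in [3.5, 7] or `"auto"`.
#' @param external_annotations Tibble (`onset_s`, `duration_s`); defaults to
#'   the recording's own annotations.
#' @param hp_hz High-pass cutoff used before thresholding (Hz).
#' @return List: `mask` (logical per sample), `k` (chosen), `threshold_mask`,
#'   `annotation_mask`, `n_flagged`.
#' @export
detect_artifacts <- function(rec, k = "auto", external_annotations = NULL,
                             hp_hz = 0.007) {
  if (is.null(external_annotations)) external_annotations <- rec$annotations
  dt <- diff(rec$times_s)
  rate <- 1 / mean(dt)
  x <- rec$amplitudes
  if (rec$signal == "intensity") x <- -log(x / rowMeans(x))
  adj <- (sqrt(2) - 1)^(1 / 4)
  hp <- signal::butter(2, (hp_hz * adj) / (rate / 2), type = "high")
  xf <- t(apply(x, 1, function(v) signal::filtfilt(hp, v - mean(v))))
  sds <- apply(xf, 1, stats::sd)
  sds[sds == 0] <- Inf
  z <- abs(xf / sds)
  zmax <- apply(z, 2, max)
  mask_at <- function(kk) zmax > kk
  if (identical(k, "auto")) {
    grid <- seq(3.5, 7, by = 0.25)
    counts <- vapply(grid, function(kk) sum(mask_at(kk)), numeric(1))
    k <- lcurve_knee(grid, counts)
  } else if (!is.numeric(k) || k < 3.5 || k > 7) {
    rlang::abort("k must be in [3.5, 7] or \"auto\"")
  }
  thr_mask <- mask_at(k)
  ann_mask <- rep(FALSE, length(rec$times_s))
  if (nrow(external_annotations) > 0) {
    for (i in seq_len(nrow(external_annotations))) {
      ann_mask <- ann_mask |
        (rec$times_s >= external_annotations$onset_s[i] &
           rec$times_s <= external_annotations$onset_s[i] + external_annotations$duration_s[i])
    }
  }
  mask <- thr_mask | ann_mask
  list(mask = mask, k = k, threshold_mask = thr_mask,
       annotation_mask = ann_mask, n_flagged = sum(mask))
}

#' Exclude triggers overlapping masked samples; inclusion verdict
#'
#' A trigger is retained iff no masked sample falls inside its epoch
#' (`onset + epoch_span_s`). The recording passes inclusion iff every
#' condition retains at least `min_reps` triggers.
#'
#' @param triggers Tibble `onset_s`, `condition`.
#' @param mask Logical per-sample mask (TRUE = bad).
#' @param times_s Sample times matching `mask`.
#' @param epoch_span_s Epoch window relative to onset (s), default [-1, 18].
#' @param min_reps Minimum clean repetitions per condition (default 5).
#' @return List: `retained` (tibble), `excluded` (tibble), `included`
#'   (logical verdict), `reps` (tibble condition x n_clean).
#' @export
exclude_triggers <- function(triggers, mask, times_s,
                             epoch_span_s = c(-1, 18), min_reps = 5) {
  bad_times <- times_s[mask]
  keep <- vapply(seq_len(nrow(triggers)), function(i) {
    o <- triggers$onset_s[i]
    !any(bad_times >= o + epoch_span_s[1] & bad_times <= o + epoch_span_s[2])
  }, logical(1))
  if (nrow(triggers) == 0) keep <- logical(0)
  retained <- triggers[keep, , drop = FALSE]
  conds <- unique(triggers$condition)
  reps <- tibble::tibble(
    condition = conds,
    n_clean = unname(vapply(conds, function(cc) sum(retained$condition == cc),
                            numeric(1)))
  )
  list(
    retained = retained,
    excluded = triggers[!keep, , drop = FALSE],
    included = all(reps$n_clean >= min_reps),
    reps = reps
  )
}

#' Standard preprocessing chain
#'
#' resample -> optical density -> bandpass -> SSR -> artifact detection ->
#' trigger exclusion, with the configuration of [preprocess_config()].
#'
#' @param rec A raw `dot_recording`.
#' @param config A `dot_preprocess_config`.
#' @return List: `recording` (preprocessed), `artifacts` (from
#'   [detect_artifacts()]), `triggers` (from [exclude_triggers()]).
#' @export
preprocess <- function(rec, config = preprocess_config()) {
  rec <- resample_to_common_base(rec, config$target_rate_hz)
  rec <- optical_density(rec)
  rec <- bandpass(rec, config$band_lo_hz, config$band_hi_hz)
  rec <- superficial_signal_regression(rec, config$ssr_sds_mm)
  art <- detect_artifacts(rec, config$artifact_k, hp_hz = config$band_lo_hz)
  trg <- exclude_triggers(rec$triggers, art$mask, rec$times_s,
                          config$epoch_span_s, config$min_reps_per_condition)
  list(recording = rec, artifacts = art, triggers = trg)
}
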