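# Stimulus schedules, habituated neuronal trains, canonical HRF responses.

CONDITIONS <- c("neutral", "happy", "angry", "sad")

#' Generate a randomized block stimulus schedule
#'
#' Blocks of emotional speech (11 s, four phrases) in randomized condition
#' order, separated by rest periods drawn uniformly from `rest_bounds_s`
#' (20-30 s by default).
#'
#' @param n_blocks_per_condition Blocks per condition (>= 1).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param conditions Condition labels (default neutral/happy/angry/sad).
#' @param block_duration_s Block length in s (default 11).
#' @param rest_bounds_s Length-2 numeric, uniform rest-duration bounds in s.
#' @param lead_in_s Rest before the first block (default 30 s).
#' @return A `dot_schedule`: tibble with `onset_s`, `duration_s`, `condition`,
#'   plus attributes `rest_bounds_s`, `seed`, `conditions`.
#' @export
make_schedule <- function(n_blocks_per_condition, seed = 1,
                          conditions = CONDITIONS,
                          block_duration_s = 11,
                          rest_bounds_s = c(20, 30),
                          lead_in_s = 30) {
  stopifnot(n_blocks_per_condition >= 1, length(rest_bounds_s) == 2,
            rest_bounds_s[1] <= rest_bounds_s[2])
  n <- n_blocks_per_condition * length(conditions)
  ord <- withr::with_seed(seed, {
    list(
      cond = sample(rep(conditions, n_blocks_per_condition)),
      rests = runif(n - 1, rest_bounds_s[1], rest_bounds_s[2])
    )
  })
  onsets <- lead_in_s + cumsum(c(0, ord$rests + block_duration_s))
  out <- tibble::tibble(
    onset_s = onsets,
    duration_s = block_duration_s,
    condition = ord$cond
  )
  structure(out,
    class = c("dot_schedule", class(out)),
    rest_bounds_s = rest_bounds_s, seed = seed, conditions = conditions
  )
}

#' Habituation profile for a four-phrase block
#'
#' Within an 11 s block of four spoken phrases, the neuronal response to
#' repeated phrases habituates; the default amplitudes 1, 0.6, 0.3, 0.2
#' encode strong habituation after the first phrase. Set all amplitudes to 1
#' for the no-habituation variant.
#'
#' @param amplitudes Non-increasing per-phrase amplitudes.
#' @param phrase_duration_s Duration of each phrase (s).
#' @param phrase_gap_s Silent gap between phrases (s).
#' @return A `dot_habituation` list.
#' @export
habituation_profile <- function(amplitudes = c(1, 0.6, 0.3, 0.2),
                                phrase_duration_s = 2.2,
                                phrase_gap_s = 0.7) {
  if (any(diff(amplitudes) > 1e-12)) {
    rlang::abort("habituation amplitudes must be non-increasing")
  }
  structure(list(
    amplitudes = amplitudes,
    phrase_duration_s = phrase_duration_s,
    phrase_gap_s = phrase_gap_s
  ), class = "dot_habituation")
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard adult canonical HRF: difference of two gamma densities with
#' response delay 6 s, undershoot delay 16 s, unit dispersions and a
#' response:undershoot ratio of 6. The HbO2 kernel is the base kernel shifted
#' by `hbo2_shift_s` (default -1 s, HbO2 leading); the HbR kernel is the base
#' kernel scaled by `hbr_scale` (default -1/6, giving an HbR:HbO2 amplitude
#' ratio of -1:6).
#'
#' @param response_delay_s,undershoot_delay_s Gamma peak delays (s).
#' @param response_dispersion,undershoot_dispersion Gamma scale parameters.
#' @param ratio Response:undershoot amplitude ratio.
#' @param hbo2_shift_s Time shift applied to the HbO2 kernel (s).
#' @param hbr_scale Multiplier converting the base kernel into HbR.
#' @param duration_s Kernel support length (s).
#' @return A `dot_hrf` parameter list.
#' @export
canonical_hrf <- function(response_delay_s = 6, undershoot_delay_s = 16,
                          response_dispersion = 1, undershoot_dispersion = 1,
                          ratio = 6, hbo2_shift_s = -1, hbr_scale = -1 / 6,
                          duration_s = 32) {
  structure(list(
    response_delay_s = response_delay_s,
    undershoot_delay_s = undershoot_delay_s,
    response_dispersion = response_dispersion,
    undershoot_dispersion = undershoot_dispersion,
    ratio = ratio,
    hbo2_shift_s = hbo2_shift_s,
    hbr_scale = hbr_scale,
    duration_s = duration_s
  ), class = "dot_hrf")
}

#' Evaluate the HRF kernel on a time grid
#' @param hrf A `dot_hrf`.
#' @param dt_s Sampling interval (s).
#' @param shift_s Time shift (s); positive shifts delay the kernel.
#' @return Numeric kernel sampled at `seq(0, duration_s, by = dt_s)`.
#' @export
hrf_kernel <- function(hrf, dt_s, shift_s = 0) {
  t <- seq(0, hrf$duration_s, by = dt_s) - shift_s
  a1 <- hrf$response_delay_s / hrf$response_dispersion
  a2 <- hrf$undershoot_delay_s / hrf$undershoot_dispersion
  h <- stats::dgamma(t, shape = a1, scale = hrf$response_dispersion) -
    stats::dgamma(t, shape = a2, scale = hrf$undershoot_dispersion) / hrf$ratio
  h[t < 0] <- 0
  h / max(h) # unit peak for the base kernel
}

#' Boxcar neuronal train for a schedule
#'
#' Each block contributes four phrase boxcars scaled by the habituation
#' amplitudes (or, in `"block"` mode, one 11 s boxcar at amplitude 1).
#'
#' @param schedule A `dot_schedule`.
#' @param habituation A `dot_habituation`.
#' @param dt_s Sampling interval (s), must be <= 0.5 for convolution accuracy.
#' @param t_end_s End of the time grid; default covers the last block + 40 s.
#' @param mode `"phrases"` (default): four phrase boxcars per block;
#'   `"block"`: single whole-block boxcar.
#' @param conditions Restrict to these conditions (default: all present).
#' @return Tibble `time_s`, one column per condition, plus `total`.
#' @export
neuronal_train <- function(schedule, habituation = habituation_profile(),
                           dt_s = 0.1, t_end_s = NULL,
                           mode = c("phrases", "block"),
                           conditions = NULL) {
  mode <- match.arg(mode)
  if (dt_s > 0.5) rlang::abort("dt_s must be <= 0.5 s for convolution accuracy")
  hp <- habituation
  n_phr <- length(hp$amplitudes)
  span <- n_phr * hp$phrase_duration_s + (n_phr - 1) * hp$phrase_gap_s
  if (span > max(schedule$duration_s) + 1e-9) {
    rlang::abort("phrases exceed block duration")
  }
  if (is.null(t_end_s)) t_end_s <- max(schedule$onset_s) + max(schedule$duration_s) + 40
  time_s <- seq(0, t_end_s, by = dt_s)
  if (is.null(conditions)) conditions <- unique(schedule$condition)
  cols <- lapply(conditions, function(cc) {
    x <- numeric(length(time_s))
    on <- schedule$onset_s[schedule$condition == cc]
    for (o in on) {
      if (mode == "block") {
        x <- x + as.numeric(time_s >= o & time_s < o + schedule$duration_s[1])
      } else {
        for (p in seq_len(n_phr)) {
          p0 <- o + (p - 1) * (hp$phrase_duration_s + hp$phrase_gap_s)
          x <- x + hp$amplitudes[p] *
            as.numeric(time_s >= p0 & time_s < p0 + hp$phrase_duration_s)
        }
      }
    }
    x
  })
  names(cols) <- conditions
  out <- tibble::tibble(time_s = time_s, !!!cols)
  out$total <- rowSums(as.matrix(out[, conditions]))
  out
}

#' Simulate HbO2 / HbR / HbT responses to a stimulus train
#'
#' Convolves the habituated boxcar train with the canonical HRF. HbO2 is the
#' convolution with the time-shifted kernel; HbR is the convolution with the
#' base kernel scaled by `hbr_scale`; HbT = HbO2 + HbR pointwise.
#'
#' @inheritParams neuronal_train
#' @param hrf A `dot_hrf`.
#' @param amplitude_scale Multiplies all outputs (arbitrary units; set to a
#'   concentration to obtain uM).
#' @return Tibble with `time_s`, `condition`, `hbo2`, `hbr`, `hbt` (long).
#' @export
simulate_response <- function(schedule, habituation = habituation_profile(),
                              hrf = canonical_hrf(), dt_s = 0.1,
                              t_end_s = NULL, mode = c("phrases", "block"),
                              amplitude_scale = 1) {
  mode <- match.arg(mode)
  tr <- neuronal_train(schedule, habituation, dt_s, t_end_s, mode)
  conds <- setdiff(names(tr), c("time_s", "total"))
  k_base <- hrf_kernel(hrf, dt_s, shift_s = 0)
  k_shift <- hrf_kernel(hrf, dt_s, shift_s = hrf$hbo2_shift_s)
  conv_full <- function(x, k) {
    y <- stats::convolve(x, rev(k), type = "open") * dt_s
    y[seq_along(x)]
  }
  purrr::map_dfr(conds, function(cc) {
    x <- tr[[cc]]
    hbo2 <- conv_full(x, k_shift) * amplitude_scale
    hbr <- conv_full(x, k_base) * hrf$hbr_scale * amplitude_scale
    tibble::tibble(time_s = tr$time_s, condition = cc,
                   hbo2 = hbo2, hbr = hbr, hbt = hbo2 + hbr)
  })
}

#' Simulated single-block HbT response shape
#'
#' Convenience: the response to one isolated block starting at t = 0,
#' returned on a lag grid; used as the planted ground-truth HbT time course
#' by the data generator.
#'
#' @inheritParams simulate_response
#' @param lags_s Lag grid (s) relative to block onset.
#' @export
block_response_shape <- function(habituation = habituation_profile(),
                                 hrf = canonical_hrf(), dt_s = 0.1,
                                 lags_s = seq(-5, 30, by = 1),
                                 mode = "phrases") {
  sch <- tibble::tibble(onset_s = 40, duration_s = 11, condition = "stim")
  class(sch) <- c("dot_schedule", class(sch))
  sim <- simulate_response(sch, habituation, hrf, dt_s = dt_s,
                           t_end_s = 40 + max(lags_s) + 5, mode = mode)
  stats::approx(sim$time_s - 40, sim$hbt, xout = lags_s, rule = 2)$y
}
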