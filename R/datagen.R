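# Synthetic channel-data generator: forward-projects known voxel activations
# through the sensitivity matrix and adds global physiology, drift,
# oscillations, photon noise and movement artifacts.

#' Specify planted activations and noise structure
#'
#' Activations are Gaussian blobs of peak total-hemoglobin change (uM),
#' supported on gray-matter voxels, one or more per condition. Noise terms
#' emulate the statistical structure of infant optical recordings: a shared
#' superficial/global physiological signal (band-limited 0.01-0.1 Hz) whose
#' coupling grows as source-detector separation shrinks, slow drift, an
#' aliased cardiac line, photon (shot) noise in log-amplitude, and sparse
#' high-amplitude movement artifacts with ground-truth annotations.
#'
#' @param blobs Tibble with columns `condition`, `x_mm`, `y_mm`, `z_mm`
#'   (blob center), `sigma_mm`, `peak_um` (peak HbT change in uM). May have
#'   zero rows for a null recording.
#' @param global_amp Amplitude (log-units SD) of the global physiological
#'   signal before coupling.
#' @param global_band_hz Passband of the global signal (Hz).
#' @param coupling_decay_mm SDS scale of superficial coupling
#'   `exp(-sds / coupling_decay_mm)`.
#' @param drift_sd Log-units SD of slow per-channel drift over the recording.
#' @param cardiac_amp,cardiac_hz Amplitude (log-units) and frequency of the
#'   cardiac sinusoid (aliased by the frame rate).
#' @param shot_sd Per-sample log-amplitude photon-noise SD.
#' @param artifact_rate_per_min Expected movement artifacts per minute.
#' @param artifact_amp_mult Artifact amplitude as a multiple of the total
#'   background signal SD.
#' @param extinction_hbt Extinction coefficient of total hemoglobin at the
#'   working wavelength, 1/(mM mm); converts uM HbT to 1/mm absorption.
#' @param seed Integer seed.
#' @return A `dot_activation_spec` list.
#' @export
activation_spec <- function(blobs = tibble::tibble(condition = character(),
                                                   x_mm = numeric(), y_mm = numeric(),
                                                   z_mm = numeric(), sigma_mm = numeric(),
                                                   peak_um = numeric()),
                            global_amp = 2e-3,
                            global_band_hz = c(0.01, 0.1),
                            coupling_decay_mm = 15,
                            drift_sd = 2e-3,
                            cardiac_amp = 5e-4,
                            cardiac_hz = 1.1,
                            shot_sd = 5e-4,
                            artifact_rate_per_min = 0.4,
                            artifact_amp_mult = 10,
                            extinction_hbt = 0.1,
                            seed = 1) {
  stopifnot(global_amp >= 0, drift_sd >= 0, cardiac_amp >= 0, shot_sd >= 0,
            artifact_rate_per_min >= 0, extinction_hbt > 0)
  structure(list(
    blobs = tibble::as_tibble(blobs),
    global_amp = global_amp, global_band_hz = global_band_hz,
    coupling_decay_mm = coupling_decay_mm, drift_sd = drift_sd,
    cardiac_amp = cardiac_amp, cardiac_hz = cardiac_hz, shot_sd = shot_sd,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_amp_mult = artifact_amp_mult,
    extinction_hbt = extinction_hbt, seed = seed
  ), class = "dot_activation_spec")
}

# Gaussian blob evaluated on the sensitivity matrix's voxel set, restricted
# to gray matter; returns a per-column uM map.
blob_map <- function(S, head, x_mm, y_mm, z_mm, sigma_mm, peak_um) {
  gs <- S$grid_shape
  vs <- S$voxel_size_mm
  ijk <- arrayInd(S$voxel_index, gs) - 1L
  cx <- ijk[, 1] * vs + vs / 2
  cy <- ijk[, 2] * vs + vs / 2
  cz <- ijk[, 3] * vs + vs / 2
  if (x_mm < 0 || y_mm < 0 || z_mm < 0 ||
      x_mm > gs[1] * vs || y_mm > gs[2] * vs || z_mm > gs[3] * vs) {
    rlang::abort("activation center outside the grid")
  }
  d2 <- (cx - x_mm)^2 + (cy - y_mm)^2 + (cz - z_mm)^2
  m <- peak_um * exp(-d2 / (2 * sigma_mm^2))
  gm <- head$tissue_levels[head$labels][S$voxel_index] == "gm"
  m[!gm] <- 0
  m
}

#' Per-condition planted HbT maps (uM) for an activation spec
#' @param spec A `dot_activation_spec`.
#' @param S A `dot_sensitivity`.
#' @param head The `dot_head_model`.
#' @return Named list of per-voxel-column uM maps, one per condition present.
#' @export
activation_maps <- function(spec, S, head) {
  if (nrow(spec$blobs) == 0) return(list())
  conds <- unique(spec$blobs$condition)
  maps <- lapply(conds, function(cc) {
    rows <- spec$blobs[spec$blobs$condition == cc, ]
    m <- numeric(ncol(S$J))
    for (i in seq_len(nrow(rows))) {
      m <- m + blob_map(S, head, rows$x_mm[i], rows$y_mm[i], rows$z_mm[i],
                        rows$sigma_mm[i], rows$peak_um[i])
    }
    m
  })
  names(maps) <- conds
  maps
}

# band-limited Gaussian signal via FFT shaping (deterministic under seed)
bandlimited_noise <- function(n, dt_s, band_hz, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- rnorm(n)
  f <- seq(0, 1 / dt_s, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, 1 / dt_s - f) # two-sided frequency magnitude
  keep <- f >= band_hz[1] & f <= band_hz[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * sd_target
}

#' Generate a synthetic channel recording
#'
#' Forward model in log-amplitude (Rytov convention, matching the sensitivity
#' matrix): per channel,
#' \deqn{\log A(t) = \log A_0 - J \Delta\mu_a(t) + w \cdot g(t) + d(t) + c(t) + \epsilon(t)}
#' where \eqn{\Delta\mu_a(t)} is the planted per-condition activation map
#' modulated by the simulated block HbT time course and converted from uM via
#' the Beer-Lambert extinction coefficient; \eqn{w = \exp(-SDS/\tau)} couples
#' the shared global signal more strongly into short channels; d is slow
#' drift, c an aliased cardiac sinusoid and \eqn{\epsilon} photon noise.
#' Movement artifacts are inserted as high-amplitude transients with matching
#' annotation rows. Everything is reproducible from the spec seed.
#'
#' Amplitudes are produced on the native ~1.2 s frame grid with a per-source
#' scan offset (sources are activated sequentially within a frame), so
#' resampling to a common time base is a real operation downstream.
#'
#' @param head A `dot_head_model`.
#' @param S A `dot_sensitivity` consistent with `head` and its probe.
#' @param schedule A `dot_schedule`.
#' @param spec A `dot_activation_spec`.
#' @param hrf A `dot_hrf`.
#' @param habituation A `dot_habituation`.
#' @param frame_interval_s Native frame interval (s), default 1.2.
#' @param baseline_amplitude Mean raw intensity A0 (arbitrary units).
#' @return A `dot_recording` (`signal = "intensity"`); `meta$truth` holds the
#'   planted uM maps, the block HbT shape, the noise-free channel projection
#'   and the ground-truth artifact table.
#' @export
generate_recording <- function(head, S, schedule, spec = activation_spec(),
                               hrf = canonical_hrf(),
                               habituation = habituation_profile(),
                               frame_interval_s = 1.2,
                               baseline_amplitude = 1e4) {
  t_end <- max(schedule$onset_s) + max(schedule$duration_s) + 40
  times <- seq(0, t_end, by = frame_interval_s)
  nt <- length(times)
  ch <- S$channels
  nch <- nrow(ch)
  nsrc <- max(ch$source)
  offsets <- (ch$source - 1) / nsrc * frame_interval_s

  maps <- activation_maps(spec, S, head)
  # block HbT shape (unit peak) evaluated where needed; linear forward model
  # means each condition contributes (J map) x course(t)
  shape_lags <- seq(-5, 40, by = 0.2)
  shape <- block_response_shape(habituation, hrf, dt_s = 0.1, lags_s = shape_lags)
  pk <- max(abs(shape))
  if (pk > 0) shape <- shape / pk
  y_act <- matrix(0, nch, nt) # -dlog amplitude from activation
  for (cc in names(maps)) {
    jm <- as.numeric(S$J %*% (maps[[cc]] * 1e-3 * spec$extinction_hbt))
    on <- schedule$onset_s[schedule$condition == cc]
    # the scan offset depends only on the source, so the modulation course is
    # shared by all channels of a source
    for (s in unique(ch$source)) {
      rows <- which(ch$source == s)
      tk <- times + offsets[rows[1]]
      gk <- numeric(nt)
      for (o in on) {
        gk <- gk + stats::approx(shape_lags, shape, xout = tk - o,
                                 yleft = 0, yright = 0)$y
      }
      y_act[rows, ] <- y_act[rows, , drop = FALSE] + outer(jm[rows], gk)
    }
  }

  noise <- withr::with_seed(spec$seed, {
    g <- bandlimited_noise(nt, frame_interval_s, spec$global_band_hz, spec$global_amp)
    w <- exp(-ch$sds_mm / spec$coupling_decay_mm)
    drift <- matrix(0, nch, nt)
    if (spec$drift_sd > 0) {
      tt <- (times - mean(times)) / (diff(range(times)) / 2)
      for (k in seq_len(nch)) {
        cf <- rnorm(2, 0, spec$drift_sd)
        drift[k, ] <- cf[1] * tt + cf[2] * (tt^2 - mean(tt^2))
      }
    }
    cardiac <- if (spec$cardiac_amp > 0) {
      ph <- runif(1, 0, 2 * pi)
      outer(rep(spec$cardiac_amp, nch),
            sin(2 * pi * spec$cardiac_hz * times + ph))
    } else matrix(0, nch, nt)
    shot <- if (spec$shot_sd > 0) {
      matrix(rnorm(nch * nt, 0, spec$shot_sd), nch, nt)
    } else matrix(0, nch, nt)

    # movement artifacts: Poisson events, 1-3 s, all channels, with labels
    dur_min <- t_end / 60
    n_art <- stats::rpois(1, spec$artifact_rate_per_min * dur_min)
    art <- tibble::tibble(onset_s = numeric(), duration_s = numeric(), label = character())
    art_sig <- matrix(0, nch, nt)
    if (n_art > 0) {
      onsets <- sort(runif(n_art, 5, t_end - 5))
      durs <- runif(n_art, 1, 3)
      labels <- sample(c("movement", "crying", "noise"), n_art, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15))
      bg_sd <- sqrt(spec$global_amp^2 + spec$shot_sd^2 + spec$drift_sd^2 +
                      spec$cardiac_amp^2)
      for (a in seq_len(n_art)) {
        idx <- which(times >= onsets[a] & times <= onsets[a] + durs[a])
        if (length(idx) == 0) next
        # movement artifacts are spiky, broad-band transients
        art_sig[, idx] <- art_sig[, idx] +
          matrix(rnorm(nch * length(idx), 0, spec$artifact_amp_mult * bg_sd),
                 nch, length(idx))
      }
      art <- tibble::tibble(onset_s = onsets, duration_s = durs, label = labels)
    }
    list(global = g, w = w, drift = drift, cardiac = cardiac, shot = shot,
         art = art, art_sig = art_sig)
  })

  log_amp <- log(baseline_amplitude) - y_act +
    outer(noise$w, noise$global) + noise$drift + noise$cardiac + noise$shot +
    noise$art_sig
  amplitudes <- exp(log_amp)

  trig <- tibble::tibble(onset_s = schedule$onset_s, condition = schedule$condition)
  new_recording(
    amplitudes, times, ch |> dplyr::mutate(time_offset_s = offsets,
                                           wavelength_nm = head$wavelength_nm),
    triggers = trig, annotations = noise$art,
    signal = "intensity",
    meta = list(
      frame_interval_s = frame_interval_s, seed = spec$seed,
      truth = list(maps_um = maps, shape_lags_s = shape_lags,
                   hbt_shape = shape, y_act = y_act,
                   artifacts = noise$art),
      extinction_hbt = spec$extinction_hbt
    )
  )
}
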