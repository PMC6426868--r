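# Resampling, bandpass contract, superficial signal regression, artifact
# detection, trigger exclusion.

test_that("resampling a uniform 1 Hz recording is the identity", {
  x <- matrix(rnorm(3 * 50), 3, 50)
  rec <- matrix_recording(x, rate_hz = 1)
  out <- resample_to_common_base(rec, 1)
  expect_equal(out$amplitudes, x[, match(out$times_s, rec$times_s)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("linear interpolation is exact on affine signals", {
  tt <- seq(0, 120, by = 1.2)
  x <- rbind(2 + 0.5 * tt, 5 - 0.1 * tt)
  ch <- tibble::tibble(source = 1:2, detector = 1:2, sds_mm = 30,
                       time_offset_s = c(0, 0.3))
  x[2, ] <- 5 - 0.1 * (tt + 0.3)
  rec <- new_recording(x, tt, ch, signal = "od")
  out <- resample_to_common_base(rec, 1)
  expect_equal(out$amplitudes[1, ], 2 + 0.5 * out$times_s, tolerance = 1e-10)
  expect_equal(out$amplitudes[2, ], 5 - 0.1 * out$times_s, tolerance = 1e-10)
})

test_that("interpolation error on a slow sinusoid is within the h^2 bound", {
  f <- 0.05
  tt <- seq(0, 200, by = 1.2)
  x <- matrix(sin(2 * pi * f * tt), 1)
  rec <- matrix_recording(x, rate_hz = 1)
  rec$times_s <- tt
  rec <- validate_recording(rec)
  out <- resample_to_common_base(rec, 1)
  truth <- sin(2 * pi * f * out$times_s)
  bound <- 1.2^2 * (2 * pi * f)^2 / 8 # h^2 max|f''| / 8
  expect_lt(max(abs(out$amplitudes[1, ] - truth)), bound + 1e-12)
})

test_that("excessive upsampling is refused", {
  x <- matrix(rnorm(20), 1)
  rec <- matrix_recording(x, rate_hz = 1)
  expect_error(resample_to_common_base(rec, 20), "upsample")
})

test_that("bandpass removes DC and meets the -3 dB contract", {
  rate <- 1
  tt <- seq(0, 4999, by = 1)
  dc <- matrix(3, 1, length(tt))
  rec <- matrix_recording(dc, rate_hz = rate)
  out <- bandpass(rec)
  expect_lt(max(abs(out$amplitudes)), 1e-6)

  gain_at <- function(f) {
    x <- matrix(sin(2 * pi * f * tt), 1)
    r <- bandpass(matrix_recording(x, rate_hz = rate))
    fitted_amplitude(r$amplitudes[1, ], tt, f)
  }
  g_mid <- gain_at(sqrt(0.007 * 0.2))
  expect_gt(g_mid, 0.95); expect_lt(g_mid, 1.05)
  g_pass <- gain_at(0.05)
  expect_gt(g_pass, 0.95); expect_lt(g_pass, 1.05)
  db <- function(g) 20 * log10(g)
  expect_lt(abs(db(gain_at(0.007)) + 3), 0.5)
  expect_lt(abs(db(gain_at(0.2)) + 3), 0.5)
})

test_that("short recordings warn but still filter", {
  x <- matrix(rnorm(60), 1)
  rec <- matrix_recording(x, rate_hz = 1)
  expect_warning(bandpass(rec), "3 periods")
})

test_that("SSR residuals are orthogonal to the regressor", {
  withr::with_seed(41, {
    g <- rnorm(300)
    brain <- rnorm(300)
    x <- rbind(g, g, brain + 0.8 * g, 0.3 * g - 0.2 * brain)
  })
  rec <- matrix_recording(x, sds_mm = c(8, 10, 30, 35))
  out <- superficial_signal_regression(rec, 12)
  reg <- out$meta$ssr_regressor
  for (k in 3:4) {
    expect_lt(abs(stats::cor(out$amplitudes[k, ], reg)), 1e-10)
  }
  # channels equal to the short-channel average are annihilated outright
  expect_lt(max(abs(out$amplitudes[1, ])), 1e-10)
  expect_lt(max(abs(out$amplitudes[2, ])), 1e-10)
})

test_that("SSR recovers an orthogonal brain signal at r > 0.99", {
  withr::with_seed(42, {
    g <- rnorm(500)
    brain <- stats::residuals(stats::lm(rnorm(500) ~ g)) # orthogonal by construction
  })
  x <- rbind(g, brain + 0.8 * g)
  rec <- matrix_recording(x, sds_mm = c(8, 30))
  out <- superficial_signal_regression(rec, 12)
  expect_gt(stats::cor(out$amplitudes[2, ], brain), 0.99)
})

test_that("a zero regressor degenerates to mean-centering", {
  withr::with_seed(43, x <- rbind(rep(0, 100), rnorm(100, mean = 5)))
  rec <- matrix_recording(x, sds_mm = c(8, 30))
  out <- superficial_signal_regression(rec, 12)
  expect_equal(out$amplitudes[2, ], x[2, ] - mean(x[2, ]), tolerance = 1e-12)
})

test_that("SSR without short channels errors or passes through", {
  x <- matrix(rnorm(60), 2, 30)
  rec <- matrix_recording(x, sds_mm = c(20, 30))
  expect_error(superficial_signal_regression(rec, 12), "short-channel")
  expect_warning(out <- superficial_signal_regression(rec, 12, "passthrough"),
                 "skipped")
  expect_equal(out$amplitudes, x, ignore_attr = TRUE)
})

test_that("SSR is idempotent and commutes with channel permutation", {
  withr::with_seed(44, x <- matrix(rnorm(5 * 200), 5, 200))
  sds <- c(8, 9, 25, 30, 40)
  rec <- matrix_recording(x, sds_mm = sds)
  once <- superficial_signal_regression(rec, 12)
  twice <- superficial_signal_regression(once, 12)
  expect_equal(twice$amplitudes, once$amplitudes, tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  rec_p <- matrix_recording(x[perm, ], sds_mm = sds[perm])
  out_p <- superficial_signal_regression(rec_p, 12)
  expect_equal(out_p$amplitudes, once$amplitudes[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("clean white noise is almost never flagged at k = 7", {
  withr::with_seed(45, x <- matrix(rnorm(4 * 2000), 4, 2000))
  rec <- matrix_recording(x)
  det <- detect_artifacts(rec, k = 7)
  bound <- 2 * (2 * stats::pnorm(-7)) * 4 * 2000 + 3 # Gaussian tail + margin
  expect_lte(det$n_flagged, bound)
})

test_that("a 10xSD transient is flagged at any k in [3.5, 7]", {
  withr::with_seed(46, x <- matrix(rnorm(2 * 800), 2, 800))
  x[1, 400:402] <- 10 * stats::sd(x[1, ])
  rec <- matrix_recording(x)
  for (k in c(3.5, 5, 7)) {
    det <- detect_artifacts(rec, k = k)
    expect_true(all(det$mask[400:402]))
  }
})

test_that("annotation-only input reproduces the annotated intervals", {
  x <- matrix(0, 1, 100) + 1e-9 * sin(seq_len(100))
  rec <- matrix_recording(x)
  ann <- tibble::tibble(onset_s = 20, duration_s = 5, label = "movement")
  det <- detect_artifacts(rec, k = 7, external_annotations = ann)
  expect_equal(which(det$mask), which(rec$times_s >= 20 & rec$times_s <= 25))
})

test_that("auto-k lies in [3.5, 7] and catches >= 5xSD artifacts", {
  sc <- small_scene()
  sch <- make_schedule(3, seed = 47)
  spec <- activation_spec(artifact_rate_per_min = 1, artifact_amp_mult = 5,
                          seed = 48)
  rec <- generate_recording(sc$head, sc$S, sch, spec)
  pre <- resample_to_common_base(rec, 1)
  pre <- optical_density(pre)
  det <- detect_artifacts(pre, k = "auto")
  expect_gte(det$k, 3.5); expect_lte(det$k, 7)
  truth <- rec$meta$truth$artifacts
  expect_gt(nrow(truth), 0)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    idx <- pre$times_s >= truth$onset_s[i] & pre$times_s <= truth$onset_s[i] + truth$duration_s[i]
    any(det$threshold_mask[idx])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("trigger exclusion honors epoch overlap and the >=5 rule", {
  trig <- tibble::tibble(onset_s = c(30, 90, 150, 210, 270, 330),
                         condition = rep("happy", 6))
  times <- seq(0, 400)
  # empty mask: everything retained
  res <- exclude_triggers(trig, rep(FALSE, length(times)), times)
  expect_equal(nrow(res$retained), 6)
  expect_true(res$included)
  # one masked sample touching an epoch boundary excludes that trigger
  mask <- times == 48 # trigger at 30 spans [29, 48]
  res2 <- exclude_triggers(trig, mask, times)
  expect_equal(nrow(res2$retained), 5)
  expect_false(30 %in% res2$retained$onset_s)
  expect_true(res2$included)
  # a condition left with 4 clean repetitions fails inclusion
  mask2 <- times %in% c(30, 90)
  res3 <- exclude_triggers(trig, mask2, times)
  expect_equal(res3$reps$n_clean, 4)
  expect_false(res3$included)
})

test_that("rerunning SSR after the full chain changes nothing", {
  sc <- small_scene()
  sch <- make_schedule(2, seed = 49)
  rec <- generate_recording(sc$head, sc$S, sch, activation_spec(seed = 50))
  pre <- preprocess(rec, preprocess_config(artifact_k = 5))
  again <- superficial_signal_regression(pre$recording, 12)
  expect_equal(again$amplitudes, pre$recording$amplitudes, tolerance = 1e-8)
})
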