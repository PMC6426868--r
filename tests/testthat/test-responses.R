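# FIR deconvolution, baseline correction, window magnitude.

# recording with responses injected at known onsets
injected_recording <- function(course, onsets, conditions, n_time, nch = 2,
                               lags = seq(-5, 30), noise_sd = 0) {
  x <- matrix(0, nch, n_time)
  tt <- seq(0, n_time - 1)
  for (i in seq_along(onsets)) {
    idx <- onsets[i] + lags
    ok <- idx >= 0 & idx < n_time
    for (k in seq_len(nch)) {
      x[k, idx[ok] + 1] <- x[k, idx[ok] + 1] + course[[conditions[i]]][ok] * k
    }
  }
  if (noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, noise_sd), nch)
  matrix_recording(x, triggers = tibble::tibble(onset_s = onsets,
                                                condition = conditions))
}

hbt_course <- function(lags = seq(-5, 30)) {
  block_response_shape(lags_s = lags)
}

test_that("deconvolution equals the epoch average for separated epochs", {
  course <- list(happy = hbt_course())
  onsets <- c(40, 120, 200, 280)
  rec <- injected_recording(course, onsets, rep("happy", 4), 360)
  resp <- deconvolve_responses(rec, lag_range_s = c(-5, 30))
  # epoch-average oracle
  for (k in 1:2) {
    epochs <- sapply(onsets, function(o) rec$amplitudes[k, o + seq(-5, 30) + 1])
    expect_equal(resp$coef[, k, "happy"], rowMeans(epochs), tolerance = 1e-8)
  }
})

test_that("overlapping conditions are separated exactly when full rank", {
  course <- list(happy = hbt_course(), neutral = -0.5 * hbt_course())
  onsets <- c(40, 55, 100, 130, 170, 205, 240, 270)
  conds <- rep(c("happy", "neutral"), 4)
  rec <- injected_recording(course, onsets, conds, 340)
  resp <- deconvolve_responses(rec, lag_range_s = c(-5, 30))
  expect_equal(resp$coef[, 1, "happy"], course$happy, tolerance = 1e-8)
  expect_equal(resp$coef[, 1, "neutral"], course$neutral, tolerance = 1e-8)
})

test_that("zero recordings give zero responses", {
  rec <- matrix_recording(matrix(0, 2, 200),
                          triggers = tibble::tibble(onset_s = c(50, 120),
                                                    condition = c("happy", "sad")))
  resp <- deconvolve_responses(rec)
  expect_equal(max(abs(resp$coef)), 0)
})

test_that("coincident triggers give a rank-deficiency error", {
  rec <- matrix_recording(matrix(rnorm(200), 1),
                          triggers = tibble::tibble(onset_s = c(50, 50),
                                                    condition = c("happy", "sad")))
  expect_error(deconvolve_responses(rec), "rank-deficient")
})

test_that("deconvolution is linear in the recording", {
  course_a <- list(happy = hbt_course())
  course_b <- list(happy = 2.5 * hbt_course())
  onsets <- c(40, 110, 180)
  ra <- injected_recording(course_a, onsets, rep("happy", 3), 260)
  rb <- injected_recording(course_b, onsets, rep("happy", 3), 260)
  rsum <- ra
  rsum$amplitudes <- ra$amplitudes + rb$amplitudes
  da <- deconvolve_responses(ra)$coef
  db <- deconvolve_responses(rb)$coef
  ds <- deconvolve_responses(rsum)$coef
  expect_equal(ds, da + db, tolerance = 1e-9)
})

test_that("masked samples are dropped from the fit", {
  course <- list(happy = hbt_course())
  onsets <- c(40, 120, 200)
  rec <- injected_recording(course, onsets, rep("happy", 3), 280)
  # corrupt some samples of the second epoch, then mask them out
  bad <- 125:130
  rec$amplitudes[, bad + 1] <- 100
  mask <- rep(FALSE, 280); mask[bad + 1] <- TRUE
  resp <- deconvolve_responses(rec, mask = mask)
  clean <- injected_recording(course, onsets, rep("happy", 3), 280)
  ref <- deconvolve_responses(clean)
  expect_equal(resp$coef[, 1, 1], ref$coef[, 1, 1], tolerance = 1e-8)
})

test_that("baseline correction zeroes the pre-stimulus window and is idempotent", {
  course <- list(happy = hbt_course() + 2.5)
  rec <- injected_recording(course, c(40, 120), rep("happy", 2), 200)
  resp <- deconvolve_responses(rec)
  bc <- baseline_correct(resp)
  sel <- bc$lags_s >= -1 & bc$lags_s <= 0
  expect_equal(max(abs(apply(bc$coef[sel, , , drop = FALSE], c(2, 3), mean))), 0,
               tolerance = 1e-10)
  expect_equal(baseline_correct(bc)$coef, bc$coef, tolerance = 1e-12)
  # constant course collapses to zero
  const <- resp
  const$coef[] <- 4.2
  expect_equal(max(abs(baseline_correct(const)$coef)), 0, tolerance = 1e-12)
})

test_that("baseline correction needs the baseline window in the lag range", {
  rec <- matrix_recording(matrix(rnorm(200), 1),
                          triggers = tibble::tibble(onset_s = 100, condition = "happy"))
  resp <- deconvolve_responses(rec, lag_range_s = c(2, 20))
  expect_error(baseline_correct(resp), "baseline")
})

test_that("window magnitude matches a numeric integration oracle", {
  lags <- seq(-5, 30)
  sim <- hbt_course(lags)
  resp <- structure(list(
    coef = array(sim, dim = c(length(lags), 1, 1), dimnames = list(NULL, NULL, "happy")),
    lags_s = lags, conditions = "happy", n_reps = c(happy = 1),
    baseline_window_s = c(-1, 0), magnitude_window_s = c(2, 18),
    baseline_corrected = TRUE
  ), class = "dot_responses")
  mag <- window_magnitude(resp)
  # oracle: direct quadrature of the same course over [2, 18]
  oracle <- mean(sim[lags >= 2 & lags <= 18])
  expect_equal(mag$magnitude, oracle, tolerance = 1e-12)
  fine <- block_response_shape(lags_s = seq(2, 18, by = 0.05))
  expect_equal(mag$magnitude, mean(fine), tolerance = 0.1)
  # zero course
  resp$coef[] <- 0
  expect_equal(window_magnitude(resp)$magnitude, 0)
})

test_that("extending the window changes the magnitude only slightly", {
  lags <- seq(-5, 30)
  sim <- hbt_course(lags)
  resp <- structure(list(
    coef = array(sim, dim = c(length(lags), 1, 1), dimnames = list(NULL, NULL, "happy")),
    lags_s = lags, conditions = "happy", n_reps = c(happy = 1),
    baseline_window_s = c(-1, 0), magnitude_window_s = c(2, 18),
    baseline_corrected = TRUE
  ), class = "dot_responses")
  m18 <- window_magnitude(resp, c(2, 18))$magnitude
  m21 <- window_magnitude(resp, c(2, 21))$magnitude
  expect_lt(abs(m21 - m18), 0.25 * abs(m18))
  expect_error(window_magnitude(resp, c(2, 40)), "outside")
})

test_that("planted amplitudes are recovered with small bias, RMSE shrinking in reps", {
  course <- list(happy = hbt_course())
  true_mag <- mean(course$happy[seq(-5, 30) >= 2 & seq(-5, 30) <= 18])
  rmse <- sapply(c(5, 10, 20), function(nrep) {
    errs <- sapply(1:8, function(r) {
      withr::with_seed(1000 + 17 * r + nrep, {
        onsets <- 40 + (seq_len(nrep) - 1) * 45
        rec <- injected_recording(course, onsets, rep("happy", nrep),
                                  max(onsets) + 40, nch = 1, noise_sd = 0.3)
        resp <- baseline_correct(deconvolve_responses(rec))
        window_magnitude(resp)$magnitude - true_mag
      })
    })
    c(bias = mean(errs), rmse = sqrt(mean(errs^2)))
  })
  expect_lt(abs(rmse["bias", 3]) / abs(true_mag), 0.05)
  expect_lt(rmse["rmse", 3], rmse["rmse", 1])
})
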