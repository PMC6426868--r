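# Group statistics: Bonferroni, Tukey-Kramer, global analysis, voxelwise
# maps, adaptive clustering, ROI analysis.

test_that("bonferroni is monotone, capped and validates input", {
  expect_equal(bonferroni(0.5, 120), 1)
  expect_equal(bonferroni(1e-4, 10), 1e-3)
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
  expect_true(all(bonferroni(p, 7) >= bonferroni(p, 3)))
  expect_true(all(bonferroni(p, 1000) <= 1))
  expect_error(bonferroni(1.2, 2), "0, 1")
  expect_error(bonferroni(0.5, 0), "n must")
})

test_that("tukey_kramer on two groups matches the pooled t-test", {
  withr::with_seed(71, {
    a <- rnorm(12); b <- rnorm(12, 0.8)
  })
  tk <- tukey_kramer(list(g1 = a, g2 = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, sqrt(2) * abs(unname(tt$statistic)), tolerance = 1e-9)
  # identical groups: p ~ 1
  tk0 <- tukey_kramer(list(g1 = a, g2 = a + 1e-14))
  expect_gt(tk0$p_value, 0.999)
})

test_that("tukey_kramer agrees with TukeyHSD as an independent reference", {
  withr::with_seed(72, {
    d <- data.frame(
      value = c(rnorm(10), rnorm(12, 0.5), rnorm(9, -0.3)),
      group = rep(c("a", "b", "c"), c(10, 12, 9))
    )
  })
  tk <- tukey_kramer(d, "value", "group")
  ref <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  for (i in seq_len(nrow(tk))) {
    key1 <- paste0(tk$group2[i], "-", tk$group1[i])
    key2 <- paste0(tk$group1[i], "-", tk$group2[i])
    key <- if (key1 %in% rownames(ref)) key1 else key2
    expect_equal(tk$p_value[i], ref[key, "p adj"], tolerance = 1e-8)
  }
})

test_that("a 5-SD shifted group dominates the pairwise flags", {
  hits <- sapply(1:60, function(r) {
    withr::with_seed(5000 + r, {
      g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10), d = rnorm(10) + 5)
    })
    tk <- tukey_kramer(g)
    sig <- tk$p_value < 0.05
    withd <- tk$group1 == "d" | tk$group2 == "d"
    all(sig[withd]) && !any(sig[!withd])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tukey_kramer validates group sizes", {
  expect_error(tukey_kramer(list(a = 1:3)), "2 groups")
  expect_error(tukey_kramer(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("global ANOVA holds its nominal type-I error on null data", {
  n_rep <- 400
  rej <- sapply(seq_len(n_rep), function(r) {
    withr::with_seed(9000 + r, {
      v <- rnorm(4 * 21)
    })
    d <- data.frame(value = v, condition = rep(c("n", "h", "a", "s"), each = 21))
    fit <- stats::aov(value ~ condition, data = d)
    summary(fit)[[1]][1, "Pr(>F)"] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("global analysis detects a shifted condition with Tukey attribution", {
  sc <- small_scene()
  hits <- sapply(1:30, function(r) {
    smp <- noise_group_sample(sc, 21, sd = 1, seed = 300 + r)
    # shift happy by +3 pooled SD at the subject-mean level: the spatial mean
    # over the mask averages voxel noise, so shift the subject means directly
    nv <- dim(smp$maps)[1]
    smp$maps[, "happy", ] <- smp$maps[, "happy", ] + 3
    g <- global_analysis(smp, positivity_mask = FALSE)
    tkpairs <- g$tukey
    if (is.null(tkpairs)) return(FALSE)
    sig <- tkpairs$p_value < 0.05
    withh <- tkpairs$group1 == "happy" | tkpairs$group2 == "happy"
    g$anova$p_value < 0.01 && all(sig[withh]) && !any(sig[!withh])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("global analysis respects the positivity mask", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 5, sd = 1, seed = 301)
  smp$maps <- smp$maps + 10 # all group means positive: mask = all GM in FOV
  g <- global_analysis(smp)
  expect_equal(g$n_mask_voxels, sum(sc$fov & smp$gm_mask))
  smp$maps <- smp$maps - 20 # all negative: empty mask
  expect_error(global_analysis(smp), "empty")
  expect_error(global_analysis(noise_group_sample(sc, 2, seed = 1)), "3 subjects")
})

test_that("tidy and glance summarize global results", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 8, sd = 1, seed = 302)
  g <- global_analysis(smp, positivity_mask = FALSE)
  td <- tidy(g)
  expect_equal(td$condition, c("speech_average", "neutral", "happy", "angry", "sad"))
  gl <- glance(g)
  expect_true(all(c("anova_p", "bartlett_p", "n_mask_voxels") %in% names(gl)))
})

test_that("voxelwise p-values are well calibrated under the null", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 21, sd = 1, seed = 303)
  for (tst in c("avg_vs_zero", "anova")) {
    pm <- voxelwise_pmap(smp, tst)
    ks <- stats::ks.test(pm$p, "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("planted effects drive voxelwise p below the seed threshold", {
  sc <- small_scene()
  sig <- matrix(0, length(sc$S$voxel_index), 4)
  blob <- infantdot:::blob_map(sc$S, sc$head, 24, 24, 10, 6, 1)
  sig[, 2] <- blob * 8 # strong happy effect
  smp <- noise_group_sample(sc, 21, signal = sig, sd = 1, seed = 304)
  pm <- voxelwise_pmap(smp, "anova")
  core <- which.max(blob)
  expect_lt(pm$p[core], 0.001)
})

test_that("condition-vs-baseline reduces to the one-sample test", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 10, sd = 1, seed = 305)
  pm1 <- voxelwise_pmap(smp, "condition_vs_baseline", condition = "happy")
  manual <- apply(smp$maps[, "happy", ], 1, function(v) stats::t.test(v)$p.value)
  expect_equal(pm1$p[1:50], manual[1:50], tolerance = 1e-10)
  expect_error(voxelwise_pmap(smp, "condition_vs_baseline"), "condition")
})

test_that("zero-variance voxels get p = 1 with a warning", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 6, sd = 1, seed = 306)
  smp$maps[1, , ] <- 0
  expect_warning(pm <- voxelwise_pmap(smp, "avg_vs_zero"), "zero-variance")
  expect_equal(pm$p[1], 1)
})

test_that("a planted blob becomes one sufficiently large cluster", {
  sc <- small_scene()
  sig <- matrix(0, length(sc$S$voxel_index), 4)
  blob <- infantdot:::blob_map(sc$S, sc$head, 24, 24, 10, 8, 1)
  for (k in 1:4) sig[, k] <- blob * 5
  smp <- noise_group_sample(sc, 21, signal = sig, sd = 1, seed = 307)
  sm <- smooth_group_sample(smp)
  pm <- voxelwise_pmap(sm, "avg_vs_zero")
  cl <- adaptive_cluster(pm, sm, min_vox = 200)
  expect_equal(nrow(cl$table), 1)
  expect_gte(cl$table$n_vox, 200)
  # the blob core is inside the cluster
  expect_true(sc$S$voxel_index[which.max(blob)] %in% cl$voxels[[1]])
  # nesting: seed set within level-2 within level-3
  lv <- cl$levels[[1]]
  expect_true(all(lv[[1]] %in% lv[[2]]))
  expect_true(all(lv[[2]] %in% lv[[3]]))
  # corrected p respects the Bonferroni identity
  expect_equal(cl$table$p_corrected,
               pmin(1, cl$table$p_uncorrected * 120))
})

test_that("seeds merging at a looser threshold become one cluster", {
  # two nearby seeds whose p < 0.01 regions connect
  sc <- small_scene()
  nv <- length(sc$S$voxel_index)
  smp <- noise_group_sample(sc, 10, sd = 1, seed = 308)
  ijk <- arrayInd(sc$S$voxel_index, sc$head$grid_shape)
  pvec <- rep(0.5, nv)
  in_gmfov <- (smp$gm_mask & smp$fov_mask)[sc$S$voxel_index]
  seed_a <- in_gmfov & ijk[, 1] %in% 9:10 & ijk[, 2] %in% 11:13 & ijk[, 3] %in% 5:9
  seed_b <- in_gmfov & ijk[, 1] %in% 14:15 & ijk[, 2] %in% 11:13 & ijk[, 3] %in% 5:9
  bridge <- in_gmfov & ijk[, 1] %in% 11:13 & ijk[, 2] %in% 11:13 & ijk[, 3] %in% 5:9
  pvec[seed_a | seed_b] <- 1e-5
  pvec[bridge] <- 0.005 # below 0.01, above 0.0033
  pm <- list(p = pvec, stat = NULL, test = "avg_vs_zero", condition = NULL)
  cl <- adaptive_cluster(pm, smp, min_vox = 1)
  expect_equal(nrow(cl$table), 1)
  # without the bridge: two clusters
  pvec[bridge] <- 0.5
  cl2 <- adaptive_cluster(list(p = pvec, stat = NULL, test = "avg_vs_zero",
                               condition = NULL), smp, min_vox = 1)
  expect_equal(nrow(cl2$table), 2)
})

test_that("undersized clusters are discarded", {
  sc <- small_scene()
  sig <- matrix(0, length(sc$S$voxel_index), 4)
  blob <- infantdot:::blob_map(sc$S, sc$head, 24, 24, 10, 2.5, 1)
  for (k in 1:4) sig[, k] <- blob * 6
  smp <- noise_group_sample(sc, 21, signal = sig, sd = 1, seed = 309)
  pm <- voxelwise_pmap(smp, "avg_vs_zero")
  cl <- adaptive_cluster(pm, smp, min_vox = 200)
  expect_equal(nrow(cl$table), 0)
  # but they are reported when the extent rule is relaxed
  cl2 <- adaptive_cluster(pm, smp, min_vox = 1)
  expect_gte(nrow(cl2$table), 1)
})

test_that("ROI analysis is null on zero images and flags planted contrasts", {
  sc <- full_scene()
  nv <- length(sc$S$voxel_index)
  zero <- group_sample(array(0, dim = c(nv, 4, 6)), sc$S$voxel_index,
                       sc$head$grid_shape, c("neutral", "happy", "angry", "sad"),
                       array(sc$head$tissue_levels[sc$head$labels] == "gm",
                             dim = sc$head$grid_shape), sc$fov, 2)
  suppressWarnings(r0 <- roi_analysis(zero))
  expect_true(all(r0$table$magnitude == 0))
  expect_false(any(r0$table$significant_uncorrected))

  # negative angry effect planted at the pSTS template center
  rois <- default_roi_set()
  ctr <- rois[rois$roi == "pSTS", ]
  sig <- matrix(0, nv, 4)
  sig[, 3] <- -6 * infantdot:::blob_map(sc$S, sc$head, ctr$x_mm, ctr$y_mm,
                                        ctr$z_mm, 8, 1)
  smp <- noise_group_sample(sc, 21, signal = sig, sd = 1, seed = 310)
  suppressWarnings(rr <- roi_analysis(smp))
  row <- rr$table[rr$table$roi == "pSTS" & rr$table$condition == "angry", ]
  expect_lt(row$magnitude, 0)
  expect_lt(row$p_value, 0.05)
})

test_that("radius-0 ROI equals single-voxel statistics", {
  sc <- small_scene()
  smp <- noise_group_sample(sc, 12, sd = 1, seed = 311)
  roi <- default_roi_set(radius_mm = 0,
                         template_affine = rbind(c(0, 1, 0, 28),
                                                 c(0, 0, 1, 24),
                                                 c(1, 0, 0, 38)))
  suppressWarnings(rr <- roi_analysis(smp, roi[1, ], radius_mm = 0))
  # oracle: nearest gray-matter voxel's own t-test
  ijk <- arrayInd(sc$S$voxel_index, sc$head$grid_shape) - 1L
  cx <- ijk[, 1] * 2 + 1; cy <- ijk[, 2] * 2 + 1; cz <- ijk[, 3] * 2 + 1
  gm_rows <- smp$gm_mask[sc$S$voxel_index]
  d2 <- (cx - roi$x_mm[1])^2 + (cy - roi$y_mm[1])^2 + (cz - roi$z_mm[1])^2
  d2[!gm_rows] <- Inf
  v <- smp$maps[which.min(d2), "happy", ]
  expect_equal(rr$table$p_value[rr$table$condition == "happy"],
               stats::t.test(v)$p.value, tolerance = 1e-10)
})
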