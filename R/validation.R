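# Parameter-recovery validation: null calibration of the clustering
# statistic and end-to-end recovery of a planted condition contrast.

#' Familywise-error calibration of adaptive clustering on null data
#'
#' Simulates group studies with no true effect: per replicate, iid Gaussian
#' magnitude maps for `n_subjects` subjects and four conditions on the
#' scene's reconstruction voxels, smoothed like real magnitude images, then
#' tested voxelwise and clustered with the full adaptive procedure
#' (seed/expansion thresholds, 200-voxel extent rule, Bonferroni N_MC).
#' Reports the fraction of replicates with any corrected-significant
#' cluster.
#'
#' @param scene A scene list (`head`, `S`, `fov`) as built by the pipeline.
#' @param n_replicates Number of simulated studies.
#' @param n_subjects Subjects per study (study design: 21).
#' @param seed Integer seed.
#' @param test Voxelwise group test driving the clustering.
#' @param smoothing_radius_vox Gaussian radius before clustering.
#' @param alpha Corrected significance level.
#' @param min_vox,n_mc Cluster extent rule and Bonferroni factor.
#' @return List: `fwer`, `n_replicates`, `hits` (logical per replicate).
#' @export
simulate_null_fwer <- function(scene, n_replicates = 200, n_subjects = 21,
                               seed = 1, test = "avg_vs_zero",
                               smoothing_radius_vox = 1.5, alpha = 0.05,
                               min_vox = 200, n_mc = 120) {
  nv <- length(scene$S$voxel_index)
  gm <- array(scene$head$tissue_levels[scene$head$labels] == "gm",
              dim = scene$head$grid_shape)
  bm <- brain_mask(scene$head)
  conds <- c("neutral", "happy", "angry", "sad")
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, n_replicates))
  hits <- vapply(seq_len(n_replicates), function(r) {
    maps <- withr::with_seed(rep_seeds[r], {
      array(rnorm(nv * 4 * n_subjects), dim = c(nv, 4, n_subjects))
    })
    smp <- group_sample(maps, scene$S$voxel_index, scene$head$grid_shape,
                        conds, gm, scene$fov, scene$head$voxel_size_mm)
    smp <- smooth_group_sample(smp, smoothing_radius_vox, bm)
    pm <- voxelwise_pmap(smp, test)
    cl <- adaptive_cluster(pm, smp, min_vox = min_vox, n_mc = n_mc)
    nrow(cl$table) > 0 && any(cl$table$p_corrected < alpha)
  }, logical(1))
  list(fwer = mean(hits), n_replicates = n_replicates, hits = hits)
}

# generate one synthetic subject for a config/scene (in memory)
generate_subject <- function(config, scene, hrf, hab, subject_seed, blobs = NULL) {
  dg <- config$datagen
  sch <- make_schedule(config$hemodynamics$n_blocks_per_condition,
                       seed = subject_seed,
                       block_duration_s = config$hemodynamics$block_duration_s,
                       rest_bounds_s = config$hemodynamics$rest_bounds_s)
  spec <- activation_spec(
    blobs = if (is.null(blobs)) tibble::tibble(condition = character(),
                                               x_mm = numeric(), y_mm = numeric(),
                                               z_mm = numeric(), sigma_mm = numeric(),
                                               peak_um = numeric()) else blobs,
    global_amp = dg$global_amp, global_band_hz = dg$global_band_hz,
    coupling_decay_mm = dg$coupling_decay_mm, drift_sd = dg$drift_sd,
    cardiac_amp = dg$cardiac_amp, cardiac_hz = dg$cardiac_hz,
    shot_sd = dg$shot_sd, artifact_rate_per_min = dg$artifact_rate_per_min,
    artifact_amp_mult = dg$artifact_amp_mult,
    extinction_hbt = dg$extinction_hbt, seed = subject_seed
  )
  generate_recording(scene$head, scene$S, sch, spec, hrf, hab,
                     frame_interval_s = dg$frame_interval_s)
}

#' End-to-end recovery of a planted happy > neutral contrast
#'
#' Runs the complete study simulation: a happy-condition activation blob is
#' planted in anterior temporal gray matter (the aSTS template center) at a
#' prescribed multiple of the between-subject noise SD, subjects are
#' generated with full physiology/noise/artifacts, and the standard pipeline
#' (preprocess, inclusion at >= 5 clean repetitions, deconvolution,
#' reconstruction, smoothing, ANOVA clustering with Tukey-Kramer post hoc,
#' ROI analysis) is applied to the first `n_subjects` included subjects —
#' mirroring a design that measures more infants than it analyzes.
#'
#' The planted amplitude is calibrated at run time: a null study measures
#' the between-subject SD of the reconstructed magnitude at the target
#' voxel, a noise-free planted recording measures the reconstruction gain,
#' and the blob peak is set so the reconstructed group effect equals
#' `effect_multiple` times the null SD.
#'
#' @param config A `dot_pipeline_config`.
#' @param n_subjects Analyzed (included) subjects, default 21.
#' @param seed Integer seed.
#' @param effect_multiple Planted effect size in units of between-subject
#'   noise SD (default 3).
#' @param sigma_mm Blob width (mm).
#' @param max_measured Cap on generated subjects while collecting included
#'   ones.
#' @param scene Optional precomputed scene.
#' @return List: `report` (full `dot_pipeline_report`), `anova_clusters`
#'   (tibble), `tukey` (per-cluster pairwise tables), `roi` (ROI stats),
#'   `planted` (calibration details), `n_measured`.
#' @export
planted_effect_study <- function(config = pipeline_config(), n_subjects = 21,
                                 seed = 1, effect_multiple = 3, sigma_mm = 8,
                                 max_measured = 90, scene = NULL) {
  if (is.null(scene)) scene <- build_scene(config)
  hrf <- config_hrf(config)
  hab <- config_habituation(config)
  rcfg <- do.call(reconstruction_config, config$reconstruct)
  op <- reconstruction_operator(scene$S, rcfg)
  rois <- default_roi_set(config$stats$roi_radius_mm)
  target <- rois[rois$roi == "aSTS", ]

  ijk <- arrayInd(scene$S$voxel_index, scene$head$grid_shape) - 1L
  vs <- scene$head$voxel_size_mm
  d2 <- (ijk[, 1] * vs + vs / 2 - target$x_mm)^2 +
    (ijk[, 2] * vs + vs / 2 - target$y_mm)^2 +
    (ijk[, 3] * vs + vs / 2 - target$z_mm)^2
  gm_rows <- scene$head$tissue_levels[scene$head$labels][scene$S$voxel_index] == "gm"
  d2[!gm_rows] <- Inf
  target_row <- which.min(d2)

  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, max_measured))

  # 1. null study: between-subject SD of the reconstructed magnitude at the
  #    target voxel (first n_subjects included null subjects)
  null_vals <- numeric(0)
  included_seeds <- integer(0)
  i <- 0
  while (length(null_vals) < n_subjects && i < max_measured) {
    i <- i + 1
    rec <- generate_subject(config, scene, hrf, hab, seeds[i])
    res <- analyze_subject(rec, config, op)
    if (isTRUE(res$included)) {
      avg <- rowMeans(res$magnitude_image$values)
      null_vals <- c(null_vals, avg[target_row])
      included_seeds <- c(included_seeds, seeds[i])
    }
  }
  if (length(null_vals) < 3) rlang::abort("too few included null subjects")
  sd_null <- stats::sd(null_vals)

  # 2. pipeline gain at the target under study conditions: paired runs with
  #    and without a reference blob, identical seeds (identical noise) and a
  #    shared artifact mask, so the reconstructed difference isolates the
  #    planted contrast through the full processing chain (incl. SSR)
  ref_um <- 10
  unit_blob <- tibble::tibble(condition = "happy", x_mm = target$x_mm,
                              y_mm = target$y_mm, z_mm = target$z_mm,
                              sigma_mm = sigma_mm, peak_um = ref_um)
  pcfg <- do.call(preprocess_config, config$preprocess)
  gains <- vapply(included_seeds[seq_len(min(3, length(included_seeds)))],
                  function(sd_i) {
    paired_mag <- function(blobs) {
      rec <- generate_subject(config, scene, hrf, hab, sd_i, blobs)
      pre <- preprocess(rec, pcfg)
      resp <- baseline_correct(deconvolve_responses(
        rec = pre$recording, triggers = rec$triggers,
        lag_range_s = config$responses$lag_range_s,
        mask = pre$artifacts$annotation_mask))
      mg <- window_magnitude(resp, config$responses$magnitude_window_s)
      y <- matrix(mg$magnitude, ncol = length(resp$conditions))
      img <- mua_to_hbt(reconstruct_mua(y, op), rcfg)
      img$values[target_row, resp$conditions == "happy"]
    }
    (paired_mag(unit_blob) - paired_mag(NULL)) / ref_um
  }, numeric(1))
  gain <- mean(gains)
  if (gain <= 0) rlang::abort("non-positive reconstruction gain at the target")

  peak_um <- effect_multiple * sd_null / gain
  blobs <- unit_blob
  blobs$peak_um <- peak_um

  # 3. planted study on fresh subjects, analyzing the first n_subjects that
  #    pass inclusion
  planted_seeds <- withr::with_seed(seed + 1L, sample.int(.Machine$integer.max - 1, max_measured))
  recs <- list()
  included <- 0
  n_measured <- 0
  pcfg <- do.call(preprocess_config, config$preprocess)
  while (included < n_subjects && n_measured < max_measured) {
    n_measured <- n_measured + 1
    rec <- generate_subject(config, scene, hrf, hab, planted_seeds[n_measured], blobs)
    pre_ok <- tryCatch({
      pre <- preprocess(rec, pcfg)
      pre$triggers$included
    }, error = function(e) FALSE)
    recs[[length(recs) + 1]] <- rec
    if (isTRUE(pre_ok)) included <- included + 1
  }
  report <- run_pipeline(config, recs, scene = scene,
                         cluster_tests = c("avg_vs_zero", "anova"),
                         max_included = n_subjects)

  # Tukey-Kramer on each ANOVA cluster's per-subject means
  anova_cl <- report$clusters[["anova"]]
  tukeys <- lapply(seq_along(anova_cl$voxels), function(ci) {
    vs_idx <- anova_cl$voxels[[ci]]
    pos <- match(vs_idx, report$sample_smoothed$voxel_index)
    pos <- pos[!is.na(pos)]
    cm <- apply(report$sample_smoothed$maps[pos, , , drop = FALSE], c(2, 3), mean)
    df <- tibble::tibble(
      value = as.vector(cm),
      condition = rep(report$sample_smoothed$conditions, times = ncol(cm))
    )
    tukey_kramer(df, "value", "condition")
  })

  list(report = report, anova_clusters = anova_cl$table, tukey = tukeys,
       roi = report$rois,
       planted = list(sd_null = sd_null, gain = gain, peak_um = peak_um,
                      target_row = target_row, target = target),
       n_measured = n_measured)
}
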