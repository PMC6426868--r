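# Pipeline orchestration: configuration, fixture generation, end-to-end run.

#' Pipeline configuration
#'
#' A nested configuration with one section per stage; every tunable named by
#' the other modules appears here exactly once. Round-trips losslessly
#' through YAML.
#'
#' @param ... Named overrides of nested fields, e.g.
#'   `phantom = list(grid_shape = c(30, 30, 30))` (merged over defaults).
#' @param seed Global integer seed.
#' @param output_dir Default output directory.
#' @return A `dot_pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1, output_dir = "infantdot-out") {
  defaults <- list(
    seed = seed,
    output_dir = output_dir,
    phantom = list(
      grid_shape = c(40, 40, 40),
      voxel_size_mm = 2,
      layer_thicknesses_mm = c(scalp = 2, skull = 2, csf = 1, gm = 20),
      wavelength_nm = 798,
      probe_layout = c(5, 6),
      probe_spacing_mm = 13,
      probe_style = "offset",
      max_sds_mm = 45,
      fov_threshold = 0.001
    ),
    hemodynamics = list(
      n_blocks_per_condition = 6,
      block_duration_s = 11,
      rest_bounds_s = c(20, 30),
      habituation_amplitudes = c(1, 0.6, 0.3, 0.2),
      phrase_duration_s = 2.2,
      phrase_gap_s = 0.7,
      hrf = list(response_delay_s = 6, undershoot_delay_s = 16,
                 response_dispersion = 1, undershoot_dispersion = 1,
                 ratio = 6, hbo2_shift_s = -1, hbr_scale = -1 / 6)
    ),
    datagen = list(
      frame_interval_s = 1.2,
      global_amp = 2e-3, global_band_hz = c(0.01, 0.1),
      coupling_decay_mm = 15, drift_sd = 2e-3,
      cardiac_amp = 5e-4, cardiac_hz = 1.1, shot_sd = 5e-4,
      artifact_rate_per_min = 0.4, artifact_amp_mult = 10,
      extinction_hbt = 0.1
    ),
    preprocess = list(
      target_rate_hz = 1, band_lo_hz = 0.007, band_hi_hz = 0.2,
      ssr_sds_mm = 12, artifact_k = "auto", min_reps_per_condition = 5,
      epoch_span_s = c(-1, 18)
    ),
    responses = list(lag_range_s = c(-5, 30),
                     baseline_window_s = c(-1, 0),
                     magnitude_window_s = c(2, 18)),
    reconstruct = list(lambda = 0.01, extinction_hbt = 0.1,
                       smoothing_radius_vox = 1.5, smoothing_is_fwhm = FALSE,
                       ridge = 1e-6),
    stats = list(p_thresholds = c(0.001, 0.0033, 0.01), min_cluster_vox = 200,
                 n_mc = 120, connectivity = 6, roi_radius_mm = 8,
                 n_roi_bonferroni = 6)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], over[[nm]])
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "dot_pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A `dot_pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors must become maps to keep their names in YAML
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(prep(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), c("seed", "output_dir"))])
  cfg$seed <- raw$seed
  cfg$output_dir <- raw$output_dir
  # YAML returns lists for vectors; renormalize numeric vectors
  renum <- function(x) {
    if (is.list(x) && length(x) > 0 && all(vapply(x, is.numeric, logical(1))) &&
        all(lengths(x) == 1) && is.null(names(x))) {
      unlist(x)
    } else if (is.list(x)) {
      lapply(x, renum)
    } else x
  }
  out <- renum(unclass(cfg))
  # named numeric vectors (layer thicknesses) come back as named lists
  lt <- out$phantom$layer_thicknesses_mm
  if (is.list(lt)) out$phantom$layer_thicknesses_mm <- unlist(lt)
  structure(out, class = "dot_pipeline_config")
}

# shared scene: phantom, probe, sensitivity, operator, fov
build_scene <- function(config) {
  ph <- config$phantom
  head <- build_layered_phantom(ph$grid_shape, ph$layer_thicknesses_mm,
                                ph$voxel_size_mm, wavelength_nm = ph$wavelength_nm)
  probe <- place_probe(head, ph$probe_layout, ph$probe_spacing_mm, ph$max_sds_mm,
                       style = ph$probe_style %||% "offset")
  S <- compute_jacobian(head, probe)
  fov <- compute_fov(S, head, ph$fov_threshold)
  list(head = head, probe = probe, S = S, fov = fov)
}

config_hrf <- function(config) do.call(canonical_hrf, config$hemodynamics$hrf)

config_habituation <- function(config) {
  h <- config$hemodynamics
  habituation_profile(h$habituation_amplitudes, h$phrase_duration_s, h$phrase_gap_s)
}

#' Generate a synthetic multi-subject fixture dataset
#'
#' Writes, per subject, a TSV-dialect recording, its stimulus schedule, and
#' the ground-truth activation summary; a manifest records every seed and
#' file hash so reruns are verifiable byte-for-byte.
#'
#' @param config A `dot_pipeline_config`.
#' @param n_subjects Number of subjects (the study design uses 21).
#' @param seed Global seed (overrides `config$seed` when given).
#' @param out_dir Dataset directory.
#' @param blobs Planted activation blob table (see [activation_spec()]);
#'   default none (null data).
#' @param force Overwrite an existing non-empty directory.
#' @param scene Optional precomputed scene from the same config (speeds up
#'   repeated calls).
#' @return The manifest (list), invisibly; written to `manifest.json`.
#' @export
make_fixtures <- function(config = pipeline_config(), n_subjects = 21,
                          seed = NULL, out_dir = config$output_dir,
                          blobs = NULL, force = FALSE, scene = NULL) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    rlang::abort("output directory exists and is not empty; use force = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(scene)) scene <- build_scene(config)
  hrf <- config_hrf(config)
  hab <- config_habituation(config)
  dg <- config$datagen
  subject_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, max(n_subjects, 1)))
  manifest <- list(seed = seed, n_subjects = n_subjects,
                   subject_seeds = subject_seeds[seq_len(n_subjects)],
                   subjects = list())
  for (i in seq_len(n_subjects)) {
    si <- subject_seeds[i]
    sch <- make_schedule(config$hemodynamics$n_blocks_per_condition, seed = si,
                         block_duration_s = config$hemodynamics$block_duration_s,
                         rest_bounds_s = config$hemodynamics$rest_bounds_s)
    spec <- activation_spec(
      blobs = if (is.null(blobs)) tibble::tibble(condition = character(), x_mm = numeric(),
                                                 y_mm = numeric(), z_mm = numeric(),
                                                 sigma_mm = numeric(), peak_um = numeric())
              else blobs,
      global_amp = dg$global_amp, global_band_hz = dg$global_band_hz,
      coupling_decay_mm = dg$coupling_decay_mm, drift_sd = dg$drift_sd,
      cardiac_amp = dg$cardiac_amp, cardiac_hz = dg$cardiac_hz,
      shot_sd = dg$shot_sd, artifact_rate_per_min = dg$artifact_rate_per_min,
      artifact_amp_mult = dg$artifact_amp_mult,
      extinction_hbt = dg$extinction_hbt, seed = si
    )
    rec <- generate_recording(scene$head, scene$S, sch, spec, hrf, hab,
                              frame_interval_s = dg$frame_interval_s)
    sdir <- file.path(out_dir, sprintf("sub-%02d", i))
    write_recording(rec, file.path(sdir, "recording"), "tsv")
    write_schedule(sch, file.path(sdir, "events.tsv"))
    files <- list.files(sdir, recursive = TRUE, full.names = TRUE)
    manifest$subjects[[i]] <- list(
      id = sprintf("sub-%02d", i), seed = si,
      hashes = as.list(tools::md5sum(files))
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# single-subject analysis: preprocess -> deconvolve -> reconstruct magnitudes
analyze_subject <- function(rec, config, recon_op) {
  pc <- do.call(preprocess_config, config$preprocess)
  pre <- preprocess(rec, pc)
  if (!pre$triggers$included) {
    return(list(included = FALSE, reps = pre$triggers$reps))
  }
  mask <- pre$artifacts$mask
  resp <- deconvolve_responses(pre$recording, pre$triggers$retained,
                               config$responses$lag_range_s, mask = mask)
  resp <- baseline_correct(resp, config$responses$baseline_window_s)
  mag <- window_magnitude(resp, config$responses$magnitude_window_s)
  # channel magnitudes -> voxel magnitude map per condition (linear in y)
  ymat <- matrix(mag$magnitude, ncol = length(resp$conditions))
  colnames(ymat) <- resp$conditions
  rcfg <- do.call(reconstruction_config, config$reconstruct)
  img <- reconstruct_mua(ymat, recon_op)
  img <- mua_to_hbt(img, rcfg)
  list(included = TRUE, reps = pre$triggers$reps, responses = resp,
       magnitude_image = img, artifacts = pre$artifacts)
}

#' Run the full analysis pipeline on a dataset
#'
#' Per subject: preprocessing, inclusion check (>= 5 clean repetitions per
#' condition), FIR deconvolution, baseline correction, window magnitudes,
#' regularized HbT reconstruction. At the group level: Gaussian smoothing,
#' global analysis, adaptive voxel-based clustering (speech-average,
#' ANOVA, and per-condition-vs-baseline tests) and ROI analysis. Writes
#' cluster/ROI tables as TSV, cluster masks as NIfTI, and a JSON run report.
#'
#' @param config A `dot_pipeline_config`.
#' @param data Dataset directory from [make_fixtures()], or a list of
#'   in-memory `dot_recording`s.
#' @param out_dir Output directory (NULL = no files written).
#' @param scene Optional precomputed scene.
#' @param cluster_tests Which voxelwise tests drive clustering.
#' @param max_included Analyze at most this many included subjects (first
#'   come), mirroring a study design that recruits until a target analyzed
#'   sample is reached; NULL = all included.
#' @return A `dot_pipeline_report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), data,
                         out_dir = NULL, scene = NULL,
                         cluster_tests = c("avg_vs_zero", "anova"),
                         max_included = NULL) {
  t_start <- Sys.time()
  if (is.null(scene)) scene <- build_scene(config)
  rcfg <- do.call(reconstruction_config, config$reconstruct)
  recon_op <- reconstruction_operator(scene$S, rcfg)

  recs <- if (is.character(data)) {
    subs <- sort(list.dirs(data, recursive = FALSE))
    subs <- subs[grepl("sub-", basename(subs))]
    stats::setNames(lapply(subs, function(s) read_recording(file.path(s, "recording"))),
                    basename(subs))
  } else data
  n <- length(recs)
  results <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    results[[i]] <- tryCatch(
      analyze_subject(recs[[i]], config, recon_op),
      error = function(e) list(included = FALSE, error = conditionMessage(e))
    )
    if (!results[[i]]$included) {
      failures <- c(failures, names(recs)[i] %||% as.character(i))
    }
  }
  ok <- which(vapply(results, function(r) isTRUE(r$included), logical(1)))
  if (!is.null(max_included) && length(ok) > max_included) {
    ok <- ok[seq_len(max_included)]
  }
  if (length(ok) < 3) {
    rlang::abort(paste0("fewer than 3 subjects pass inclusion (",
                        length(ok), " of ", n, ")"))
  }

  conds <- results[[ok[1]]]$responses$conditions
  nvox <- length(scene$S$voxel_index)
  maps <- array(0, dim = c(nvox, length(conds), length(ok)))
  for (k in seq_along(ok)) maps[, , k] <- results[[ok[k]]]$magnitude_image$values
  gm <- array(scene$head$tissue_levels[scene$head$labels] == "gm",
              dim = scene$head$grid_shape)
  sample_raw <- group_sample(maps, scene$S$voxel_index, scene$head$grid_shape,
                             conds, gm, scene$fov, config$phantom$voxel_size_mm)

  # smoothing only before clustering, per the analysis design
  sample_sm <- smooth_group_sample(sample_raw, rcfg$smoothing_radius_vox,
                                   brain_mask(scene$head), rcfg$smoothing_is_fwhm)

  global <- global_analysis(sample_raw)
  st <- config$stats
  clusters <- lapply(cluster_tests, function(tt) {
    pm <- voxelwise_pmap(sample_sm, tt)
    adaptive_cluster(pm, sample_sm, st$p_thresholds, st$min_cluster_vox,
                     st$n_mc, st$connectivity)
  })
  names(clusters) <- cluster_tests
  rois <- roi_analysis(sample_raw, default_roi_set(st$roi_radius_mm))

  report <- structure(list(
    n_subjects = n, n_included = length(ok),
    included = names(recs)[ok] %||% ok, excluded = failures,
    reps = lapply(results, function(r) r$reps),
    global = global, clusters = clusters, rois = rois,
    sample = sample_raw, sample_smoothed = sample_sm,
    config = config,
    timing_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "dot_pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tt in names(clusters)) {
      utils::write.table(clusters[[tt]]$table,
                         file.path(out_dir, paste0("clusters_", tt, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (length(clusters[[tt]]$voxels) > 0) {
        cm <- array(0L, dim = scene$head$grid_shape)
        for (ci in seq_along(clusters[[tt]]$voxels)) {
          cm[clusters[[tt]]$voxels[[ci]]] <- ci
        }
        write_volume(cm, file.path(out_dir, paste0("clusters_", tt, ".nii")),
                     config$phantom$voxel_size_mm)
      }
    }
    utils::write.table(rois$table, file.path(out_dir, "roi_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tidy(global), file.path(out_dir, "global_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cfg_file <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_file)
    jsonlite::write_json(list(
      n_subjects = n, n_included = length(ok), excluded = failures,
      config_hash = unname(tools::md5sum(cfg_file)),
      timing_s = report$timing_s,
      r_version = as.character(getRversion())
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.dot_pipeline_report <- function(x, ...) {
  cat("<dot_pipeline_report> ", x$n_included, "/", x$n_subjects,
      " subjects included; ", sum(vapply(x$clusters, function(cl) nrow(cl$table), numeric(1))),
      " clusters reported\n", sep = "")
  invisible(x)
}
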