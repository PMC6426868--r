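# Persistence: recordings (TSV and SNIRF-structured JSON dialects),
# schedules, probes, head models, images.

#' Write a recording to disk
#'
#' Two dialects are supported. `"tsv"` writes a directory of plain-text
#' tables: `amplitudes.tsv` (wide, one column per channel), `channels.tsv`,
#' `triggers.tsv`, `annotations.tsv` and `meta.json`. `"snirf-json"` writes a
#' single JSON file mirroring the SNIRF group hierarchy
#' (`nirs/data1/dataTimeSeries`, `nirs/data1/time`, `nirs/probe`,
#' `nirs/stim*`, measurement-list entries).
#'
#' @param rec A `dot_recording`.
#' @param path Output directory (tsv) or file (snirf-json).
#' @param dialect `"tsv"` or `"snirf-json"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("tsv", "snirf-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    amp <- as.data.frame(t(rec$amplitudes))
    names(amp) <- paste0("ch", seq_len(nrow(rec$amplitudes)))
    amp <- cbind(time_s = rec$times_s, amp)
    wr <- function(d, f) utils::write.table(
      d, file.path(path, f), sep = "\t", row.names = FALSE, quote = FALSE
    )
    wr(format(amp, digits = 17, scientific = TRUE, trim = TRUE), "amplitudes.tsv")
    wr(rec$channels, "channels.tsv")
    wr(rec$triggers, "triggers.tsv")
    wr(rec$annotations, "annotations.tsv")
    jsonlite::write_json(
      list(signal = rec$signal,
           meta = rec$meta[setdiff(names(rec$meta), "truth")]),
      file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    obj <- list(
      formatVersion = "1.0",
      nirs = list(
        data1 = list(
          dataTimeSeries = unname(apply(rec$amplitudes, 1, as.numeric, simplify = FALSE)),
          time = rec$times_s,
          measurementList = lapply(seq_len(nrow(rec$channels)), function(i) {
            list(sourceIndex = rec$channels$source[i],
                 detectorIndex = rec$channels$detector[i],
                 sourceDetectorSeparation = rec$channels$sds_mm[i],
                 timeOffset = rec$channels$time_offset_s[i])
          })
        ),
        stim = list(onset = rec$triggers$onset_s,
                    condition = rec$triggers$condition),
        aux_annotations = list(onset = rec$annotations$onset_s,
                               duration = rec$annotations$duration_s,
                               label = rec$annotations$label),
        metaDataTags = list(signal = rec$signal,
                            frame_interval_s = rec$meta$frame_interval_s)
      )
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Dialect is inferred from the path (directory = tsv, file = snirf-json).
#' Parsed recordings are re-validated; malformed tables raise parse errors
#' naming the offending file.
#'
#' @param path Directory or file path.
#' @return A `dot_recording`.
#' @export
read_recording <- function(path) {
  if (dir.exists(path)) {
    rd <- function(f, required = TRUE) {
      fp <- file.path(path, f)
      if (!file.exists(fp)) {
        if (required) rlang::abort(paste0("missing recording file: ", fp))
        return(NULL)
      }
      out <- tryCatch(
        utils::read.table(fp, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
        error = function(e) rlang::abort(paste0("parse error in ", fp, ": ", conditionMessage(e)))
      )
      tibble::as_tibble(out)
    }
    amp <- rd("amplitudes.tsv")
    channels <- rd("channels.tsv")
    triggers <- rd("triggers.tsv")
    annotations <- rd("annotations.tsv")
    meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
    if (!"time_s" %in% names(amp)) {
      rlang::abort(paste0("parse error in ", file.path(path, "amplitudes.tsv"),
                          ": missing time_s column"))
    }
    new_recording(
      t(as.matrix(amp[, -1, drop = FALSE])), amp$time_s, channels,
      triggers = triggers, annotations = annotations,
      signal = meta$signal, meta = as.list(meta$meta)
    )
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    n <- obj$nirs
    if (is.null(n$data1)) rlang::abort(paste0("parse error in ", path, ": missing nirs/data1"))
    amp <- do.call(rbind, lapply(n$data1$dataTimeSeries, function(r) unlist(r)))
    ml <- n$data1$measurementList
    channels <- tibble::tibble(
      source = vapply(ml, function(m) as.integer(m$sourceIndex), integer(1)),
      detector = vapply(ml, function(m) as.integer(m$detectorIndex), integer(1)),
      sds_mm = vapply(ml, function(m) as.numeric(m$sourceDetectorSeparation), numeric(1)),
      time_offset_s = vapply(ml, function(m) as.numeric(m$timeOffset %||% 0), numeric(1))
    )
    trig <- tibble::tibble(
      onset_s = as.numeric(unlist(n$stim$onset)),
      condition = as.character(unlist(n$stim$condition))
    )
    ann <- tibble::tibble(
      onset_s = as.numeric(unlist(n$aux_annotations$onset)),
      duration_s = as.numeric(unlist(n$aux_annotations$duration)),
      label = as.character(unlist(n$aux_annotations$label))
    )
    new_recording(amp, as.numeric(unlist(n$data1$time)), channels,
                  triggers = trig, annotations = ann,
                  signal = n$metaDataTags$signal %||% "intensity",
                  meta = list(frame_interval_s = n$metaDataTags$frame_interval_s))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a stimulus schedule as events TSV
#'
#' Columns `onset_s`, `duration_s`, `condition` (a BIDS-events-like dialect).
#' @param schedule A `dot_schedule` (or compatible tibble).
#' @param path TSV file path.
#' @return `path` / the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule)[, c("onset_s", "duration_s", "condition")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             stringsAsFactors = FALSE))
  class(out) <- c("dot_schedule", class(out))
  out
}

#' Write / read probe optodes as TSV (id, type, x, y, z in mm)
#' @param probe A `dot_probe`.
#' @param path TSV file path.
#' @param max_sds_mm,wavelength_nm Channel-list parameters on read.
#' @export
write_probe <- function(probe, path) {
  utils::write.table(as.data.frame(probe$optodes), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_probe
#' @export
read_probe <- function(path, max_sds_mm = 45, wavelength_nm = 798) {
  opt <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             stringsAsFactors = FALSE))
  probe_from_optodes(opt, max_sds_mm, wavelength_nm)
}

#' Persist a head model as NIfTI labels plus a YAML sidecar
#'
#' The label volume is written as an integer NIfTI image (voxel dimensions in
#' mm); tissue level names, optical properties and the wavelength go to a
#' YAML sidecar next to it.
#'
#' @param head A `dot_head_model`.
#' @param path Output path without extension; writes `<path>.nii` and
#'   `<path>.yaml`.
#' @export
write_head_model <- function(head, path) {
  img <- RNifti::asNifti(array(as.integer(head$labels), dim = head$grid_shape),
                         pixdim = rep(head$voxel_size_mm, 3))
  RNifti::writeNifti(img, paste0(path, ".nii"))
  yaml::write_yaml(list(
    tissue_levels = head$tissue_levels,
    voxel_size_mm = head$voxel_size_mm,
    wavelength_nm = head$wavelength_nm,
    optical_props = lapply(seq_len(nrow(head$optical_props)), function(i)
      as.list(head$optical_props[i, ]))
  ), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii"))
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  op <- dplyr::bind_rows(lapply(side$optical_props, tibble::as_tibble))
  structure(list(
    grid_shape = dim(img),
    voxel_size_mm = side$voxel_size_mm,
    labels = array(as.integer(img), dim = dim(img)),
    tissue_levels = unlist(side$tissue_levels),
    optical_props = op,
    wavelength_nm = side$wavelength_nm
  ), class = "dot_head_model")
}

#' Write a grid-shaped volume as NIfTI
#' @param vol 3D numeric/logical array.
#' @param path Output `.nii` path.
#' @param voxel_size_mm Voxel side length.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)),
                         pixdim = rep(voxel_size_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
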