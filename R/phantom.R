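# Layered optical head phantom: grid, tissue labels, optical properties,
# probe placement.

TISSUES <- c("outside", "scalp", "skull", "csf", "gm", "wm")

#' Default per-tissue optical properties
#'
#' Absorption (`mu_a`) and reduced scattering (`mu_sp`) coefficients in 1/mm
#' at the working wavelength (near-infrared, ~798 nm). These are configurable
#' placeholders in the physiological range for infant tissue; they are carried
#' in the head-model object, never hard-coded downstream.
#'
#' @param wavelength_nm Working wavelength in nm (stored as metadata; a single
#'   near-isosbestic wavelength is assumed).
#' @return A tibble with columns `tissue`, `mu_a`, `mu_sp`.
#' @export
default_optical_props <- function(wavelength_nm = 798) {
  out <- tibble::tibble(
    tissue = c("scalp", "skull", "csf", "gm", "wm"),
    mu_a   = c(0.016, 0.012, 0.002, 0.015, 0.010),
    mu_sp  = c(0.74, 0.94, 0.30, 1.00, 1.20)
  )
  attr(out, "wavelength_nm") <- wavelength_nm
  out
}

#' Build a layered slab head phantom
#'
#' Constructs a voxelized slab model with planar scalp, skull and CSF shells
#' over gray matter, with white matter filling the remaining depth. The slab
#' stands in for a segmented infant head: in young infants the combined
#' superficial layers are thin, so brain tissue starts approximately 5 mm
#' below the outer scalp surface.
#'
#' Coordinates are 0-based, axis order (x, y, z) with z depth-positive into
#' the head; positions are in mm from the grid origin corner. Voxel centers
#' sit at `(index + 0.5) * voxel_size_mm`.
#'
#' @param grid_shape Integer vector of length 3: voxel counts per axis.
#' @param layer_thicknesses_mm Named numeric vector with entries `scalp`,
#'   `skull`, `csf`, `gm` (mm). White matter fills the rest of the depth.
#'   A zero thickness removes that layer.
#' @param voxel_size_mm Isotropic voxel side length in mm (default 2).
#' @param optical_props Tibble as from [default_optical_props()].
#' @param wavelength_nm Working wavelength (nm).
#' @return An object of class `dot_head_model`: list with `grid_shape`,
#'   `voxel_size_mm`, `labels` (3D integer array, values indexing
#'   `tissue_levels`), `tissue_levels`, `optical_props`, `wavelength_nm`.
#' @export
build_layered_phantom <- function(grid_shape = c(40, 40, 40),
                                  layer_thicknesses_mm = c(scalp = 2, skull = 2, csf = 1, gm = 20),
                                  voxel_size_mm = 2,
                                  optical_props = default_optical_props(wavelength_nm),
                                  wavelength_nm = 798) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3)
  th <- layer_thicknesses_mm
  need <- c("scalp", "skull", "csf", "gm")
  if (!all(need %in% names(th))) {
    rlang::abort("layer_thicknesses_mm must name scalp, skull, csf and gm")
  }
  th <- th[need]
  if (any(th < 0)) rlang::abort("layer thicknesses must be non-negative")
  # cumulative boundaries in voxels; ceiling keeps every nonzero layer at
  # least one voxel thick and avoids overlap
  bounds <- ceiling(cumsum(th) / voxel_size_mm)
  if (bounds[length(bounds)] >= grid_shape[3]) {
    rlang::abort("grid too small in depth to contain all layers plus white matter")
  }
  nz <- grid_shape[3]
  zcode <- integer(nz)                       # per-depth tissue code
  zidx <- seq_len(nz) - 1L                   # 0-based depth index
  lab <- function(t) match(t, TISSUES)
  zcode[] <- lab("wm")
  zcode[zidx < bounds["gm"]] <- lab("gm")
  zcode[zidx < bounds["csf"]] <- lab("csf")
  zcode[zidx < bounds["skull"]] <- lab("skull")
  zcode[zidx < bounds["scalp"]] <- lab("scalp")
  # zero-thickness layers: ceiling of equal cumsums gives zero-width bands
  labels <- array(rep(zcode, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  structure(
    list(
      grid_shape = grid_shape,
      voxel_size_mm = voxel_size_mm,
      labels = labels,
      tissue_levels = TISSUES,
      optical_props = optical_props,
      wavelength_nm = wavelength_nm
    ),
    class = "dot_head_model"
  )
}

#' Build a homogeneous phantom (single tissue, no shells)
#'
#' Convenience for analytic checks: every voxel is gray matter, so the
#' semi-infinite diffusion solution applies throughout.
#' @inheritParams build_layered_phantom
#' @export
build_homogeneous_phantom <- function(grid_shape = c(40, 40, 40), voxel_size_mm = 2,
                                      optical_props = default_optical_props(wavelength_nm),
                                      wavelength_nm = 798) {
  m <- build_layered_phantom(grid_shape,
    layer_thicknesses_mm = c(scalp = 0, skull = 0, csf = 0, gm = (grid_shape[3] - 1) * voxel_size_mm),
    voxel_size_mm = voxel_size_mm, optical_props = optical_props,
    wavelength_nm = wavelength_nm
  )
  m$labels[] <- match("gm", TISSUES)
  m
}

#' @export
print.dot_head_model <- function(x, ...) {
  cat("<dot_head_model> ", paste(x$grid_shape, collapse = " x "),
      " voxels @ ", x$voxel_size_mm, " mm\n", sep = "")
  tab <- table(factor(x$tissue_levels[x$labels], levels = x$tissue_levels))
  print(tab[tab > 0])
  invisible(x)
}

#' Per-tissue voxel counts and volumes
#' @param head A `dot_head_model`.
#' @return Tibble with `tissue`, `n_voxels`, `volume_mm3`.
#' @export
tissue_volumes <- function(head) {
  tab <- table(factor(head$tissue_levels[head$labels], levels = head$tissue_levels))
  tibble::tibble(
    tissue = names(tab),
    n_voxels = as.integer(tab),
    volume_mm3 = as.numeric(tab) * head$voxel_size_mm^3
  ) |> dplyr::filter(.data$n_voxels > 0)
}

#' Logical brain mask (gray + white matter)
#' @param head A `dot_head_model`.
#' @return 3D logical array.
#' @export
brain_mask <- function(head) {
  array(head$tissue_levels[head$labels] %in% c("gm", "wm"), dim = head$grid_shape)
}

#' Place a high-density optode probe on the phantom surface
#'
#' Lays out 15 sources and 15 detectors in an interleaved grid on the scalp
#' surface (z = 0 plane) and enumerates source-detector channels up to a
#' maximum separation.
#'
#' @param head A `dot_head_model`.
#' @param layout Integer vector `c(rows, cols)` of the combined optode grid;
#'   the default 5 x 6 grid holds 15 sources and 15 detectors.
#' @param spacing_mm Pitch between neighboring optodes (mm).
#' @param max_sds_mm Channels with source-detector separation above this are
#'   dropped (default 45 mm).
#' @param style `"checkerboard"` alternates sources and detectors on one
#'   grid (minimum SDS = pitch); `"offset"` puts detectors on a sub-grid
#'   shifted by half a pitch diagonally, creating short channels at
#'   pitch/sqrt(2) that sample superficial tissue (needed for superficial
#'   signal regression).
#' @param origin_mm Optional (x, y) mm position of the first optode; default
#'   centers the layout on the surface.
#' @return An object of class `dot_probe`: `optodes` tibble
#'   (id, type, x, y, z), `channels` tibble (source, detector, sds_mm),
#'   `wavelength_nm`.
#' @export
place_probe <- function(head, layout = c(5, 6), spacing_mm = 13,
                        max_sds_mm = 45, style = c("checkerboard", "offset"),
                        origin_mm = NULL) {
  style <- match.arg(style)
  ext <- (head$grid_shape[1:2]) * head$voxel_size_mm
  if (style == "checkerboard") {
    span <- (rev(layout) - 1) * spacing_mm # (x span, y span): cols along x
    if (is.null(origin_mm)) origin_mm <- (ext - span) / 2
    if (any(origin_mm < 0) || any(origin_mm + span > ext)) {
      rlang::abort("probe layout does not fit on the model's top surface")
    }
    ij <- expand.grid(row = seq_len(layout[1]), col = seq_len(layout[2]))
    is_src <- (ij$row + ij$col) %% 2 == 0
    opt <- tibble::tibble(
      type = ifelse(is_src, "source", "detector"),
      x = origin_mm[1] + (ij$col - 1) * spacing_mm,
      y = origin_mm[2] + (ij$row - 1) * spacing_mm,
      z = 0
    )
  } else {
    rows <- layout[1]
    cols <- layout[2] %/% 2
    span <- c((cols - 1) * spacing_mm + spacing_mm / 2,
              (rows - 1) * spacing_mm + spacing_mm / 2)
    if (is.null(origin_mm)) origin_mm <- (ext - span) / 2
    if (any(origin_mm < 0) || any(origin_mm + span > ext)) {
      rlang::abort("probe layout does not fit on the model's top surface")
    }
    ij <- expand.grid(row = seq_len(rows), col = seq_len(cols))
    opt <- dplyr::bind_rows(
      tibble::tibble(type = "source",
                     x = origin_mm[1] + (ij$col - 1) * spacing_mm,
                     y = origin_mm[2] + (ij$row - 1) * spacing_mm, z = 0),
      tibble::tibble(type = "detector",
                     x = origin_mm[1] + (ij$col - 1) * spacing_mm + spacing_mm / 2,
                     y = origin_mm[2] + (ij$row - 1) * spacing_mm + spacing_mm / 2,
                     z = 0)
    )
  }
  opt <- opt |>
    dplyr::arrange(dplyr::desc(.data$type == "source"), .data$y, .data$x) |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("id", "type", "x", "y", "z")
  new_probe(opt, max_sds_mm, head$wavelength_nm)
}

# assemble probe + channel list from an optode table
new_probe <- function(optodes, max_sds_mm, wavelength_nm) {
  src <- dplyr::filter(optodes, .data$type == "source")
  det <- dplyr::filter(optodes, .data$type == "detector")
  ch <- tidyr::expand_grid(source = src$id, detector = det$id)
  si <- match(ch$source, src$id)
  di <- match(ch$detector, det$id)
  ch$sds_mm <- sqrt(
    (src$x[si] - det$x[di])^2 + (src$y[si] - det$y[di])^2 +
      (src$z[si] - det$z[di])^2
  )
  ch <- ch |>
    dplyr::filter(.data$sds_mm <= max_sds_mm) |>
    dplyr::arrange(.data$source, .data$detector)
  structure(
    list(optodes = optodes, channels = ch, wavelength_nm = wavelength_nm,
         max_sds_mm = max_sds_mm),
    class = "dot_probe"
  )
}

#' Build a probe from explicit optode positions
#'
#' @param optodes Tibble/data frame with columns `id`, `type`
#'   ("source"/"detector"), `x`, `y`, `z` (mm).
#' @param max_sds_mm Maximum source-detector separation retained.
#' @param wavelength_nm Wavelength metadata.
#' @export
probe_from_optodes <- function(optodes, max_sds_mm = 45, wavelength_nm = 798) {
  optodes <- tibble::as_tibble(optodes)
  stopifnot(all(c("id", "type", "x", "y", "z") %in% names(optodes)))
  new_probe(optodes, max_sds_mm, wavelength_nm)
}

#' @export
print.dot_probe <- function(x, ...) {
  cat("<dot_probe> ", sum(x$optodes$type == "source"), " sources, ",
      sum(x$optodes$type == "detector"), " detectors, ",
      nrow(x$channels), " channels (SDS <= ", x$max_sds_mm, " mm)\n", sep = "")
  invisible(x)
}
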