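# Diffusion-approximation sensitivity matrix (Rytov convention) and field of
# view. The forward model is the continuous-wave photon-diffusion equation in
# a semi-infinite homogeneous medium with an extrapolated boundary; each
# channel's sensitivity to a voxel absorption perturbation is the normalized
# product of source and detector (adjoint) Green's functions.

# effective homogeneous optical properties: volume-weighted over tissues
effective_props <- function(head) {
  vols <- tissue_volumes(head)
  op <- dplyr::inner_join(vols, head$optical_props, by = "tissue")
  if (nrow(op) == 0) rlang::abort("no tissue with optical properties in model")
  w <- op$n_voxels / sum(op$n_voxels)
  list(mu_a = sum(w * op$mu_a), mu_sp = sum(w * op$mu_sp))
}

# CW fluence Green's function, semi-infinite medium, extrapolated boundary.
# Point source at (x0, y0, z0) below the z = 0 surface; evaluation points as
# columns of a 3 x n matrix. Units: 1/mm^2 (per unit source power / D).
fluence_semi_inf <- function(pts, pos0, z0, mu_eff, D, zb) {
  dx <- pts[1, ] - pos0[1]
  dy <- pts[2, ] - pos0[2]
  r1 <- sqrt(dx^2 + dy^2 + (pts[3, ] - z0)^2)
  r2 <- sqrt(dx^2 + dy^2 + (pts[3, ] + z0 + 2 * zb)^2)
  r1 <- pmax(r1, 1e-6)
  r2 <- pmax(r2, 1e-6)
  (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D)
}

#' Compute the channel-by-voxel sensitivity matrix
#'
#' Builds the Jacobian of channel \eqn{-\Delta\log} amplitude with respect to
#' voxel absorption changes \eqn{\Delta\mu_a} (units mm), using analytic
#' diffusion-approximation Green's functions for a semi-infinite homogeneous
#' medium with an extrapolated boundary. The Rytov (first-order in
#' log-amplitude) normalization divides the source-detector fluence product by
#' the unperturbed source-to-detector fluence, so that the forward projection
#' `J %*% dmua` is the first-order change in \eqn{-\log} amplitude.
#'
#' The homogeneous background uses volume-weighted average optical properties
#' of the phantom's tissues. Columns cover the requested voxel set (brain by
#' default). `relative_sensitivity` is, per voxel, the maximum over channels
#' of each channel's Jacobian normalized by that channel's own maximum within
#' brain tissue.
#'
#' @param head A `dot_head_model`.
#' @param probe A `dot_probe`.
#' @param voxels `"brain"` (gray + white matter columns, default) or `"all"`.
#' @param refr_mismatch_A Boundary refractive-index mismatch factor A in the
#'   extrapolated-boundary distance `zb = 2 A D`; 1 = matched.
#' @return A `dot_sensitivity` object: `J` (channels x voxels, mm),
#'   `channels` tibble (`source`, `detector`, `sds_mm`), `voxel_index`
#'   (1-based linear indices into the grid), `relative_sensitivity` (vector
#'   aligned with columns), `grid_shape`, `voxel_size_mm`, `convention`
#'   ("rytov"), effective properties in `props`.
#' @export
compute_jacobian <- function(head, probe, voxels = c("brain", "all"),
                             refr_mismatch_A = 1) {
  voxels <- match.arg(voxels)
  pr <- effective_props(head)
  if (pr$mu_sp <= 0) rlang::abort("diffusion approximation invalid: mu_s' must be > 0")
  if (pr$mu_a <= 0) rlang::abort("mu_a must be > 0")
  D <- 1 / (3 * (pr$mu_a + pr$mu_sp))
  mu_eff <- sqrt(pr$mu_a / D)
  z0 <- 1 / pr$mu_sp
  zb <- 2 * refr_mismatch_A * D

  gs <- head$grid_shape
  vs <- head$voxel_size_mm
  tiss <- head$tissue_levels[head$labels]
  in_brain_all <- tiss %in% c("gm", "wm")
  vox_idx <- if (voxels == "brain") which(in_brain_all) else seq_along(head$labels)
  if (length(vox_idx) == 0) rlang::abort("no voxels selected")
  ijk <- arrayInd(vox_idx, gs) - 1L
  pts <- Matrix::t(ijk) * vs + vs / 2 # 3 x n voxel centers (mm)
  pts <- matrix(as.numeric(pts), nrow = 3)

  opt <- probe$optodes
  src <- dplyr::filter(opt, .data$type == "source")
  det <- dplyr::filter(opt, .data$type == "detector")
  ch <- probe$channels
  nch <- nrow(ch)

  # fluence fields per unique optode (source and adjoint-detector identical
  # in CW), evaluated at every voxel center
  field_for <- function(tab) {
    out <- matrix(0, nrow(tab), ncol(pts))
    for (i in seq_len(nrow(tab))) {
      out[i, ] <- fluence_semi_inf(pts, c(tab$x[i], tab$y[i]), z0, mu_eff, D, zb)
    }
    out
  }
  fs <- field_for(src)
  fd <- field_for(det)

  si <- match(ch$source, src$id)
  di <- match(ch$detector, det$id)
  # unperturbed source->detector fluence (detector optode at its nominal
  # buried depth z0, mirroring the adjoint placement)
  dpts <- rbind(det$x[di], det$y[di], rep(z0, nch))
  phi0 <- vapply(seq_len(nch), function(k) {
    fluence_semi_inf(dpts[, k, drop = FALSE], c(src$x[si[k]], src$y[si[k]]),
                     z0, mu_eff, D, zb)
  }, numeric(1))

  J <- (fs[si, , drop = FALSE] * fd[di, , drop = FALSE]) * (vs^3 / phi0)
  J[J < 0] <- 0 # clip tiny negative lobes from the image term

  # relative sensitivity: per-channel normalization by within-brain maximum
  brain_cols <- in_brain_all[vox_idx]
  if (!any(brain_cols)) rlang::abort("no brain voxels within the selected set")
  chmax <- apply(J[, brain_cols, drop = FALSE], 1, max)
  chmax[chmax <= 0] <- Inf
  rel <- apply(J / chmax, 2, max)

  structure(
    list(
      J = J,
      channels = ch,
      voxel_index = vox_idx,
      relative_sensitivity = rel,
      grid_shape = gs,
      voxel_size_mm = vs,
      convention = "rytov",
      props = pr,
      brain_cols = brain_cols
    ),
    class = "dot_sensitivity"
  )
}

#' @export
print.dot_sensitivity <- function(x, ...) {
  cat("<dot_sensitivity> ", nrow(x$J), " channels x ", ncol(x$J),
      " voxels (", x$convention, ")\n", sep = "")
  invisible(x)
}

#' Field of view from relative sensitivity
#'
#' The FOV is the set of gray/white-matter voxels whose relative sensitivity
#' exceeds a threshold. With multiple subjects (a list of sensitivity
#' objects on a shared grid), a voxel is kept when it passes the threshold in
#' at least `min_subjects` of them.
#'
#' @param S A `dot_sensitivity` or list of them (shared grid).
#' @param head The `dot_head_model` (for the gray/white mask).
#' @param threshold Relative-sensitivity threshold in (0, 1]; default 0.001.
#' @param min_subjects Minimum number of subjects a voxel must pass in
#'   (default 1, the single-synthetic-subject case).
#' @return 3D logical array (grid-shaped FOV mask).
#' @export
compute_fov <- function(S, head, threshold = 0.001, min_subjects = 1) {
  if (!(threshold > 0)) rlang::abort("threshold must be in (0, 1]")
  if (inherits(S, "dot_sensitivity")) S <- list(S)
  gs <- S[[1]]$grid_shape
  counts <- array(0L, dim = gs)
  for (s in S) {
    stopifnot(identical(s$grid_shape, gs))
    pass <- s$voxel_index[s$relative_sensitivity > threshold]
    counts[pass] <- counts[pass] + 1L
  }
  bm <- brain_mask(head)
  (counts >= min_subjects) & bm
}
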