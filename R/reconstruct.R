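# Linear image reconstruction with Laplacian smoothing regularization,
# Beer-Lambert conversion to HbT, and masked Gaussian smoothing.

#' Reconstruction configuration
#'
#' @param lambda Regularization weight, relative to the mean diagonal of the
#'   dual operator `J R^-1 J'` (dimensionless; larger = smoother images).
#' @param extinction_hbt Extinction coefficient of total hemoglobin at the
#'   working wavelength, 1/(mM mm).
#' @param smoothing_radius_vox Gaussian smoothing radius before clustering
#'   (voxels); read as the Gaussian sigma by default.
#' @param smoothing_is_fwhm If TRUE, `smoothing_radius_vox` is interpreted as
#'   FWHM instead of sigma.
#' @param ridge Tiny Tikhonov term added to the Laplacian penalty for
#'   uniqueness (the reflecting-boundary Laplacian annihilates constants).
#' @return A `dot_reconstruction_config` list.
#' @export
reconstruction_config <- function(lambda = 0.01, extinction_hbt = 0.1,
                                  smoothing_radius_vox = 1.5,
                                  smoothing_is_fwhm = FALSE,
                                  ridge = 1e-6) {
  stopifnot(lambda > 0, extinction_hbt > 0, ridge >= 0)
  structure(list(lambda = lambda, extinction_hbt = extinction_hbt,
                 smoothing_radius_vox = smoothing_radius_vox,
                 smoothing_is_fwhm = smoothing_is_fwhm, ridge = ridge),
            class = "dot_reconstruction_config")
}

# 6-neighbor graph Laplacian over an arbitrary voxel set (reflecting
# boundary: edges only between voxels both inside the set)
voxel_laplacian <- function(voxel_index, grid_shape) {
  n <- length(voxel_index)
  pos <- integer(prod(grid_shape))
  pos[voxel_index] <- seq_len(n)
  ijk <- arrayInd(voxel_index, grid_shape)
  ii <- integer(0); jj <- integer(0)
  strides <- c(1, grid_shape[1], grid_shape[1] * grid_shape[2])
  for (ax in 1:3) {
    ok <- ijk[, ax] < grid_shape[ax]
    nb <- voxel_index[ok] + strides[ax]
    has <- pos[nb] > 0
    a <- pos[voxel_index[ok][has]]
    b <- pos[nb[has]]
    ii <- c(ii, a, b)
    jj <- c(jj, b, a)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(n, deg) - A
}

# If the voxel set fills a complete axis-aligned box, the 6-neighbor graph
# Laplacian is the Kronecker sum of 1D path-graph Laplacians and
# diagonalizes in the cosine basis; R^-1 then applies spectrally, which is
# orders of magnitude faster than a sparse factorization.
box_structure <- function(voxel_index, grid_shape) {
  ijk <- arrayInd(voxel_index, grid_shape)
  rng <- apply(ijk, 2, range)
  dims <- rng[2, ] - rng[1, ] + 1L
  if (length(voxel_index) != prod(dims)) return(NULL)
  # sorted linear indices of a full box are exactly this enumeration
  expected <- as.vector(outer(
    outer(seq(rng[1, 1], rng[2, 1]),
          (seq(rng[1, 2], rng[2, 2]) - 1L) * grid_shape[1], "+"),
    (seq(rng[1, 3], rng[2, 3]) - 1L) * grid_shape[1] * grid_shape[2], "+"
  ))
  if (!identical(as.integer(sort(voxel_index)), as.integer(expected))) return(NULL)
  list(dims = dims, origin = rng[1, ])
}

# orthonormal eigenbasis of the 1D path-graph Laplacian (Neumann):
# eigenvalues 4 sin^2(pi k / 2n), eigenvectors cosine modes
path_laplacian_eigen <- function(n) {
  k <- 0:(n - 1)
  j <- 1:n
  U <- sqrt(2 / n) * cos(outer(j - 0.5, k) * pi / n)
  U[, 1] <- sqrt(1 / n)
  list(U = U, values = 4 * sin(pi * k / (2 * n))^2)
}

# multiply a 4D array by M along the given mode (1..3)
mode_mult <- function(arr, M, mode) {
  d <- dim(arr)
  if (mode == 1) { # no permutation needed along the fastest dimension
    return(array(M %*% matrix(arr, d[1]), dim = c(nrow(M), d[-1])))
  }
  perm <- c(mode, setdiff(seq_along(d), mode))
  a <- aperm(arr, perm)
  da <- dim(a)
  out <- array(M %*% matrix(a, da[1]), dim = c(nrow(M), da[-1]))
  aperm(out, order(perm))
}

# B = (L'L + delta I)^-1 J' via the spectral decomposition on a box
spectral_B <- function(J, box, ridge) {
  e <- lapply(box$dims, path_laplacian_eigen)
  lam <- outer(outer(e[[1]]$values, e[[2]]$values, "+"), e[[3]]$values, "+")
  denom <- lam^2 + ridge
  G <- array(t(J), dim = c(box$dims, nrow(J)))
  for (m in 1:3) G <- mode_mult(G, t(e[[m]]$U), m)
  G <- G / as.vector(denom)
  for (m in 1:3) G <- mode_mult(G, e[[m]]$U, m)
  matrix(G, ncol = nrow(J))
}

#' Precompute the regularized reconstruction operator
#'
#' Prepares a solver for \eqn{\min_x \|Jx - y\|^2 + \lambda(\|Lx\|^2 +
#' \delta\|x\|^2)} with L the 6-neighbor Laplacian over the reconstruction
#' voxel set. The solution is computed through the push-through identity
#' \eqn{x = R^{-1}J'(J R^{-1} J' + \lambda I)^{-1} y} with
#' \eqn{R = L'L + \delta I}, which factors once and then solves any number
#' of right-hand sides (lags, conditions, subjects) at negligible cost.
#'
#' @param S A `dot_sensitivity` (columns define the reconstruction voxels).
#' @param config A `dot_reconstruction_config`.
#' @param method `"auto"` uses the spectral (cosine-basis) solver when the
#'   voxel set fills a complete box and the sparse Cholesky otherwise; the
#'   two are numerically interchangeable.
#' @return A `dot_recon_operator`.
#' @export
reconstruction_operator <- function(S, config = reconstruction_config(),
                                    method = c("auto", "spectral", "sparse")) {
  method <- match.arg(method)
  J <- S$J
  box <- box_structure(S$voxel_index, S$grid_shape)
  use_spectral <- switch(method,
    auto = !is.null(box),
    spectral = { if (is.null(box)) rlang::abort("voxel set is not a full box"); TRUE },
    sparse = FALSE
  )
  if (use_spectral) {
    B <- spectral_B(J, box, config$ridge) # R^-1 J'  (voxels x channels)
  } else {
    L <- voxel_laplacian(S$voxel_index, S$grid_shape)
    R <- Matrix::forceSymmetric(Matrix::crossprod(L) + Matrix::Diagonal(ncol(J), config$ridge))
    ch <- Matrix::Cholesky(R, LDL = FALSE)
    B <- as.matrix(Matrix::solve(ch, Matrix::t(J)))
  }
  K <- J %*% B                                    # dual operator (channels^2)
  lam <- config$lambda * mean(diag(K))
  Kf <- chol(K + lam * diag(nrow(K)))
  structure(list(B = B, Kf = Kf, lambda = config$lambda, lambda_abs = lam,
                 channels = S$channels, voxel_index = S$voxel_index,
                 grid_shape = S$grid_shape, voxel_size_mm = S$voxel_size_mm,
                 config = config, convention = S$convention),
            class = "dot_recon_operator")
}

#' Reconstruct voxel absorption changes from channel data
#'
#' Solves the Laplacian-regularized linear inverse problem per column of `y`
#' (one solve per lag or per condition). Deterministic; linear in `y`.
#'
#' @param y Channel response matrix (channels x lags), row order matching
#'   the sensitivity matrix's channel table, in \eqn{-\Delta\log} amplitude
#'   units.
#' @param S A `dot_sensitivity`, or a precomputed `dot_recon_operator`.
#' @param config A `dot_reconstruction_config` (ignored when `S` is already
#'   an operator).
#' @return A `dot_mua_image`: `values` (voxels x lags, 1/mm), `voxel_index`,
#'   `grid_shape`, `voxel_size_mm`, `unit = "1/mm"`.
#' @export
reconstruct_mua <- function(y, S, config = reconstruction_config()) {
  op <- if (inherits(S, "dot_recon_operator")) S else reconstruction_operator(S, config)
  y <- as.matrix(y)
  if (nrow(y) != nrow(op$Kf)) rlang::abort("y rows must match the channel count")
  z <- backsolve(op$Kf, backsolve(op$Kf, y, transpose = TRUE))
  x <- op$B %*% z
  structure(list(values = x, voxel_index = op$voxel_index,
                 grid_shape = op$grid_shape, voxel_size_mm = op$voxel_size_mm,
                 unit = "1/mm", lambda = op$lambda,
                 smoothing = NULL),
            class = "dot_mua_image")
}

#' Convert absorption changes to total-hemoglobin changes (Beer-Lambert)
#'
#' \eqn{\Delta HbT [\mu M] = \Delta\mu_a / \epsilon_{HbT} \times 1000} with
#' the extinction coefficient in 1/(mM mm). Linear and invertible.
#'
#' @param img A `dot_mua_image` (unit 1/mm).
#' @param config A `dot_reconstruction_config` (supplies `extinction_hbt`).
#' @return The image with `values` in uM and `unit = "uM"`.
#' @export
mua_to_hbt <- function(img, config = reconstruction_config()) {
  if (config$extinction_hbt <= 0) rlang::abort("extinction coefficient must be > 0")
  if (!is.null(img$unit) && img$unit == "uM") return(img)
  img$values <- img$values / config$extinction_hbt * 1000
  img$unit <- "uM"
  img$extinction_hbt <- config$extinction_hbt
  img
}

#' Expand image columns onto the full grid
#' @param img A `dot_mua_image`.
#' @param col Column (lag) to expand, default 1.
#' @param fill Value outside the reconstruction voxels.
#' @return 3D array.
#' @export
image_volume <- function(img, col = 1, fill = 0) {
  v <- array(fill, dim = img$grid_shape)
  v[img$voxel_index] <- img$values[, col]
  v
}

# separable 1D Gaussian smoothing matrices along each axis
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (d in seq(-half, half)) {
    idx <- seq_len(n)
    j <- idx + d
    ok <- j >= 1 & j <= n
    M[cbind(idx[ok], j[ok])] <- M[cbind(idx[ok], j[ok])] + k[d + half + 1]
  }
  M
}

# apply separable smoothing to a 3D array (zero padding)
smooth3d <- function(vol, sigma) {
  d <- dim(vol)
  Mx <- gauss_band(d[1], sigma)
  My <- gauss_band(d[2], sigma)
  Mz <- gauss_band(d[3], sigma)
  v <- array(Mx %*% matrix(vol, d[1]), dim = d)
  v <- aperm(array(My %*% matrix(aperm(v, c(2, 1, 3)), d[2]), dim = d[c(2, 1, 3)]),
             c(2, 1, 3))
  v <- aperm(array(Mz %*% matrix(aperm(v, c(3, 1, 2)), d[3]), dim = d[c(3, 1, 2)]),
             c(2, 3, 1))
  v
}

# batched separable smoothing of many volumes (4D: grid dims x n)
smooth4d <- function(vols, sigma) {
  d <- dim(vols)
  Ms <- lapply(d[1:3], gauss_band, sigma = sigma)
  for (m in 1:3) vols <- mode_mult(vols, Ms[[m]], m)
  vols
}

#' Mask-normalized Gaussian smoothing of a brain image
#'
#' Gaussian smoothing restricted to the brain mask, normalized by the
#' smoothed mask so that a constant image is unchanged and brain-interior
#' mass is preserved; applied before voxel-based clustering to reduce noise.
#'
#' @param x A `dot_mua_image`, or a 3D array.
#' @param radius_vox Gaussian radius in voxels (sigma unless `is_fwhm`).
#' @param mask 3D logical brain mask (required for arrays; defaults to the
#'   image's voxel set for `dot_mua_image`).
#' @param is_fwhm Interpret `radius_vox` as FWHM.
#' @return Same type as `x`, smoothed within the mask (zero outside).
#' @export
smooth_image <- function(x, radius_vox = 1.5, mask = NULL, is_fwhm = FALSE) {
  sigma <- if (is_fwhm) radius_vox / (2 * sqrt(2 * log(2))) else radius_vox
  if (inherits(x, "dot_mua_image")) {
    if (is.null(mask)) {
      mask <- array(FALSE, dim = x$grid_shape)
      mask[x$voxel_index] <- TRUE
    }
    sm_mask <- smooth3d(array(as.numeric(mask), dim = dim(mask)), sigma)
    out <- x$values
    for (j in seq_len(ncol(x$values))) {
      vol <- array(0, dim = x$grid_shape)
      vol[x$voxel_index] <- x$values[, j]
      vol[!mask] <- 0
      sm <- smooth3d(vol, sigma)
      res <- sm / pmax(sm_mask, .Machine$double.eps)
      out[, j] <- res[x$voxel_index] * mask[x$voxel_index]
    }
    x$values <- out
    x$smoothing <- list(radius_vox = radius_vox, sigma_vox = sigma,
                        is_fwhm = is_fwhm)
    x
  } else {
    if (is.null(mask)) rlang::abort("mask required when smoothing a bare array")
    vol <- x
    vol[!mask] <- 0
    sm <- smooth3d(vol, sigma)
    sm_mask <- smooth3d(array(as.numeric(mask), dim = dim(mask)), sigma)
    res <- sm / pmax(sm_mask, .Machine$double.eps)
    res[!mask] <- 0
    res
  }
}
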