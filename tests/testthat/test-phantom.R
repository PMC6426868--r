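# Layered phantom, probe placement, sensitivity matrix, field of view.

test_that("layered phantom puts brain tissue ~5 mm below the surface", {
  head <- build_layered_phantom(c(40, 40, 40),
                                c(scalp = 2, skull = 2, csf = 1, gm = 20), 2)
  zlab <- head$tissue_levels[head$labels[1, 1, ]]
  gm_start_mm <- (which(zlab == "gm")[1] - 1) * 2
  expect_gte(gm_start_mm, 4)
  expect_lte(gm_start_mm, 6)
  # labels partition the grid
  expect_equal(sum(tissue_volumes(head)$n_voxels), prod(head$grid_shape))
})

test_that("zero-thickness CSF layer yields a valid model without CSF", {
  head <- build_layered_phantom(c(20, 20, 20),
                                c(scalp = 2, skull = 2, csf = 0, gm = 16), 2)
  expect_false("csf" %in% tissue_volumes(head)$tissue)
  expect_true("gm" %in% tissue_volumes(head)$tissue)
})

test_that("tissue volumes conserve total grid volume", {
  head <- build_layered_phantom(c(16, 18, 20))
  tv <- tissue_volumes(head)
  expect_equal(sum(tv$volume_mm3), prod(head$grid_shape) * head$voxel_size_mm^3)
})

test_that("layers that exceed the grid depth are rejected", {
  expect_error(
    build_layered_phantom(c(10, 10, 10),
                          c(scalp = 5, skull = 5, csf = 5, gm = 10), 2),
    "too small"
  )
})

test_that("checkerboard probe has 15+15 optodes and SDS 13-45 mm", {
  head <- build_layered_phantom(c(40, 40, 40))
  probe <- place_probe(head, c(5, 6), 13, style = "checkerboard")
  expect_equal(sum(probe$optodes$type == "source"), 15)
  expect_equal(sum(probe$optodes$type == "detector"), 15)
  expect_gte(min(probe$channels$sds_mm), 13)
  expect_lte(max(probe$channels$sds_mm), 45)
  # multiple separation groups, as in a high-density arrangement
  expect_gte(length(unique(round(probe$channels$sds_mm, 3))), 3)
})

test_that("offset probe creates short channels below 12 mm", {
  head <- build_layered_phantom(c(40, 40, 40))
  probe <- place_probe(head, c(5, 6), 13, style = "offset")
  expect_equal(sum(probe$optodes$type == "source"), 15)
  expect_equal(sum(probe$optodes$type == "detector"), 15)
  expect_lt(min(probe$channels$sds_mm), 12)
})

test_that("single source-detector pair gives exactly one channel", {
  opt <- tibble::tibble(id = c(1, 1), type = c("source", "detector"),
                        x = c(10, 40), y = c(20, 20), z = c(0, 0))
  probe <- probe_from_optodes(opt, max_sds_mm = 45)
  expect_equal(nrow(probe$channels), 1)
  expect_equal(probe$channels$sds_mm, 30)
  # zero cutoff: empty channel list
  expect_equal(nrow(probe_from_optodes(opt, max_sds_mm = 0)$channels), 0)
})

test_that("probe that does not fit on the surface is rejected", {
  head <- build_layered_phantom(c(10, 10, 20))
  expect_error(place_probe(head, c(5, 6), 13), "does not fit")
})

test_that("sensitivity matrix is non-negative and forward-linear", {
  S <- small_scene()$S
  expect_true(all(S$J >= 0))
  nv <- ncol(S$J)
  withr::with_seed(4, {
    x1 <- rnorm(nv); x2 <- rnorm(nv)
  })
  expect_equal(as.numeric(S$J %*% (x1 + x2)),
               as.numeric(S$J %*% x1 + S$J %*% x2), tolerance = 1e-12)
  expect_equal(as.numeric(S$J %*% numeric(nv)), rep(0, nrow(S$J)))
})

test_that("relative sensitivity is in [0,1] with maximum 1 in brain", {
  S <- small_scene()$S
  expect_gte(min(S$relative_sensitivity), 0)
  expect_lte(max(S$relative_sensitivity), 1 + 1e-12)
  expect_equal(max(S$relative_sensitivity[S$brain_cols]), 1)
})

test_that("mirror-symmetric probe gives mirror-symmetric sensitivity", {
  head <- build_homogeneous_phantom(c(21, 21, 12), 4)
  mid <- 21 * 4 / 2
  opt <- tibble::tibble(id = c(1, 1), type = c("source", "detector"),
                        x = mid + c(-15, 15), y = c(mid, mid), z = c(0, 0))
  S <- compute_jacobian(head, probe_from_optodes(opt))
  vol <- array(0, dim = head$grid_shape)
  vol[S$voxel_index] <- S$J[1, ]
  flipped <- vol[rev(seq_len(21)), , ]
  expect_equal(vol, flipped, tolerance = 1e-9)
})

test_that("sensitivity decays monotonically with depth beyond its peak", {
  head <- build_homogeneous_phantom(c(21, 21, 12), 4)
  mid <- 21 * 4 / 2
  opt <- tibble::tibble(id = c(1, 1), type = c("source", "detector"),
                        x = mid + c(-15, 15), y = c(mid, mid), z = c(0, 0))
  S <- compute_jacobian(head, probe_from_optodes(opt))
  ijk <- arrayInd(S$voxel_index, S$grid_shape)
  col <- which(ijk[, 1] == 11 & ijk[, 2] == 11)
  prof <- S$J[1, col[order(ijk[col, 3])]]
  pk <- which.max(prof)
  expect_true(all(diff(prof[pk:length(prof)]) <= 0))
})

test_that("sensitivity-peak depth matches the photon Monte Carlo oracle", {
  # frozen oracle: random-walk photon Monte Carlo (4e5 photons, homogeneous
  # semi-infinite medium mu_a 0.015 mu_sp 1.0, 8 mm scoring grid, SDS 30 mm)
  # run once; the midplane sensitivity maximum fell in depth voxel 0.
  mc_depth_voxel <- 0
  head <- build_homogeneous_phantom(
    c(17, 17, 10), 8,
    optical_props = tibble::tibble(tissue = "gm", mu_a = 0.015, mu_sp = 1.0)
  )
  opt <- tibble::tibble(id = c(1, 1), type = c("source", "detector"),
                        x = c(53, 83), y = c(68, 68), z = c(0, 0))
  S <- compute_jacobian(head, probe_from_optodes(opt))
  ijk <- arrayInd(S$voxel_index, S$grid_shape) - 1L
  col <- which(ijk[, 1] == 8 & ijk[, 2] == 8)
  prof <- S$J[1, col[order(ijk[col, 3])]]
  expect_lte(abs((which.max(prof) - 1) - mc_depth_voxel), 1)
})

test_that("diffusion approximation rejects zero scattering", {
  head <- build_homogeneous_phantom(
    c(10, 10, 10), 4,
    optical_props = tibble::tibble(tissue = "gm", mu_a = 0.01, mu_sp = 0)
  )
  opt <- tibble::tibble(id = c(1, 1), type = c("source", "detector"),
                        x = c(10, 30), y = c(20, 20), z = c(0, 0))
  expect_error(compute_jacobian(head, probe_from_optodes(opt)), "mu_s")
})

test_that("FOV masks nest across thresholds and respect bounds", {
  sc <- small_scene()
  m1 <- compute_fov(sc$S, sc$head, 0.1)
  m2 <- compute_fov(sc$S, sc$head, 0.01)
  m3 <- compute_fov(sc$S, sc$head, 0.001)
  expect_true(all(m1 <= m2))
  expect_true(all(m2 <= m3))
  expect_gt(sum(m3), sum(m1))
  # threshold above 1: empty (relative sensitivity <= 1)
  expect_equal(sum(compute_fov(sc$S, sc$head, 1.000001)), 0)
  # FOV only contains brain voxels
  expect_true(all(brain_mask(sc$head)[m3]))
  expect_error(compute_fov(sc$S, sc$head, 0), "threshold")
})

test_that("head model round-trips through NIfTI + YAML", {
  head <- build_layered_phantom(c(12, 12, 16),
                                c(scalp = 2, skull = 2, csf = 1, gm = 16))
  path <- file.path(withr::local_tempdir(), "head")
  write_head_model(head, path)
  back <- read_head_model(path)
  expect_equal(back$labels, head$labels, ignore_attr = TRUE)
  expect_equal(back$voxel_size_mm, head$voxel_size_mm)
  expect_equal(back$optical_props$mu_a, head$optical_props$mu_a)
})
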