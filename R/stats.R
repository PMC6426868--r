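# Group-level statistics: global field-of-view analysis, voxelwise tests,
# adaptive voxel-based clustering with Bonferroni correction, Tukey-Kramer
# post hoc tests, and ROI analysis.

#' Assemble a group sample of window-magnitude maps
#'
#' @param maps Numeric array voxels x conditions x subjects (window-magnitude
#'   HbT, uM), voxel rows aligned with `voxel_index`.
#' @param voxel_index 1-based linear grid indices of the rows.
#' @param grid_shape Grid dimensions.
#' @param conditions Condition names (columns).
#' @param gm_mask,fov_mask 3D logical arrays (gray matter; field of view).
#' @param voxel_size_mm Voxel side (mm).
#' @return A `dot_group_sample`.
#' @export
group_sample <- function(maps, voxel_index, grid_shape, conditions,
                         gm_mask, fov_mask, voxel_size_mm = 2) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[1] == length(voxel_index),
            dim(maps)[2] == length(conditions))
  dimnames(maps)[[2]] <- conditions
  structure(list(
    maps = maps, voxel_index = voxel_index, grid_shape = grid_shape,
    conditions = conditions, gm_mask = gm_mask, fov_mask = fov_mask,
    voxel_size_mm = voxel_size_mm, n_subjects = dim(maps)[3]
  ), class = "dot_group_sample")
}

#' @export
print.dot_group_sample <- function(x, ...) {
  cat("<dot_group_sample> ", x$n_subjects, " subjects x ",
      length(x$conditions), " conditions x ", length(x$voxel_index),
      " voxels\n", sep = "")
  invisible(x)
}

#' Smooth every subject-condition map of a group sample
#'
#' Applies the mask-normalized Gaussian smoothing of [smooth_image()] to each
#' subject x condition magnitude map (the step taken before voxel-based
#' clustering).
#'
#' @param sample A `dot_group_sample`.
#' @param radius_vox Gaussian radius (voxels).
#' @param mask 3D logical smoothing domain; default gray+white matter is
#'   approximated by the sample's voxel set.
#' @param is_fwhm Interpret the radius as FWHM.
#' @return The smoothed `dot_group_sample`.
#' @export
smooth_group_sample <- function(sample, radius_vox = 1.5, mask = NULL,
                                is_fwhm = FALSE) {
  if (is.null(mask)) {
    mask <- array(FALSE, dim = sample$grid_shape)
    mask[sample$voxel_index] <- TRUE
  }
  sigma <- if (is_fwhm) radius_vox / (2 * sqrt(2 * log(2))) else radius_vox
  d <- sample$grid_shape
  nc <- dim(sample$maps)[2]
  ns <- dim(sample$maps)[3]
  # batch all subject x condition volumes through one separable pass
  vols <- array(0, dim = c(d, nc * ns))
  flat <- matrix(vols, prod(d))
  inmask <- mask[sample$voxel_index]
  flat[sample$voxel_index, ] <- matrix(sample$maps, ncol = nc * ns) * inmask
  vols <- array(flat, dim = c(d, nc * ns))
  sm <- smooth4d(vols, sigma)
  sm_mask <- smooth3d(array(as.numeric(mask), dim = d), sigma)
  denom <- pmax(as.vector(sm_mask), .Machine$double.eps)
  res <- matrix(sm, prod(d)) / denom
  out <- res[sample$voxel_index, , drop = FALSE] * inmask
  sample$maps <- array(out, dim = dim(sample$maps),
                       dimnames = dimnames(sample$maps))
  sample
}

#' Bonferroni correction
#' @param p P-value(s) in [0, 1].
#' @param n Number of comparisons (>= 1).
#' @return `min(1, p * n)`, vectorized.
#' @export
bonferroni <- function(p, n) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p must lie in [0, 1]")
  if (n < 1) rlang::abort("n must be >= 1")
  pmin(1, p * n)
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' Studentized-range pairwise tests after a one-way ANOVA, honoring unequal
#' group sizes via the Kramer standard error
#' \eqn{\sqrt{MSE/2 (1/n_i + 1/n_j)}}.
#'
#' @param data Data frame with a response and a grouping column, or a list
#'   of numeric vectors.
#' @param value,group Column names when `data` is a data frame.
#' @return Tibble: `group1`, `group2`, `estimate` (mean1 - mean2), `q`,
#'   `p_value`.
#' @export
tukey_kramer <- function(data, value = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- data
  } else {
    groups <- split(data[[value]], data[[group]])
  }
  kg <- length(groups)
  if (kg < 2) rlang::abort("need at least 2 groups")
  ns <- vapply(groups, length, numeric(1))
  if (any(ns < 2)) rlang::abort("every group needs n >= 2")
  means <- vapply(groups, mean, numeric(1))
  df <- sum(ns) - kg
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  pairs <- utils::combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    est <- means[a] - means[b]
    q <- abs(est) / se
    tibble::tibble(group1 = a, group2 = b, estimate = unname(est),
                   q = unname(q),
                   p_value = stats::ptukey(q, kg, df, lower.tail = FALSE))
  })
}

# one-sample two-tailed t vs zero, defined for zero-variance input
# (p = 1 when the data are identically zero, p = 0 for a nonzero constant)
safe_t <- function(v) {
  if (stats::sd(v) == 0) {
    if (mean(v) == 0) return(list(statistic = 0, p.value = 1))
    return(list(statistic = sign(mean(v)) * Inf, p.value = 0))
  }
  tt <- stats::t.test(v)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

# one-way ANOVA across conditions (subjects as replicates); repeated-measures
# variant removes the subject main effect
anova_conditions <- function(values, conditions, subjects, repeated = FALSE) {
  d <- data.frame(value = values, condition = factor(conditions),
                  subject = factor(subjects))
  if (repeated) {
    fit <- stats::aov(value ~ condition + Error(subject), data = d)
    s <- summary(fit)
    tab <- s[["Error: Within"]][[1]]
    list(statistic = tab["condition", "F value"], p_value = tab["condition", "Pr(>F)"],
         df = unname(tab[, "Df"]))
  } else {
    fit <- stats::aov(value ~ condition, data = d)
    tab <- summary(fit)[[1]]
    list(statistic = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
         df = unname(tab[, "Df"]))
  }
}

#' Global field-of-view analysis
#'
#' Considers gray-matter voxels inside the field of view whose group-mean
#' magnitude is positive for at least one condition, averages each subject's
#' magnitudes over that mask, and runs: a two-tailed one-sample t-test of
#' the across-condition average against zero, Bartlett's variance-equality
#' test, a one-way ANOVA across conditions (Tukey-Kramer post hoc when
#' p < 0.05), and per-condition t-tests against zero.
#'
#' @param sample A `dot_group_sample`.
#' @param positivity_mask Use only voxels positive (group mean) for >= 1
#'   condition (default TRUE, mirroring the activation-outline rule).
#' @param repeated Use a repeated-measures ANOVA (subject term) instead of
#'   the default one-way layout.
#' @return A `dot_global_stats` list: `table` (per-condition tibble),
#'   `anova`, `bartlett`, `tukey` (NULL unless ANOVA p < 0.05), `mask`
#'   (3D logical), `n_mask_voxels`, `subject_means` tibble.
#' @export
global_analysis <- function(sample, positivity_mask = TRUE, repeated = FALSE) {
  if (sample$n_subjects < 3) rlang::abort("need at least 3 subjects")
  gmfov <- sample$gm_mask & sample$fov_mask
  in_mask <- gmfov[sample$voxel_index]
  if (positivity_mask) {
    gmean <- matrix(0, dim(sample$maps)[1], length(sample$conditions))
    for (k in seq_len(sample$n_subjects)) gmean <- gmean + sample$maps[, , k]
    in_mask <- in_mask & (gmean[cbind(seq_len(nrow(gmean)),
                                      max.col(gmean))] > 0)
  }
  if (!any(in_mask)) rlang::abort("empty analysis mask")
  sel <- which(in_mask)
  # per-subject, per-condition spatial means
  sm <- apply(sample$maps[sel, , , drop = FALSE], c(2, 3), mean)
  subj_means <- tibble::tibble(
    subject = rep(seq_len(sample$n_subjects), each = length(sample$conditions)),
    condition = rep(sample$conditions, times = sample$n_subjects),
    magnitude = as.vector(sm)
  )
  avg <- colMeans(sm) # per-subject across-condition average
  t_avg <- safe_t(avg)
  bart <- stats::bartlett.test(split(subj_means$magnitude, subj_means$condition))
  an <- anova_conditions(subj_means$magnitude, subj_means$condition,
                         subj_means$subject, repeated)
  tk <- if (!is.na(an$p_value) && an$p_value < 0.05) {
    tukey_kramer(subj_means, "magnitude", "condition")
  } else NULL
  cond_tests <- purrr::map_dfr(sample$conditions, function(cc) {
    v <- sm[cc, ]
    tt <- safe_t(v)
    tibble::tibble(condition = cc, magnitude = mean(v),
                   t = tt$statistic, p_value = tt$p.value)
  })
  mask3d <- array(FALSE, dim = sample$grid_shape)
  mask3d[sample$voxel_index[sel]] <- TRUE
  structure(list(
    table = cond_tests,
    speech_average = tibble::tibble(magnitude = mean(avg),
                                    t = t_avg$statistic,
                                    p_value = t_avg$p.value),
    anova = an, bartlett = list(statistic = unname(bart$statistic),
                                p_value = bart$p.value),
    tukey = tk, mask = mask3d, n_mask_voxels = length(sel),
    subject_means = subj_means, repeated = repeated
  ), class = "dot_global_stats")
}

#' @export
print.dot_global_stats <- function(x, ...) {
  cat("<dot_global_stats> mask:", x$n_mask_voxels, "voxels; ANOVA p =",
      signif(x$anova$p_value, 3), "\n")
  print(x$table)
  invisible(x)
}

#' @method tidy dot_global_stats
#' @export
tidy.dot_global_stats <- function(x, ...) {
  out <- x$table
  out$term <- out$condition
  avg <- tibble::tibble(condition = "speech_average", term = "speech_average",
                        magnitude = x$speech_average$magnitude,
                        t = x$speech_average$t,
                        p_value = x$speech_average$p_value)
  dplyr::bind_rows(avg, out)[, c("term", "condition", "magnitude", "t", "p_value")]
}

#' @method glance dot_global_stats
#' @export
glance.dot_global_stats <- function(x, ...) {
  tibble::tibble(
    n_mask_voxels = x$n_mask_voxels,
    anova_f = x$anova$statistic, anova_p = x$anova$p_value,
    bartlett_p = x$bartlett$p_value
  )
}

#' Voxelwise p-value map
#'
#' Vectorized per-voxel group tests over subjects: `avg_vs_zero` (one-sample
#' two-tailed t of the across-condition average), `anova` (one-way across
#' conditions), or `condition_vs_baseline` (one-sample two-tailed t of one
#' condition; baseline is already subtracted upstream). Voxels with zero
#' variance get p = 1 with a warning.
#'
#' @param sample A `dot_group_sample` (use smoothed maps for clustering).
#' @param test One of `"avg_vs_zero"`, `"anova"`, `"condition_vs_baseline"`.
#' @param condition Condition name for `condition_vs_baseline`.
#' @return List: `p` (per sample voxel), `stat`, `test`, `condition`.
#' @export
voxelwise_pmap <- function(sample,
                           test = c("avg_vs_zero", "anova", "condition_vs_baseline"),
                           condition = NULL) {
  test <- match.arg(test)
  n <- sample$n_subjects
  nv <- dim(sample$maps)[1]
  if (test == "anova") {
    kg <- length(sample$conditions)
    x <- sample$maps # voxels x cond x subj
    gm <- matrix(0, nv, kg)                 # voxel x cond means
    for (k in seq_len(n)) gm <- gm + x[, , k]
    gm <- gm / n
    overall <- rowMeans(gm)
    ssb <- n * rowSums((gm - overall)^2)
    sse <- rowSums(matrix((x - as.vector(gm))^2, nv))
    df1 <- kg - 1
    df2 <- kg * (n - 1)
    msb <- ssb / df1
    mse <- sse / df2
    zerovar <- mse <= 0
    f <- ifelse(zerovar, 0, msb / pmax(mse, .Machine$double.xmin))
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    p[zerovar] <- 1
    if (any(zerovar)) rlang::warn("zero-variance voxels set to p = 1")
    list(p = p, stat = f, test = test, condition = NULL)
  } else {
    v <- if (test == "avg_vs_zero") {
      kg <- length(sample$conditions)
      out <- sample$maps[, 1, ]
      for (k in seq_len(kg)[-1]) out <- out + sample$maps[, k, ]
      out / kg # voxels x subjects
    } else {
      if (is.null(condition) || !condition %in% sample$conditions) {
        rlang::abort("condition_vs_baseline needs a valid condition")
      }
      sample$maps[, condition, ] # voxels x subjects
    }
    m <- rowMeans(v)
    s <- sqrt(rowSums((v - m)^2) / (n - 1))
    zerovar <- s <= 0
    tstat <- ifelse(zerovar, 0, m / (pmax(s, .Machine$double.xmin) / sqrt(n)))
    p <- 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
    p[zerovar] <- 1
    if (any(zerovar)) rlang::warn("zero-variance voxels set to p = 1")
    list(p = p, stat = tstat, test = test, condition = condition)
  }
}

# connected components of a logical 3D array (6- or 26-connectivity)
connected_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  lab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      ijk <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(ijk, 2, offs[o, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- lab
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

# geodesic region growing: voxels of `super` reachable from `seed` through
# `super` (both linear index vectors on grid `d`)
grow_region <- function(seed, super, d, connectivity = 6) {
  inset <- array(FALSE, dim = d)
  inset[super] <- TRUE
  comp <- connected_components(inset, connectivity)
  keep <- unique(comp[seed])
  keep <- keep[keep != 0L]
  which(array(comp %in% keep & inset, dim = d))
}

#' Adaptive voxel-based clustering
#'
#' Seeds are connected components of voxels with p below the strictest
#' threshold (0.001); each seed is expanded geodesically inside the 0.0033
#' and 0.01 superlevel sets; seeds whose expansions meet are merged into one
#' cluster. For each cluster and level, the cluster-mean magnitude per
#' subject is re-tested with the same group test, and the level with the
#' smallest p becomes the cluster p-value. Clusters with fewer than
#' `min_vox` voxels at the chosen level are discarded (spurious edge
#' clusters), and the Bonferroni factor `n_mc` corrects for multiple
#' comparisons.
#'
#' @param pmap Result of [voxelwise_pmap()] on the (smoothed) sample.
#' @param sample The `dot_group_sample` the map came from.
#' @param p_thresholds Significance levels, strictest first.
#' @param min_vox Minimum cluster extent at the chosen level (default 200).
#' @param n_mc Bonferroni correction factor (default 120).
#' @param connectivity 6 (default) or 26.
#' @param analysis_mask Optional 3D logical restricting clustering (default
#'   GM-and-FOV).
#' @return A `dot_cluster_result`: tibble with `cluster`, `level`,
#'   `n_vox`, `p_uncorrected`, `p_corrected`, condition means, and a
#'   `voxels` list-column of linear indices (chosen level).
#' @export
adaptive_cluster <- function(pmap, sample,
                             p_thresholds = c(0.001, 0.0033, 0.01),
                             min_vox = 200, n_mc = 120, connectivity = 6,
                             analysis_mask = NULL) {
  d <- sample$grid_shape
  if (is.null(analysis_mask)) analysis_mask <- sample$gm_mask & sample$fov_mask
  pvol <- array(1, dim = d)
  pvol[sample$voxel_index] <- pmap$p
  pvol[!analysis_mask] <- 1

  seed_mask <- pvol < p_thresholds[1]
  seed_labels <- connected_components(seed_mask, connectivity)
  ns <- max(seed_labels)
  empty <- tibble::tibble(cluster = integer(), level = integer(),
                          n_vox = integer(), p_uncorrected = numeric(),
                          p_corrected = numeric())
  if (ns == 0) {
    return(structure(list(table = empty, voxels = list(), levels = list(),
                          p_thresholds = p_thresholds, n_mc = n_mc,
                          test = pmap$test),
                     class = "dot_cluster_result"))
  }
  seeds <- lapply(seq_len(ns), function(l) which(seed_labels == l))
  # per-seed expansions at each lower level
  expansions <- lapply(seq_along(p_thresholds), function(li) {
    if (li == 1) return(seeds)
    super <- which(pvol < p_thresholds[li])
    lapply(seeds, function(s) grow_region(s, super, d, connectivity))
  })
  # merge seeds whose expansions intersect at any level (union-find)
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (li in seq_along(expansions)) {
    ex <- expansions[[li]]
    for (a in seq_len(ns - 1)) for (b in seq((a + 1), ns)) {
      if (length(intersect(ex[[a]], ex[[b]])) > 0) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))
  groups <- split(seq_len(ns), roots)

  # per-cluster per-level voxel sets and re-tests
  vox_pos <- integer(prod(d))
  vox_pos[sample$voxel_index] <- seq_along(sample$voxel_index)
  rows <- list(); vox_out <- list(); lev_out <- list()
  ci <- 0
  for (g in groups) {
    ci <- ci + 1
    level_sets <- lapply(seq_along(p_thresholds), function(li) {
      sort(unique(unlist(expansions[[li]][g])))
    })
    ps <- vapply(level_sets, function(vs) {
      rowsel <- vox_pos[vs]
      rowsel <- rowsel[rowsel > 0]
      if (length(rowsel) == 0) return(NA_real_)
      sub <- sample$maps[rowsel, , , drop = FALSE]
      cm <- apply(sub, c(2, 3), mean) # cond x subj cluster means
      if (pmap$test == "anova") {
        df <- tibble::tibble(
          value = as.vector(cm),
          condition = rep(sample$conditions, times = ncol(cm)),
          subject = rep(seq_len(ncol(cm)), each = nrow(cm))
        )
        anova_conditions(df$value, df$condition, df$subject)$p_value
      } else if (pmap$test == "avg_vs_zero") {
        stats::t.test(colMeans(cm))$p.value
      } else {
        stats::t.test(cm[pmap$condition, ])$p.value
      }
    }, numeric(1))
    best <- which.min(ps)
    vs <- level_sets[[best]]
    if (length(vs) < min_vox) next
    rowsel <- vox_pos[vs]; rowsel <- rowsel[rowsel > 0]
    cm <- apply(sample$maps[rowsel, , , drop = FALSE], c(2, 3), mean)
    cond_means <- rowMeans(cm)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster = ci, level = best, n_vox = length(vs),
      p_uncorrected = ps[best],
      p_corrected = bonferroni(ps[best], n_mc),
      !!!stats::setNames(as.list(cond_means), paste0("mean_", sample$conditions))
    )
    vox_out[[length(vox_out) + 1]] <- vs
    lev_out[[length(lev_out) + 1]] <- level_sets
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else empty
  structure(list(table = tab, voxels = vox_out, levels = lev_out,
                 p_thresholds = p_thresholds, n_mc = n_mc, test = pmap$test,
                 condition = pmap$condition),
            class = "dot_cluster_result")
}

#' @export
print.dot_cluster_result <- function(x, ...) {
  cat("<dot_cluster_result> test =", x$test,
      if (!is.null(x$condition)) paste0("(", x$condition, ")"), "\n")
  if (nrow(x$table) == 0) cat("no clusters reported\n") else print(x$table)
  invisible(x)
}

#' @method tidy dot_cluster_result
#' @export
tidy.dot_cluster_result <- function(x, ...) x$table

#' Default regions of interest (left temporo-frontal template centers)
#'
#' Six left-hemisphere ROIs at infant-template coordinates: anterior STS,
#' superior temporal gyrus, inferior frontal gyrus, anterior insula,
#' mid-insula and posterior STS. Template coordinates (RAS mm) are mapped
#' onto the phantom grid by the affine in `template_affine` (rows give
#' phantom x/y/z as affine combinations of template x/y/z).
#'
#' @param radius_mm Sphere radius (mm), default 8.
#' @param template_affine 3 x 4 matrix mapping template (x, y, z, 1) to
#'   phantom mm coordinates.
#' @return A `dot_roi_set` tibble: `roi`, template coords, phantom coords.
#' @export
default_roi_set <- function(radius_mm = 8,
                            template_affine = rbind(c(0, 1, 0, 40),
                                                    c(0, 0, 1, 36),
                                                    c(1, 0, 0, 34))) {
  rois <- tibble::tribble(
    ~roi, ~tx, ~ty, ~tz,
    "aSTS", -26, -4, 1,
    "STG", -20, -6, -2,
    "IFG", -21, -9, 6,
    "AI", -24, 0, 8,
    "MI", -26, -8, 4,
    "pSTS", -20, -15, 1
  )
  pm <- t(apply(as.matrix(rois[, c("tx", "ty", "tz")]), 1, function(t3) {
    as.numeric(template_affine %*% c(t3, 1))
  }))
  rois$x_mm <- pm[, 1]; rois$y_mm <- pm[, 2]; rois$z_mm <- pm[, 3]
  structure(rois, class = c("dot_roi_set", class(rois)),
            radius_mm = radius_mm, template_affine = template_affine)
}

#' Region-of-interest analysis
#'
#' For each ROI (sphere about its template center intersected with gray
#' matter): per-condition mean window magnitudes across subjects, two-tailed
#' one-sample t-tests against baseline, a one-way ANOVA across conditions
#' with Tukey-Kramer post hoc when p < 0.05, and Bonferroni flags across the
#' six regions.
#'
#' @param sample A `dot_group_sample`.
#' @param rois A `dot_roi_set` (default [default_roi_set()]).
#' @param radius_mm Sphere radius override (mm).
#' @return A `dot_roi_stats`: `table` tibble (one row per ROI x condition:
#'   `magnitude`, `p_value`, `p_bonferroni`, `significant`), `anova` tibble
#'   (per ROI), `tukey` named list, `coverage` tibble.
#' @export
roi_analysis <- function(sample, rois = default_roi_set(), radius_mm = NULL) {
  if (is.null(radius_mm)) radius_mm <- attr(rois, "radius_mm")
  d <- sample$grid_shape
  vs <- sample$voxel_size_mm
  ijk <- arrayInd(sample$voxel_index, d) - 1L
  cx <- ijk[, 1] * vs + vs / 2
  cy <- ijk[, 2] * vs + vs / 2
  cz <- ijk[, 3] * vs + vs / 2
  gm_rows <- sample$gm_mask[sample$voxel_index]
  fov_rows <- sample$fov_mask[sample$voxel_index]
  n_roi <- nrow(rois)
  tab <- list(); an_rows <- list(); tks <- list(); cov_rows <- list()
  for (i in seq_len(n_roi)) {
    insph <- (cx - rois$x_mm[i])^2 + (cy - rois$y_mm[i])^2 +
      (cz - rois$z_mm[i])^2 <= radius_mm^2
    sel <- which(insph & gm_rows)
    if (length(sel) == 0) {
      # radius 0 fallback: nearest gray-matter voxel to the center
      d2 <- (cx - rois$x_mm[i])^2 + (cy - rois$y_mm[i])^2 + (cz - rois$z_mm[i])^2
      d2[!gm_rows] <- Inf
      sel <- which.min(d2)
    }
    cover <- if (any(insph)) mean(fov_rows[which(insph & gm_rows)]) else 0
    if (!is.finite(cover)) cover <- 0
    if (cover < 1) {
      rlang::warn(paste0("ROI ", rois$roi[i], " only partially inside the FOV (",
                         signif(100 * cover, 3), "% coverage)"))
    }
    cov_rows[[i]] <- tibble::tibble(roi = rois$roi[i], n_vox = length(sel),
                                    fov_coverage = cover)
    cm <- apply(sample$maps[sel, , , drop = FALSE], c(2, 3), mean) # cond x subj
    an <- anova_conditions(
      as.vector(cm), rep(sample$conditions, times = ncol(cm)),
      rep(seq_len(ncol(cm)), each = nrow(cm))
    )
    an_rows[[i]] <- tibble::tibble(roi = rois$roi[i], anova_f = an$statistic,
                                   anova_p = an$p_value)
    if (!is.na(an$p_value) && an$p_value < 0.05) {
      df <- tibble::tibble(value = as.vector(cm),
                           condition = rep(sample$conditions, times = ncol(cm)))
      tks[[rois$roi[i]]] <- tukey_kramer(df, "value", "condition")
    }
    tab[[i]] <- purrr::map_dfr(sample$conditions, function(cc) {
      tt <- safe_t(cm[cc, ])
      tibble::tibble(roi = rois$roi[i], condition = cc,
                     magnitude = mean(cm[cc, ]),
                     t = tt$statistic, p_value = tt$p.value)
    })
  }
  table <- dplyr::bind_rows(tab) |>
    dplyr::mutate(p_bonferroni = bonferroni(.data$p_value, n_roi),
                  significant_uncorrected = .data$p_value < 0.05,
                  significant_corrected = .data$p_bonferroni < 0.05)
  structure(list(table = table, anova = dplyr::bind_rows(an_rows),
                 tukey = tks, coverage = dplyr::bind_rows(cov_rows),
                 rois = rois, radius_mm = radius_mm),
            class = "dot_roi_stats")
}

#' @export
print.dot_roi_stats <- function(x, ...) {
  cat("<dot_roi_stats>", nrow(x$anova), "ROIs\n")
  print(dplyr::left_join(x$anova, x$coverage, by = "roi"))
  invisible(x)
}

#' @method tidy dot_roi_stats
#' @export
tidy.dot_roi_stats <- function(x, ...) x$table

#' Plot per-condition magnitudes for each ROI
#' @param object A `dot_roi_stats`.
#' @param ... Unused.
#' @method autoplot dot_roi_stats
#' @export
autoplot.dot_roi_stats <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$condition, .data$magnitude,
                               fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = NULL, y = "HbT magnitude (uM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
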