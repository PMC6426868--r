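# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small layered scene (24^3 grid at 2 mm) used by most unit tests
small_scene <- function() {
  cached("small_scene", function() {
    head <- build_layered_phantom(c(24, 24, 24))
    probe <- place_probe(head, layout = c(3, 4), spacing_mm = 13,
                         style = "offset")
    S <- compute_jacobian(head, probe)
    fov <- compute_fov(S, head, 0.001)
    list(head = head, probe = probe, S = S, fov = fov)
  })
}

# full-scale scene (40^3 at 2 mm, study probe) for acceptance tests
full_scene <- function() {
  cached("full_scene", function() infantdot:::build_scene(pipeline_config()))
}

# uniform recording straight from a channel x time matrix
matrix_recording <- function(x, rate_hz = 1, sds_mm = NULL, signal = "od",
                             triggers = NULL) {
  nch <- nrow(x)
  if (is.null(sds_mm)) sds_mm <- rep(30, nch)
  ch <- tibble::tibble(source = seq_len(nch), detector = seq_len(nch),
                       sds_mm = sds_mm, time_offset_s = 0)
  tt <- seq(0, by = 1 / rate_hz, length.out = ncol(x))
  if (is.null(triggers)) {
    triggers <- tibble::tibble(onset_s = numeric(), condition = character())
  }
  new_recording(x, tt, ch, triggers = triggers, signal = signal)
}

# group sample with given deterministic signal maps (voxels x conditions)
# plus iid subject noise, on the small scene grid
noise_group_sample <- function(scene, n_subjects, signal = NULL, sd = 1,
                               seed = 1, conditions = c("neutral", "happy", "angry", "sad")) {
  nv <- length(scene$S$voxel_index)
  nc <- length(conditions)
  maps <- withr::with_seed(seed, {
    m <- array(rnorm(nv * nc * n_subjects, 0, sd), dim = c(nv, nc, n_subjects))
    if (!is.null(signal)) m <- m + as.vector(signal)
    m
  })
  gm <- array(scene$head$tissue_levels[scene$head$labels] == "gm",
              dim = scene$head$grid_shape)
  group_sample(maps, scene$S$voxel_index, scene$head$grid_shape, conditions,
               gm, scene$fov, scene$head$voxel_size_mm)
}

# amplitude of a sinusoid at frequency f in x (least-squares fit on the
# central portion, avoiding filter edge transients)
fitted_amplitude <- function(x, t, f, trim = 0.2) {
  n <- length(x)
  keep <- seq(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  X <- cbind(sin(2 * pi * f * t[keep]), cos(2 * pi * f * t[keep]))
  cf <- stats::coef(stats::lm.fit(X, x[keep]))
  sqrt(sum(cf^2))
}
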