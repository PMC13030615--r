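# Shared fixtures, all generated in code. Scenes are cached per test file so
# repeated expectations on the same configuration do not regenerate it.

.fixtures <- new.env()

cached_scene <- function(name, config) {
  if (is.null(.fixtures[[name]]))
    assign(name, generate_scene(config), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default noise-free trial used by many tests
clean_bundle <- function() {
  cached_scene("clean", scene_config(n_cameras = 4, n_refpoints = 120,
                                     n_frames = 40, rng_seed = 1))
}

# a realistic multi-camera rig around a point, for calibration/triangulation
# oracles: returns list of projection matrices built from known parameters
oracle_cameras <- function(n, target = c(50, 0, -10), seed = 1,
                           focal = 2000) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pos <- c(runif(1, 0, 100),
             sample(c(-1, 1), 1) * runif(1, 25, 40),
             runif(1, -12, 5))
    R <- ptzmocap:::look_at_rotation(pos, target)
    camera_matrix(focal, c(1920, 1080), R, pos)
  })
}

# points scattered in front of the oracle cameras
oracle_points <- function(n, seed = 1, centre = c(50, 0, -10), spread = 8) {
  set.seed(seed)
  sweep(matrix(runif(3 * n, -spread, spread), n, 3), 2, centre, "+")
}
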