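# Shared fixtures built in code.

# a dark horizontal stripe (body rows) on a bright background
stripe_image <- function(nr = 40, nc = 60, rows = 18:25, bg = 200, body = 60) {
  img <- matrix(bg, nr, nc)
  img[rows, ] <- body
  img
}

# a rendered, unperturbed default-scale scene per family (memoised: scenes
# are reused by several tests)
.fixture_env <- new.env(parent = emptyenv())
fixture_scene <- function(family, seed = 5) {
  key <- paste(family, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    sp <- sample_posture(family, seed = seed)
    .fixture_env[[key]] <- render_scene(scene_spec(sp))
  }
  .fixture_env[[key]]
}

fixture_detection <- function(family, seed = 5) {
  key <- paste("det", family, seed, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    sc <- fixture_scene(family, seed)
    .fixture_env[[key]] <- detect_posture(sc$image, worm_config())
  }
  .fixture_env[[key]]
}

# analytic circular-arc midline with given total turning
arc_midline <- function(total_turning, n = 81, length = 180) {
  if (abs(total_turning) < 1e-12)
    return(cbind(seq(0, length, length.out = n), 0))
  r <- length / abs(total_turning)
  th <- seq(0, total_turning, length.out = n)
  cbind(r * sign(total_turning) * (1 - cos(th)), r * sin(abs(th)))
}

# traveling-wave angle series; dir = +1 moves bends from head toward tail
# (forward locomotion), dir = -1 the reverse
wave_angles <- function(n_frames, fps, dir = 1, amp = 0.5, freq = 0.4) {
  tt <- (seq_len(n_frames) - 1) / fps
  amp * sin(2 * pi * outer(tt * freq * dir, (1:18) / 12, "+"))
}
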