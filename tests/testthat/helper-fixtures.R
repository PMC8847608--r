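# Shared fixtures: small deterministic synthetic inputs built in code.

tiny_scene <- function(seed = 1) {
  scene_config(arena_side = 128L, body_axes = c(18, 10), body_osc = c(4, 8),
               facial_osc = c(2, 4), pixel_noise_rate = 0.002, seed = seed)
}

tiny_prep_config <- function() {
  preprocess_config(crop_side = 64L, out_side = 32L)
}

# random label track with valid bout structure (no rendering)
random_truth_track <- function(n_bouts = 4) {
  script_to_track(random_script(n_bouts))
}

# independent run-length scan used as oracle for bout extraction
oracle_bouts <- function(v) {
  out <- list()
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (v[i] != 0L) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      out[[length(out) + 1L]] <- c(cls = v[i], start = i - 1L, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, out)
}
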