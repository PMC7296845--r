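# Small builders shared across test files. All randomness is seeded locally.

random_frame <- function(nr = 8, nc = 8, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(nr * nc, 100, 10), nr, nc))
}

# A noise-free stack with one growing cluster; degenerate (MAD = 0) frames by
# construction, which is exactly what the zero-noise planted case produces.
monotone_cluster_stack <- function(n_frames = 10, onset = 5, gain = NULL) {
  amps <- seq(20, by = 15, length.out = n_frames - onset + 1)
  spec <- stack_spec(16, 16, n_frames, background_noise_sd = 0,
                     clusters = list(cluster_spec(c(8, 8), 3, onset, amps)),
                     global_gain_drift = gain, seed = 11)
  simulate_stack(spec)
}

fig2d_spec <- function(noise_sd = 0, seed = 1) {
  competition_spec_default(noise_sd = noise_sd, seed = seed)
}

expect_same_groups <- function(got, want) {
  norm <- function(gs) {
    gs <- lapply(gs, sort)
    gs[order(vapply(gs, `[`, character(1), 1L))]
  }
  expect_identical(norm(got), norm(want))
}
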