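#' Specification of one planted fluorescence cluster
#'
#' A hard disk of extra intensity appearing at a given frame, emulating a
#' somatic accumulation of internalized pHrodo-labelled antibody. Hard disks
#' keep area and count ground truth exact.
#'
#' @param center Length-2 vector `(row, col)` of the disk centre, 1-based
#'   pixel coordinates.
#' @param radius Disk radius in pixels (>= 1); a pixel belongs to the disk
#'   when its centre distance is <= `radius`.
#' @param onset_frame 1-based frame index at which the cluster first appears.
#' @param amplitude_curve Non-negative intensity added on the disk per frame,
#'   indexed from `onset_frame`; if the stack outlasts the curve the last
#'   value is held (plateau).
#' @return A `ClusterSpec` list.
#' @export
cluster_spec <- function(center, radius, onset_frame, amplitude_curve) {
  if (length(center) != 2L || any(!is.finite(center))) {
    mq_stop("`center` must be (row, col)", "mq_validation_error", field = "center")
  }
  stopifnot_scalar_num(radius, "radius")
  if (radius < 1) mq_stop("`radius` must be >= 1", "mq_validation_error", field = "radius")
  stopifnot_scalar_num(onset_frame, "onset_frame", positive = TRUE, integerish = TRUE)
  if (!is.numeric(amplitude_curve) || length(amplitude_curve) < 1L ||
      any(amplitude_curve < 0)) {
    mq_stop("`amplitude_curve` must be non-negative", "mq_validation_error",
            field = "amplitude_curve")
  }
  structure(list(center = as.numeric(center), radius = radius,
                 onset_frame = as.integer(onset_frame),
                 amplitude_curve = as.numeric(amplitude_curve)),
            class = "ClusterSpec")
}

#' Specification of a synthetic time-lapse stack
#'
#' Describes the simulated acquisition: frame geometry, a flat background
#' with additive Gaussian noise (clipped at 0; fluorescence cannot be
#' negative), planted clusters, and an optional frame-global multiplicative
#' gain drift that exercises the scale invariance of the MAD normalization.
#'
#' @param height,width Frame dimensions in pixels.
#' @param n_frames Number of frames (>= 4: the time-lapse threshold pools
#'   four baseline frames).
#' @param frame_interval Minutes between frames (default 15).
#' @param background_level Background intensity (a.u.).
#' @param background_noise_sd SD of the additive Gaussian pixel noise (a.u.).
#' @param clusters List of [cluster_spec()] objects.
#' @param global_gain_drift Strictly positive per-frame multiplicative
#'   factors (length `n_frames`; default all 1).
#' @param seed Integer seed; identical spec + seed gives a bit-identical stack.
#' @return A `StackSpec` list.
#' @export
stack_spec <- function(height, width, n_frames, frame_interval = 15,
                       background_level = 100, background_noise_sd = 5,
                       clusters = list(), global_gain_drift = NULL, seed = 1L) {
  stopifnot_scalar_num(height, "height", positive = TRUE, integerish = TRUE)
  stopifnot_scalar_num(width, "width", positive = TRUE, integerish = TRUE)
  stopifnot_scalar_num(n_frames, "n_frames", positive = TRUE, integerish = TRUE)
  if (n_frames < 4) {
    mq_stop("`n_frames` must be >= 4 (four baseline frames are pooled)",
            "mq_validation_error", field = "n_frames")
  }
  stopifnot_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  stopifnot_scalar_num(background_level, "background_level")
  if (background_level < 0) {
    mq_stop("`background_level` must be >= 0", "mq_validation_error",
            field = "background_level")
  }
  stopifnot_scalar_num(background_noise_sd, "background_noise_sd")
  if (background_noise_sd < 0) {
    mq_stop("`background_noise_sd` must be >= 0", "mq_validation_error",
            field = "background_noise_sd")
  }
  if (is.null(global_gain_drift)) global_gain_drift <- rep(1, n_frames)
  if (length(global_gain_drift) != n_frames || any(global_gain_drift <= 0)) {
    mq_stop("`global_gain_drift` must have one strictly positive factor per frame",
            "mq_validation_error", field = "global_gain_drift")
  }
  clusters <- lapply(clusters, function(cl) {
    if (!inherits(cl, "ClusterSpec")) cl <- do.call(cluster_spec, cl)
    if (cl$onset_frame > n_frames) {
      mq_stop("cluster `onset_frame` beyond stack length", "mq_validation_error",
              field = "onset_frame")
    }
    if (cl$center[1] < 1 || cl$center[1] > height ||
        cl$center[2] < 1 || cl$center[2] > width) {
      mq_stop("cluster `center` outside the frame", "mq_validation_error",
              field = "center")
    }
    cl
  })
  stopifnot_scalar_num(seed, "seed", integerish = TRUE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), frame_interval = frame_interval,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd, clusters = clusters,
                 global_gain_drift = as.numeric(global_gain_drift),
                 seed = as.integer(seed)),
            class = "StackSpec")
}

disk_mask <- function(height, width, center, radius) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Simulate a time-lapse fluorescence stack with known ground truth
#'
#' Frame `t` is `gain[t] * clip0(background + noise + sum of active cluster
#' disks)`, where a cluster is active from its onset frame on, contributing
#' its amplitude-curve value for that frame on its disk.
#'
#' @param spec A [stack_spec()].
#' @param position_id Identifier stored in the resulting stack.
#' @return List with `stack` (a [FrameStack][frame_stack]) and `truth`:
#'   per-cluster logical masks (`masks`), the combined integer `label_mask`
#'   (clusters numbered in spec order), `n_clusters`, and the `spec`.
#' @export
simulate_stack <- function(spec, position_id = "sim") {
  if (!inherits(spec, "StackSpec")) mq_stop("`spec` must be a StackSpec", "mq_validation_error")
  masks <- lapply(spec$clusters, function(cl)
    disk_mask(spec$height, spec$width, cl$center, cl$radius))
  frames <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(t) {
      f <- matrix(spec$background_level, spec$height, spec$width)
      if (spec$background_noise_sd > 0) {
        f <- f + matrix(stats::rnorm(length(f), 0, spec$background_noise_sd),
                        spec$height, spec$width)
      }
      for (i in seq_along(spec$clusters)) {
        cl <- spec$clusters[[i]]
        if (t >= cl$onset_frame) {
          idx <- min(t - cl$onset_frame + 1L, length(cl$amplitude_curve))
          f[masks[[i]]] <- f[masks[[i]]] + cl$amplitude_curve[idx]
        }
      }
      pmax(f, 0) * spec$global_gain_drift[t]
    })
  })
  label_mask <- matrix(0L, spec$height, spec$width)
  for (i in seq_along(masks)) label_mask[masks[[i]]] <- i
  list(stack = frame_stack(frames, spec$frame_interval, position_id),
       truth = list(masks = masks, label_mask = label_mask,
                    n_clusters = length(masks), spec = spec))
}
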