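#' Robust per-frame normalization of a fluorescence image
#'
#' Centres a frame by its median and scales by its raw median absolute
#' deviation (MAD, no consistency constant by default), the robust z-score
#' used to suppress inter-frame noise before computing the internalization
#' statistic. The output median is 0 and the result is invariant under
#' frame-global affine changes `a * frame + b` with `a > 0`, which is what
#' makes the downstream statistic immune to acquisition gain drift.
#'
#' @param frame Numeric matrix of non-negative intensities (a.u.).
#' @param mad_constant Multiplier applied to the raw MAD; `1` (default) is the
#'   plain MAD, `1.4826` the Gaussian-consistent version.
#' @return A `NormalizedFrame`: list with `values` (dimensionless matrix),
#'   `source_median` and `source_mad` (a.u.).
#' @details A frame whose MAD is exactly 0 (more than half the pixels share
#'   one value) cannot be scaled; this function then signals a classed error
#'   `mq_degenerate_frame` carrying the frame median, leaving the fallback
#'   policy to the caller (see [quantify_timelapse()]).
#' @examples
#' nf <- normalize_frame(matrix(c(1, 2, 3, 4, 5), nrow = 1))
#' nf$values  # (-2, -1, 0, 1, 2)
#' @seealso [quantify_timelapse()], [sum_above_threshold()]
#' @export
normalize_frame <- function(frame, mad_constant = 1) {
  frame <- as_frame_matrix(frame)
  stopifnot_scalar_num(mad_constant, "mad_constant", positive = TRUE)
  med <- stats::median(frame)
  s <- stats::median(abs(frame - med)) * mad_constant
  if (s == 0) {
    mq_stop("degenerate frame: MAD is 0 (constant or near-constant frame)",
            "mq_degenerate_frame", frame_median = med)
  }
  structure(
    list(values = (frame - med) / s, source_median = med, source_mad = s),
    class = "NormalizedFrame"
  )
}

# Normalization with the stack-level fallback cascade for MAD = 0 frames.
# "scale-cascade" (default): MAD, else mean absolute deviation from the
# median (still gain-equivariant), else centre-only (scale 1).
# "centre-only": MAD, else scale 1. "error": propagate the degenerate error.
normalize_with_fallback <- function(frame, mad_constant = 1,
                                    degenerate = c("scale-cascade", "centre-only", "error")) {
  degenerate <- match.arg(degenerate)
  frame <- as_frame_matrix(frame)
  med <- stats::median(frame)
  dev <- abs(frame - med)
  s <- stats::median(dev) * mad_constant
  scale_used <- "mad"
  if (s == 0) {
    if (degenerate == "error") {
      mq_stop("degenerate frame: MAD is 0", "mq_degenerate_frame", frame_median = med)
    }
    if (degenerate == "scale-cascade") {
      s <- mean(dev)
      scale_used <- "mean-absdev"
    }
    if (s == 0) {
      s <- 1
      scale_used <- "centre-only"
    }
  }
  structure(
    list(values = (frame - med) / s, source_median = med, source_mad = s,
         scale_used = scale_used),
    class = "NormalizedFrame"
  )
}

#' Background threshold from baseline frames of a time-lapse stack
#'
#' The time-lapse threshold `k` is the 99th percentile of the pooled pixel
#' values of the first `n_baseline` normalized frames (with 15-min acquisition
#' intervals, four frames cover the first hour, before internalization
#' signal develops).
#'
#' @param frames List of normalized frames ([NormalizedFrame][normalize_frame]
#'   objects or plain matrices already on the normalized scale).
#' @param n_baseline Number of leading frames pooled (default 4).
#' @param prob Percentile used (default 0.99).
#' @param quantile_type Quantile convention, as in [stats::quantile()]
#'   (default type 7, linear interpolation).
#' @return The scalar threshold `k` on the normalized (dimensionless) scale.
#' @export
estimate_threshold_timelapse <- function(frames, n_baseline = 4L, prob = 0.99,
                                         quantile_type = 7L) {
  stopifnot_scalar_num(n_baseline, "n_baseline", positive = TRUE, integerish = TRUE)
  if (!is.list(frames) || length(frames) < n_baseline) {
    mq_stop(sprintf("need at least n_baseline = %d frames, got %d",
                    n_baseline, length(frames)), "mq_validation_error")
  }
  pool <- unlist(lapply(frames[seq_len(n_baseline)], as_frame_matrix),
                 use.names = FALSE)
  mq_quantile(pool, prob, quantile_type)
}

#' Background threshold from control-condition images (static variant)
#'
#' For single-time-point experiments the threshold `k` is the 99th percentile
#' of the pooled pixels of images from a control-antibody condition,
#' normalized by the same convention as the test images.
#'
#' @param control_images List of normalized control images (matrices or
#'   `NormalizedFrame`s).
#' @inheritParams estimate_threshold_timelapse
#' @return The scalar threshold `k`.
#' @export
estimate_threshold_static <- function(control_images, prob = 0.99,
                                      quantile_type = 7L) {
  if (!is.list(control_images) || length(control_images) == 0L) {
    mq_stop("need at least one control image", "mq_validation_error")
  }
  pool <- unlist(lapply(control_images, as_frame_matrix), use.names = FALSE)
  mq_quantile(pool, prob, quantile_type)
}

#' Sum of normalized intensity strictly above a threshold
#'
#' The internalization statistic for one frame:
#' `S_int = sum_x x * [x > k]`, with Iverson bracket and strict inequality —
#' pixels at or below `k` contribute nothing.
#'
#' @param values Numeric matrix (or `NormalizedFrame`) on the normalized scale.
#' @param k Scalar threshold.
#' @return Scalar `S_int`.
#' @examples
#' sum_above_threshold(c(0, 1, 2, 3), k = 1)  # 5
#' @export
sum_above_threshold <- function(values, k) {
  values <- as_frame_matrix(values, "values")
  stopifnot_scalar_num(k, "k")
  sum(values[values > k])
}

#' Quantify internalization over a time-lapse stack
#'
#' Applies the full time-lapse pipeline: each frame is independently
#' median-centred and MAD-scaled, the threshold `k` is the 99th percentile of
#' the pooled first `n_baseline` normalized frames, and the per-frame
#' statistic `S_int` (sum of normalized intensity strictly above `k`) is
#' returned. Internalized antibody appearing as bright somatic accumulations
#' drives `S_int` up over frames, while frame-global gain drift and
#' background shifts cancel in the normalization.
#'
#' @param stack A [FrameStack][frame_stack] or plain list of numeric matrices.
#' @inheritParams estimate_threshold_timelapse
#' @param mad_constant See [normalize_frame()].
#' @param degenerate Fallback policy for frames with MAD = 0:
#'   `"scale-cascade"` (default; MAD, then mean absolute deviation from the
#'   median, then centre-only), `"centre-only"`, or `"error"`.
#' @return An `InternalizationResult`: list with `k`, `per_frame_Sint`,
#'   `threshold_mode = "time-lapse"`, `n_baseline_frames`,
#'   `degenerate_frames` (indices that needed the fallback) and the
#'   normalization settings used.
#' @export
quantify_timelapse <- function(stack, n_baseline = 4L, prob = 0.99,
                               quantile_type = 7L, mad_constant = 1,
                               degenerate = c("scale-cascade", "centre-only", "error")) {
  degenerate <- match.arg(degenerate)
  frames <- stack_frames(stack)
  stopifnot_scalar_num(n_baseline, "n_baseline", positive = TRUE, integerish = TRUE)
  if (length(frames) < n_baseline) {
    mq_stop(sprintf("stack has %d frames, need >= n_baseline = %d",
                    length(frames), n_baseline), "mq_validation_error")
  }
  norm <- lapply(frames, normalize_with_fallback, mad_constant = mad_constant,
                 degenerate = degenerate)
  degen <- which(vapply(norm, function(f) f$scale_used != "mad", logical(1)))
  k <- estimate_threshold_timelapse(norm, n_baseline = n_baseline, prob = prob,
                                    quantile_type = quantile_type)
  s <- vapply(norm, function(f) sum_above_threshold(f$values, k), numeric(1))
  structure(
    list(k = k, per_frame_Sint = s, threshold_mode = "time-lapse",
         n_baseline_frames = as.integer(n_baseline),
         degenerate_frames = as.integer(degen),
         normalization = list(mad_constant = mad_constant, prob = prob,
                              quantile_type = quantile_type,
                              degenerate = degenerate)),
    class = "InternalizationResult"
  )
}

#' Quantify internalization in single-time-point images
#'
#' Static variant: test and control images are normalized by the same
#' median/MAD convention, `k` is the 99th percentile of the pooled normalized
#' control-antibody pixels, and `S_int` is reported per test image.
#'
#' @param test_images,control_images Lists of numeric intensity matrices.
#' @inheritParams quantify_timelapse
#' @return An `InternalizationResult` with `threshold_mode = "static"` and one
#'   `per_frame_Sint` entry per test image.
#' @export
quantify_static <- function(test_images, control_images, prob = 0.99,
                            quantile_type = 7L, mad_constant = 1,
                            degenerate = c("scale-cascade", "centre-only", "error")) {
  degenerate <- match.arg(degenerate)
  if (!is.list(test_images) || length(test_images) == 0L) {
    mq_stop("`test_images` must be a non-empty list", "mq_validation_error")
  }
  if (!is.list(control_images) || length(control_images) == 0L) {
    mq_stop("`control_images` must be a non-empty list", "mq_validation_error")
  }
  norm_test <- lapply(test_images, normalize_with_fallback,
                      mad_constant = mad_constant, degenerate = degenerate)
  norm_ctrl <- lapply(control_images, normalize_with_fallback,
                      mad_constant = mad_constant, degenerate = degenerate)
  degen <- which(vapply(norm_test, function(f) f$scale_used != "mad", logical(1)))
  k <- estimate_threshold_static(norm_ctrl, prob = prob,
                                 quantile_type = quantile_type)
  s <- vapply(norm_test, function(f) sum_above_threshold(f$values, k), numeric(1))
  structure(
    list(k = k, per_frame_Sint = s, threshold_mode = "static",
         n_baseline_frames = NA_integer_,
         degenerate_frames = as.integer(degen),
         normalization = list(mad_constant = mad_constant, prob = prob,
                              quantile_type = quantile_type,
                              degenerate = degenerate)),
    class = "InternalizationResult"
  )
}

#' @export
print.InternalizationResult <- function(x, ...) {
  cat(sprintf("<InternalizationResult> mode = %s, k = %.4g, %d frame(s)\n",
              x$threshold_mode, x$k, length(x$per_frame_Sint)))
  cat("S_int:", format(x$per_frame_Sint, digits = 4), "\n")
  if (length(x$degenerate_frames)) {
    cat("degenerate frames (fallback scale):",
        paste(x$degenerate_frames, collapse = ", "), "\n")
  }
  invisible(x)
}
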