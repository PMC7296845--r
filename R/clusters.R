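#' Count super-threshold clusters in a normalized image
#'
#' Algorithmic surrogate for blinded manual counting of pHrodo-positive
#' somatic clusters: pixels strictly above `k` are segmented into connected
#' components (4- or 8-connectivity) and components smaller than `min_area`
#' pixels are discarded. Labels are assigned deterministically in raster
#' order (row by row, left to right, by each component's first pixel).
#'
#' @param values Numeric matrix (or `NormalizedFrame`) on the normalized scale.
#' @param k Threshold; pixels with `value > k` form the mask.
#' @param min_area Minimum component area in pixels (default 5).
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   default).
#' @return A `ClusterCount`: list with `n_clusters`, integer `cluster_labels`
#'   matrix (0 = background), `min_area`, `connectivity`.
#' @export
count_clusters <- function(values, k, min_area = 5L, connectivity = 8L) {
  values <- as_frame_matrix(values, "values")
  stopifnot_scalar_num(k, "k")
  stopifnot_scalar_num(min_area, "min_area", positive = TRUE, integerish = TRUE)
  if (!connectivity %in% c(4L, 8L)) {
    mq_stop("`connectivity` must be 4 or 8", "mq_validation_error",
            field = "connectivity")
  }
  mask <- values > k
  lab <- label_components(mask, connectivity)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area)
    relabel <- integer(max(lab))
    relabel[keep] <- seq_along(keep)   # raster order preserved: labels ascend
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  structure(
    list(n_clusters = max(lab), cluster_labels = lab,
         min_area = as.integer(min_area), connectivity = as.integer(connectivity)),
    class = "ClusterCount"
  )
}

# Connected-component labelling by flood fill, components numbered by the
# raster position of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(c(-1L, 0L, 1L), each = 3L), rep(c(-1L, 0L, 1L), 3L))[-5L, , drop = FALSE]
  }
  cur <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      queue <- matrix(c(i, j), ncol = 2L)
      lab[i, j] <- cur
      while (nrow(queue) > 0L) {
        p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
        for (o in seq_len(nrow(offs))) {
          ni <- p[1L] + offs[o, 1L]; nj <- p[2L] + offs[o, 2L]
          if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- rbind(queue, c(ni, nj))
          }
        }
      }
    }
  }
  lab
}

#' Per-ROI internalization calls
#'
#' Computes `S_int` within each region of interest (one cell or neuron,
#' delimited externally) and flags the ROI positive when its `S_int` exceeds
#' the positivity threshold.
#'
#' @param values Numeric matrix (or `NormalizedFrame`) on the normalized scale.
#' @param rois Named list of ROI masks: logical matrices with the image
#'   dimensions, or integer pixel-index vectors into the image.
#' @param k Intensity threshold for `S_int`.
#' @param positivity_threshold An ROI is positive when its `S_int` strictly
#'   exceeds this (default 0).
#' @return A `RoiPositivity`: list with `roi_ids`, `per_roi_Sint`,
#'   `positive_flags`, `fraction_positive`.
#' @export
classify_rois <- function(values, rois, k, positivity_threshold = 0) {
  values <- as_frame_matrix(values, "values")
  stopifnot_scalar_num(k, "k")
  stopifnot_scalar_num(positivity_threshold, "positivity_threshold")
  if (!is.list(rois) || length(rois) == 0L) {
    mq_stop("`rois` must be a non-empty list", "mq_validation_error", field = "rois")
  }
  ids <- names(rois)
  if (is.null(ids)) ids <- paste0("roi", seq_along(rois))
  s <- vapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    if (is.logical(roi)) {
      if (!identical(dim(roi), dim(values))) {
        mq_stop(sprintf("ROI '%s' mask dimensions do not match the image", ids[i]),
                "mq_roi_bounds_error", roi = ids[i])
      }
      px <- values[roi]
    } else {
      roi <- as.integer(roi)
      if (any(roi < 1L | roi > length(values))) {
        mq_stop(sprintf("ROI '%s' has pixel indices outside the image", ids[i]),
                "mq_roi_bounds_error", roi = ids[i])
      }
      px <- values[roi]
    }
    sum(px[px > k])
  }, numeric(1))
  names(s) <- ids
  flags <- s > positivity_threshold
  structure(
    list(roi_ids = ids, per_roi_Sint = s, positive_flags = flags,
         fraction_positive = mean(flags)),
    class = "RoiPositivity"
  )
}
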