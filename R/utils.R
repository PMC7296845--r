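# Internal helpers: classed conditions, seed handling, validation.

mq_stop <- function(msg, class, ...) {
  cond <- structure(
    class = c(class, "mabquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    mq_stop(sprintf("`%s` must be a single finite number", name), "mq_validation_error",
            field = name)
  }
  if (positive && x <= 0) {
    mq_stop(sprintf("`%s` must be > 0", name), "mq_validation_error", field = name)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    mq_stop(sprintf("`%s` must be a whole number", name), "mq_validation_error",
            field = name)
  }
  invisible(x)
}

# Quantile with a configurable convention; default type 7 (linear interpolation
# between closest order statistics, the mainstream numeric-stack default).
mq_quantile <- function(x, prob, type = 7L) {
  unname(stats::quantile(x, probs = prob, type = type, names = FALSE))
}

as_frame_matrix <- function(frame, name = "frame") {
  if (inherits(frame, "NormalizedFrame")) frame <- frame$values
  if (is.null(dim(frame))) frame <- matrix(frame, nrow = 1L)
  if (!is.numeric(frame) || length(frame) == 0L) {
    mq_stop(sprintf("`%s` must be a non-empty numeric matrix", name),
            "mq_validation_error", field = name)
  }
  if (any(!is.finite(frame))) {
    mq_stop(sprintf("`%s` contains non-finite values", name),
            "mq_validation_error", field = name)
  }
  frame
}
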