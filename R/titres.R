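#' End-point titre of a dilution series
#'
#' Reproducible surrogate for blinded visual end-point calls: a dilution is
#' positive when its signal exceeds a threshold derived from control wells
#' (default `mean(control) + 3 * sd(control)`), and the titre is the largest
#' reciprocal dilution still positive. An all-negative series yields titre 0
#' (below the starting dilution); a series positive at the last dilution is
#' flagged `unsaturated`.
#'
#' @param dilutions Strictly increasing reciprocal dilution factors
#'   (e.g. 40, 80, 160, ...).
#' @param signals Fluorescence signals (a.u.), one per dilution.
#' @param control_signals Control-well signals used by the default rule
#'   (>= 2 values); may be omitted when `rule` is a fixed numeric threshold.
#' @param rule Positivity rule: a function `control_signals -> threshold`, or
#'   a single numeric threshold. Default [endpoint_rule_mean_sd()].
#' @return An `EndpointTitre`: list with `titre` (reciprocal dilution, 0 if
#'   negative), `threshold`, `positive` (per-dilution logical),
#'   `unsaturated`.
#' @export
endpoint_titre <- function(dilutions, signals, control_signals = NULL,
                           rule = endpoint_rule_mean_sd()) {
  if (length(dilutions) != length(signals) || length(dilutions) == 0L) {
    mq_stop("`dilutions` and `signals` must be aligned and non-empty",
            "mq_validation_error", field = "dilutions")
  }
  if (any(diff(dilutions) <= 0)) {
    mq_stop("`dilutions` must be strictly increasing", "mq_validation_error",
            field = "dilutions")
  }
  threshold <- if (is.numeric(rule)) {
    stopifnot_scalar_num(rule, "rule")
    rule
  } else {
    if (is.null(control_signals) || length(control_signals) < 2L) {
      mq_stop("the control-based rule needs `control_signals` (>= 2 values)",
              "mq_validation_error", field = "control_signals")
    }
    rule(control_signals)
  }
  positive <- signals > threshold
  titre <- if (any(positive)) max(dilutions[positive]) else 0
  structure(
    list(titre = titre, threshold = threshold, positive = positive,
         unsaturated = all(positive)),
    class = "EndpointTitre"
  )
}

#' Default end-point positivity rule: mean(control) + n_sd * sd(control)
#'
#' @param n_sd Number of control standard deviations above the control mean
#'   (default 3).
#' @return A rule function for [endpoint_titre()].
#' @export
endpoint_rule_mean_sd <- function(n_sd = 3) {
  force(n_sd)
  function(control_signals) mean(control_signals) + n_sd * stats::sd(control_signals)
}

#' Ratio of LRR to EPTP domain end-point titres
#'
#' Tracks the relative contribution of the two LGI1 domains to a serum's
#' reactivity over time. A zero denominator is reported as a one-sided
#' domain-negative result, never as infinity.
#'
#' @param lrr_titre,eptp_titre Reciprocal end-point titres (>= 0).
#' @param orientation `"lrr_over_eptp"` (default) or `"eptp_over_lrr"`.
#' @return A `DomainRatio`: list with `ratio` (NA when one-sided), `flag`
#'   (`"ok"`, `"EPTP-negative"`, `"LRR-negative"`, or `"both-negative"`),
#'   and the `orientation`.
#' @examples
#' domain_ratio(80, 640)$ratio  # 0.125: an 8-fold EPTP excess
#' @export
domain_ratio <- function(lrr_titre, eptp_titre,
                         orientation = c("lrr_over_eptp", "eptp_over_lrr")) {
  orientation <- match.arg(orientation)
  stopifnot_scalar_num(lrr_titre, "lrr_titre")
  stopifnot_scalar_num(eptp_titre, "eptp_titre")
  if (lrr_titre < 0 || eptp_titre < 0) {
    mq_stop("titres must be >= 0", "mq_validation_error", field = "lrr_titre")
  }
  num <- if (orientation == "lrr_over_eptp") lrr_titre else eptp_titre
  den <- if (orientation == "lrr_over_eptp") eptp_titre else lrr_titre
  flag <- "ok"
  ratio <- NA_real_
  if (lrr_titre == 0 && eptp_titre == 0) {
    flag <- "both-negative"
  } else if (eptp_titre == 0) {
    flag <- "EPTP-negative"
    if (orientation == "eptp_over_lrr") ratio <- 0
  } else if (lrr_titre == 0) {
    flag <- "LRR-negative"
    if (orientation == "lrr_over_eptp") ratio <- 0
  } else {
    ratio <- num / den
  }
  structure(list(ratio = ratio, flag = flag, orientation = orientation),
            class = "DomainRatio")
}

# All permutations of 1..n, one per row (n! rows). Used for exact p-values.
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}

#' Spearman rank correlation with a permutation p-value
#'
#' Rank correlation (mid-ranks for ties) between paired titres, with a
#' two-sided p-value by exhaustive enumeration of all rank permutations when
#' `n <= exact_max_n`, and seeded Monte-Carlo permutation otherwise —
#' appropriate for the small panels typical of patient-derived antibody
#' studies.
#'
#' @param x,y Paired numeric vectors, length >= 4.
#' @param exact_max_n Use exhaustive enumeration up to this n (default 7).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `rho`, `p_value`, `method` (`"exact"` or
#'   `"permutation"`), `n`.
#' @export
correlate_titres <- function(x, y, exact_max_n = 7L, n_perm = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 4L) {
    mq_stop("`x` and `y` must be aligned with length >= 4", "mq_validation_error")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    mq_stop("correlation undefined for a constant vector", "mq_constant_input_error")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (n <= exact_max_n) {
    perms <- permutations_all(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    p_value <- withr::with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    })
    method <- "permutation"
  }
  list(rho = rho, p_value = p_value, method = method, n = n)
}
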