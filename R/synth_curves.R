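#' Specification of a synthetic one-site titration
#'
#' Ground-truth counterpart of the one-site hyperbola parameters: specific
#' binding `y = Bmax * x / (x + Kd)` evaluated on a concentration grid with
#' additive Gaussian noise (clipped at 0).
#'
#' @param true_Kd Equilibrium dissociation constant (µg/ml), > 0.
#' @param true_Bmax Maximal specific binding (a.u.), > 0.
#' @param concentrations Antibody concentrations (µg/ml), >= 0, at least 4
#'   distinct values.
#' @param noise_sd SD of the additive measurement noise (a.u.).
#' @param seed Integer seed.
#' @return A `TitrationSpec` list.
#' @export
titration_spec <- function(true_Kd, true_Bmax, concentrations, noise_sd = 0,
                           seed = 1L) {
  stopifnot_scalar_num(true_Kd, "true_Kd", positive = TRUE)
  stopifnot_scalar_num(true_Bmax, "true_Bmax", positive = TRUE)
  if (!is.numeric(concentrations) || any(concentrations < 0) ||
      length(unique(concentrations)) < 4L) {
    mq_stop("`concentrations` must be >= 0 with at least 4 distinct values",
            "mq_validation_error", field = "concentrations")
  }
  stopifnot_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) mq_stop("`noise_sd` must be >= 0", "mq_validation_error",
                            field = "noise_sd")
  stopifnot_scalar_num(seed, "seed", integerish = TRUE)
  structure(list(true_Kd = true_Kd, true_Bmax = true_Bmax,
                 concentrations = as.numeric(concentrations),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "TitrationSpec")
}

#' Simulate a titration curve from the one-site model
#'
#' @param spec A [titration_spec()].
#' @return A [titration_curve()] with attribute `truth` holding the
#'   generating parameters.
#' @export
simulate_titration <- function(spec) {
  if (!inherits(spec, "TitrationSpec")) {
    mq_stop("`spec` must be a TitrationSpec", "mq_validation_error")
  }
  x <- spec$concentrations
  mu <- spec$true_Bmax * x / (x + spec$true_Kd)
  y <- if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, pmax(mu + stats::rnorm(length(x), 0, spec$noise_sd), 0))
  } else {
    mu
  }
  curve <- titration_curve(x, y)
  attr(curve, "truth") <- list(Kd = spec$true_Kd, Bmax = spec$true_Bmax,
                               noise_sd = spec$noise_sd, seed = spec$seed)
  curve
}

#' Simulate a dilution series with a known end-point titre
#'
#' Generates signals for a doubling (or arbitrary) dilution ladder: dilutions
#' up to the planted titre read `positive_signal`, the rest read background,
#' each with additive Gaussian noise (clipped at 0); control signals are
#' background draws.
#'
#' @param dilutions Strictly increasing reciprocal dilution factors
#'   (e.g. `c(40, 80, 160, ...)`).
#' @param true_titre Planted reciprocal end-point titre; must be one of
#'   `dilutions` or 0 (all-negative series).
#' @param positive_signal,background_signal Mean signals (a.u.) for positive
#'   and negative wells.
#' @param noise_sd SD of additive noise (a.u.).
#' @param n_controls Number of control wells.
#' @param seed Integer seed.
#' @return List with `dilutions`, `signals`, `control_signals`, and `truth`.
#' @export
simulate_dilution_series <- function(dilutions, true_titre,
                                     positive_signal = 1000,
                                     background_signal = 100,
                                     noise_sd = 10, n_controls = 8L, seed = 1L) {
  if (!is.numeric(dilutions) || any(diff(dilutions) <= 0)) {
    mq_stop("`dilutions` must be strictly increasing", "mq_validation_error",
            field = "dilutions")
  }
  if (!(true_titre == 0 || true_titre %in% dilutions)) {
    mq_stop("`true_titre` must be 0 or one of `dilutions`", "mq_validation_error",
            field = "true_titre")
  }
  if (positive_signal <= background_signal) {
    mq_stop("`positive_signal` must exceed `background_signal`",
            "mq_validation_error", field = "positive_signal")
  }
  withr::with_seed(seed, {
    mu <- ifelse(dilutions <= true_titre, positive_signal, background_signal)
    signals <- pmax(mu + stats::rnorm(length(dilutions), 0, noise_sd), 0)
    controls <- pmax(background_signal + stats::rnorm(n_controls, 0, noise_sd), 0)
    list(dilutions = as.numeric(dilutions), signals = signals,
         control_signals = controls,
         truth = list(titre = true_titre, seed = seed))
  })
}
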