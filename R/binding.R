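#' Titration curve container
#'
#' Antibody concentration versus background-corrected specific-binding
#' fluorescence, the input to the one-site fit. Background subtraction is
#' the caller's duty: `y` must already be specific binding.
#'
#' @param x Concentrations (µg/ml), >= 0, at least 4 points and 3 distinct
#'   values.
#' @param y Specific-binding fluorescence (a.u.), same length as `x`.
#' @return A `TitrationCurve` data.frame with columns `x`, `y`.
#' @export
titration_curve <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    mq_stop("`x` and `y` must have equal length >= 4", "mq_validation_error",
            field = "x")
  }
  if (any(x < 0) || any(!is.finite(x)) || any(!is.finite(y))) {
    mq_stop("`x` must be >= 0 and finite, `y` finite", "mq_validation_error",
            field = "x")
  }
  if (length(unique(x)) < 3L) {
    mq_stop("need at least 3 distinct concentrations", "mq_validation_error",
            field = "x")
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            class = c("TitrationCurve", "data.frame"))
}

one_site_mu <- function(x, Bmax, Kd) Bmax * x / (x + Kd)

#' Fit the one-site specific-binding hyperbola
#'
#' Least-squares estimation of `y = Bmax * x / (x + Kd)` by damped
#' (Levenberg–Marquardt) least squares on `(log Bmax, log Kd)`, which
#' enforces positivity of both parameters. Starting values are
#' `Bmax0 = max(y)` and `Kd0 =` the smallest concentration at which `y`
#' reaches half of `Bmax0`. Standard errors come from the local curvature
#' (Gauss–Newton approximation `J'J` at the optimum, residual variance
#' `rss / (n - 2)`).
#'
#' @param curve A [titration_curve()] (or any list/data.frame with `x`, `y`).
#' @param max_iter Maximum LM iterations.
#' @param tol Convergence tolerance on the relative RSS decrease and gradient.
#' @return A `BindingFit`: list with `Kd`, `Bmax`, `standard_errors`
#'   (named, on the natural scale), `rss`, `converged`, `n_iter`.
#' @examples
#' curve <- simulate_titration(titration_spec(2, 500, c(0.25, 0.5, 1, 2, 4, 8, 16, 32)))
#' fit <- fit_one_site(curve)
#' c(fit$Kd, fit$Bmax)  # 2, 500 at machine precision (noise-free)
#' @export
fit_one_site <- function(curve, max_iter = 200L, tol = 1e-12) {
  x <- curve$x; y <- curve$y
  if (is.null(x) || is.null(y)) {
    mq_stop("`curve` must have components x and y", "mq_validation_error")
  }
  if (all(y == y[1])) {
    mq_stop("all y values equal; no binding signal to fit", "mq_validation_error",
            field = "y")
  }
  if (all(y == 0)) mq_stop("all y values are zero", "mq_validation_error", field = "y")

  Bmax0 <- max(y)
  ord <- order(x)
  half_idx <- which(y[ord] >= Bmax0 / 2)[1]
  Kd0 <- x[ord][half_idx]
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- stats::median(x[x > 0])
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- 1

  theta <- c(log(Bmax0), log(Kd0))  # (log Bmax, log Kd)
  resid_fun <- function(theta) y - one_site_mu(x, exp(theta[1]), exp(theta[2]))
  jac_fun <- function(theta) {
    Bmax <- exp(theta[1]); Kd <- exp(theta[2])
    mu <- one_site_mu(x, Bmax, Kd)
    # d(resid)/d(theta) = -d(mu)/d(theta)
    cbind(-mu, mu * Kd / (x + Kd))
  }

  r <- resid_fun(theta)
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fun(theta)
    g <- crossprod(J, r)          # gradient of rss/2
    A <- crossprod(J)
    step_ok <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(solve(A + lambda * diag(diag(A) + 1e-12)), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      delta <- -delta %*% g
      theta_new <- theta + as.numeric(delta)
      r_new <- resid_fun(theta_new)
      rss_new <- sum(r_new^2)
      if (is.finite(rss_new) && rss_new <= rss) {
        theta <- theta_new; r <- r_new
        improve <- (rss - rss_new) / max(rss, .Machine$double.eps)
        rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        if (improve < tol || sqrt(sum(g^2)) < tol * (1 + rss)) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no downhill step: local optimum
    if (converged) break
  }

  Bmax <- exp(theta[1]); Kd <- exp(theta[2])
  # Curvature-based SEs on the natural (Bmax, Kd) scale.
  u <- x / (x + Kd)
  Jnat <- cbind(u, -Bmax * x / (x + Kd)^2)
  n <- length(y)
  se <- c(Bmax = NA_real_, Kd = NA_real_)
  if (n > 2) {
    sigma2 <- rss / (n - 2)
    covm <- tryCatch(solve(crossprod(Jnat)) * sigma2, error = function(e) NULL)
    if (!is.null(covm)) se <- c(Bmax = sqrt(covm[1, 1]), Kd = sqrt(covm[2, 2]))
  }
  structure(
    list(Kd = Kd, Bmax = Bmax, standard_errors = se, rss = rss,
         converged = converged, n_iter = iter),
    class = "BindingFit"
  )
}

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf("<BindingFit> Kd = %.4g (SE %.3g) ug/ml, Bmax = %.4g (SE %.3g) a.u.\n",
              x$Kd, x$standard_errors["Kd"], x$Bmax, x$standard_errors["Bmax"]))
  cat(sprintf("rss = %.4g, converged = %s after %d iteration(s)\n",
              x$rss, x$converged, x$n_iter))
  invisible(x)
}
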