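#' Robust simple linear regression under the Huber loss
#'
#' Fits `y = intercept + slope * x` by iteratively reweighted least
#' squares minimising the Huber loss. Residual scale is re-estimated each
#' iteration by the normalised median absolute deviation (MAD, consistency
#' constant 1.4826); observations with `|residual| <= k * scale` get unit
#' weight, larger residuals get weight `k * scale / |residual|`. Iteration
#' stops when the largest coefficient change is below `tol` or after
#' `max_iter` iterations (non-convergence is flagged and the last iterate
#' returned). The default tuning constant `k = 1.345` gives 95% efficiency
#' at the Gaussian model; as `k -> Inf` the fit approaches ordinary least
#' squares.
#'
#' @param x,y equal-length finite numeric vectors, `n >= 3`; in the
#'   dominance analysis `x` holds CFC effect sizes and `y` CE effect sizes.
#' @param k Huber tuning constant (default 1.345).
#' @param max_iter maximum IRLS iterations (default 200).
#' @param tol convergence tolerance on the coefficients (default 1e-8).
#' @return An object of class `"huber_fit"`: list with `intercept`,
#'   `slope`, `tuning_constant`, `scale_estimate`, `n_points`, `converged`,
#'   `iterations`, `pearson_r` (plain Pearson correlation of `x` and `y`),
#'   `fitted`, `residuals`, `x`, `y`.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' huber_fit(x, 2 * x + 1)
#' @export
huber_fit <- function(x, y, k = 1.345, max_iter = 200L, tol = 1e-8) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) stop("x and y must be finite", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (max(x) == min(x)) {
    stop("degenerate design: x is constant", call. = FALSE)
  }
  check_positive(k, "k")

  wls <- function(w) {
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    sxx <- sum(w * (x - mx)^2)
    slope <- sum(w * (x - mx) * (y - my)) / sxx
    c(my - slope * mx, slope)
  }

  coefs <- wls(rep(1, n))  # OLS start
  converged <- FALSE
  s <- 0
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- y - coefs[1] - coefs[2] * x
    s <- mad(r)  # normalised MAD about the median
    if (s < 1e-12) {        # (near-)interpolating fit; nothing to reweight
      converged <- TRUE
      break
    }
    u <- abs(r) / (k * s)
    w <- ifelse(u <= 1, 1, 1 / u)
    new <- wls(w)
    delta <- max(abs(new - coefs))
    coefs <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Huber IRLS did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  fitted <- coefs[1] + coefs[2] * x
  structure(list(intercept = coefs[1], slope = coefs[2],
                 tuning_constant = k, scale_estimate = s,
                 n_points = n, converged = converged, iterations = it,
                 pearson_r = cor(x, y),
                 fitted = fitted, residuals = y - fitted,
                 x = x, y = y),
            class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat(sprintf(
    "Huber regression (k = %g): y = %.4f x + %.4f\n", x$tuning_constant,
    x$slope, x$intercept))
  cat(sprintf("  n = %d, Pearson r = %.4f, scale (MAD) = %.4g, %s\n",
              x$n_points, x$pearson_r, x$scale_estimate,
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations)
              else "NOT converged"))
  invisible(x)
}

#' @param object a `huber_fit`.
#' @param newdata optional numeric vector of x values (defaults to the
#'   training x).
#' @param ... unused.
#' @rdname huber_fit
#' @export
predict.huber_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * xx
}

#' Bootstrap percentile confidence bands for Huber-predicted values
#'
#' Resamples `(x, y)` pairs with replacement `n_boot` times, refits the
#' Huber regression on each resample, and takes the 2.5 and 97.5
#' percentiles (for `level = 0.95`) of the fitted values at each original
#' `x`. Resamples with constant `x` cannot be fitted; they are skipped and
#' counted in the `n_skipped` attribute. The procedure is deterministic
#' given `seed`.
#'
#' @inheritParams huber_fit
#' @param n_boot number of bootstrap resamples (default 5000; a warning is
#'   issued below 100).
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @param level confidence level (default 0.95).
#' @return Data frame with `x`, `fit` (full-data fitted value), `ci_low`,
#'   `ci_high`, one row per original point (in input order); attributes
#'   `n_skipped` and `fit` (the full-data `huber_fit`).
#' @export
bootstrap_prediction_ci <- function(x, y, n_boot = 5000L, seed = NULL,
                                    level = 0.95, k = 1.345) {
  n_boot <- check_count(n_boot, "n_boot")
  if (n_boot < 100L) {
    warning("n_boot < 100 gives unstable percentile intervals")
  }
  fit <- huber_fit(x, y, k = k)
  n <- fit$n_points
  alpha <- (1 - level) / 2
  with_seed_(seed, {
    boots <- matrix(NA_real_, n_boot, n)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- fit$x[idx]
      if (max(xb) == min(xb)) {
        skipped <- skipped + 1L
        next
      }
      fb <- huber_fit(xb, fit$y[idx], k = k)
      boots[b, ] <- fb$intercept + fb$slope * fit$x
    }
    if (skipped > 0L) {
      message(skipped, " degenerate resamples (constant x) skipped")
    }
    ci <- apply(boots, 2, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE)
    out <- data.frame(x = fit$x, fit = fit$fitted,
                      ci_low = ci[1, ], ci_high = ci[2, ])
    attr(out, "n_skipped") <- skipped
    attr(out, "fit") <- fit
    out
  })
}
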