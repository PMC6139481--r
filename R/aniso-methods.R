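# S3 methods for the aniso_fit estimator.

#' @export
print.aniso_fit <- function(x, ...) {
  cat("Anisotropic B-tensor fit (", x$source, " data)\n", sep = "")
  cat(sprintf("  eigenvalues (A^2): %.2f %.2f %.2f   delta-B = %.2f\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3],
              delta_b(x)))
  cat(sprintf("  %d reflections used, %d rejected in %d cycle(s)\n",
              x$n_used, x$n_rejected, x$cycles))
  invisible(x)
}

#' Coefficients of an anisotropic B-tensor fit
#'
#' @param object An `aniso_fit`.
#' @param ... Unused.
#' @return Named vector of the six unique tensor components (A^2) plus
#'   the log-scale intercept.
#' @export
coef.aniso_fit <- function(object, ...) {
  b <- object$b_cart
  c(b11 = b[1, 1], b22 = b[2, 2], b33 = b[3, 3],
    b12 = b[1, 2], b13 = b[1, 3], b23 = b[2, 3],
    log_scale = object$scale_log)
}

#' Summarize an anisotropic B-tensor fit
#'
#' @param object An `aniso_fit`.
#' @param ... Unused.
#' @return An object of class `summary.aniso_fit` with eigenstructure,
#'   delta-B, anisotropy ratio of eigenvalues, rejection statistics and
#'   residual RMS.
#' @export
summary.aniso_fit <- function(object, ...) {
  structure(list(
    source = object$source,
    b_cart = object$b_cart,
    eigenvalues = object$eigenvalues,
    eigenvectors = object$eigenvectors,
    delta_b = delta_b(object),
    n_used = object$n_used,
    n_rejected = object$n_rejected,
    pct_rejected = pct_rejected(object$n_rejected, object$n_used),
    cycles = object$cycles,
    rms_residual = sqrt(mean(object$residuals^2))
  ), class = "summary.aniso_fit")
}

#' @export
print.summary.aniso_fit <- function(x, ...) {
  cat("Anisotropic B-tensor fit (", x$source, " data)\n\n", sep = "")
  cat("B tensor (Cartesian, A^2):\n")
  print(round(x$b_cart, 3))
  cat("\nPrincipal components:\n")
  for (k in 1:3) {
    cat(sprintf("  b%d = %8.3f A^2  axis (%6.3f %6.3f %6.3f)\n", k,
                x$eigenvalues[k], x$eigenvectors[1, k],
                x$eigenvectors[2, k], x$eigenvectors[3, k]))
  }
  cat(sprintf("\ndelta-B: %.3f A^2\n", x$delta_b))
  cat(sprintf("residual RMS: %.4f (log-intensity units)\n", x$rms_residual))
  cat(sprintf("rejected: %d of %d (%.2f%%) in %d cycle(s)\n",
              x$n_rejected, x$n_used, x$pct_rejected, x$cycles))
  invisible(x)
}

#' Residuals of the tensor fit
#'
#' @param object An `aniso_fit`.
#' @param ... Unused.
#' @return Log-intensity residuals for the reflections used in the fit.
#' @export
residuals.aniso_fit <- function(object, ...) object$residuals

#' Predicted directional log-attenuation
#'
#' Evaluates the fitted model c - 2 s^2 (n' B n) for new Miller indices
#' in the fit's cell: the expected log ratio of intensity to its
#' resolution-shell mean.
#'
#' @param object An `aniso_fit`.
#' @param newdata Integer n x 3 matrix of Miller indices; when omitted the
#'   fitted values of the training reflections are returned.
#' @param ... Unused.
#' @return Numeric vector of predicted log-intensity residuals.
#' @export
predict.aniso_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  hkl <- as.matrix(newdata)
  s <- scattering_vector(hkl, object$cell)
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  slen2 <- rowSums(s^2)
  nhat <- s / sqrt(slen2)
  proj <- rowSums((nhat %*% object$b_cart) * nhat)
  s2 <- slen2 / 4  # s = |s_vec|/2 under the 1/(2d) convention
  object$scale_log - 2 * s2 * proj
}

#' Diagnostic plot of the tensor fit
#'
#' Residual log-intensity against s^2, coloured by the alignment of each
#' reflection with the weakest-diffracting principal axis. A clean fit
#' shows no residual trend.
#'
#' @param x An `aniso_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.aniso_fit <- function(x, ...) {
  align <- abs(x$nhat %*% x$eigenvectors[, 3])
  cols <- grDevices::gray(1 - 0.8 * align)
  graphics::plot(x$s2, x$residuals, pch = 16, cex = 0.4, col = cols,
                 xlab = expression(s^2 ~ (ring(A)^-2)),
                 ylab = "log-intensity residual",
                 main = sprintf("aniso fit (%s), delta-B = %.1f A^2",
                                x$source, delta_b(x)), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Simulate reflection sets from a fitted tensor
#'
#' Draws Wilson-distributed synthetic reflection sets whose directional
#' attenuation follows the fitted B tensor, in the fit's own cell.
#'
#' @param object An `aniso_fit`.
#' @param nsim Number of sets.
#' @param seed Integer seed.
#' @param dmin High-resolution limit of the simulated sets (Angstrom).
#' @param ... Unused.
#' @return List of [reflection_set()] objects of length `nsim`.
#' @export
simulate.aniso_fit <- function(object, nsim = 1, seed = NULL, dmin = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(sd) {
    gen_reflections(simulation_spec(
      cell = object$cell, dmin = dmin,
      b_tensor = object$b_cart - diag(min(object$eigenvalues), 3),
      seed = sd))
  })
}
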