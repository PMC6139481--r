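# Reciprocal-space statistics: resolution-shell binning, the Wilson
# B-factor, and the anisotropic B-tensor least-squares fit with its
# derived quantities (delta-B, directional F/sigF limits, delta_res).
#
# Convention used everywhere: s = sin(theta)/lambda = 1/(2d). Amplitudes
# attenuate as exp(-B(n) s^2), intensities as exp(-2 B(n) s^2), where
# B(n) = n' B n is the tensor projected on the unit scattering direction.

#' Resolution-shell binning
#'
#' Partitions reflections with usable working intensity into `n_shells`
#' shells of near-equal population (sizes differ by at most one), ordered
#' from low resolution (shell 1, largest d) to high.
#'
#' @param refl A [reflection_set()].
#' @param n_shells Number of shells.
#' @param source Use intensities directly or squared amplitudes.
#' @return List with `shell` (per-reflection shell index, NA where the
#'   working intensity is unusable), `mean_i`, `mean_d`, `mean_s2`
#'   (per-shell means; s = 1/(2d)) and `n` (per-shell counts).
#' @export
shell_binning <- function(refl, n_shells = 20,
                          source = c("amplitudes", "intensities")) {
  source <- match.arg(source)
  iw <- .working_intensity(refl, source)
  d <- refl_d(refl)
  usable <- is.finite(iw)
  n_use <- sum(usable)
  if (n_use < n_shells) {
    stop("only ", n_use, " usable reflections for ", n_shells,
         " shells; use a smaller n_shells")
  }
  ord <- order(d[usable], decreasing = TRUE)
  idx <- which(usable)[ord]
  # near-equal partition: first (n mod k) shells get one extra reflection
  base <- n_use %/% n_shells
  extra <- n_use %% n_shells
  sizes <- rep(base, n_shells) + c(rep(1L, extra), rep(0L, n_shells - extra))
  shell <- rep(NA_integer_, refl$n)
  shell[idx] <- rep(seq_len(n_shells), times = sizes)
  s2 <- 1 / (4 * d^2)
  mean_i <- tapply(iw[idx], shell[idx], mean)
  mean_d <- tapply(d[idx], shell[idx], mean)
  mean_s2 <- tapply(s2[idx], shell[idx], mean)
  list(shell = shell, mean_i = as.numeric(mean_i),
       mean_d = as.numeric(mean_d), mean_s2 = as.numeric(mean_s2),
       n = as.integer(sizes))
}

#' Wilson B-factor
#'
#' Weighted least-squares straight line of per-shell log mean intensity
#' against mean s^2 (s = 1/(2d)); the Wilson B is -slope/2. Shells with
#' mean resolution coarser than `d_max_fit` are excluded (the
#' low-resolution regime does not follow Wilson statistics); shells with
#' non-positive mean intensity are dropped with a warning. Weights are the
#' shell populations.
#'
#' @param refl A [reflection_set()].
#' @param source Data path: squared amplitudes or intensities.
#' @param n_shells Number of resolution shells (default 20).
#' @param d_max_fit Low-resolution cutoff for the fit, Angstrom.
#' @return Wilson B in square Angstrom. Negative values are possible for
#'   pathological input and flagged with a warning.
#' @examples
#' refl <- gen_reflections(simulation_spec(b_tensor = diag(30, 3), seed = 1,
#'                                         noise_free = TRUE))
#' wilson_b(refl, source = "intensities")  # close to 30
#' @export
wilson_b <- function(refl, source = c("amplitudes", "intensities"),
                     n_shells = 20, d_max_fit = 4.5) {
  source <- match.arg(source)
  sb <- shell_binning(refl, n_shells = n_shells, source = source)
  keep <- sb$mean_d <= d_max_fit
  bad <- keep & sb$mean_i <= 0
  if (any(bad)) {
    warning(sum(bad), " shell(s) with non-positive mean intensity dropped")
    keep <- keep & !bad
  }
  if (sum(keep) < 3) {
    stop("fewer than 3 shells inside the Wilson fit range (d <= ",
         d_max_fit, " A)")
  }
  fit <- stats::lm.wfit(cbind(1, sb$mean_s2[keep]), log(sb$mean_i[keep]),
                        w = sb$n[keep])
  b <- -fit$coefficients[2] / 2
  if (!is.finite(b)) stop("Wilson fit did not produce a finite slope")
  if (b < 0) warning("negative Wilson B (", signif(b, 4),
                     " A^2): non-Wilson intensity falloff")
  unname(b)
}

#' Fit the anisotropic B tensor
#'
#' Iterative least squares for the symmetric 3x3 anisotropic displacement
#' tensor from the directional falloff of intensity. The working residual
#' for reflection h is y_h = log(I_h / <I>_shell); it is modelled as
#' c - 2 s^2 (n' B n) with s = 1/(2d) and n the unit scattering direction,
#' linear in the six unique tensor components and the scale. The scale c
#' is resolved per resolution shell (one intercept per shell, the binned
#' scale of anisotropy-correction programs) so that the radial falloff
#' left by the per-shell normalization is absorbed by the scale and not
#' mistaken for directional signal. Reflections with |residual| > 3 RMS
#' are rejected and the fit repeated, up to `max_cycles` cycles or until
#' the rejection set stabilizes. The rejection threshold has a small
#' numerical floor so that exactly-modelled (noise-free) data rejects
#' nothing. The final tensor is symmetrized over the point-group
#' rotations of the space group.
#'
#' Because the per-shell normalization removes the radial mean falloff,
#' the isotropic part of the fitted tensor is only determined up to an
#' additive constant; the eigenvalue spread (delta-B) is the meaningful,
#' invariant quantity.
#'
#' @param refl A [reflection_set()].
#' @param source Data path: squared amplitudes or intensities.
#' @param n_shells Shells for the normalization (default 20).
#' @param max_cycles Maximum rejection/refit cycles (default 5).
#' @param min_reflections Minimum usable reflections (default 50).
#' @return An object of class `aniso_fit`; see [coef.aniso_fit()],
#'   [summary.aniso_fit()] and friends. Key fields: `b_cart` (symmetric
#'   tensor, A^2), `eigenvalues` (ascending), `eigenvectors` (columns,
#'   orthonormal), `n_rejected`, `n_total`, `cycles`.
#' @examples
#' spec <- simulation_spec(b_tensor = diag(c(20, 20, 70)), seed = 7,
#'                         noise_free = TRUE)
#' fit <- fit_anisotropy(gen_reflections(spec), source = "intensities")
#' delta_b(fit)  # close to 50
#' @export
fit_anisotropy <- function(refl, source = c("amplitudes", "intensities"),
                           n_shells = 20, max_cycles = 5,
                           min_reflections = 50) {
  source <- match.arg(source)
  stopifnot(inherits(refl, "reflection_set"))
  iw <- .working_intensity(refl, source)
  d <- refl_d(refl)
  sb <- shell_binning(refl, n_shells = n_shells, source = source)
  usable <- is.finite(iw) & iw > 0 & !is.na(sb$shell)
  if (sum(usable) < min_reflections) {
    stop("need at least ", min_reflections,
         " usable positive-intensity reflections, have ", sum(usable))
  }

  s <- scattering_vector(refl$hkl, refl$cell)
  slen <- sqrt(rowSums(s^2))
  nhat_all <- s / slen
  s2 <- (1 / (2 * d))^2

  iu <- iw[usable]
  shell_u <- sb$shell[usable]
  q <- 2 * s2[usable]
  nhat <- nhat_all[usable, , drop = FALSE]
  n1 <- nhat[, 1]; n2 <- nhat[, 2]; n3 <- nhat[, 3]
  m_shell <- tapply(iu, shell_u, mean)[as.character(shell_u)]
  y <- log(iu / as.numeric(m_shell))

  shells_present <- sort(unique(shell_u))
  dummies <- outer(shell_u, shells_present, `==`) * 1
  Xt <- cbind(-q * n1^2, -q * n2^2, -q * n3^2,
              -2 * q * n1 * n2, -2 * q * n1 * n3, -2 * q * n2 * n3)
  X <- cbind(dummies, Xt)
  if (qr(Xt)$rank < 6 || qr(X)$rank < ncol(X)) {
    stop("degenerate reflection geometry: directions do not span ",
         "3 dimensions (coplanar or collinear scattering vectors)")
  }

  active <- rep(TRUE, length(iu))
  beta <- NULL
  res <- NULL
  cycles <- 0
  repeat {
    cycles <- cycles + 1
    fit <- stats::lm.fit(X[active, , drop = FALSE], y[active])
    beta <- fit$coefficients
    res <- y - as.numeric(X %*% beta)
    rms <- sqrt(mean(res[active]^2))
    # floor keeps pure numerical jitter from triggering rejections
    new_active <- abs(res) <= max(3 * rms, 1e-8)
    converged <- identical(new_active, active)
    active <- new_active
    if (cycles >= max_cycles || converged) break
  }
  nb <- length(shells_present)
  bt <- beta[nb + 1:6]
  b <- matrix(c(bt[1], bt[4], bt[5],
                bt[4], bt[2], bt[6],
                bt[5], bt[6], bt[3]), 3, 3)
  # enforce crystallographic admissibility: average over the point group
  rots <- point_group_rotations(refl$spacegroup, refl$cell)
  b_sym <- Reduce(`+`, lapply(rots, function(qr_) t(qr_) %*% b %*% qr_)) /
    length(rots)
  b_sym <- (b_sym + t(b_sym)) / 2

  eg <- eigen(b_sym, symmetric = TRUE)
  ord <- order(eg$values)

  structure(list(
    b_cart = b_sym,
    eigenvalues = eg$values[ord],
    eigenvectors = eg$vectors[, ord, drop = FALSE],
    scale_log = unname(mean(beta[seq_len(nb)])),
    source = source,
    n_total = refl$n,
    n_used = sum(usable),
    n_rejected = sum(!active),
    cycles = cycles,
    residuals = res,
    fitted = y - res,
    y = y,
    s2 = s2[usable],
    nhat = nhat,
    cell = refl$cell,
    spacegroup = refl$spacegroup,
    call = match.call()
  ), class = "aniso_fit")
}

#' Anisotropic delta-B
#'
#' The spread between the largest and smallest eigenvalue of the
#' anisotropic B tensor. Invariant under adding any isotropic component.
#'
#' @param x An `aniso_fit`, or a symmetric 3x3 tensor matrix.
#' @return delta-B in square Angstrom (non-negative).
#' @export
delta_b <- function(x) {
  ev <- if (inherits(x, "aniso_fit")) {
    x$eigenvalues
  } else {
    x <- as.matrix(x)
    if (max(abs(x - t(x))) > 1e-8) stop("tensor must be symmetric")
    eigen(x, symmetric = TRUE)$values
  }
  max(ev) - min(ev)
}

#' Directional F/sigma(F) resolution limits
#'
#' For each of three principal axes, selects reflections whose scattering
#' vector lies within `cone_deg` of the axis (Friedel mates pooled, so the
#' cone is +/- the axis), bins the selection by resolution into `n_bins`
#' near-equal-count bins ordered from low to high resolution, and walks
#' the bins: the limit is the high-resolution edge (minimum d) of the last
#' bin, before any bin fails, whose mean F/sigF is at or above `threshold`.
#' If the very first bin fails, the limit is the lowest-resolution d of
#' the selection; if no bin fails, it is the selection's dmin. The result
#' is quantized to bin edges (about half a bin width).
#'
#' When the set carries no amplitudes they are derived from intensities as
#' F = sqrt(I), sigF = sigI/(2F), excluding I <= 0.
#'
#' @param refl A [reflection_set()].
#' @param axes 3x3 matrix with orthonormal axes in columns (typically the
#'   eigenvectors of an [fit_anisotropy()] tensor).
#' @param threshold F/sigF cutoff (default 3.0).
#' @param cone_deg Cone half-angle in degrees (default 20).
#' @param n_bins Resolution bins per axis (default 10).
#' @param min_count Cones with fewer reflections are flagged unreliable.
#' @return Numeric length-3 vector of limits (Angstrom), attribute
#'   `unreliable` a logical length-3 vector.
#' @export
directional_limits <- function(refl, axes, threshold = 3.0, cone_deg = 20,
                               n_bins = 10, min_count = 20) {
  stopifnot(inherits(refl, "reflection_set"))
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3, 3))) stop("axes must be a 3x3 matrix")
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-6) {
    stop("axes must be orthonormal columns")
  }
  if (!is.null(refl$f)) {
    f <- refl$f; sig_f <- refl$sig_f
  } else {
    pos <- is.finite(refl$i) & refl$i > 0
    f <- ifelse(pos, sqrt(pmax(refl$i, 0)), NA_real_)
    sig_f <- ifelse(pos, refl$sig_i / (2 * f), NA_real_)
  }
  fsig <- f / sig_f
  d <- refl_d(refl)
  s <- scattering_vector(refl$hkl, refl$cell)
  nhat <- s / sqrt(rowSums(s^2))
  cos_cut <- cos(cone_deg * pi / 180)

  limits <- numeric(3)
  unreliable <- logical(3)
  for (ax in 1:3) {
    ca <- abs(nhat %*% axes[, ax])
    sel <- which(ca >= cos_cut & is.finite(fsig))
    if (length(sel) < min_count) {
      warning("axis ", ax, " cone holds only ", length(sel),
              " reflections; limit flagged unreliable")
      unreliable[ax] <- TRUE
    }
    if (length(sel) == 0) {
      limits[ax] <- NA_real_
      next
    }
    limits[ax] <- .walk_limit(d[sel], fsig[sel], threshold, n_bins)
  }
  attr(limits, "unreliable") <- unreliable
  limits
}

# bin-walk shared by directional_limits: near-equal-count bins in
# decreasing d; returns the resolution limit under bin-edge semantics
.walk_limit <- function(d, fsig, threshold, n_bins) {
  ord <- order(d, decreasing = TRUE)
  d <- d[ord]; fsig <- fsig[ord]
  n <- length(d)
  k <- min(n_bins, n)
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  bin <- rep(seq_len(k), times = sizes)
  means <- tapply(fsig, bin, mean)
  ok <- means >= threshold
  if (!ok[1]) return(max(d))      # already below threshold at low resolution
  first_bad <- which(!ok)[1]
  if (is.na(first_bad)) return(min(d))  # never drops below threshold
  min(d[bin == (first_bad - 1)])  # inner edge of the last passing bin
}

#' Spread of directional resolution limits (delta_res)
#'
#' @param limits Numeric length-3 vector of per-axis resolution limits.
#' @return `max(limits) - min(limits)` in Angstrom (non-negative).
#' @export
delta_res <- function(limits) {
  limits <- as.numeric(limits)
  if (length(limits) != 3 || any(!is.finite(limits)) || any(limits <= 0)) {
    stop("need 3 positive finite resolution limits")
  }
  max(limits) - min(limits)
}

#' Anisotropy-to-Wilson ratio
#'
#' @param aniso_b Anisotropic delta-B (square Angstrom).
#' @param wilson_b Wilson B-factor (square Angstrom).
#' @return `aniso_b / wilson_b`, or `NA` (flagged with a warning) when the
#'   Wilson B is not positive — absence, not zero or infinity.
#' @export
aniso_ratio <- function(aniso_b, wilson_b) {
  if (!is.finite(wilson_b) || wilson_b <= 0) {
    warning("non-positive Wilson B: ratio undefined, returning NA")
    return(NA_real_)
  }
  aniso_b / wilson_b
}

#' Percentage of rejected reflections
#'
#' @param n_rejected,n_total Counts from the tensor-fit rejection cycles.
#' @return Percentage in [0, 100].
#' @export
pct_rejected <- function(n_rejected, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_rejected < 0 || n_rejected > n_total) {
    stop("n_rejected must lie in [0, n_total]")
  }
  100 * n_rejected / n_total
}

#' Full anisotropy audit of one reflection set
#'
#' Runs every reciprocal-space metric on both data paths when available:
#' Wilson B and the anisotropic tensor fit on amplitudes and on
#' intensities, delta-B, the aniso/Wilson ratio, the directional F/sigF
#' resolution limits along the fitted principal axes, delta_res, and the
#' rejection percentage. Failures on one path degrade to `NA` fields.
#'
#' @param refl A [reflection_set()].
#' @param n_shells,fsigf_threshold,cone_deg Tuning knobs; defaults 20,
#'   3.0, 20 degrees.
#' @return Object of class `aniso_result`: list with `aniso_b_amp`,
#'   `aniso_b_int`, `wilson_b_amp`, `wilson_b_int`, `ratio_amp`,
#'   `ratio_int`, `axis_limits`, `delta_res`, `pct_rejected`,
#'   `n_reflections_total`, `n_rejected` and the underlying `fit_amp` /
#'   `fit_int` objects.
#' @export
anisotropy_audit <- function(refl, n_shells = 20, fsigf_threshold = 3.0,
                             cone_deg = 20) {
  stopifnot(inherits(refl, "reflection_set"))
  res <- list(aniso_b_amp = NA_real_, aniso_b_int = NA_real_,
              wilson_b_amp = NA_real_, wilson_b_int = NA_real_,
              ratio_amp = NA_real_, ratio_int = NA_real_,
              axis_limits = rep(NA_real_, 3), delta_res = NA_real_,
              pct_rejected = NA_real_, n_reflections_total = refl$n,
              n_rejected = NA_integer_, fit_amp = NULL, fit_int = NULL)
  try_quiet <- function(expr) tryCatch(suppressWarnings(expr),
                                       error = function(e) NULL)
  if (!is.null(refl$f)) {
    res$fit_amp <- try_quiet(fit_anisotropy(refl, "amplitudes",
                                            n_shells = n_shells))
    wb <- try_quiet(wilson_b(refl, "amplitudes", n_shells = n_shells))
    if (!is.null(wb)) res$wilson_b_amp <- wb
  }
  if (!is.null(refl$i)) {
    res$fit_int <- try_quiet(fit_anisotropy(refl, "intensities",
                                            n_shells = n_shells))
    wb <- try_quiet(wilson_b(refl, "intensities", n_shells = n_shells))
    if (!is.null(wb)) res$wilson_b_int <- wb
  }
  if (!is.null(res$fit_amp)) {
    res$aniso_b_amp <- delta_b(res$fit_amp)
    if (is.finite(res$wilson_b_amp) && res$wilson_b_amp > 0) {
      res$ratio_amp <- res$aniso_b_amp / res$wilson_b_amp
    }
  }
  if (!is.null(res$fit_int)) {
    res$aniso_b_int <- delta_b(res$fit_int)
    if (is.finite(res$wilson_b_int) && res$wilson_b_int > 0) {
      res$ratio_int <- res$aniso_b_int / res$wilson_b_int
    }
  }
  # limits along the principal axes of the primary (amplitude) fit
  lead <- if (!is.null(res$fit_amp)) res$fit_amp else res$fit_int
  if (!is.null(lead)) {
    lim <- try_quiet(directional_limits(refl, lead$eigenvectors,
                                        threshold = fsigf_threshold,
                                        cone_deg = cone_deg))
    if (!is.null(lim) && all(is.finite(lim))) {
      res$axis_limits <- as.numeric(lim)
      res$delta_res <- delta_res(lim)
    }
    res$n_rejected <- lead$n_rejected
    res$pct_rejected <- pct_rejected(lead$n_rejected, lead$n_used)
  }
  structure(res, class = "aniso_result")
}

#' @export
print.aniso_result <- function(x, ...) {
  cat("anisotropy audit\n")
  fmt <- function(v) if (is.finite(v)) sprintf("%.3f", v) else "absent"
  cat("  delta-B (amplitudes):  ", fmt(x$aniso_b_amp), " A^2\n", sep = "")
  cat("  delta-B (intensities): ", fmt(x$aniso_b_int), " A^2\n", sep = "")
  cat("  Wilson B (amp/int):    ", fmt(x$wilson_b_amp), " / ",
      fmt(x$wilson_b_int), " A^2\n", sep = "")
  cat("  ratio (amp/int):       ", fmt(x$ratio_amp), " / ",
      fmt(x$ratio_int), "\n", sep = "")
  cat("  axis limits:           ",
      paste(sprintf("%.2f", x$axis_limits), collapse = " "), " A\n", sep = "")
  cat("  delta_res:             ", fmt(x$delta_res), " A\n", sep = "")
  cat("  rejected:              ", fmt(x$pct_rejected), " %\n", sep = "")
  invisible(x)
}
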