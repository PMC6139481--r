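# Shell binning, Wilson B, the tensor fit and its derived scalars.

test_that("shells are balanced and ordered by decreasing d", {
  refl <- gen_reflections(quick_spec(seed = 2))
  sb <- shell_binning(refl, n_shells = 10, source = "intensities")
  expect_true(max(sb$n) - min(sb$n) <= 1)
  expect_equal(sum(sb$n), refl$n)
  expect_true(all(diff(sb$mean_d) < 0))
  # shell index increases as d decreases
  d <- refl_d(refl)
  expect_true(all(tapply(d, sb$shell, max) >= tapply(d, sb$shell, min)))
  expect_error(shell_binning(refl, n_shells = refl$n + 1), "smaller n_shells")
})

test_that("per-shell mean intensity decays with resolution for isotropic B", {
  refl <- gen_reflections(quick_spec(b_tensor = diag(30, 3), seed = 3,
                                     noise_free = TRUE))
  sb <- shell_binning(refl, n_shells = 15, source = "intensities")
  expect_true(all(diff(log(sb$mean_i)) < 0))
})

test_that("constant intensities give Wilson B of zero", {
  set.seed(1)
  hkl <- as.matrix(expand.grid(h = 0:6, k = 0:6, l = 1:6))
  refl <- reflection_set(hkl, i = rep(100, nrow(hkl)),
                         sig_i = rep(1, nrow(hkl)), cell = cubic_cell(12))
  expect_equal(wilson_b(refl, "intensities", n_shells = 8), 0, tolerance = 1e-9)
})

test_that("Wilson B recovers the imposed isotropic B", {
  for (b in c(10, 30, 80)) {
    refl <- gen_reflections(quick_spec(b_tensor = diag(b, 3), seed = b,
                                       noise_free = TRUE))
    expect_equal(wilson_b(refl, "intensities"), b, tolerance = 1 / b)
    expect_equal(wilson_b(refl, "amplitudes"), b, tolerance = 1 / b)
  }
  noisy <- gen_reflections(quick_spec(b_tensor = diag(30, 3), seed = 9))
  expect_equal(wilson_b(noisy, "intensities"), 30, tolerance = 2 / 30)
})

test_that("tensor fit recovers an imposed diagonal anisotropy", {
  refl <- gen_reflections(quick_spec(b_tensor = diag(c(20, 20, 70)), seed = 7,
                                     noise_free = TRUE))
  fit <- fit_anisotropy(refl, "intensities")
  expect_equal(delta_b(fit), 50, tolerance = 1e-6)
  expect_lt(abs(fit$eigenvalues[2] - fit$eigenvalues[1]), 1e-6)
  expect_equal(fit$n_rejected, 0)  # no outliers exist in noise-free data
  expect_equal(pct_rejected(fit$n_rejected, fit$n_used), 0)
})

test_that("isotropic input gives three equal eigenvalues", {
  fit <- fit_anisotropy(gen_reflections(quick_spec(b_tensor = diag(25, 3),
                                                   seed = 5,
                                                   noise_free = TRUE)),
                        "intensities")
  expect_lt(diff(range(fit$eigenvalues)), 1e-6)
  # with Wilson counting noise at this small problem size (~4,100
  # reflections) the eigenvalue spread stays a small noise floor
  noisy <- fit_anisotropy(gen_reflections(quick_spec(b_tensor = diag(25, 3),
                                                     seed = 5)),
                          "intensities")
  expect_lt(diff(range(noisy$eigenvalues)), 5)
})

test_that("amplitude and intensity sources agree on noise-free data", {
  refl <- gen_reflections(quick_spec(b_tensor = diag(c(10, 30, 55)), seed = 8,
                                     noise_free = TRUE))
  fa <- fit_anisotropy(refl, "amplitudes")
  fi <- fit_anisotropy(refl, "intensities")
  expect_equal(fa$b_cart, fi$b_cart, tolerance = 1e-6)
})

test_that("the fit is equivariant under rotation of the Cartesian frame", {
  b0 <- diag(c(15, 25, 60))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f1 <- fit_anisotropy(gen_reflections(quick_spec(b_tensor = b0, seed = 21,
                                                  noise_free = TRUE)),
                       "intensities")
  f2 <- fit_anisotropy(gen_reflections(quick_spec(b_tensor = R %*% b0 %*% t(R),
                                                  seed = 21,
                                                  noise_free = TRUE)),
                       "intensities")
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-6)
  expect_equal(delta_b(f1), delta_b(f2), tolerance = 1e-6)
  # the principal axes rotate with the frame
  v1 <- f1$eigenvectors[, 3]
  v2 <- f2$eigenvectors[, 3]
  expect_equal(abs(sum((R %*% v1) * v2)), 1, tolerance = 1e-4)
})

test_that("coplanar reflection geometry is reported as degenerate", {
  hkl <- as.matrix(expand.grid(h = -6:6, k = -6:6, l = 0))
  hkl <- hkl[rowSums(hkl != 0) > 0, ]
  hkl <- hkl[hkl[, 2] > 0 | (hkl[, 2] == 0 & hkl[, 1] > 0), ]
  refl <- reflection_set(hkl, i = rexp(nrow(hkl), 0.01),
                         sig_i = rep(1, nrow(hkl)), cell = cubic_cell(12))
  expect_error(fit_anisotropy(refl, "intensities", n_shells = 5),
               "degenerate")
})

test_that("delta_b is eigenvalue spread, invariant to isotropic shifts", {
  expect_equal(delta_b(diag(c(10, 20, 60))), 50)
  expect_equal(delta_b(diag(c(7, 7, 7))), 0)
  expect_equal(delta_b(diag(c(10, 20, 60)) + 15 * diag(3)), 50)
  expect_error(delta_b(matrix(1:9, 3)), "symmetric")
})

test_that("delta_b is invariant to adding isotropic B to the generator", {
  for (b_iso in c(0, 40)) {
    fit <- fit_anisotropy(gen_reflections(quick_spec(
      b_tensor = diag(c(0, 0, 35)) + diag(b_iso, 3), seed = 13,
      noise_free = TRUE)), "intensities")
    expect_equal(delta_b(fit), 35, tolerance = 1e-5)
  }
})

test_that("ratio and rejection-percentage arithmetic behaves at the edges", {
  expect_equal(aniso_ratio(50, 25), 2)
  expect_equal(aniso_ratio(0, 25), 0)
  expect_warning(r <- aniso_ratio(50, 0), "undefined")
  expect_true(is.na(r))
  expect_equal(pct_rejected(5, 100), 5)
  expect_equal(pct_rejected(0, 100), 0)
  expect_error(pct_rejected(1, 0), "positive")
  expect_error(pct_rejected(5, 4), "n_total")
})

test_that("anisotropy_audit populates both paths and the derived scalars", {
  refl <- gen_reflections(quick_spec(b_tensor = diag(c(10, 10, 50)) +
                                       diag(20, 3), seed = 6))
  res <- anisotropy_audit(refl)
  expect_s3_class(res, "aniso_result")
  expect_equal(res$aniso_b_amp, 40, tolerance = 0.1)
  expect_equal(res$aniso_b_int, 40, tolerance = 0.1)
  expect_gt(res$wilson_b_amp, 0)
  expect_equal(res$ratio_amp, res$aniso_b_amp / res$wilson_b_amp)
  expect_true(all(is.finite(res$axis_limits)))
  expect_gte(res$delta_res, 0)
  expect_true(res$pct_rejected >= 0 && res$pct_rejected <= 100)
})
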