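test_that("mode spectrum matches eigen-decomposition of the discrete coupling matrix", {
  for (N in c(4, 8, 16)) {
    m <- stack_model(K_C = 17, B = 3e-6, N_layers = N, L_r = 500, D = 58)
    for (q in c(0.005, 0.02, 0.08)) {
      # periodic layer-coupling matrix: K_C q^4 I + B (2I - S - S^T)
      Tm <- diag(2, N)
      Tm[cbind(1:N, c(2:N, 1))] <- Tm[cbind(1:N, c(2:N, 1))] - 1
      Tm[cbind(c(2:N, 1), 1:N)] <- Tm[cbind(c(2:N, 1), 1:N)] - 1
      if (N == 2) Tm <- matrix(c(2, -2, -2, 2), 2) # degenerate wrap
      H <- 17 * q^4 * diag(N) + 3e-6 * Tm
      ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
      analytic <- sort(1 / (500^2 * mode_spectrum(m, q, 0:(N - 1))))
      expect_equal(analytic, ev * 1, tolerance = 1e-10)
    }
  }
})

test_that("the q_r = 0 Goldstone mode is rejected and limits behave", {
  m <- test_stack()
  expect_error(mode_spectrum(m, 0, 0), "Goldstone")
  # B -> infinity recovers the single-membrane bending amplitude for mode 0
  stiff <- stack_model(K_C = 20, B = 1e3, N_layers = 8, L_r = 800, D = 60)
  q <- 0.03
  expect_equal(mode_spectrum(stiff, q, 0), 1 / (800^2 * 20 * q^4),
               tolerance = 1e-12)
  # doubling K_C halves a bending-dominated amplitude
  m1 <- stack_model(20, 1e-12, 8, 800, 60)
  m2 <- stack_model(40, 1e-12, 8, 800, 60)
  q <- 0.05 # bending dominates: K_C q^4 >> B
  expect_equal(mode_spectrum(m1, q, 3) / mode_spectrum(m2, q, 3), 2,
               tolerance = 1e-6)
})

test_that("height correlations match an independent 2D Cartesian q-sum oracle", {
  m <- stack_model(K_C = 20, B = 2e-6, N_layers = 8, L_r = 100, D = 60)
  qmin <- 2 * pi / 100
  dq <- 0.004
  qx <- seq(-2, 2, by = dq); qy <- qx
  Q2 <- outer(qx^2, qy^2, `+`)
  mask <- Q2 >= qmin^2 & Q2 <= 4
  KQ4 <- 20 * Q2^2
  for (r in c(10, 30)) {
    cosx <- cos(outer(qx * r, rep(1, length(qy))))
    for (k in c(0, 1, 4)) {
      acc <- 0
      for (mm in 0:7) {
        E <- KQ4 + 2 * 2e-6 * (1 - cos(2 * pi * mm / 8))
        cmk <- cos(2 * pi * mm * k / 8)
        acc <- acc + sum(((1 - cosx * cmk) / E)[mask])
      }
      oracle <- 2 / 8 * acc * dq^2 / (2 * pi)^2
      got <- height_correlation(m, k, r)
      expect_equal(got, oracle, tolerance = 0.02)
    }
  }
})

test_that("height correlations vanish at zero separation and grow with r", {
  m <- test_stack(N = 8)
  expect_lt(abs(height_correlation(m, 0, 0)), 1e-8)
  r <- c(0, 5, 20, 80, 300)
  for (k in c(0, 2)) {
    d <- height_correlation(m, k, r)
    expect_true(all(diff(d) > -1e-9))
  }
})

test_that("sampled Gaussian modes reproduce the discrete height-difference law", {
  # discrete in-plane box matching the stack's lateral cutoff: modes at
  # multiples of 2 pi / L; 1e4 realizations of u_n(r) from equipartition
  # amplitudes must reproduce the discrete-sum delta_k(r) within 3 SE
  set.seed(101)
  L <- 100; N <- 8
  m <- stack_model(K_C = 20, B = 2e-6, N_layers = N, L_r = L, D = 60)
  qs <- 2 * pi / L * (1:6) # a few radial mode shells along x
  k_off <- 2; r <- 25
  n_rep <- 10000
  # exact discrete prediction for this mode set (sum of independent modes)
  var_terms <- vapply(qs, function(q) {
    sum(vapply(0:(N - 1), function(mm) {
      amp <- mode_spectrum(m, q, mm) # <|u|^2> per mode
      cmk <- cos(2 * pi * mm * k_off / N)
      2 * amp * (1 - cos(q * r) * cmk)
    }, numeric(1)))
  }, numeric(1))
  delta_exact <- sum(var_terms)
  # Monte Carlo: u_n(x) = sum_q sum_m a_qm sqrt(2 amp) cos(q x + 2 pi m n/N + phase)
  diffs <- replicate(n_rep, {
    du <- 0
    for (qi in seq_along(qs)) for (mm in 0:(N - 1)) {
      amp <- mode_spectrum(m, qs[qi], mm)
      a <- rnorm(1, 0, sqrt(amp)); ph <- runif(1, 0, 2 * pi)
      u_n_r <- a * sqrt(2) * cos(qs[qi] * r + 2 * pi * mm * 0 / N + ph)
      u_nk_0 <- a * sqrt(2) * cos(0 + 2 * pi * mm * k_off / N + ph)
      du <- du + (u_n_r - u_nk_0)
    }
    du^2
  })
  se <- sd(diffs) / sqrt(n_rep)
  expect_lt(abs(mean(diffs) - delta_exact), 3 * se)
})

test_that("rigid stacks reproduce the finite-lattice Bragg interference", {
  N <- 12; D <- 60
  m <- stack_model(K_C = 20, B = 2e-6, N_layers = N, L_r = 400, D = D)
  r <- seq(0, 400, length.out = 256)
  delta0 <- matrix(0, N, 256) # frozen stack
  S_bragg <- structure_factor(m, 2 * pi / D, 0, n_r = 256, delta = delta0)
  expect_equal(drop(S_bragg), N^2, tolerance = 1e-6)
  # off-Bragg q_z gives much weaker interference
  S_off <- structure_factor(m, 2 * pi / D * 1.5, 0, n_r = 256, delta = delta0)
  expect_lt(abs(drop(S_off)), 0.05 * N^2)
})

test_that("the structure factor is symmetric in q_r", {
  m <- test_stack(N = 8)
  qz <- c(0.15, 0.22)
  S_pos <- structure_factor(m, qz, 0.03)
  S_neg <- structure_factor(m, qz, -0.03)
  expect_equal(S_pos, S_neg, tolerance = 1e-12)
})

test_that("predicted patterns factorize, scale linearly, and mask the beam region", {
  m <- test_stack(N = 8)
  qz <- seq(0.02, 0.3, length.out = 12)
  qr <- seq(0.005, 0.05, length.out = 8)
  p1 <- predict_pattern(m, NULL, qz, qr, scale = 1)
  p2 <- predict_pattern(m, NULL, qz, qr, scale = 2)
  expect_equal(p2$intensity, 2 * p1$intensity)
  expect_true(all(is.na(p1$intensity[qz < 0.05, ])))
  expect_true(all(is.finite(p1$intensity[qz >= 0.05, ])))
  ff <- function(q) 1 + 0 * q
  p3 <- predict_pattern(m, ff, qz, qr)
  expect_equal(p3$intensity, p1$intensity)
})

test_that("symmetrization averages mirror images after background subtraction", {
  qr <- seq(-0.05, 0.05, length.out = 11)
  qz <- seq(0.1, 0.2, length.out = 6)
  asym <- outer(qz, qr, function(z, r) 1 + z + r) # asymmetric in q_r
  bg <- matrix(0.5, 6, 11)
  pat <- new_diffuse_pattern(qr, qz, asym)
  out <- symmetrize_and_subtract(pat, bg)
  manual <- (asym - bg + (asym - bg)[, 11:1]) / 2
  expect_equal(out$intensity, manual)
  # symmetric input is a fixed point; subtracting itself gives zeros
  sym <- outer(qz, qr, function(z, r) z + r^2)
  pat_sym <- new_diffuse_pattern(qr, qz, sym)
  expect_equal(symmetrize_and_subtract(pat_sym, matrix(0, 6, 11))$intensity, sym)
  expect_equal(symmetrize_and_subtract(pat_sym, sym)$intensity, matrix(0, 6, 11))
  expect_error(symmetrize_and_subtract(pat, matrix(0, 2, 2)), "shape")
})

test_that("noiseless synthetic patterns are refit to better than 1 percent", {
  truth <- test_stack(K_C = 20, B = 2e-6)
  qz <- seq(0.12, 0.32, length.out = 24)
  qr <- seq(0.002, 0.06, length.out = 16)
  pat <- predict_pattern(truth, NULL, qz, qr)
  pat <- new_diffuse_pattern(pat$q_r, pat$q_z, pat$intensity,
                             sigma = 0.01 * abs(pat$intensity) + 1e-9)
  init <- test_stack(K_C = 40, B = 5e-7)
  fit <- fit_elasticity(pat, NULL, init,
                        fit_window = list(q_z = c(0.12, 0.32), q_r = c(0.002, 0.06)))
  expect_equal(fit$K_C_hat, 20, tolerance = 0.01)
  expect_equal(fit$B_hat, 2e-6, tolerance = 0.01)
  expect_equal(fit$status, "converged")
})

test_that("nearly rigid patterns push K_C to the stiff bound and are flagged", {
  # data from a stack far stiffer than the allowed fit range: the estimate
  # runs away upward and pins at the bound
  stiff <- test_stack(K_C = 2e3, B = 2e-6)
  qz <- seq(0.12, 0.3, length.out = 12)
  qr <- seq(0.002, 0.05, length.out = 10)
  pat <- predict_pattern(stiff, NULL, qz, qr)
  pat <- new_diffuse_pattern(pat$q_r, pat$q_z, pat$intensity,
                             sigma = 0.01 * abs(pat$intensity) + 1e-12)
  fit <- fit_elasticity(pat, NULL, test_stack(K_C = 50, B = 2e-6),
                        fit_window = list(q_z = c(0.1, 0.3), q_r = c(0, 0.05)),
                        log_kc_bounds = log(c(1e-2, 1e2)))
  expect_equal(fit$status, "kc_at_upper_bound")
  expect_gte(fit$K_C_hat, 1e2 * 0.999)
})

test_that("bending moduli convert between kBT and Joule consistently", {
  expect_equal(kc_from_joule(kc_to_joule(20)), 20)
  # about 4.28e-21 J per kBT at 37 C
  expect_equal(kc_to_joule(1), 1.380649e-23 * 310.15)
})
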