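test_that("single sharp interfaces reproduce the Fresnel closed form", {
  q <- seq(0.005, 0.33, length.out = 80)
  for (pair in list(c(2.07, 6.36), c(0, 4.5), c(-0.56, 2.07))) {
    R <- reflectivity(list(thickness = c(0, 0), sld = pair), q)$R
    k0 <- sqrt(as.complex((q / 2)^2))
    k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * diff(pair) * 1e-6))
    Rf <- pmin(Mod((k0 - k1) / (k0 + k1))^2, 1)
    expect_equal(R, Rf, tolerance = 1e-12)
  }
})

test_that("reflectivity is total below the critical edge and zero without contrast", {
  q <- seq(0.002, 0.2, length.out = 60)
  R <- reflectivity(list(thickness = c(0, 0), sld = c(0, 6.36)), q)$R
  qc <- sqrt(16 * pi * 6.36e-6)
  expect_true(all(R[q < 0.95 * qc] > 1 - 1e-9))
  R0 <- reflectivity(list(thickness = c(0, 30, 0), sld = c(2, 2, 2)), q)$R
  expect_true(all(R0 < 1e-20))
})

test_that("a uniform slab matches the two-interface interference formula", {
  q <- seq(0.02, 0.33, length.out = 70)
  R <- reflectivity(list(thickness = c(0, 40, 0), sld = c(2.07, 4.5, 6.36)), q)$R
  k0 <- sqrt(as.complex((q / 2)^2))
  k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (4.5 - 2.07) * 1e-6))
  k2 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (6.36 - 2.07) * 1e-6))
  r01 <- (k0 - k1) / (k0 + k1)
  r12 <- (k1 - k2) / (k1 + k2)
  ph <- exp(2i * k1 * 40)
  Rc <- pmin(Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2, 1)
  expect_equal(R, Rc, tolerance = 1e-10)
})

test_that("dynamical and Born reflectivities agree well above the critical edge", {
  z <- seq(-20, 80, by = 0.5)
  sld <- tibble::tibble(
    z = z, sld = 2.07 + (6.36 - 2.07) * pnorm(z, 30, 6))
  qc <- sqrt(16 * pi * (6.36 - 2.07) * 1e-6)
  q <- seq(5 * qc, 0.25, length.out = 40)
  R_dyn <- reflectivity(sld, q)$R
  # kinematic (Born) approximation from the SLD gradient
  drho <- diff(sld$sld * 1e-6) / diff(z)
  zm <- (z[-1] + z[-length(z)]) / 2
  R_born <- vapply(q, function(qq) {
    amp <- sum(drho * exp(1i * qq * zm)) * 0.5
    (16 * pi^2 / qq^4) * Mod(amp)^2
  }, numeric(1))
  expect_equal(R_dyn, R_born, tolerance = 0.05)
})

test_that("reflectivity is invariant to translating the free interface profile", {
  z <- seq(-40, 160, by = 1)
  prof1 <- stblm_profile(z, hc_thickness = 28)
  q <- seq(0.02, 0.3, length.out = 50)
  # translate the whole soft structure by shifting the grid origin
  prof2 <- prof1
  prof2$z <- prof2$z + 25
  R1 <- reflectivity(sld_profile(prof1, "d2o"), q)$R
  R2 <- reflectivity(sld_profile(prof2, "d2o"), q)$R
  expect_equal(R1, R2, tolerance = 1e-9)
})

test_that("occupancies sum to one and the contrast switch only affects solvated regions", {
  z <- seq(-30, 140, by = 1)
  prof <- stblm_profile(z, hc_thickness = 30, coverage = 0.9,
                        peptide = list(control_z = c(14, 29, 44),
                                       control_v = c(0, 0.1, 0)))
  expect_true(all(abs(rowSums(as.matrix(prof[-1])) - 1) < 1e-9))
  s_h <- sld_profile(prof, "h2o")
  s_d <- sld_profile(prof, "d2o")
  dsld <- s_d$sld - s_h$sld
  expect_equal(dsld, (6.36 - (-0.56)) * prof$water, tolerance = 1e-9)
  # two-component mixture: hand-computed weighted sums at spot points
  i <- which(prof$water > 0.2 & prof$hydrocarbon > 0.2)[1]
  expect_equal(s_h$sld[i],
               sum(as.numeric(prof[i, -1]) * c(4.5, 0, 1.8, -0.4, 2.2, -0.56)),
               tolerance = 1e-9)
})

test_that("Hermite occupancy splines are clamped, local, and zero outside support", {
  z <- seq(0, 100, by = 0.5)
  expect_equal(spline_occupancy(c(10, 25, 40), c(0, 0, 0), z), rep(0, length(z)))
  bump <- spline_occupancy(c(10, 25, 40), c(0, 0.3, 0), z)
  expect_equal(max(bump), 0.3, tolerance = 1e-9)
  expect_equal(z[which.max(bump)], 25)
  expect_true(all(bump[z < 10 | z > 40] == 0))
  expect_true(all(bump >= 0 & bump <= 1))
  expect_error(spline_occupancy(c(10, 12), c(0, 1), z), "spacing")
  expect_error(spline_occupancy(c(10, 30), c(-0.1, 0.2), z), "non-negative")
})

test_that("spline occupancy integrates consistently with volume bookkeeping", {
  z <- seq(-30, 140, by = 0.25)
  pep <- list(control_z = c(14, 29, 44, 59), control_v = c(0, 0.08, 0.04, 0))
  # coverage low enough that peptide plus bilayer never overfill the cell
  prof <- stblm_profile(z, coverage = 0.85, peptide = pep)
  direct <- spline_occupancy(pep$control_z, pep$control_v, z)
  expect_equal(prof$peptide, direct, tolerance = 1e-9)
  expect_gt(pracma::trapz(z, prof$peptide), 0)
})

test_that("a joint two-contrast fit shares one structure and recovers a known profile", {
  z <- seq(-30, 120, by = 1)
  truth <- c(hc_thickness = 28, coverage = 0.95, pep_v1 = 0.08, pep_v2 = 0.04)
  par <- stblm_parameterization(z)
  prof <- par$build(truth)
  curves <- gen_nr(prof, noise = 0.03, seed = 11)
  fit <- suppressWarnings(
    fit_contrast_pair(curves, par, z, n_steps = 1200, burn = 400, seed = 2))
  expect_equal(fit$summary$median, unname(truth), tolerance = 0.15)
  expect_gt(fit$acceptance, 0.05)
  # identical structural parameters underlie both contrasts by construction:
  # the builder maps one parameter vector to one profile
  expect_equal(sld_profile(par$build(truth), "h2o")$z,
               sld_profile(par$build(truth), "d2o")$z)
})

test_that("peptide-free data fit with a peptide spline returns amplitude near zero", {
  z <- seq(-30, 120, by = 1)
  par <- stblm_parameterization(z)
  prof0 <- par$build(c(28, 0.95, 0, 0))
  curves <- gen_nr(prof0, noise = 0.03, seed = 4)
  fit <- suppressWarnings(
    fit_contrast_pair(curves, par, z, n_steps = 1200, burn = 400, seed = 3))
  amp <- fit$summary[fit$summary$parameter %in% c("pep_v1", "pep_v2"), ]
  expect_true(all(amp$lower68 < 0.02))
  expect_true(all(amp$median < 0.05))
})
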