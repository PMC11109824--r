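zg <- seq(-45, 45, by = 0.1)

test_that("volume probabilities conserve total occupancy and asymptote to water", {
  m <- sdp_model(A_L = 70.8)
  occ <- volume_probabilities(m, zg)
  expect_true(all(abs(occ$total - 1) < 1e-6))
  far <- abs(zg) > 40
  expect_true(all(occ$water[far] > 0.999))
  expect_true(all(as.matrix(occ[c("phos", "cg", "ch2", "ch3")]) > -1e-12))
})

test_that("outside the hydrocarbon envelope the peptide displaces water one-for-one", {
  pep <- list(placement = "headgroup", z = 24, sigma = 3,
              electrons = 1020, volume = 2236, ratio = 75)
  with_pep <- sdp_model(A_L = 73, peptide = pep)
  without <- sdp_model(A_L = 73)
  o1 <- volume_probabilities(with_pep, zg)
  o0 <- volume_probabilities(without, zg)
  out <- abs(zg) >= 24 # far from the slab edge, where water is displaced
  expect_equal((o0$water - o1$water)[out], o1$peptide[out], tolerance = 1e-4)
  # inside the slab the peptide displaces methylenes instead
  hc <- 0.5 * (pracma::erf((with_pep$D_C - zg) / (sqrt(2) * with_pep$sigma_HC)) +
               pracma::erf((with_pep$D_C + zg) / (sqrt(2) * with_pep$sigma_HC)))
  inner <- abs(zg) <= 5
  expect_equal((o0$ch2 - o1$ch2)[inner], (o1$peptide * hc)[inner],
               tolerance = 1e-6)
})

test_that("a water-only model has the electron density of water", {
  # shrink all non-water contributions to nothing
  m <- sdp_model(A_L = 1e6)
  ed <- electron_density(m, zg)
  expect_equal(ed$total, rep(10 / 30.0, length(zg)), tolerance = 1e-3)
})

test_that("electron density is symmetric and consistent with the occupancies", {
  pep <- list(placement = "headgroup", z = 20, sigma = 4,
              electrons = 1287, volume = 2876, ratio = 75)
  m <- sdp_model(A_L = 72, peptide = pep)
  ed <- electron_density(m, zg)
  flip <- electron_density(m, -zg)
  expect_equal(ed$total, flip$total, tolerance = 1e-12)
  # the grid density must equal occupancy times component density, summed
  occ <- volume_probabilities(m, zg)
  rho <- c(phos = 110 / 220, cg = 67 / 150, ch2 = 256 / 921, ch3 = 18 / 109,
           peptide = 1287 / 2876, water = 10 / 30)
  manual <- as.matrix(occ[names(rho)]) %*% rho
  expect_equal(ed$total, drop(manual), tolerance = 1e-12)
})

test_that("form factor at q = 0 equals the excess electrons per area in the cell", {
  m <- sdp_model(A_L = 70.8)
  rho_w <- 10 / 30
  # excess electrons per area from the occupancy curves (independent path)
  occ <- volume_probabilities(m, zg)
  rho <- c(phos = 110 / 220, cg = 67 / 150, ch2 = 256 / 921, ch3 = 18 / 109)
  excess <- sum(vapply(names(rho), function(cn) {
    (rho[[cn]] - rho_w) * pracma::trapz(zg, occ[[cn]])
  }, numeric(1)))
  expect_equal(form_factor(m, 0), excess, tolerance = 1e-5)
})

test_that("analytic form factor matches quadrature of the density to 1e-10", {
  pep <- list(placement = "hydrocarbon", z = 7, sigma = 4,
              electrons = 1020, volume = 2236, ratio = 75)
  m <- sdp_model(A_L = 73, peptide = pep)
  rho_w <- 10 / 30
  for (q in c(0.05, 0.2, 0.45)) {
    num <- stats::integrate(function(z) {
      (electron_density(m, z)$total - rho_w) * cos(q * z)
    }, -60, 60, rel.tol = 1e-13, abs.tol = 1e-13, subdivisions = 400L)$value
    expect_equal(form_factor(m, q), num, tolerance = 1e-10)
  }
})

test_that("a pure slab model reduces to the sin(q D_C)/q closed form", {
  # shrink the headgroups to nothing and match the CH3 density to CH2 so
  # only a uniform sharp slab carries contrast
  rho_w <- 10 / 30
  m <- sdp_model(A_L = 70, sigma_HC = 1e-6,
                 V_P = 1e-12, n_P = rho_w * 1e-12,
                 V_CG = 1e-12, n_CG = rho_w * 1e-12,
                 n_CH3 = (256 / 921) * 109, # CH3 density equals CH2 density
                 V_CH3 = 109, V_CH2 = 921)
  D_C <- m$D_C
  drho <- 256 / 921 - rho_w
  q <- seq(0.01, 0.6, by = 0.01)
  expect_equal(form_factor(m, q), 2 * drho * sin(q * D_C) / q,
               tolerance = 1e-12)
})

test_that("Parseval: the form-factor power equals the density autocorrelation power", {
  m <- sdp_model(A_L = 70.8)
  rho_w <- 10 / 30
  q <- seq(0, 6, by = 0.002)
  Fq <- form_factor(m, q)
  lhs <- 2 * pracma::trapz(q, Fq^2) # integral over the full q line (even)
  z <- seq(-60, 60, by = 0.01)
  drho <- electron_density(m, z)$total - rho_w
  rhs <- 2 * pi * pracma::trapz(z, drho^2)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("structural readout matches construction and responds to translation", {
  m <- sdp_model_from_structure(70.8, 39.2, 29.1)
  s <- derive_structure(m)
  expect_equal(s$A_L, 70.8)
  expect_equal(s$D_HH, 39.2, tolerance = 1e-3)
  expect_equal(s$two_D_C, 29.1, tolerance = 1e-3)
  # slab FWHM readout is exact for a constructed half-width
  m2 <- sdp_model(A_L = 70, V_CH2 = 70 * 14.55 - 109, V_CH3 = 109)
  expect_equal(derive_structure(m2)$two_D_C, 29.1, tolerance = 1e-3)
  # moving both headgroup Gaussians out by delta moves D_HH by 2 delta
  m3 <- m; m3$z_P <- m$z_P + 1.5; m3$z_CG <- m$z_CG + 1.5
  expect_equal(derive_structure(m3)$D_HH, s$D_HH + 3, tolerance = 5e-3)
})

test_that("noiseless form factors are refit within the printed uncertainties", {
  pep <- list(placement = "hydrocarbon", z = 7, sigma = 4,
              electrons = 1020, volume = 2236, ratio = 75)
  truth <- sdp_model_from_structure(73.0, 38.1, 28.9, peptide = pep)
  dat <- gen_formfactor(truth, noise = 0, seed = 1)
  init <- truth
  init$z_P <- truth$z_P - 1.2
  fit <- fit_form_factor(dat, init, placement = "hydrocarbon")
  expect_equal(fit$structure$A_L, 73.0, tolerance = 1.0 / 73)
  expect_lt(abs(fit$structure$D_HH - 38.1), 0.5)
  expect_lt(abs(fit$structure$two_D_C - 28.9), 0.5)
})

test_that("overpacked models are rejected", {
  expect_error(
    volume_probabilities(sdp_model(A_L = 20, V_P = 5000), zg),
    "overpacked")
})

test_that("peptide electron bookkeeping follows the residue table", {
  pe <- peptide_electrons("GG")
  expect_equal(pe$electrons, 2 * 30 + 10)
  tab <- residue_properties()
  expect_setequal(tab$residue, names(fauchere_pliska()))
})
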