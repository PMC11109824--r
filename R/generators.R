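#' Synthetic-data generators
#'
#' Seeded generators producing every input modality the analysis modules
#' consume, with known ground truth attached as the `"truth"` attribute
#' (retrieve with [generator_truth()]). Identical arguments and seed give
#' identical output.
#'
#' @name generators
NULL

#' Ground truth of a generated dataset
#'
#' @param x Object returned by a `gen_*()` generator.
#' @return The truth parameter list serialized alongside the data.
#' @export
generator_truth <- function(x) attr(x, "truth")

.with_truth <- function(x, truth) {
  attr(x, "truth") <- truth
  x
}

#' @describeIn generators CD spectrum as a known basis mixture plus
#'   Gaussian noise (sd = `noise` x max |MRE|). `fractions` must lie on
#'   the simplex.
#' @param fractions Named or ordered numeric of length 4 (helix, sheet,
#'   turn, coil) summing to 1.
#' @param basis Basis tibble from [cd_basis()].
#' @param noise Relative noise level.
#' @param seed Integer seed.
#' @export
gen_cd <- function(fractions, basis = cd_basis(), noise = 0, seed = 1) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    abort("fractions must be non-negative and sum to 1")
  B <- as.matrix(basis[c("helix", "sheet", "turn", "coil")])
  mu <- drop(B %*% as.numeric(fractions))
  mre <- withr::with_seed(seed,
    mu + rnorm(length(mu), 0, noise * max(abs(mu))))
  .with_truth(tibble(wavelength_nm = basis$wavelength_nm, mre = mre),
              list(fractions = as.numeric(fractions), noise = noise,
                   seed = seed))
}

#' @describeIn generators Diffuse low-angle pattern from a fluctuating
#'   stack: [predict_pattern()] plus multiplicative Gaussian noise of
#'   relative width `noise`, with matching per-pixel `sigma`.
#' @param stack A [stack_model()].
#' @param formfactor |F(q_z)| function or NULL.
#' @param q_z,q_r Pattern grids.
#' @param ... Passed to [predict_pattern()].
#' @export
gen_xds <- function(stack, formfactor = NULL, q_z, q_r, noise = 0.05,
                    seed = 1, ...) {
  pat <- predict_pattern(stack, formfactor, q_z, q_r, ...)
  I <- pat$intensity
  sig <- noise * abs(I)
  Inoisy <- withr::with_seed(seed,
    I + matrix(rnorm(length(I), 0, 1), nrow(I)) * sig)
  out <- new_diffuse_pattern(pat$q_r, pat$q_z, Inoisy,
                             sigma = pmax(sig, noise * max(abs(I), na.rm = TRUE) * 1e-3))
  .with_truth(out, list(K_C = stack$K_C, B = stack$B,
                        N_layers = stack$N_layers, L_r = stack$L_r,
                        D = stack$D, noise = noise, seed = seed))
}

#' @describeIn generators Wide-angle angular profile from the tilted-rod
#'   arc model at concentration `m`, with flat background and
#'   multiplicative Gaussian noise (sd = `noise` x intensity, the
#'   counting-statistics convention of the detector modalities), binned at
#'   1 degree.
#' @param m Concentration parameter.
#' @param scale,background Arc model amplitude and flat offset.
#' @param phi_deg Angular grid (degrees from the equator).
#' @param projection Arc projection model, as in [fit_order()].
#' @export
gen_waxs <- function(m, scale = 100, background = 10,
                     phi_deg = seq(0.5, 89.5, by = 1), noise = 0,
                     seed = 1, projection = "approx") {
  base <- .arc_model(m, phi_deg, projection)
  base <- base / max(base)
  mu <- scale * base + background
  y <- withr::with_seed(seed, mu + rnorm(length(mu), 0, noise * mu))
  out <- tibble(phi_deg = phi_deg, intensity = y)
  class(out) <- c("angular_profile", class(out))
  .with_truth(out, list(m = m, S_xray = sxray_from_m(m), noise = noise,
                        seed = seed, projection = projection))
}

#' @describeIn generators |F(q_z)| data from an [sdp_model()]:
#'   absolute-valued form factor with relative Gaussian noise, sigma =
#'   `noise` x |F| (the counting-statistics convention: I ~ F^2 with
#'   constant relative error gives sigma_F proportional to F), floored
#'   near the form-factor zeros, on an experimental-style q grid.
#' @param model An [sdp_model()].
#' @export
gen_formfactor <- function(model, q_z = seq(0.02, 0.8, by = 0.005),
                           noise = 0, seed = 1) {
  Fm <- abs(form_factor(model, q_z))
  sig <- pmax(pmax(noise * Fm, noise * max(Fm) * 0.02), 1e-9)
  y <- withr::with_seed(seed, pmax(Fm + rnorm(length(Fm), 0, sig), 0))
  .with_truth(tibble(q_z = q_z, absF = y, sigma = sig),
              list(A_L = model$A_L,
                   structure = derive_structure(model),
                   placement = if (is.null(model$peptide)) "none"
                   else model$peptide$placement,
                   noise = noise, seed = seed))
}

# paracrystalline finite-stack interference function with cumulative
# lattice disorder sigma_D
.paracrystal_sf <- function(q, D, N, sigma_D = 0) {
  if (N <= 1) return(rep(1, length(q)))
  S <- rep(N, length(q))
  for (k in 1:(N - 1))
    S <- S + 2 * (N - k) * cos(k * q * D) * exp(-k * (q * sigma_D)^2 / 2)
  S / N
}

#' @describeIn generators Solution SAXS curve: finite-N paracrystalline
#'   lamellar structure factor times a smooth bilayer form factor, mixed
#'   with a diffuse unilamellar lobe (weight `diffuse_fraction`), a 1/q^2
#'   vesicle Lorentz factor, and Gaussian noise.
#' @param D Repeat spacing (Angstrom).
#' @param n_layers Coherently stacked bilayers (1 = pure ULV).
#' @param diffuse_fraction Weight of the uncorrelated-bilayer component.
#' @param sigma_D Cumulative lattice disorder (Angstrom).
#' @param q q grid (1/Angstrom), default the instrument range 0.03-0.73.
#' @export
gen_saxs <- function(D = 51.1, n_layers = 30, diffuse_fraction = 0.3,
                     sigma_D = 0.5, q = seq(0.03, 0.73, by = 0.001),
                     scale = 1000, noise = 0.02, seed = 1) {
  stopifnot(D > 0, n_layers >= 1)
  # smooth symmetric-bilayer form factor (slab with soft edges)
  Fq <- 2 * sin(q * 14.5) / q * exp(-q^2 * 2.0^2 / 2)
  S <- .paracrystal_sf(q, D, n_layers, sigma_D)
  mu <- scale * ((1 - diffuse_fraction) * S + diffuse_fraction) * Fq^2 / q^2
  sig <- pmax(noise * abs(mu), noise * max(abs(mu)) * 1e-3)
  y <- withr::with_seed(seed, mu + rnorm(length(mu), 0, sig))
  .with_truth(tibble(q = q, intensity = y, sigma = sig),
              list(D = D, n_layers = n_layers,
                   diffuse_fraction = diffuse_fraction, sigma_D = sigma_D,
                   noise = noise, seed = seed))
}

#' @describeIn generators Two-contrast reflectivity pair from a known
#'   stBLM occupancy profile: exact dynamical curves for H2O and D2O plus
#'   Gaussian noise with sigma = `noise` x R (floored at `sigma_floor`).
#' @param profile Occupancy tibble from [stblm_profile()].
#' @param sigma_floor Absolute uncertainty floor.
#' @export
gen_nr <- function(profile, q_z = seq(0.012, 0.33, length.out = 70),
                   noise = 0.03, sigma_floor = 1e-7, seed = 1,
                   truth = NULL) {
  curves <- withr::with_seed(seed, {
    purrr::map(c(h2o = "h2o", d2o = "d2o"), function(ct) {
      R <- reflectivity(sld_profile(profile, ct), q_z)$R
      sig <- pmax(noise * R, sigma_floor)
      # noise is left unclipped: truncating at zero would bias the
      # low-reflectivity points relative to the Gaussian error model
      tibble(q_z = q_z, R = R + rnorm(length(R), 0, sig), sigma = sig)
    })
  })
  .with_truth(curves, c(truth, list(noise = noise, seed = seed)))
}

#' @describeIn generators Strain-resolved MIC panel: per species, strain
#'   MICs are log-normal around the species mean with coefficient of
#'   variation `strain_cv`, optionally quantized to the two-fold dilution
#'   series.
#' @param species_means Named numeric of species-level mean MICs (uM).
#' @param strain_cv Log-normal coefficient of variation across strains.
#' @param n_strains Strains per species.
#' @param peptide Peptide label for the output.
#' @param twofold Quantize to powers of two of the panel minimum.
#' @export
gen_mic_panel <- function(species_means, strain_cv = 0.3, n_strains = 4,
                          peptide = "pep", twofold = FALSE, seed = 1) {
  stopifnot(all(species_means > 0), strain_cv >= 0, n_strains >= 1)
  sdlog <- sqrt(log(1 + strain_cv^2))
  withr::with_seed(seed, {
    rows <- purrr::imap(species_means, function(mu, sp) {
      v <- if (strain_cv == 0) rep(mu, n_strains)
      else rlnorm(n_strains, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      if (twofold) v <- 2^round(log2(v))
      tibble(peptide = peptide, species = sp,
             strain = paste0(sp, "_", seq_len(n_strains)), mic = v)
    })
    .with_truth(dplyr::bind_rows(rows),
                list(species_means = species_means, strain_cv = strain_cv,
                     n_strains = n_strains, seed = seed))
  })
}
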