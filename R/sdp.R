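#' Residue electron counts and volumes
#'
#' Electrons per in-chain residue (atomic numbers summed over the residue
#' formula, i.e. amino acid minus one water) and typical residue volumes
#' (Angstrom^3, Zamyatnin-style consensus values), used to convert a
#' peptide sequence into the electron and volume budget of its bilayer
#' Gaussian.
#'
#' @return Tibble with columns `residue`, `electrons`, `volume_A3`.
#' @export
residue_properties <- function() {
  tibble(
    residue = c("G","A","S","P","V","T","C","L","I","N","D","Q","K","E",
                "M","H","F","R","Y","W"),
    electrons = c(30, 38, 46, 52, 54, 54, 54, 62, 62, 60, 59, 68, 71, 67,
                  70, 72, 78, 85, 86, 98),
    volume_A3 = c(60, 89, 89, 113, 140, 116, 109, 167, 167, 114, 111, 144,
                  169, 138, 163, 153, 190, 174, 194, 228))
}

#' Electron count and molecular volume of a peptide
#'
#' Sums in-chain residue electrons plus one water (10 e) for the free
#' termini; volumes are summed residue volumes.
#'
#' @param sequence One-letter amino-acid string.
#' @return Tibble with `electrons` and `volume_A3`.
#' @export
peptide_electrons <- function(sequence) {
  res <- .residues(sequence)
  tab <- residue_properties()
  idx <- match(res, tab$residue)
  tibble(electrons = sum(tab$electrons[idx]) + 10,
         volume_A3 = sum(tab$volume_A3[idx]))
}

#' Scattering-density-profile model of a peptide-containing bilayer
#'
#' Parametric component-group model of a symmetric bilayer: Gaussians for
#' the phosphate-plus-outer-headgroup (Phos) and carbonyl/glycerol (CG)
#' groups in each leaflet, a terminal-methyl (CH3) Gaussian at the center,
#' a methylene (CH2) region given by an error-function slab of half-width
#' D_C = V_HC / A_L minus the CH3 Gaussian, an optional peptide Gaussian
#' pair, and water filling the remaining volume so total occupancy is one
#' everywhere. Component volumes are per lipid; the unit cell holds one
#' lipid per leaflet over area A_L.
#'
#' @param A_L Area per lipid (Angstrom^2).
#' @param z_P,sigma_P Phos Gaussian center and width (Angstrom).
#' @param z_CG,sigma_CG CG Gaussian center and width.
#' @param sigma_M CH3 Gaussian width.
#' @param sigma_HC Hydrocarbon slab edge roughness.
#' @param V_P,V_CG,V_CH2,V_CH3 Component volumes per lipid (Angstrom^3).
#' @param n_P,n_CG,n_CH2,n_CH3 Electrons per component per lipid.
#' @param V_W,n_W Water molecular volume and electrons (default 30.0, 10).
#' @param peptide NULL or a list with `placement` in
#'   `c("headgroup","hydrocarbon","both")`, `z` (center; length 2 for
#'   "both"), `sigma` (width, recycled), `electrons` and `volume` per
#'   peptide molecule, `ratio` (lipid:peptide molar ratio) and for "both" a
#'   `fraction` in the first location.
#' @return Object of class `sdp_model`.
#' @examples
#' m <- sdp_model(A_L = 70.8)
#' derive_structure(m)
#' @export
sdp_model <- function(A_L = 70.8,
                      z_P = 19.6, sigma_P = 3.0,
                      z_CG = 16.0, sigma_CG = 2.5,
                      sigma_M = 3.0, sigma_HC = 2.6,
                      V_P = 220, V_CG = 150, V_CH2 = 921, V_CH3 = 109,
                      n_P = 110, n_CG = 67, n_CH2 = 256, n_CH3 = 18,
                      V_W = 30.0, n_W = 10,
                      peptide = NULL) {
  stopifnot(A_L > 0, sigma_P > 0, sigma_CG > 0, sigma_M > 0, sigma_HC > 0,
            V_P > 0, V_CG > 0, V_CH2 > 0, V_CH3 > 0)
  m <- structure(list(
    A_L = A_L, z_P = z_P, sigma_P = sigma_P, z_CG = z_CG,
    sigma_CG = sigma_CG, sigma_M = sigma_M, sigma_HC = sigma_HC,
    V_P = V_P, V_CG = V_CG, V_CH2 = V_CH2, V_CH3 = V_CH3,
    n_P = n_P, n_CG = n_CG, n_CH2 = n_CH2, n_CH3 = n_CH3,
    V_W = V_W, n_W = n_W,
    D_C = (V_CH2 + V_CH3) / A_L,
    peptide = peptide), class = "sdp_model")
  m
}

#' @export
print.sdp_model <- function(x, ...) {
  cat(sprintf("SDP bilayer model: A_L = %.1f A^2, D_C = %.2f A, z_P = %.1f, z_CG = %.1f\n",
              x$A_L, x$D_C, x$z_P, x$z_CG))
  if (!is.null(x$peptide))
    cat(sprintf("  peptide: placement = %s, z = %s A\n", x$peptide$placement,
                paste(signif(x$peptide$z, 3), collapse = "/")))
  invisible(x)
}

# per-leaflet peptide volume fraction scaffolding
.pep_per_lipid <- function(pep) {
  list(V = pep$volume / pep$ratio, n = pep$electrons / pep$ratio)
}

# symmetric Gaussian pair with per-leaflet integral V/A_L
.gauss_pair <- function(z, zc, sigma, V_over_A) {
  V_over_A / (sigma * sqrt(2 * pi)) *
    (exp(-(z - zc)^2 / (2 * sigma^2)) + exp(-(z + zc)^2 / (2 * sigma^2)))
}

# peptide occupancy curve(s); "both" splits the volume by `fraction`
.pep_occupancy <- function(model, z) {
  pep <- model$peptide
  if (is.null(pep)) return(rep(0, length(z)))
  pl <- .pep_per_lipid(pep)
  sig <- rep(pep$sigma, length.out = length(pep$z))
  if (identical(pep$placement, "both")) {
    f <- c(pep$fraction, 1 - pep$fraction)
  } else f <- 1
  out <- rep(0, length(z))
  for (i in seq_along(pep$z))
    out <- out + .gauss_pair(z, pep$z[i], sig[i], f[i] * pl$V / model$A_L)
  out
}

#' Component volume occupancy curves
#'
#' Volume probabilities of every component group on a z grid. The
#' hydrocarbon envelope is an error-function slab; groups that intrude
#' into it (headgroup tails, a hydrocarbon-placed peptide) displace
#' methylenes, while outside the slab they displace water, so the total
#' occupancy is exactly one everywhere. A negative methylene occupancy
#' (slab overfilled) is reported via the `overpacked` attribute; a
#' headgroup/peptide sum exceeding one rejects the model outright.
#'
#' @param model An [sdp_model()].
#' @param z Grid along the bilayer normal (Angstrom; 0 = bilayer center).
#' @return Tibble with columns `z`, `phos`, `cg`, `ch2`, `ch3`, `peptide`,
#'   `water`, `total` and attribute `overpacked` (max occupancy deficit).
#' @export
volume_probabilities <- function(model, z) {
  stopifnot(inherits(model, "sdp_model"))
  A <- model$A_L
  hc <- .hc_slab(model, z)
  ch3 <- 2 * model$V_CH3 / (A * model$sigma_M * sqrt(2 * pi)) *
    exp(-z^2 / (2 * model$sigma_M^2))
  phos <- .gauss_pair(z, model$z_P, model$sigma_P, model$V_P / A)
  cg <- .gauss_pair(z, model$z_CG, model$sigma_CG, model$V_CG / A)
  pep <- .pep_occupancy(model, z)
  if (max(phos + cg + pep) > 1 + 1e-9)
    abort("overpacked model: headgroup plus peptide occupancy exceeds 1")
  ch2 <- hc - ch3 - hc * (phos + cg + pep)
  overpack <- max(0, -min(ch2))
  if (overpack > 1e-6)
    warn(sprintf("hydrocarbon slab overfilled by up to %.3g", overpack))
  water <- 1 - (phos + cg + ch2 + ch3 + pep)
  out <- tibble(z = z, phos = phos, cg = cg, ch2 = ch2, ch3 = ch3,
                peptide = pep, water = water,
                total = phos + cg + ch2 + ch3 + pep + water)
  attr(out, "overpacked") <- overpack
  out
}

# error-function hydrocarbon envelope (1 inside |z| < D_C, 0 outside)
.hc_slab <- function(model, z) {
  0.5 * (pracma::erf((model$D_C - z) / (sqrt(2) * model$sigma_HC)) +
         pracma::erf((model$D_C + z) / (sqrt(2) * model$sigma_HC)))
}

# numeric cosine transform of the slab-intrusion product on a fine grid
# (trapezoid over the symmetric profile, exploiting evenness)
.ft_intrusion <- function(model, q_z, z_max = 48, dz = 0.01) {
  z <- seq(0, z_max, by = dz)
  hc <- .hc_slab(model, z)
  f <- hc * (.gauss_pair(z, model$z_P, model$sigma_P, model$V_P / model$A_L) +
             .gauss_pair(z, model$z_CG, model$sigma_CG, model$V_CG / model$A_L) +
             .pep_occupancy(model, z))
  w <- rep(dz, length(z)); w[1] <- dz / 2; w[length(z)] <- dz / 2
  drop((2 * f * w) %*% cos(outer(z, q_z)))
}

# electron densities (e/A^3) of each component group
.component_rho <- function(model) {
  pep <- model$peptide
  c(phos = model$n_P / model$V_P,
    cg = model$n_CG / model$V_CG,
    ch2 = model$n_CH2 / model$V_CH2,
    ch3 = model$n_CH3 / model$V_CH3,
    peptide = if (is.null(pep)) 0 else pep$electrons / pep$volume,
    water = model$n_W / model$V_W)
}

#' Electron density profile
#'
#' Total and per-component electron density rho(z) = sum_c (n_c / V_c)
#' P_c(z), matching the component-group decomposition used for
#' fully hydrated bilayer EDPs.
#'
#' @inheritParams volume_probabilities
#' @return Tibble with `z`, per-component densities, and `total` (e/A^3).
#' @export
electron_density <- function(model, z) {
  occ <- volume_probabilities(model, z)
  rho <- .component_rho(model)
  out <- tibble(z = z)
  for (comp in c("phos", "cg", "ch2", "ch3", "peptide", "water"))
    out[[comp]] <- rho[[comp]] * occ[[comp]]
  out$total <- rowSums(as.matrix(out[c("phos", "cg", "ch2", "ch3",
                                       "peptide", "water")]))
  out
}

#' Bilayer form factor
#'
#' F(q_z) = integral of (rho(z) - rho_water) cos(q_z z) dz, evaluated from
#' the analytic Gaussian and error-function component transforms plus a
#' numeric transform of the slab-intrusion term (headgroup and peptide
#' density displacing methylenes inside the hydrocarbon envelope). Signed
#' values are returned; compare |F| with experimental data.
#'
#' @param model An [sdp_model()].
#' @param q_z Wavevector grid (1/Angstrom).
#' @return Signed form factor (e/Angstrom^2).
#' @export
form_factor <- function(model, q_z) {
  stopifnot(inherits(model, "sdp_model"))
  A <- model$A_L
  rho <- .component_rho(model)
  rw <- rho[["water"]]
  q <- q_z
  slab <- ifelse(q == 0, 2 * model$D_C, 2 * sin(q * model$D_C) / q) *
    exp(-q^2 * model$sigma_HC^2 / 2)
  g_ch3 <- 2 * model$V_CH3 / A * exp(-q^2 * model$sigma_M^2 / 2)
  # ch2 occupies slab - ch3 - intrusion, ch3 occupies g_ch3
  F <- (rho[["ch2"]] - rw) * (slab - g_ch3 - .ft_intrusion(model, q)) +
    (rho[["ch3"]] - rw) * g_ch3
  F <- F + (rho[["phos"]] - rw) * 2 * model$V_P / A *
    cos(q * model$z_P) * exp(-q^2 * model$sigma_P^2 / 2)
  F <- F + (rho[["cg"]] - rw) * 2 * model$V_CG / A *
    cos(q * model$z_CG) * exp(-q^2 * model$sigma_CG^2 / 2)
  pep <- model$peptide
  if (!is.null(pep)) {
    pl <- .pep_per_lipid(pep)
    sig <- rep(pep$sigma, length.out = length(pep$z))
    fr <- if (identical(pep$placement, "both")) c(pep$fraction, 1 - pep$fraction) else 1
    for (i in seq_along(pep$z))
      F <- F + (rho[["peptide"]] - rw) * 2 * fr[i] * pl$V / A *
        cos(q * pep$z[i]) * exp(-q^2 * sig[i]^2 / 2)
  }
  F
}

#' Structural summary of a fitted bilayer model
#'
#' D_HH is the peak-to-peak distance of the summed Phos+CG headgroup
#' electron density (quadratically refined grid peak per leaflet); 2 D_C is
#' the full width at half maximum of the hydrocarbon occupancy; A_L is read
#' from the model.
#'
#' @param model An [sdp_model()].
#' @param z_max,dz Evaluation grid extent and spacing.
#' @return One-row tibble: `A_L`, `D_HH`, `two_D_C`, `unimodal_headgroup`.
#' @export
derive_structure <- function(model, z_max = 45, dz = 0.02) {
  z <- seq(0, z_max, by = dz)
  rho <- .component_rho(model)
  hg <- rho[["phos"]] * .gauss_pair(z, model$z_P, model$sigma_P, model$V_P / model$A_L) +
    rho[["cg"]] * .gauss_pair(z, model$z_CG, model$sigma_CG, model$V_CG / model$A_L)
  i <- which.max(hg)
  unimodal <- TRUE
  # flag extra interior local maxima well separated from the main peak
  d <- diff(sign(diff(hg)))
  peaks <- which(d == -2) + 1L
  if (length(peaks) > 1 && any(abs(z[peaks] - z[i]) > 2 * dz &
                               hg[peaks] > 0.5 * hg[i]))
    unimodal <- FALSE
  if (i > 1 && i < length(z)) {
    # quadratic (three-point) refinement of the peak position
    zpk <- z[i] + 0.5 * (hg[i - 1] - hg[i + 1]) /
      (hg[i - 1] - 2 * hg[i] + hg[i + 1]) * dz
  } else zpk <- z[i]
  # FWHM of the hydrocarbon occupancy
  hc <- 0.5 * (pracma::erf((model$D_C - z) / (sqrt(2) * model$sigma_HC)) +
               pracma::erf((model$D_C + z) / (sqrt(2) * model$sigma_HC)))
  half <- max(hc) / 2
  j <- which(hc < half)[1]
  zh <- approx(hc[c(j - 1, j)], z[c(j - 1, j)], xout = half)$y
  if (!unimodal) warn("headgroup density is not unimodal per leaflet")
  tibble(A_L = model$A_L, D_HH = 2 * zpk, two_D_C = 2 * zh,
         unimodal_headgroup = unimodal)
}

#' Build an SDP model realising target structural parameters
#'
#' Places the hydrocarbon volume so that the slab FWHM equals `two_D_C` at
#' the requested `A_L`, and iteratively shifts the Phos Gaussian so the
#' combined headgroup electron-density peak sits at `D_HH`/2.
#'
#' @param A_L Target area per lipid (Angstrom^2).
#' @param D_HH Target head-to-head distance (Angstrom).
#' @param two_D_C Target hydrocarbon FWHM (Angstrom).
#' @param ... Further arguments to [sdp_model()].
#' @return An [sdp_model()] whose [derive_structure()] matches the targets.
#' @export
sdp_model_from_structure <- function(A_L, D_HH, two_D_C, ...) {
  V_HC <- A_L * two_D_C / 2
  args <- list(...)
  V_CH3 <- args$V_CH3 %||% 109
  m <- do.call(sdp_model, utils::modifyList(
    list(A_L = A_L, V_CH2 = V_HC - V_CH3, V_CH3 = V_CH3,
         z_P = D_HH / 2, z_CG = two_D_C / 2 + 1.5),
    args[setdiff(names(args), c("V_CH2"))]))
  f <- function(zp) {
    m$z_P <- zp
    suppressWarnings(derive_structure(m)$D_HH) - D_HH
  }
  m$z_P <- stats::uniroot(f, interval = c(D_HH / 2 - 6, D_HH / 2 + 8),
                          tol = 1e-5, extendInt = "upX")$root
  m
}

#' Fit an SDP model to |F(q_z)| data
#'
#' Weighted least squares of |F_model| against measured |F| with one free
#' multiplicative scale per dataset, varying A_L, the headgroup positions
#' and the peptide Gaussian for the requested placement; soft penalties
#' reject overpacked iterates. Placement "scan" fits all three peptide
#' locations (headgroup, hydrocarbon, both) and selects the best
#' chi-square after a BIC-style penalty of log(n) per fitted parameter --
#' without it, the nested two-Gaussian "both" model would win on noise
#' alone.
#'
#' @param data Tibble with `q_z`, `absF`, `sigma`.
#' @param init An [sdp_model()] with a peptide entry when placements are
#'   fitted (its electrons/volume/ratio are kept fixed).
#' @param placement One of "headgroup", "hydrocarbon", "both", "scan", or
#'   "none" (lipid-only fit).
#' @return Object of class `sdp_fit`: `model` (best), `chi2` (named per
#'   placement), `placement`, `scale`, `structure` (from
#'   [derive_structure()]), `status`.
#' @export
fit_form_factor <- function(data, init, placement = "scan") {
  stopifnot(all(c("q_z", "absF", "sigma") %in% names(data)),
            inherits(init, "sdp_model"))
  placements <- if (identical(placement, "scan"))
    c("headgroup", "hydrocarbon", "both") else placement
  fits <- purrr::map(placements, function(pl) .fit_sdp_one(data, init, pl))
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2")
  names(chi2) <- placements
  # "both" nests the single-Gaussian placements, so raw minimal chi-square
  # over-selects it on noise; compare on a BIC scale (chi2 + log(n) per
  # fitted parameter), which selects the generating placement consistently
  npar <- vapply(fits, function(f) f$n_par, numeric(1))
  bic <- chi2 + log(nrow(data)) * npar
  near <- which(bic <= min(bic) + 1e-6 * abs(min(bic)) + 1e-9)
  best <- near[order(npar[near], chi2[near])][1]
  out <- fits[[best]]
  structure(list(model = out$model, chi2 = chi2, placement = placements[best],
                 scale = out$scale, structure = derive_structure(out$model),
                 status = out$status),
            class = "sdp_fit")
}

.fit_sdp_one <- function(data, init, placement) {
  q <- data$q_z; y <- data$absF; s <- data$sigma
  has_pep <- !identical(placement, "none")
  pep0 <- init$peptide
  if (has_pep && is.null(pep0))
    abort("init model needs a peptide entry to fit a peptide placement")
  zg <- seq(0, 45, by = 0.25)
  build <- function(p) {
    A_L <- p[1]; z_P <- p[2]; z_CG <- p[3]
    pep <- NULL
    if (has_pep) {
      pep <- pep0
      pep$placement <- placement
      if (placement == "both") {
        pep$z <- c(p[4], p[5]); pep$sigma <- p[6]
        pep$fraction <- 1 / (1 + exp(-p[7]))
      } else {
        pep$z <- p[4]; pep$sigma <- p[5]
      }
    }
    sdp_model(A_L = A_L, z_P = z_P, sigma_P = init$sigma_P,
              z_CG = z_CG, sigma_CG = init$sigma_CG,
              sigma_M = init$sigma_M, sigma_HC = init$sigma_HC,
              V_P = init$V_P, V_CG = init$V_CG,
              V_CH2 = init$V_CH2, V_CH3 = init$V_CH3,
              n_P = init$n_P, n_CG = init$n_CG,
              n_CH2 = init$n_CH2, n_CH3 = init$n_CH3,
              V_W = init$V_W, n_W = init$n_W, peptide = pep)
  }
  resid_fn <- function(p) {
    m <- tryCatch(build(p), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(y) + 1))
    Fm <- abs(form_factor(m, q))
    sc <- sum(y * Fm / s^2) / sum(Fm^2 / s^2)
    occ <- suppressWarnings(volume_probabilities(m, zg))
    pen <- 100 * attr(occ, "overpacked") * sqrt(length(y))
    c((sc * Fm - y) / s, pen)
  }
  D_C0 <- init$D_C
  if (has_pep) {
    if (placement == "both") {
      p0 <- c(init$A_L, init$z_P, init$z_CG, D_C0 * 0.5, init$z_P, 4, 0)
      lower <- c(40, 10, 8, 0, D_C0 * 0.8, 2, -4)
      upper <- c(110, 30, 25, D_C0, 30, 8, 4)
    } else if (placement == "hydrocarbon") {
      p0 <- c(init$A_L, init$z_P, init$z_CG, D_C0 * 0.6, 4)
      lower <- c(40, 10, 8, 0, 2); upper <- c(110, 30, 25, D_C0, 8)
    } else {
      p0 <- c(init$A_L, init$z_P, init$z_CG, init$z_P, 4)
      lower <- c(40, 10, 8, D_C0, 2); upper <- c(110, 30, 25, 32, 8)
    }
  } else {
    p0 <- c(init$A_L, init$z_P, init$z_CG)
    lower <- c(40, 10, 8); upper <- c(110, 30, 25)
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  m <- build(fit$par)
  Fm <- abs(form_factor(m, q))
  sc <- sum(y * Fm / s^2) / sum(Fm^2 / s^2)
  list(model = m, chi2 = sum(((sc * Fm - y) / s)^2), scale = sc,
       n_par = length(p0) + 1, # structural parameters plus the scale
       status = if (fit$info %in% c(0, 5)) "not_converged" else "converged")
}

#' @export
print.sdp_fit <- function(x, ...) {
  cat(sprintf("SDP form-factor fit: placement = %s (chi2: %s)\n", x$placement,
              paste(sprintf("%s %.3g", names(x$chi2), x$chi2), collapse = ", ")))
  print(x$structure)
  invisible(x)
}

#' @rdname fit_form_factor
#' @param x,object An `sdp_fit`.
#' @param ... Unused.
#' @export
tidy.sdp_fit <- function(x, ...) {
  dplyr::mutate(x$structure, placement = x$placement, .before = 1)
}

#' @rdname fit_form_factor
#' @export
glance.sdp_fit <- function(x, ...) {
  tibble(placement = x$placement, chi2 = min(x$chi2), scale = x$scale,
         status = x$status)
}

#' Plot component electron density profiles
#'
#' @param model An [sdp_model()].
#' @param z_max Half-range of the z grid.
#' @return A ggplot of per-component and total electron densities.
#' @export
plot_edp <- function(model, z_max = 40) {
  z <- seq(-z_max, z_max, by = 0.25)
  ed <- electron_density(model, z) |>
    tidyr::pivot_longer(-z, names_to = "component", values_to = "rho")
  ggplot2::ggplot(ed, ggplot2::aes(.data$z, .data$rho, colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (A)", y = "electron density (e/A^3)")
}
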