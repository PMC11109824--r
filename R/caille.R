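#' Smectic stack model of a fluctuating bilayer multilayer
#'
#' Parameter container for the discrete smectic free energy
#' F = 1/2 sum_n int [ K_C (lap u_n)^2 + B (u_{n+1} - u_n)^2 ] d2r,
#' where u_n(r) is the vertical displacement of bilayer n. Thermal
#' fluctuations of this stack produce the lobes of diffuse low-angle
#' scattering whose lateral fall-off encodes the bending modulus.
#'
#' Internally all energies are in units of k_B T and lengths in Angstrom:
#' `K_C` is dimensionless x k_BT, `B` is k_BT per Angstrom^4.
#'
#' @param K_C Bending modulus (k_BT). Stiffer membranes have larger K_C.
#' @param B Interbilayer compression modulus (k_BT / A^4).
#' @param N_layers Number of bilayers in the vertical stack (effective
#'   coherence number for fitting).
#' @param L_r Lateral domain size (Angstrom); sets the in-plane infrared
#'   cutoff 2*pi/L_r.
#' @param D Lamellar repeat spacing (Angstrom).
#' @param T Temperature (K).
#' @return Object of class `stack_model`.
#' @examples
#' stack_model(K_C = 20, B = 2e-6)
#' @export
stack_model <- function(K_C = 20, B = 2e-6, N_layers = 16, L_r = 800,
                        D = 60, T = 310.15) {
  stopifnot(K_C > 0, B > 0, N_layers >= 1, N_layers == round(N_layers),
            L_r > 0, D > 0, T > 0)
  structure(list(K_C = K_C, B = B, N_layers = as.integer(N_layers),
                 L_r = L_r, D = D, T = T),
            class = "stack_model")
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf(
    "Smectic stack: K_C = %.3g kBT (%.3g x 1e-21 J at %.2f K), B = %.3g kBT/A^4\n",
    x$K_C, kc_to_joule(x$K_C, x$T) * 1e21, x$T, x$B))
  cat(sprintf("  N = %d layers, D = %.1f A, L_r = %.0f A\n",
              x$N_layers, x$D, x$L_r))
  invisible(x)
}

#' Convert a bending modulus between k_BT and Joule
#'
#' @param K_C_kbt Bending modulus in units of k_BT.
#' @param T Temperature in K (default 310.15, i.e. 37 C).
#' @return Bending modulus in Joule.
#' @export
kc_to_joule <- function(K_C_kbt, T = 310.15) K_C_kbt * .kB * T

#' @rdname kc_to_joule
#' @param K_C_J Bending modulus in Joule.
#' @export
kc_from_joule <- function(K_C_J, T = 310.15) K_C_J / (.kB * T)

# dispersion of the discrete smectic modes (k_BT / A^4 units):
# E_m(q) = K_C q^4 + 2 B (1 - cos(2 pi m / N))
.mode_energy <- function(model, q_r, mode_index) {
  model$K_C * q_r^4 +
    2 * model$B * (1 - cos(2 * pi * mode_index / model$N_layers))
}

#' Equipartition amplitude of a discrete smectic mode
#'
#' Mean-square Fourier amplitude of undulation mode `mode_index` at lateral
#' wavevector `q_r`, from equipartition of the discrete smectic free
#' energy: kBT / (A * (K_C q_r^4 + 2 B (1 - cos(2 pi m / N)))) with the
#' domain area A = L_r^2 as in-plane normalization.
#'
#' @param model A [stack_model()].
#' @param q_r Lateral wavevector (1/Angstrom).
#' @param mode_index Integer mode index in `0:(N_layers-1)`.
#' @return Mean-square amplitude (Angstrom^2).
#' @export
mode_spectrum <- function(model, q_r, mode_index) {
  stopifnot(inherits(model, "stack_model"),
            all(mode_index >= 0), all(mode_index < model$N_layers))
  if (any(q_r == 0 & (mode_index %% model$N_layers) == 0))
    abort("q_r = 0 with mode 0 is the unnormalizable Goldstone mode (zero restoring force)")
  1 / (model$L_r^2 * .mode_energy(model, q_r, mode_index))
}

# log-spaced quadrature grid in q between the finite-size cutoff and a
# molecular-scale upper cutoff
.q_grid <- function(model, n_q) {
  exp(seq(log(2 * pi / model$L_r), log(2), length.out = n_q))
}

# delta_k(r) = <(u_n(r) - u_{n+k}(0))^2> on a matrix of (k, r):
# (1/(N pi)) sum_m int q [1 - J0(q r) cos(2 pi m k/N)] / E_m(q) dq
# vectorized as matrix products; trapezoid weights on a log-q grid.
.delta_matrix <- function(model, r, n_q = 400) {
  N <- model$N_layers
  q <- .q_grid(model, n_q)
  wq <- c(diff(q) / 2, 0) + c(0, diff(q) / 2) # trapezoid
  m <- 0:(N - 1)
  E <- outer(m, q, function(mm, qq) .mode_energy(model, qq, mm)) # N x nq
  W <- sweep(1 / E, 2, q * wq, `*`)                              # N x nq
  J0 <- outer(q, r, function(qq, rr) besselJ(qq * rr, 0))        # nq x nr
  cos_mk <- outer(m, 0:(N - 1), function(mm, kk) cos(2 * pi * mm * kk / N))
  total <- sum(W)                     # the "1" term, independent of k and r
  cross <- t(cos_mk) %*% (W %*% J0)   # N_k x nr
  (total - cross) / (N * pi)
}

#' Mean-square height difference between stack layers
#'
#' delta_k(r) = <(u_n(r) - u_{n+k}(0))^2> for layer offset `k` and in-plane
#' separation `r`, computed by quadrature over the lateral mode spectrum
#' and summation over the discrete layer modes, with infrared cutoff
#' 2*pi/L_r. The quadrature grid is doubled until the result is stable to
#' 0.1% (relative); failure to stabilise is reported.
#'
#' @param model A [stack_model()].
#' @param k Layer offset, `0 <= k < N_layers`.
#' @param r In-plane separation (Angstrom, >= 0); vectorized.
#' @param n_q Initial number of quadrature points.
#' @return delta_k(r) in Angstrom^2.
#' @export
height_correlation <- function(model, k, r, n_q = 400) {
  stopifnot(inherits(model, "stack_model"), k >= 0, k < model$N_layers,
            all(r >= 0))
  d0 <- .delta_matrix(model, r, n_q)[k + 1, ]
  for (i in 1:3) {
    n_q <- n_q * 2L
    d1 <- .delta_matrix(model, r, n_q)[k + 1, ]
    ok <- all(abs(d1 - d0) <= pmax(1e-3 * abs(d1), 1e-9))
    d0 <- d1
    if (ok) return(d0)
  }
  warn(sprintf("height_correlation quadrature not stable to 0.1%% at n_q = %d", n_q))
  d0
}

#' Diffuse structure factor of the fluctuating stack
#'
#' S(q_z, q_r) = sum_k (N - |k|) cos(q_z k D) H_k(q_z, q_r) / (pi L_r^2),
#' with H_k the Hankel-type integral of exp(-q_z^2 delta_k(r)/2) over the
#' finite lateral domain. Normalised so that a frozen stack (delta == 0)
#' reproduces the ideal finite-lattice interference function: at q_r = 0 and
#' q_z = 2 pi/D a rigid stack gives S = N^2.
#'
#' @param model A [stack_model()].
#' @param q_z Vertical wavevector grid (1/Angstrom).
#' @param q_r Lateral wavevector grid (1/Angstrom).
#' @param n_r Number of radial integration points.
#' @param n_q Quadrature points for the height correlations.
#' @param delta Optional precomputed `N x n_r` height-difference matrix
#'   (internal reuse during fitting).
#' @return Matrix of S values, `length(q_z)` rows x `length(q_r)` columns.
#' @export
structure_factor <- function(model, q_z, q_r, n_r = 256, n_q = 400,
                             delta = NULL) {
  stopifnot(inherits(model, "stack_model"))
  N <- model$N_layers
  r <- seq(0, model$L_r, length.out = n_r)
  wr <- c(diff(r) / 2, 0) + c(0, diff(r) / 2)
  if (is.null(delta)) delta <- .delta_matrix(model, r, n_q)
  J0r <- outer(r, q_r, function(rr, qq) besselJ(abs(qq) * rr, 0)) # J0 is even
  J0r <- J0r * (2 * pi * r * wr)
  kfac <- (N - (0:(N - 1))) * ifelse(0:(N - 1) == 0, 1, 2)
  S <- matrix(0, length(q_z), length(q_r))
  for (i in seq_along(q_z)) {
    qz <- q_z[i]
    Ek <- exp(-qz^2 * delta / 2)          # N_k x n_r
    Hk <- Ek %*% J0r                      # N_k x n_qr
    cz <- cos(qz * (0:(N - 1)) * model$D)
    S[i, ] <- drop((kfac * cz) %*% Hk) / (pi * model$L_r^2)
  }
  S
}

#' Predict a diffuse scattering pattern
#'
#' Observation model for background-subtracted oriented-sample data:
#' intensity = scale * S(q_z, q_r) * |F(q_z)|^2 / q_z, with the 1/q_z
#' flat-sample Lorentz correction, optionally convolved with a Gaussian
#' instrumental resolution along q_r. The region below `qz_cutoff`
#' (beam/specular) is masked to NA.
#'
#' @param model A [stack_model()].
#' @param formfactor Function of q_z returning |F(q_z)| (arbitrary units),
#'   or NULL for |F| == 1.
#' @param q_z,q_r Pattern grids (1/Angstrom).
#' @param scale Overall intensity scale.
#' @param qz_cutoff Mask q_z below this value.
#' @param resolution_sigma Optional Gaussian resolution width in q_r
#'   (1/Angstrom); 0 disables convolution.
#' @param ... Passed to [structure_factor()].
#' @return Object of class `diffuse_pattern`: list with `q_r`, `q_z`,
#'   `intensity` (matrix, q_z rows) and `sigma` (NULL).
#' @export
predict_pattern <- function(model, formfactor = NULL, q_z, q_r, scale = 1,
                            qz_cutoff = 0.05, resolution_sigma = 0, ...) {
  S <- structure_factor(model, q_z, q_r, ...)
  absF <- if (is.null(formfactor)) rep(1, length(q_z)) else formfactor(q_z)
  I <- scale * S * (absF^2 / q_z)
  I[q_z < qz_cutoff, ] <- NA_real_
  if (resolution_sigma > 0 && length(q_r) > 2) {
    dq <- mean(diff(q_r))
    half <- max(1L, ceiling(3 * resolution_sigma / dq))
    kern <- exp(-0.5 * ((-half:half) * dq / resolution_sigma)^2)
    kern <- kern / sum(kern)
    I <- t(apply(I, 1, function(row) {
      if (all(is.na(row))) return(row)
      stats::filter(row, kern, sides = 2) |> as.numeric()
    }))
  }
  new_diffuse_pattern(q_r = q_r, q_z = q_z, intensity = I)
}

#' Construct a diffuse pattern container
#'
#' @param q_r,q_z Monotone axis grids (1/Angstrom).
#' @param intensity Matrix with `length(q_z)` rows, `length(q_r)` columns.
#' @param sigma Optional per-pixel uncertainty matrix.
#' @return Object of class `diffuse_pattern`.
#' @export
new_diffuse_pattern <- function(q_r, q_z, intensity, sigma = NULL) {
  stopifnot(nrow(intensity) == length(q_z), ncol(intensity) == length(q_r))
  structure(list(q_r = q_r, q_z = q_z, intensity = intensity, sigma = sigma),
            class = "diffuse_pattern")
}

#' @export
print.diffuse_pattern <- function(x, ...) {
  cat(sprintf("Diffuse pattern: %d x %d pixels, q_z in [%.3g, %.3g], q_r in [%.3g, %.3g] 1/A\n",
              length(x$q_z), length(x$q_r), min(x$q_z), max(x$q_z),
              min(x$q_r), max(x$q_r)))
  invisible(x)
}

#' @export
as_tibble.diffuse_pattern <- function(x, ...) {
  tidyr::expand_grid(q_z = x$q_z, q_r = x$q_r) |>
    dplyr::mutate(intensity = as.vector(t(x$intensity)))
}

#' @rdname new_diffuse_pattern
#' @param object A `diffuse_pattern`.
#' @param ... Unused.
#' @export
autoplot.diffuse_pattern <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$q_r, .data$q_z, fill = log10(pmax(.data$intensity, 1e-12)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 I") +
    ggplot2::labs(x = "q_r (1/A)", y = "q_z (1/A)")
}

#' Background subtraction and lateral symmetrization
#'
#' Subtracts a background image and averages the result with its mirror
#' about q_r = 0 to increase signal-to-noise, the standard reduction for
#' oriented-sample diffuse data. Requires a q_r axis symmetric about zero.
#'
#' @param image_pos `diffuse_pattern` containing the sample exposure.
#' @param image_background Matrix of the same shape (or `diffuse_pattern`).
#' @return Symmetrized, background-subtracted `diffuse_pattern`.
#' @export
symmetrize_and_subtract <- function(image_pos, image_background) {
  stopifnot(inherits(image_pos, "diffuse_pattern"))
  bg <- if (inherits(image_background, "diffuse_pattern"))
    image_background$intensity else image_background
  if (!identical(dim(image_pos$intensity), dim(bg)))
    abort("sample and background images must have identical shapes")
  if (max(abs(image_pos$q_r + rev(image_pos$q_r))) > 1e-9 * max(abs(image_pos$q_r)))
    abort("q_r axis must be symmetric about zero for lateral symmetrization")
  I <- image_pos$intensity - bg
  I <- (I + I[, ncol(I):1, drop = FALSE]) / 2
  new_diffuse_pattern(image_pos$q_r, image_pos$q_z, I, image_pos$sigma)
}

#' Fit bending and compression moduli to a diffuse pattern
#'
#' Weighted nonlinear least squares of the predicted diffuse intensity to a
#' background-subtracted pattern over a fit window, varying (K_C, B, scale)
#' with N_layers, L_r and D held fixed at the values in `init`. The lateral
#' fall-off of lobe intensity determines K_C: a higher fitted K_C means a
#' stiffer membrane.
#'
#' @param pattern A `diffuse_pattern` with optional `sigma`.
#' @param formfactor |F(q_z)| function or NULL (|F| == 1).
#' @param init A [stack_model()] providing starting values and the fixed
#'   geometry (N_layers, L_r, D, T).
#' @param fit_window List with `q_z = c(lo, hi)` and `q_r = c(lo, hi)`
#'   selecting the lobe region (excluding beam and specular).
#' @param n_r,n_q Forward-model grid sizes.
#' @param log_kc_bounds Bounds on log(K_C) used to flag runaway stiffness.
#' @return Object of class `elasticity_fit` with elements `K_C_hat`,
#'   `B_hat`, `scale`, `ci` (tibble of 95% intervals), `chi2_reduced`,
#'   `status`, `model`.
#' @export
fit_elasticity <- function(pattern, formfactor = NULL, init,
                           fit_window, n_r = 256, n_q = 300,
                           log_kc_bounds = log(c(1e-3, 1e5))) {
  stopifnot(inherits(pattern, "diffuse_pattern"), inherits(init, "stack_model"))
  iz <- which(pattern$q_z >= fit_window$q_z[1] & pattern$q_z <= fit_window$q_z[2])
  ir <- which(pattern$q_r >= fit_window$q_r[1] & pattern$q_r <= fit_window$q_r[2])
  if (!length(iz) || !length(ir)) abort("fit window does not intersect the pattern support")
  qz <- pattern$q_z[iz]; qr <- pattern$q_r[ir]
  y <- pattern$intensity[iz, ir, drop = FALSE]
  sig <- if (!is.null(pattern$sigma)) pattern$sigma[iz, ir, drop = FALSE]
  else pmax(abs(y), max(abs(y), na.rm = TRUE) * 1e-3) * 0.05
  ok <- is.finite(y)
  absF <- if (is.null(formfactor)) rep(1, length(qz)) else formfactor(qz)
  lorentz <- absF^2 / qz
  r <- seq(0, init$L_r, length.out = n_r)

  fwd <- function(K_C, B) {
    m <- stack_model(K_C, B, init$N_layers, init$L_r, init$D, init$T)
    delta <- .delta_matrix(m, r, n_q)
    structure_factor(m, qz, qr, n_r = n_r, delta = delta) * lorentz
  }
  resid_fn <- function(p) {
    pred <- exp(p[3]) * fwd(exp(p[1]), exp(p[2]))
    ((pred - y) / sig)[ok]
  }
  p0 <- log(c(init$K_C, init$B, 1))
  # crude scale init from the data
  pred0 <- fwd(init$K_C, init$B)
  p0[3] <- log(max(sum(y[ok] * pred0[ok]) / sum(pred0[ok]^2), 1e-12))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    lower = c(log_kc_bounds[1], log(1e-12), -40),
    upper = c(log_kc_bounds[2], log(1e3), 40),
    control = minpack.lm::nls.lm.control(maxiter = 80))
  p <- fit$par
  dof <- sum(ok) - 3
  chi2r <- sum(fit$fvec^2) / max(dof, 1)
  # covariance in log space; delta-method CIs on the natural scale
  cv <- tryCatch(chol2inv(chol(fit$hessian)) * 2 * chi2r,
                 error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cv), 0))
  status <- "converged"
  if (fit$info %in% c(0, 5)) status <- "not_converged"
  if (p[1] >= log_kc_bounds[2] - 1e-6) status <- "kc_at_upper_bound"
  ci <- tibble(
    parameter = c("K_C", "B", "scale"),
    estimate = exp(p),
    lower = exp(p - 1.96 * se),
    upper = exp(p + 1.96 * se))
  structure(list(
    K_C_hat = exp(p[1]), B_hat = exp(p[2]), scale = exp(p[3]),
    ci = ci, chi2_reduced = chi2r, status = status,
    model = stack_model(exp(p[1]), exp(p[2]), init$N_layers, init$L_r,
                        init$D, init$T)),
    class = "elasticity_fit")
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat(sprintf("Elasticity fit (%s): K_C = %.3g kBT (%.3g x 1e-21 J), B = %.3g kBT/A^4, chi2_red = %.3g\n",
              x$status, x$K_C_hat, kc_to_joule(x$K_C_hat, x$model$T) * 1e21,
              x$B_hat, x$chi2_reduced))
  invisible(x)
}

#' @rdname fit_elasticity
#' @param x,object An `elasticity_fit`.
#' @param ... Unused.
#' @export
tidy.elasticity_fit <- function(x, ...) x$ci

#' @rdname fit_elasticity
#' @export
glance.elasticity_fit <- function(x, ...) {
  tibble(K_C_hat = x$K_C_hat, K_C_joule = kc_to_joule(x$K_C_hat, x$model$T),
         B_hat = x$B_hat, scale = x$scale,
         chi2_reduced = x$chi2_reduced, status = x$status)
}
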