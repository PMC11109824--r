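#' Azimuthally average a 2D SAXS image
#'
#' Bins pixels of an isotropic solution-scattering image by |q| and returns
#' the per-bin mean intensity with counting-statistics uncertainties
#' (sigma = bin SD / sqrt(n), falling back to sqrt(mean I / n) for
#' single-count bins).
#'
#' @param image Matrix with rows indexed by `q_y` and columns by `q_x`.
#' @param q_x,q_y Axis grids (1/Angstrom), e.g. from detector geometry.
#' @param q_breaks Radial bin edges; default 120 bins over the image range.
#' @return Tibble (a SAXS curve): `q`, `intensity`, `sigma`, `n_pixels`.
#' @export
azimuthal_average <- function(image, q_x, q_y, q_breaks = NULL) {
  stopifnot(nrow(image) == length(q_y), ncol(image) == length(q_x))
  qq <- sqrt(outer(q_y^2, q_x^2, `+`))
  if (is.null(q_breaks))
    q_breaks <- seq(0, max(qq), length.out = 121)
  bin <- cut(as.vector(qq), breaks = q_breaks, include.lowest = TRUE)
  v <- as.vector(image)
  keep <- !is.na(v)
  if (any(!keep)) warn(sprintf("%d masked pixels ignored", sum(!keep)))
  mu <- tapply(v[keep], bin[keep], mean)
  n <- tapply(v[keep], bin[keep], length)
  s <- tapply(v[keep], bin[keep], sd)
  centers <- (q_breaks[-1] + q_breaks[-length(q_breaks)]) / 2
  ok <- !is.na(mu)
  sig <- ifelse(is.na(s[ok]) | s[ok] == 0,
                sqrt(pmax(mu[ok], 0) / pmax(n[ok], 1)), s[ok] / sqrt(n[ok]))
  tibble(q = centers[ok], intensity = unname(mu[ok]),
         sigma = unname(sig), n_pixels = unname(n[ok]))
}

#' Subtract a water (solvent) background from a SAXS curve
#'
#' Pointwise subtraction of a measured water curve or a flat constant, with
#' uncertainties propagated in quadrature.
#'
#' @param curve Tibble with `q`, `intensity` and optionally `sigma`.
#' @param water A matching curve tibble (same q grid) or a single constant.
#' @return Background-subtracted curve tibble.
#' @export
subtract_water <- function(curve, water) {
  stopifnot(all(c("q", "intensity") %in% names(curve)))
  out <- as_tibble(curve)
  if (is.numeric(water) && length(water) == 1L) {
    out$intensity <- out$intensity - water
  } else {
    stopifnot(is.data.frame(water))
    if (!isTRUE(all.equal(out$q, water$q)))
      abort("curve and water background must share a q grid")
    out$intensity <- out$intensity - water$intensity
    if (!is.null(out$sigma) && !is.null(water$sigma))
      out$sigma <- sqrt(out$sigma^2 + water$sigma^2)
  }
  out
}

# rolling median with edge padding
.roll_median <- function(x, window) {
  half <- window %/% 2
  xx <- c(rep(x[1], half), x, rep(x[length(x)], half))
  vapply(seq_along(x), function(i) median(xx[i:(i + 2 * half)]), numeric(1))
}

#' Detect lamellar Bragg orders in a SAXS curve
#'
#' Local maxima at least `n_sigma` standard deviations above a rolling
#' median background are kept as candidate Bragg peaks; orders are assigned
#' by the best integer ratio to the lowest-q peak (within `order_tol`
#' relative), and each peak's position and FWHM are refined by a local
#' Gaussian-plus-linear fit. Peaks with no consistent integer order are
#' left unassigned with a warning. An empty peak list is a valid result
#' (unilamellar vesicles show only diffuse modulation).
#'
#' @param curve Background-subtracted SAXS curve tibble (`q`, `intensity`,
#'   optional `sigma`).
#' @param window Rolling-median window (points).
#' @param n_sigma Significance threshold above the local background.
#' @param order_tol Relative tolerance for integer order assignment.
#' @param min_prominence Minimum excess over the rolling-median background
#'   as a fraction of that background; rejects broad diffuse maxima that a
#'   pure noise threshold would pass on low-noise data.
#' @return Tibble of peaks: `q`, `order` (NA when unassigned), `fwhm`,
#'   `height`, `significance`.
#' @export
find_bragg_orders <- function(curve, window = 15, n_sigma = 3,
                              order_tol = 0.08, min_prominence = 0.2) {
  stopifnot(all(c("q", "intensity") %in% names(curve)))
  q <- curve$q; y <- curve$intensity
  bg <- .roll_median(y, window)
  excess <- y - bg
  noise <- if (!is.null(curve$sigma)) curve$sigma
  else pmax(stats::mad(excess), 1e-12)
  # base significance threshold, lifted for multiple comparisons across the
  # whole curve (family-wise 5%) so isolated noise excursions do not become
  # spurious "orders"
  n_sigma <- max(n_sigma, stats::qnorm(1 - 0.05 / length(q)))
  sign_thresh <- pmax(n_sigma * noise, min_prominence * pmax(bg, 0))
  is_peak <- c(FALSE, diff(sign(diff(y))) == -2, FALSE) & excess > sign_thresh
  idx <- which(is_peak)
  # merge maxima closer than the window into the strongest
  if (length(idx) > 1) {
    keep <- logical(length(idx)); ord <- order(-y[idx])
    taken <- rep(FALSE, length(q))
    for (j in ord) {
      i <- idx[j]
      lo <- max(1, i - window %/% 2); hi <- min(length(q), i + window %/% 2)
      if (!any(taken[lo:hi])) { keep[j] <- TRUE; taken[lo:hi] <- TRUE }
    }
    idx <- sort(idx[keep])
  }
  if (!length(idx))
    return(tibble(q = numeric(), order = integer(), fwhm = numeric(),
                  height = numeric(), significance = numeric()))
  refined <- purrr::map(idx, function(i) .refine_peak(q, y, i, window))
  pk <- dplyr::bind_rows(refined)
  pk$significance <- excess[idx] / (if (length(noise) > 1) noise[idx] else noise)
  pk$background <- bg[idx]
  # reject sub-pixel spikes and refinements that collapsed
  dq <- mean(diff(q))
  noise_idx <- if (length(noise) > 1) noise[idx] else rep(noise, length(idx))
  ok_pk <- is.finite(pk$fwhm) & pk$fwhm >= 0.8 * dq & pk$height > 0 &
    pk$height >= n_sigma * noise_idx &
    (!is.finite(pk$res_rms) | pk$height >= n_sigma * pk$res_rms) &
    abs(pk$q - q[idx]) <= 3 * dq &          # refinement drifted off the maximum
    pk$fwhm <= 0.7 * (2 * window * dq)      # fit latched onto a flank/slope
  pk <- pk[ok_pk, , drop = FALSE]
  if (!nrow(pk))
    return(tibble(q = numeric(), order = integer(), fwhm = numeric(),
                  height = numeric(), significance = numeric(),
                  background = numeric()))
  # integer order assignment against the lowest-q peak
  q0 <- pk$q[1]
  ratio <- pk$q / q0
  ord <- as.integer(round(ratio))
  good <- abs(ratio - ord) <= order_tol * pmax(ord, 1) & ord >= 1
  if (any(!good))
    warn(sprintf("%d peak(s) inconsistent with integer orders left unassigned",
                 sum(!good)))
  pk$order <- ifelse(good, ord, NA_integer_)
  pk[c("q", "order", "fwhm", "height", "significance", "background")]
}

# local Gaussian + linear fit around a candidate peak
.refine_peak <- function(q, y, i, window) {
  lo <- max(1, i - window); hi <- min(length(q), i + window)
  qq <- q[lo:hi]; yy <- y[lo:hi]
  p0 <- c(y[i] - min(yy), q[i], diff(range(qq)) / 6, min(yy), 0)
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = p0,
    fn = function(p) p[1] * exp(-(qq - p[2])^2 / (2 * p[3]^2)) +
      p[4] + p[5] * (qq - p[2]) - yy,
    lower = c(0, min(qq), 1e-6, -Inf, -Inf),
    upper = c(Inf, max(qq), diff(range(qq)), Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 120))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(tibble(q = q[i], fwhm = NA_real_, height = y[i],
                  res_rms = NA_real_))
  p <- fit$par
  # width by direct half-maximum crossings of the baseline-subtracted
  # peak: exact for non-Gaussian (e.g. finite-lattice sinc^2) line shapes
  # that a fitted Gaussian sigma would misestimate
  ybs <- yy - (p[4] + p[5] * (qq - p[2]))
  ic <- which.min(abs(qq - p[2]))
  half <- max(ybs[ic], p[1]) / 2
  cross <- function(side) {
    idxs <- if (side < 0) seq(ic, 1) else seq(ic, length(qq))
    below <- which(ybs[idxs] < half)
    if (!length(below)) return(NA_real_)
    j2 <- idxs[below[1]]; j1 <- j2 - side
    if (j1 < 1 || j1 > length(qq)) return(NA_real_)
    approx(ybs[c(j1, j2)], qq[c(j1, j2)], xout = half)$y
  }
  lo_x <- cross(-1); hi_x <- cross(1)
  fwhm <- if (is.finite(lo_x) && is.finite(hi_x)) hi_x - lo_x
  else 2 * sqrt(2 * log(2)) * p[3]
  tibble(q = p[2], fwhm = fwhm, height = p[1],
         res_rms = sqrt(mean(fit$fvec^2)))
}

#' Lamellar repeat spacing from assigned Bragg orders
#'
#' D = 2 pi n / q_n averaged over assigned orders, weighted by 1/FWHM^2
#' (sharper peaks dominate).
#'
#' @param peaks Peak tibble from [find_bragg_orders()].
#' @return Repeat spacing D in Angstrom.
#' @examples
#' d_spacing(tibble::tibble(q = 0.123, order = 1L, fwhm = 0.002))
#' @export
d_spacing <- function(peaks) {
  pk <- peaks[!is.na(peaks$order), , drop = FALSE]
  if (!nrow(pk)) abort("no assigned Bragg orders")
  d <- 2 * pi * pk$order / pk$q
  w <- if (all(is.finite(pk$fwhm)) && all(pk$fwhm > 0)) 1 / pk$fwhm^2
  else rep(1, nrow(pk))
  sum(w * d) / sum(w)
}

#' Scherrer coherence length and lamellarity
#'
#' L = 2 pi K / dq with dq the peak FWHM after quadrature deconvolution of
#' the instrumental resolution; the number of coherently stacked bilayers
#' is round(L / D). A width at or below the resolution yields only a lower
#' bound, flagged in the result.
#'
#' @param peak List or one-row tibble with `q` and `fwhm`.
#' @param D Repeat spacing (Angstrom).
#' @param K Scherrer shape factor (default 0.9).
#' @param resolution Instrumental FWHM in q (default 0).
#' @return Tibble: `L`, `n_lamellae`, `resolution_limited`.
#' @export
scherrer_lamellarity <- function(peak, D, K = 0.9, resolution = 0) {
  dq <- peak$fwhm
  if (dq <= resolution)
    return(tibble(L = 2 * pi * K / max(resolution, 1e-12),
                  n_lamellae = NA_integer_, resolution_limited = TRUE))
  dq_corr <- sqrt(dq^2 - resolution^2)
  L <- 2 * pi * K / dq_corr
  tibble(L = L, n_lamellae = as.integer(round(L / D)),
         resolution_limited = FALSE)
}

#' Classify a SAXS curve as ULV, MLV or mixed
#'
#' Multilamellar vesicles show significant assigned Bragg orders;
#' unilamellar vesicles only a diffuse modulation. When detected peaks
#' remain comparable to the diffuse background under them (peak-to-diffuse
#' contrast, fitted peak height over local rolling-median background,
#' below `mix_threshold`) the sample is classified as mixed, matching
#' curves in which only small Bragg orders ride on the first diffuse lobe.
#'
#' @param curve Background-subtracted SAXS curve tibble.
#' @param mix_threshold Peak/diffuse contrast separating mixed from MLV
#'   (default 10: a dominant Bragg order rises an order of magnitude above
#'   the diffuse lobe).
#' @param ... Passed to [find_bragg_orders()].
#' @return Character scalar: "ULV", "mixed" or "MLV", with the peak table
#'   as attribute `peaks`.
#' @export
classify_phase <- function(curve, mix_threshold = 10, ...) {
  pk <- find_bragg_orders(curve, ...)
  pk <- pk[!is.na(pk$order), , drop = FALSE]
  if (!nrow(pk)) return(structure("ULV", peaks = pk))
  # diffuse reference: median intensity halfway between the first and
  # second lamellar order, where only the uncorrelated-bilayer lobe (and
  # unresolved peak tails) contribute
  # fundamental position from all assigned orders
  q1 <- sum(pk$q / pk$order * pk$height) / sum(pk$height)
  top <- max(curve$intensity[abs(curve$q - q1) <= 0.05 * q1])
  # diffuse level at the peak interpolated (geometric mean) from the flanks
  flank <- function(fac) {
    near <- abs(curve$q - fac * q1) <= 0.06 * q1
    if (!any(near)) return(NA_real_)
    median(curve$intensity[near])
  }
  diffuse <- exp(mean(log(pmax(c(flank(0.72), flank(1.5)), 1e-300)), na.rm = TRUE))
  contrast <- (top - diffuse) / max(diffuse, 1e-300)
  cls <- if (contrast >= mix_threshold) "MLV" else "mixed"
  structure(cls, peaks = pk, contrast = contrast)
}

#' Full lamellar analysis of a SAXS curve
#'
#' Peak detection, order assignment, D-spacing, Scherrer lamellarity from
#' the first assigned order, and phase classification in one call.
#'
#' @inheritParams classify_phase
#' @param K,resolution Passed to [scherrer_lamellarity()].
#' @return Object of class `lamellar_fit`: `peaks`, `D`, `L`, `n_lamellae`,
#'   `phase_class`.
#' @export
lamellar_analysis <- function(curve, K = 0.9, resolution = 0, ...) {
  pk <- find_bragg_orders(curve, ...)
  assigned <- pk[!is.na(pk$order), , drop = FALSE]
  if (nrow(assigned)) {
    D <- d_spacing(assigned)
    sch <- scherrer_lamellarity(assigned[1, ], D, K, resolution)
    L <- sch$L; n <- sch$n_lamellae
  } else {
    D <- NA_real_; L <- NA_real_; n <- NA_integer_
  }
  structure(list(peaks = pk, D = D, L = L, n_lamellae = n,
                 phase_class = as.character(classify_phase(curve, ...))),
            class = "lamellar_fit")
}

#' @export
print.lamellar_fit <- function(x, ...) {
  cat(sprintf("Lamellar analysis: %s, %d assigned order(s)",
              x$phase_class, sum(!is.na(x$peaks$order))))
  if (is.finite(x$D))
    cat(sprintf(", D = %.1f A, L = %.0f A, n = %d", x$D, x$L, x$n_lamellae))
  cat("\n")
  invisible(x)
}

#' @rdname lamellar_analysis
#' @param x,object A `lamellar_fit`.
#' @param ... Unused.
#' @export
tidy.lamellar_fit <- function(x, ...) x$peaks

#' @rdname lamellar_analysis
#' @export
glance.lamellar_fit <- function(x, ...) {
  tibble(phase_class = x$phase_class, D = x$D, L = x$L,
         n_lamellae = x$n_lamellae, n_peaks = nrow(x$peaks))
}

#' @rdname lamellar_analysis
#' @param curve_data Optional curve to draw under the detected peaks.
#' @export
autoplot.lamellar_fit <- function(object, curve_data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(curve_data))
    p <- p + ggplot2::geom_line(
      data = curve_data, ggplot2::aes(.data$q, .data$intensity))
  p + ggplot2::geom_vline(
    data = object$peaks[!is.na(object$peaks$order), ],
    ggplot2::aes(xintercept = .data$q), linetype = 2, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/A)", y = "I(q)",
                  title = sprintf("%s, D = %.1f A", object$phase_class, object$D))
}
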