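#' Normalize a spectrum to unit area over a wavelength window
#'
#' Scales intensities so the trapezoidal integral over `window` equals 1.
#' The standard window for chlorophyll Q-band comparisons is 550-775 nm,
#' which makes spectra of complexes with equal pigment complements directly
#' comparable. Idempotent; the applied scale is recorded in metadata.
#'
#' @param spec A `spectrum` (nm axis).
#' @param window Numeric length-2, `c(lo, hi)` in nm; default `c(550, 775)`.
#' @return The normalized `spectrum`.
#' @export
normalize_area <- function(spec, window = c(550, 775)) {
  stopifnot(inherits(spec, "spectrum"), length(window) == 2, window[1] < window[2])
  if (window[1] < min(spec$axis) || window[2] > max(spec$axis)) {
    stop("normalization window outside spectrum axis range")
  }
  sel <- spec$axis >= window[1] & spec$axis <= window[2]
  # include exact window edges by interpolation so the integral is over [lo, hi]
  x <- spec$axis[sel]; y <- spec$intensity[sel]
  if (x[1] > window[1]) {
    x <- c(window[1], x)
    y <- c(stats::approx(spec$axis, spec$intensity, window[1])$y, y)
  }
  if (x[length(x)] < window[2]) {
    x <- c(x, window[2])
    y <- c(y, stats::approx(spec$axis, spec$intensity, window[2])$y)
  }
  area <- trapz(x, y)
  if (area <= 0) stop("nonpositive area over the normalization window")
  spec$intensity <- spec$intensity / area
  spec$metadata$normalization <- list(window = window, scale = 1 / area)
  spec
}

#' Difference of two area-normalized spectra
#'
#' `b` is linearly interpolated onto `a`'s axis and subtracted over the
#' overlapping axis range. Both inputs are expected to have been normalized
#' with [normalize_area()] under the same window (a warning is issued
#' otherwise).
#'
#' @param a,b `spectrum` objects with overlapping axes and equal units.
#' @return A `spectrum` holding `a - b` on the overlap.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!identical(a$unit, b$unit)) stop("spectra have different axis units")
  if (is.null(a$metadata$normalization) || is.null(b$metadata$normalization)) {
    warning("difference of spectra that were not area-normalized")
  }
  lo <- max(min(a$axis), min(b$axis))
  hi <- min(max(a$axis), max(b$axis))
  if (lo >= hi) stop("spectra have disjoint axis ranges")
  sel <- a$axis >= lo & a$axis <= hi
  bi <- stats::approx(b$axis, b$intensity, xout = a$axis[sel])$y
  new_spectrum(a$axis[sel], a$intensity[sel] - bi, unit = a$unit,
               metadata = list(operands = c(a = a$metadata$source,
                                            b = b$metadata$source)))
}

#' Peak positions, probe intensities and intensity ratios
#'
#' Locates the maximum and minimum within a region, refining each extremum
#' by a three-point parabola through the extreme sample and its neighbours;
#' evaluates intensities at probe positions by linear interpolation; and
#' forms ratios for requested probe pairs (e.g. the F722:F685 fluorescence
#' ratio used as a PSI:PSII excitation proxy).
#'
#' @param spec A `spectrum`.
#' @param region Length-2 axis interval to search; default the full axis.
#' @param probes Numeric axis positions to report intensities at.
#' @param ratio_pairs List of numeric pairs `c(num, den)`; each yields
#'   intensity(num) / intensity(den).
#' @return List with `argmax`, `max`, `argmin`, `min`, `probes` (named
#'   vector), `ratios` (named vector).
#' @export
spectral_features <- function(spec, region = range(spec$axis),
                              probes = numeric(), ratio_pairs = list()) {
  stopifnot(inherits(spec, "spectrum"))
  sel <- which(spec$axis >= region[1] & spec$axis <= region[2])
  if (length(sel) < 3) stop("region too narrow for feature extraction")
  x <- spec$axis[sel]; y <- spec$intensity[sel]
  refine <- function(i) {
    if (i == 1 || i == length(x)) return(c(x[i], y[i]))
    num <- (y[i - 1] - y[i + 1])
    den <- (y[i - 1] - 2 * y[i] + y[i + 1])
    if (abs(den) < .Machine$double.eps) return(c(x[i], y[i]))
    # uniform-spacing parabola vertex; for mildly non-uniform axes use local h
    h <- (x[i + 1] - x[i - 1]) / 2
    dx <- 0.5 * num / den * h
    c(x[i] + dx, y[i] - 0.25 * num * (0.5 * num / den))
  }
  mx <- refine(which.max(y))
  mn <- refine(which.min(y))
  pv <- if (length(probes)) {
    if (any(probes < min(spec$axis) | probes > max(spec$axis))) {
      stop("probe position outside the spectrum axis")
    }
    stats::setNames(stats::approx(spec$axis, spec$intensity, xout = probes)$y,
                    format(probes))
  } else numeric()
  rv <- vapply(ratio_pairs, function(p) {
    v <- stats::approx(spec$axis, spec$intensity, xout = p)$y
    v[1] / v[2]
  }, numeric(1))
  if (length(ratio_pairs)) {
    names(rv) <- vapply(ratio_pairs, function(p)
      paste0(format(p[1]), ":", format(p[2])), "")
  }
  list(argmax = mx[1], max = mx[2], argmin = mn[1], min = mn[2],
       probes = pv, ratios = rv)
}

gauss_eval <- function(x, center, fwhm, amplitude) {
  amplitude * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
}

gauss_mix_eval <- function(x, par) {
  k <- length(par) / 3
  ce <- par[seq_len(k)]
  fw <- par[k + seq_len(k)]
  am <- par[2 * k + seq_len(k)]
  y <- numeric(length(x))
  for (i in seq_len(k)) y <- y + gauss_eval(x, ce[i], fw[i], am[i])
  y
}

#' Fit a sum of Gaussian components to a spectral region
#'
#' Multistart bounded nonlinear least squares (Levenberg-Marquardt via
#' minpack.lm) of `n_components` Gaussians, fitted in the wavelength
#' domain. Starting centers are seeded at equally spaced positions across
#' the region under several phase offsets, plus one start anchored at the
#' observed extremum; starting FWHMs are 6 nm and starting amplitudes are
#' the local intensity. Bounds: centers inside the region, FWHM in
#' [1, 40] nm, amplitudes unconstrained (signed, so negative difference
#' features fit directly). The best-RMS converged start wins; if no start
#' converges the result is returned with `converged = FALSE` rather than
#' failing silently.
#'
#' @param spec A `spectrum` (nm axis).
#' @param region Length-2 nm interval to fit over.
#' @param n_components Number of Gaussians (>= 1).
#' @param n_starts Number of multistart phase offsets (default 16).
#' @return Object of class `gaussian_fit` with components sorted by center;
#'   supports `coef`, `fitted`, `residuals`, `summary`, `print`, `plot`.
#' @export
fit_gaussians <- function(spec, region, n_components, n_starts = 16) {
  stopifnot(inherits(spec, "spectrum"), n_components >= 1)
  sel <- spec$axis >= region[1] & spec$axis <= region[2]
  x <- spec$axis[sel]; y <- spec$intensity[sel]
  if (length(x) < 3 * n_components) {
    stop("need at least 3 data points per component in the fit region")
  }
  k <- n_components
  lower <- c(rep(region[1], k), rep(1, k), rep(-Inf, k))
  upper <- c(rep(region[2], k), rep(40, k), rep(Inf, k))
  resid_fun <- function(par) y - gauss_mix_eval(x, par)
  # deterministic multistart: phase-shifted equispaced centers + one start
  # anchored at the strongest observed feature
  starts <- list()
  for (s in seq_len(n_starts)) {
    frac <- (seq_len(k) - 0.5 + (s - 1) / n_starts) / k
    frac <- frac %% 1
    ce <- region[1] + frac * (region[2] - region[1])
    am <- stats::approx(x, y, xout = ce, rule = 2)$y
    starts[[s]] <- c(ce, rep(6, k), am)
  }
  i_ext <- which.max(abs(y))
  ce <- sort(c(x[i_ext], region[1] + (seq_len(k - 1) / k) * diff(region)))
  am <- stats::approx(x, y, xout = ce, rule = 2)$y
  starts[[n_starts + 1]] <- c(ce, rep(6, k), am)

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(p0, lower), upper), fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rms <- sqrt(mean(fit$fvec^2))
    conv <- fit$info %in% 1:3
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && rms < best$rms)) {
      best <- list(fit = fit, rms = rms, conv = conv)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  par <- best$fit$par
  ord <- order(par[seq_len(k)])
  comp <- data.frame(center = par[seq_len(k)][ord],
                     fwhm = par[k + seq_len(k)][ord],
                     amplitude = par[2 * k + seq_len(k)][ord])
  at_bound <- any(abs(comp$fwhm - 1) < 1e-6 | abs(comp$fwhm - 40) < 1e-6)
  fitted_y <- gauss_mix_eval(x, par)
  structure(list(components = comp, x = x, y = y, fitted = fitted_y,
                 residual = y - fitted_y,
                 rms_residual = best$rms, converged = best$conv,
                 width_at_bound = at_bound, region = region,
                 n_starts = length(starts)),
            class = "gaussian_fit")
}

#' @export
coef.gaussian_fit <- function(object, ...) object$components

#' @export
fitted.gaussian_fit <- function(object, ...) object$fitted

#' @export
residuals.gaussian_fit <- function(object, ...) object$residual

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d component(s) over [%.1f, %.1f]; rms %.3g; %s\n",
              nrow(x$components), x$region[1], x$region[2], x$rms_residual,
              if (x$converged) "converged" else "NOT converged"))
  print(transform(x$components,
                  center = round(center, 2), fwhm = round(fwhm, 2),
                  amplitude = signif(amplitude, 4)))
  if (x$width_at_bound) cat("note: a component width sits at its bound\n")
  invisible(x)
}

#' @export
summary.gaussian_fit <- function(object, ...) {
  print(object)
  cat(sprintf("residual range: [%.3g, %.3g] over %d points\n",
              min(object$residual), max(object$residual), length(object$x)))
  invisible(object)
}

#' @export
plot.gaussian_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", lty = 2, xlab = "wavelength (nm)",
                 ylab = "intensity", ...)
  graphics::lines(x$x, x$fitted, lwd = 2)
  for (i in seq_len(nrow(x$components))) {
    graphics::lines(x$x, gauss_eval(x$x, x$components$center[i],
                                    x$components$fwhm[i],
                                    x$components$amplitude[i]), col = i + 1)
  }
  invisible(x)
}

#' Write fitted Gaussian components as CSV
#'
#' @param fit A `gaussian_fit`.
#' @param path Output path; columns `center_nm,fwhm_nm,amplitude`.
#' @export
write_fit_csv <- function(fit, path) {
  comp <- fit$components
  names(comp) <- c("center_nm", "fwhm_nm", "amplitude")
  utils::write.csv(comp, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
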