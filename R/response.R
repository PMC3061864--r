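#' Instrument response function with polynomial chirp
#'
#' Gaussian IRF described by its centre `t0` and full width at half
#' maximum `fwhm` (sigma = fwhm / (2 sqrt(2 log 2))), plus a polynomial
#' model of the wavelength dependence of time zero (chirp): the IRF
#' centre at wavelength `lambda` is
#' `mu(lambda) = t0 + sum_j coeff_j * (lambda - lambda_c)^j`,
#' with the wavelength offset taken in the data's native channel units
#' (unnormalised) and `lambda_c` the central wavelength of the probed
#' window. Order 0 (no coefficients) means `mu(lambda) = t0` everywhere,
#' appropriate when the chirp is not resolved.
#'
#' @param t0 IRF centre time (time units).
#' @param fwhm full width at half maximum (> 0, time units).
#' @param chirp_coeffs numeric vector of polynomial coefficients for
#'   powers 1..order of the wavelength offset; may be empty (order 0).
#' @param lambda_c central wavelength of the probed window.
#' @return An object of class `irf_model`.
#' @examples
#' irf_model(t0 = 0, fwhm = 0.1)
#' irf_model(0, 0.1, chirp_coeffs = c(0.02, 1e-4), lambda_c = 500)
#' @export
irf_model <- function(t0, fwhm, chirp_coeffs = numeric(0), lambda_c = 0) {
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be > 0", call. = FALSE)
  chirp_coeffs <- as.numeric(chirp_coeffs)
  if (any(!is.finite(chirp_coeffs)))
    stop("chirp coefficients must be finite", call. = FALSE)
  structure(list(t0 = as.numeric(t0), fwhm = as.numeric(fwhm),
                 chirp_coeffs = chirp_coeffs,
                 order = length(chirp_coeffs),
                 lambda_c = as.numeric(lambda_c)),
            class = "irf_model")
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("<irf_model> t0 = %g, fwhm = %g, chirp order %d\n",
              x$t0, x$fwhm, x$order))
  if (x$order > 0)
    cat("  coeffs:", paste(signif(x$chirp_coeffs, 6), collapse = ", "),
        " (lambda_c =", x$lambda_c, ")\n")
  invisible(x)
}

#' IRF centre (time zero) at a given wavelength
#'
#' Evaluates the chirp polynomial of an [irf_model()].
#'
#' @param lambda wavelength(s) in the channel-axis units.
#' @param irf an [irf_model()].
#' @return numeric vector of IRF centre times.
#' @export
chirp_location <- function(lambda, irf) {
  mu <- rep(irf$t0, length(lambda))
  off <- lambda - irf$lambda_c
  for (j in seq_len(irf$order))
    mu <- mu + irf$chirp_coeffs[j] * off^j
  mu
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# scaled complementary error function exp(x^2) erfc(x) for x >= 0,
# through the log-scale normal tail so that neither factor overflows
.erfcx <- function(x) exp(x^2 + log(2) + stats::pnorm(-x * sqrt(2), log.p = TRUE))

#' Exponential decay convolved with a Gaussian IRF
#'
#' Analytic convolution of `exp(-k (t - mu))` (zero before `mu`) with a
#' unit-area Gaussian of width `fwhm` centred at `mu = mu(lambda)`:
#' `c(t) = exp(-k(t-mu) + (k sigma)^2 / 2) * Phi((t-mu)/sigma - k sigma)`.
#' Evaluated in an erfcx-scaled form so that large `k * sigma` neither
#' overflows the exponential prefactor nor underflows the normal CDF.
#' For `k = 0` this is the Gaussian cumulative step (0.5 at `t = mu`).
#'
#' @param t time point(s).
#' @param k relaxation rate (1/time, >= 0).
#' @param irf an [irf_model()].
#' @param lambda wavelength at which to evaluate the (chirped) IRF
#'   centre; default `irf$lambda_c`.
#' @return signal amplitude(s), in `[0, exp(k^2 sigma^2 / 2)]`-free
#'   stable form (never negative).
#' @examples
#' irf <- irf_model(0, 0.3)
#' exp_conv_irf(c(-0.5, 0, 0.5, 2), k = 1, irf = irf)
#' @export
exp_conv_irf <- function(t, k, irf, lambda = irf$lambda_c) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  sigma <- .fwhm_to_sigma(irf$fwhm)
  mu <- chirp_location(lambda, irf)
  u <- (t - mu) / sigma
  a <- k * sigma
  out <- numeric(length(u))
  z <- (a - u) / sqrt(2)
  pos <- z >= 0
  # rising edge / strongly damped branch: 0.5 exp(-u^2/2) erfcx(z)
  out[pos] <- 0.5 * exp(-u[pos]^2 / 2) * .erfcx(z[pos])
  # decay branch: exponent -a*u + a^2/2 < 0 here, direct form is safe
  out[!pos] <- exp(-a * u[!pos] + a^2 / 2) *
    stats::pnorm(u[!pos] - a)
  out
}

#' Estimate the chirp polynomial from a data matrix
#'
#' Per-channel onset delays are measured as the time of maximum absolute
#' gradient of the cross-correlation between the channel signal and a
#' discrete unit step on the data's time grid (ties broken by earliest
#' time), refined by three-point parabolic interpolation; the dispersion
#' polynomial is then least-squares fitted to those delays. With
#' `order = 0` the single global `t0` is the median onset.
#'
#' Channels with no signal are excluded with a warning; if fewer than
#' `order + 1` usable channels remain, estimation fails.
#'
#' @param data a [data_matrix()].
#' @param order polynomial order (>= 0).
#' @param lambda_c central wavelength; default midpoint of the channel
#'   axis.
#' @param fwhm IRF width carried into the returned model (not estimated
#'   from the onsets); default one median time step.
#' @return an [irf_model()] with an `onsets` attribute: data frame of
#'   `lambda` and the measured per-channel delay `mu`, exportable as a
#'   delimited table.
#' @export
estimate_chirp <- function(data, order, lambda_c = NULL, fwhm = NULL) {
  stopifnot(inherits(data, "data_matrix"))
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  tt <- data$times
  nt <- length(tt)
  if (nt < 5L) stop("need at least 5 time points", call. = FALSE)
  if (is.null(lambda_c))
    lambda_c <- (min(data$channels) + max(data$channels)) / 2
  usable <- logical(ncol(data$values))
  delays <- rep(NA_real_, ncol(data$values))
  floor_amp <- 1e-12 * max(abs(data$values), 0)
  for (j in seq_along(delays)) {
    s <- data$values[, j]
    if (all(!is.finite(s)) || max(abs(s), na.rm = TRUE) <= floor_amp) next
    s[!is.finite(s)] <- 0
    # cross-correlation with a unit step at lag tt[i]: sum of s past the lag
    cc <- rev(cumsum(rev(s)))
    g <- numeric(nt)
    g[2:(nt - 1)] <- (cc[3:nt] - cc[1:(nt - 2)]) / (tt[3:nt] - tt[1:(nt - 2)])
    ag <- abs(g[2:(nt - 1)])
    i <- which(ag == max(ag))[1] + 1L          # earliest tie
    # parabolic refinement through (t, |g|) at i-1, i, i+1
    t3 <- tt[(i - 1):(i + 1)]
    y3 <- abs(g[(i - 1):(i + 1)])
    den <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    aa <- (t3[3] * (y3[2] - y3[1]) + t3[2] * (y3[1] - y3[3]) +
             t3[1] * (y3[3] - y3[2])) / den
    bb <- (t3[3]^2 * (y3[1] - y3[2]) + t3[2]^2 * (y3[3] - y3[1]) +
             t3[1]^2 * (y3[2] - y3[3])) / den
    tv <- if (is.finite(aa) && aa < 0) -bb / (2 * aa) else tt[i]
    if (!is.finite(tv) || tv < t3[1] || tv > t3[3]) tv <- tt[i]
    delays[j] <- tv
    usable[j] <- TRUE
  }
  if (any(!usable))
    warning(sum(!usable), " channel(s) without signal excluded from chirp",
            " estimation", call. = FALSE)
  if (sum(usable) < order + 1)
    stop("fewer usable channels (", sum(usable), ") than order + 1",
         call. = FALSE)
  lam <- data$channels[usable]
  del <- delays[usable]
  if (is.null(fwhm)) fwhm <- stats::median(diff(tt))
  if (order == 0L) {
    irf <- irf_model(stats::median(del), fwhm, lambda_c = lambda_c)
  } else {
    X <- outer(lam - lambda_c, seq_len(order), `^`)
    fit <- stats::lsfit(X, del)
    irf <- irf_model(fit$coefficients[1], fwhm,
                     chirp_coeffs = unname(fit$coefficients[-1]),
                     lambda_c = lambda_c)
  }
  attr(irf, "onsets") <- data.frame(lambda = lam, mu = del)
  irf
}
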