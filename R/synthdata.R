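# Synthetic benchmark experiments. The canonical benchmark mimics a
# transient-absorption measurement of a three-state sequential
# photoreaction: lifetimes 1.87 s and 34.8 s feeding a long-lived final
# state, probed on 91 logarithmically spaced delays over 300 s.

#' Specification of the sequential three-species benchmark
#'
#' @param lifetimes component lifetimes in seconds; `Inf` marks the
#'   terminal long-lived species. Defaults to `c(1.87, 34.8, Inf)`.
#' @param n_times number of logarithmically spaced delay points
#'   (default 91) between `t_min` and `t_max`.
#' @param t_min,t_max delay range in seconds (0.01 .. 300 by default).
#' @param n_channels number of detection channels (pixels).
#' @param spectra species x channel matrix of basis spectra; the default
#'   builds three partially overlapping sums of one or two Gaussian line
#'   shapes (see [benchmark_spectra()]).
#' @param noise_fraction white-noise amplitude as a fraction of the
#'   maximum of each basis spectrum / concentration profile (0 or 0.10
#'   in the canonical variants).
#' @param seed integer RNG seed; the generated matrix is deterministic
#'   for a fixed spec + seed.
#' @return object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(lifetimes = c(1.87, 34.8, Inf), n_times = 91,
                           t_min = 0.01, t_max = 300, n_channels = 100,
                           spectra = NULL, noise_fraction = 0, seed = 1L) {
  if (any(lifetimes <= 0)) stop("lifetimes must be positive (or Inf)",
                                call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must lie in [0, 1)", call. = FALSE)
  if (is.null(spectra))
    spectra <- benchmark_spectra(n_channels, length(lifetimes))
  if (nrow(spectra) != length(lifetimes) || ncol(spectra) != n_channels)
    stop("spectra must be length(lifetimes) x n_channels", call. = FALSE)
  structure(list(lifetimes = lifetimes, n_times = n_times,
                 t_min = t_min, t_max = t_max, n_channels = n_channels,
                 spectra = spectra, noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Default benchmark basis spectra
#'
#' Sums of one or two Gaussian line shapes per species, partially
#' overlapping around the middle of the channel axis (so that an
#' inadequate parallel model exhibits compensating amplitudes there).
#'
#' @param n_channels number of channels.
#' @param n_species number of species (up to 4 shapes defined).
#' @return `n_species` x `n_channels` matrix.
#' @export
benchmark_spectra <- function(n_channels = 100, n_species = 3) {
  ch <- seq_len(n_channels)
  g <- function(c0, w, a) a * exp(-((ch / n_channels * 100) - c0)^2 / (2 * w^2))
  shapes <- list(g(30, 8, 1),
                 g(50, 10, 0.9) + g(75, 6, 0.35),
                 g(60, 9, 0.8),
                 g(40, 7, 0.5) + g(85, 5, 0.2))
  do.call(rbind, shapes[seq_len(n_species)])
}

.benchmark_times <- function(spec)
  10^seq(log10(spec$t_min), log10(spec$t_max), length.out = spec$n_times)

#' Generate the sequential benchmark data matrix
#'
#' Solves the sequential scheme defined by the spec's lifetimes on the
#' logarithmic delay grid (matrix-exponential path, so the noiseless
#' matrix is of numerically exact rank `n_species`) and multiplies by
#' the basis spectra. With `noise_fraction > 0`, Gaussian white noise
#' scaled to that fraction of the maximum of each basis spectrum is
#' added to that component's spectrum (fresh at every time point, as a
#' detector would see it), and noise scaled to the same fraction of each
#' concentration profile's maximum is added to the profile, before the
#' per-component contributions are summed. The noisy matrix therefore
#' carries a genuine full-rank noise floor on top of the rank-3 signal.
#'
#' @param spec a [benchmark_spec()].
#' @return a [data_matrix()]; attribute `truth` carries the generating
#'   scheme, concentration profiles and clean spectra.
#' @examples
#' bench <- make_benchmark(benchmark_spec())
#' dim(bench)
#' @export
make_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  rates <- ifelse(is.infinite(spec$lifetimes), 0, 1 / spec$lifetimes)
  scheme <- build_sequential_scheme(rates)
  times <- .benchmark_times(spec)
  conc <- solve_concentrations(scheme, times, tolerance = 1e-12)
  C <- conc$values
  S <- spec$spectra
  if (spec$noise_fraction == 0) {
    vals <- C %*% S
  } else {
    set.seed(spec$seed)
    nt <- nrow(C); nch <- ncol(S)
    C <- C + spec$noise_fraction *
      rep(apply(conc$values, 2, max), each = nt) *
      matrix(stats::rnorm(length(C)), nt, ncol(C))
    vals <- C %*% S
    for (i in seq_len(nrow(S))) {
      eta <- spec$noise_fraction * max(S[i, ]) *
        matrix(stats::rnorm(nt * nch), nt, nch)
      vals <- vals + C[, i] * eta
    }
  }
  out <- data_matrix(times, seq_len(spec$n_channels), vals,
                     metadata = list(content = "sequential benchmark",
                                     noise = spec$noise_fraction,
                                     seed = spec$seed))
  attr(out, "truth") <- list(scheme = scheme, concentrations = conc,
                             spectra = spec$spectra,
                             lifetimes = spec$lifetimes)
  out
}

#' Generate a chirped, IRF-convolved dataset
#'
#' Builds per-channel signals of a kinetic scheme convolved with a
#' (possibly chirped) Gaussian IRF, for exercising chirp estimation and
#' IRF-aware fitting end to end. The default kinetics is an IRF-limited
#' fast response (lifetime well below the IRF width), the configuration
#' used in practice to calibrate the chirp from the coherent artifact.
#'
#' @param scheme a [kinetic_scheme()]; default single species with a
#'   20 fs lifetime (time units are whatever the IRF/times use; the
#'   defaults are picoseconds).
#' @param irf an [irf_model()]; default 0.1 ps FWHM with a 20 fs/nm
#'   linear chirp centred at 500 nm.
#' @param times delay grid (ps); default 0.1 ps steps from -1 to 5 ps.
#' @param channels wavelength axis (nm); default 26 channels over
#'   450..550 nm.
#' @param spectra species x channel amplitude matrix; default flat unit
#'   amplitude.
#' @param noise Gaussian noise standard deviation relative to the signal
#'   maximum (default 0).
#' @param seed RNG seed used when `noise > 0`.
#' @return a [data_matrix()]; attribute `truth` holds the generating IRF
#'   and the per-channel centre `mu(lambda)`.
#' @export
make_chirped_irf_dataset <- function(scheme = build_parallel_scheme(1 / 0.02),
                                     irf = irf_model(0, 0.1,
                                                     chirp_coeffs = 0.02,
                                                     lambda_c = 500),
                                     times = seq(-1, 5, by = 0.1),
                                     channels = seq(450, 550, length.out = 26),
                                     spectra = NULL, noise = 0, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(irf, "irf_model"))
  if (is.null(spectra))
    spectra <- matrix(1, length(scheme$species), length(channels))
  design <- .model_design(scheme, times, irf, channels, 1e-10)
  if (!is.list(design)) design <- rep(list(design), length(channels))
  vals <- vapply(seq_along(channels),
                 function(j) as.vector(design[[j]] %*% spectra[, j]),
                 numeric(length(times)))
  if (noise > 0) {
    set.seed(seed)
    vals <- vals + noise * max(abs(vals)) *
      matrix(stats::rnorm(length(vals)), nrow(vals), ncol(vals))
  }
  out <- data_matrix(times, channels, vals,
                     metadata = list(content = "chirped IRF dataset"))
  attr(out, "truth") <- list(irf = irf,
                             mu = chirp_location(channels, irf))
  out
}

#' Generate a consistent pump-probe / dump-probe / pump-dump-probe set
#'
#' Constructs three synthetic experiments with planted ensemble
#' fractions so that [pure_intermediate_signal()] inverts them exactly:
#' `S_pdp = S_pp + g S_dp + phi S_int` with `g` the ensemble ground
#' fraction available to the dump and `phi` the doubly-interacting
#' fraction, both computed from the schedule by the single- and
#' multi-pulse ensemble expressions.
#'
#' @param scheme kinetic scheme of the planted intermediate; default a
#'   two-species sequential decay with a 5 s intermediate lifetime.
#' @param schedule a [multipulse_schedule()].
#' @param times delay grid; default 61 log-spaced points over
#'   0.01..300 s.
#' @param n_channels number of channels (default 40).
#' @param seed RNG seed for the random-but-reproducible basis spectra.
#' @return list with `S_pp`, `S_dp`, `S_pdp` ([data_matrix()] objects),
#'   `fractions` (as consumed by [pure_intermediate_signal()]) and
#'   `truth` (the planted `S_int` and its scheme).
#' @export
make_multipulse_experiment <- function(scheme = build_sequential_scheme(
                                         c(1 / 5, 0)),
                                       schedule,
                                       times = 10^seq(-2, log10(300),
                                                      length.out = 61),
                                       n_channels = 40, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(schedule, "multipulse_schedule"))
  set.seed(seed)
  ch <- seq_len(n_channels)
  gshape <- function() {
    c0 <- stats::runif(1, 0.2, 0.8) * n_channels
    w <- stats::runif(1, 0.05, 0.15) * n_channels
    stats::runif(1, 0.5, 1) * exp(-(ch - c0)^2 / (2 * w^2))
  }
  f1 <- ensemble_fraction(schedule$x1)
  g <- 1 - (1 - schedule$recovery) * f1
  phi <- (1 - schedule$recovery) * f1 * ensemble_fraction(schedule$x2)
  conc_int <- solve_concentrations(scheme, times, 1e-10)$values
  # the intermediate signal follows the scheme's first species kinetics
  S_int_vals <- conc_int %*% rbind(gshape(), matrix(0,
    length(scheme$species) - 1, n_channels))
  pp_scheme <- build_sequential_scheme(c(1 / 2, 1 / 40, 0))
  C_pp <- solve_concentrations(pp_scheme, times, 1e-10)$values
  S_pp_vals <- C_pp %*% rbind(gshape(), gshape(), gshape())
  dp_scheme <- build_parallel_scheme(c(1 / 10, 0))
  C_dp <- solve_concentrations(dp_scheme, times, 1e-10)$values
  S_dp_vals <- C_dp %*% rbind(gshape(), gshape())
  S_pp <- data_matrix(times, ch, S_pp_vals)
  S_dp <- data_matrix(times, ch, S_dp_vals)
  S_int <- data_matrix(times, ch, S_int_vals)
  S_pdp <- data_matrix(times, ch,
                       S_pp_vals + g * S_dp_vals + phi * S_int_vals)
  list(S_pp = S_pp, S_dp = S_dp, S_pdp = S_pdp,
       fractions = list(ground_available = g, double_interaction = phi),
       truth = list(S_int = S_int, scheme = scheme))
}
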