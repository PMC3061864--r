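# Global (variable-projection) fitting: nonlinear rate/IRF parameters are
# shared across all channels and optimised iteratively; at every step the
# per-channel spectra and baseline offsets are eliminated exactly by
# linear least squares on the concentration design.

#' Linear projection of spectra and offsets
#'
#' Least-squares solution of `data ~ concentrations %*% spectra (+ offset
#' row)` through orthogonal-triangular (QR) factorisation. The solution
#' is unique when the concentration design has full column rank; a
#' rank-deficient design (e.g. duplicated rates) triggers a warning and
#' the minimum-norm solution via the pseudoinverse, flagged in the
#' result.
#'
#' @param concentrations a `concentration_matrix` or plain time x species
#'   matrix.
#' @param data a [data_matrix()] or plain time x channel matrix on the
#'   same time axis.
#' @param offset_enabled add a constant baseline column (per-channel
#'   offset)?
#' @return list with `spectra` (species x channels), `offsets`
#'   (per-channel baseline or `NULL`), `residual_matrix`,
#'   `sum_of_squares` and `rank_deficient`.
#' @export
project_linear <- function(concentrations, data, offset_enabled = TRUE) {
  C <- if (inherits(concentrations, "concentration_matrix")) {
    if (inherits(data, "data_matrix") &&
        !isTRUE(all.equal(concentrations$times, data$times)))
      stop("time axes of concentrations and data differ", call. = FALSE)
    concentrations$values
  } else as.matrix(concentrations)
  D <- if (inherits(data, "data_matrix")) data$values else as.matrix(data)
  if (nrow(C) != nrow(D))
    stop("time axes of concentrations and data differ", call. = FALSE)
  X <- if (offset_enabled) cbind(C, offset = 1) else C
  dec <- qr(X)
  rank_deficient <- dec$rank < ncol(X)
  if (rank_deficient) {
    warning("rank-deficient concentration design; returning the ",
            "minimum-norm solution", call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% D) / sv$d[pos])
  } else {
    coef <- qr.coef(dec, D)
  }
  fittedD <- X %*% coef
  resid <- D - fittedD
  ns <- ncol(C)
  list(spectra = coef[seq_len(ns), , drop = FALSE],
       offsets = if (offset_enabled) coef[ns + 1, ] else NULL,
       residual_matrix = resid,
       sum_of_squares = sum(resid^2),
       rank_deficient = rank_deficient)
}

#' Define a global-fit problem
#'
#' Bundles the data, the kinetic scheme (whose positive rate constants
#' are the free nonlinear parameters; exact zeros are fixed long-lived
#' components), an optional IRF/chirp model, the optimisation engine and
#' the fit target.
#'
#' @param data a [data_matrix()].
#' @param scheme a [kinetic_scheme()]; its rate values are the starting
#'   guesses.
#' @param irf optional [irf_model()]; `irf_free` names the IRF
#'   parameters fitted alongside the rates (`"t0"`, `"fwhm"`, and/or
#'   `"chirp"`).
#' @param irf_free character vector, subset of
#'   `c("t0", "fwhm", "chirp")`.
#' @param engine `"gradient"` (Levenberg-Marquardt least squares) or
#'   `"pattern-search"` (derivative-free compass search).
#' @param fit_target `"full-data"`, `"svd-traces"` or
#'   `"weighted-svd-traces"`; the SVD variants require `n_keep`.
#' @param n_keep number of left singular vectors for the SVD targets.
#' @param offset_enabled fit a per-channel baseline offset (default
#'   `TRUE`).
#' @param lower,upper bounds on the rate constants (1/time); a fitted
#'   rate resting at `lower` is reported as long-lived.
#' @param tolerance ODE/matrix-exponential solver tolerance.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(data, scheme, irf = NULL, irf_free = character(0),
                        engine = c("gradient", "pattern-search"),
                        fit_target = c("full-data", "svd-traces",
                                       "weighted-svd-traces"),
                        n_keep = NULL, offset_enabled = TRUE,
                        lower = 1e-12, upper = 1e6, tolerance = 1e-8) {
  stopifnot(inherits(data, "data_matrix"), inherits(scheme, "kinetic_scheme"))
  engine <- match.arg(engine)
  fit_target <- match.arg(fit_target)
  if (fit_target != "full-data" && is.null(n_keep))
    stop("SVD fit targets require n_keep", call. = FALSE)
  if (!is.null(irf)) stopifnot(inherits(irf, "irf_model"))
  bad <- setdiff(irf_free, c("t0", "fwhm", "chirp"))
  if (length(bad))
    stop("unknown irf_free entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  free_k <- scheme$reactions$k[scheme$reactions$k > 0]
  if (any(free_k < lower | free_k > upper))
    stop("starting rates must lie within [lower, upper]", call. = FALSE)
  if (offset_enabled && any(diag(rate_matrix(scheme)) == 0))
    warning("the scheme contains a non-decaying species; together with a ",
            "free baseline offset the linear design is rank-deficient and ",
            "the spectra are not identifiable (rates are unaffected). ",
            "Consider offset_enabled = FALSE.", call. = FALSE)
  structure(list(data = data, scheme = scheme, irf = irf,
                 irf_free = irf_free, engine = engine,
                 fit_target = fit_target, n_keep = n_keep,
                 offset_enabled = offset_enabled,
                 lower = lower, upper = upper, tolerance = tolerance),
            class = "fit_problem")
}

# ---- internal parameter packing -----------------------------------------

# free nonlinear parameters: log of the positive rates, then IRF params
.pack_theta <- function(problem) {
  free <- which(problem$scheme$reactions$k > 0)
  theta <- log(problem$scheme$reactions$k[free])
  names(theta) <- paste0("log_k", free)
  lo <- rep(log(problem$lower), length(theta))
  hi <- rep(log(problem$upper), length(theta))
  if (!is.null(problem$irf)) {
    if ("t0" %in% problem$irf_free) {
      theta <- c(theta, t0 = problem$irf$t0)
      span <- diff(range(problem$data$times))
      lo <- c(lo, problem$irf$t0 - span); hi <- c(hi, problem$irf$t0 + span)
    }
    if ("fwhm" %in% problem$irf_free) {
      theta <- c(theta, log_fwhm = log(problem$irf$fwhm))
      lo <- c(lo, log(problem$irf$fwhm) - 6); hi <- c(hi, log(problem$irf$fwhm) + 6)
    }
    if ("chirp" %in% problem$irf_free && problem$irf$order > 0) {
      cc <- problem$irf$chirp_coeffs
      theta <- c(theta, stats::setNames(cc, paste0("chirp", seq_along(cc))))
      sc <- pmax(abs(cc), 1e-3)
      lo <- c(lo, cc - 100 * sc); hi <- c(hi, cc + 100 * sc)
    }
  }
  list(theta = theta, lower = lo, upper = hi, free_rates = free)
}

.unpack_theta <- function(theta, problem, packing) {
  scheme <- problem$scheme
  nk <- length(packing$free_rates)
  scheme$reactions$k[packing$free_rates] <- exp(theta[seq_len(nk)])
  irf <- problem$irf
  i <- nk
  if (!is.null(irf)) {
    if ("t0" %in% problem$irf_free) { i <- i + 1; irf$t0 <- unname(theta[i]) }
    if ("fwhm" %in% problem$irf_free) { i <- i + 1; irf$fwhm <- unname(exp(theta[i])) }
    if ("chirp" %in% problem$irf_free && irf$order > 0) {
      irf$chirp_coeffs <- unname(theta[i + seq_len(irf$order)])
      i <- i + irf$order
    }
  }
  list(scheme = scheme, irf = irf)
}

# concentration design for given scheme/irf; without chirp a single
# matrix, with chirp one matrix per channel (list). The IRF path uses the
# eigenmode form of the matrix exponential: each mode exp(lambda_j t) is
# replaced by its analytic Gaussian convolution.
.model_design <- function(scheme, times, irf, channels, tolerance) {
  if (is.null(irf)) {
    return(solve_concentrations(scheme, times, tolerance)$values)
  }
  K <- rate_matrix(scheme)
  eg <- eigen(K)
  ev <- eg$values; V <- eg$vectors
  if (is.complex(ev)) { ev <- Re(ev); V <- Re(V) }
  w <- tryCatch(solve(V, scheme$c0), error = function(e) NULL)
  if (is.null(w))
    stop("IRF convolution requires a diagonalisable scheme ",
         "(well-separated rates)", call. = FALSE)
  A <- V %*% diag(w, length(w))           # species x modes mixing
  per_lambda <- function(lam) {
    E <- vapply(ev, function(l)
      exp_conv_irf(times, k = max(-l, 0), irf = irf, lambda = lam),
      numeric(length(times)))
    E %*% t(A)
  }
  if (irf$order == 0L) per_lambda(irf$lambda_c)
  else lapply(channels, per_lambda)
}

# residual matrix for the current nonlinear parameters
.residual_matrix <- function(theta, problem, packing) {
  up <- .unpack_theta(theta, problem, packing)
  D <- problem$data$values
  design <- .model_design(up$scheme, problem$data$times, up$irf,
                          problem$data$channels, problem$tolerance)
  if (!is.list(design)) {
    pr <- suppressWarnings(
      project_linear(design, D, problem$offset_enabled))
    pr$residual_matrix
  } else {
    res <- matrix(0, nrow(D), ncol(D))
    for (j in seq_len(ncol(D))) {
      pr <- suppressWarnings(
        project_linear(design[[j]], D[, j, drop = FALSE],
                       problem$offset_enabled))
      res[, j] <- pr$residual_matrix
    }
    res
  }
}

# derivative-free compass/pattern search on the objective fn (sum of
# squares). Mesh policy: start at 25% of each parameter's bounded range,
# expand by 2 on success, contract by 0.5 on failure, stop when the mesh
# drops below mesh_tol in every coordinate.
.pattern_search <- function(fn, theta, lower, upper, expand = 2,
                            contract = 0.5, mesh_tol = 1e-6,
                            max_iter = 5000) {
  rng <- pmin(upper, theta + 6) - pmax(lower, theta - 6)
  mesh <- 0.25 * rng
  f0 <- fn(theta)
  iter <- 0L
  while (max(mesh) >= mesh_tol && iter < max_iter) {
    iter <- iter + 1L
    improved <- FALSE
    for (i in seq_along(theta)) {
      for (s in c(1, -1)) {
        cand <- theta
        cand[i] <- min(upper[i], max(lower[i], cand[i] + s * mesh[i]))
        fc <- fn(cand)
        if (fc < f0) {
          theta <- cand; f0 <- fc; improved <- TRUE
          break
        }
      }
    }
    mesh <- if (improved) mesh * expand else mesh * contract
    mesh <- pmin(mesh, rng)
  }
  list(par = theta, value = f0, iterations = iter,
       converged = max(mesh) < mesh_tol)
}

# numeric Jacobian of the residual vector at the optimum (central diff.)
.resid_jacobian <- function(theta, problem, packing, h = 1e-6) {
  r0 <- as.vector(.residual_matrix(theta, problem, packing))
  J <- matrix(0, length(r0), length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    J[, i] <- (as.vector(.residual_matrix(tp, problem, packing)) -
               as.vector(.residual_matrix(tm, problem, packing))) / (2 * h)
  }
  J
}

#' Global fit of a kinetic model to a data matrix
#'
#' Optimises the shared nonlinear parameters (log rate constants, plus
#' any free IRF/chirp parameters) with the selected engine, eliminating
#' the per-channel spectra and offsets by [project_linear()] at every
#' function evaluation (variable projection). Standard errors come from
#' the linearised covariance `(J'J)^-1 * SS / dof` at the optimum.
#'
#' @param problem a [fit_problem()].
#' @return object of class `fit_result`: fitted `rates` (with
#'   `rate_se`), `lifetimes` (sorted ascending, `Inf` for long-lived
#'   components with their flag in `long_lived`), `spectra` (species x
#'   channels), `offsets`, `residual_matrix`, `sum_of_squares`,
#'   `rank_deficient` and `engine_report`.
#' @examples
#' bench <- make_benchmark(benchmark_spec(n_channels = 20))
#' sch <- build_sequential_scheme(c(1, 1 / 20, 0))
#' fit <- fit_global(fit_problem(bench, sch))
#' fit$lifetimes
#' @export
fit_global <- function(problem) {
  stopifnot(inherits(problem, "fit_problem"))
  if (any(!is.finite(problem$data$values)))
    stop("data contains non-finite values", call. = FALSE)
  packing <- .pack_theta(problem)
  theta0 <- packing$theta
  if (length(theta0) == 0L)
    stop("no free nonlinear parameters to fit", call. = FALSE)

  if (problem$engine == "gradient") {
    ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                       maxiter = 500)
    fit <- minpack.lm::nls.lm(
      par = theta0,
      lower = packing$lower, upper = packing$upper,
      fn = function(th) as.vector(.residual_matrix(th, problem, packing)),
      control = ctrl)
    theta <- fit$par
    report <- list(engine = "gradient", iterations = fit$niter,
                   converged = fit$info %in% 1:4,
                   message = fit$message)
    JtJ <- fit$hessian
  } else {
    ps <- .pattern_search(
      function(th) sum(.residual_matrix(th, problem, packing)^2),
      theta0, packing$lower, packing$upper)
    theta <- ps$par
    report <- list(engine = "pattern-search", iterations = ps$iterations,
                   converged = ps$converged, message = "mesh below tolerance")
    J <- .resid_jacobian(theta, problem, packing)
    JtJ <- crossprod(J)
  }

  up <- .unpack_theta(theta, problem, packing)
  design <- .model_design(up$scheme, problem$data$times, up$irf,
                          problem$data$channels, problem$tolerance)
  if (!is.list(design)) {
    pr <- suppressWarnings(
      project_linear(design, problem$data$values, problem$offset_enabled))
    spectra <- pr$spectra
    offsets <- pr$offsets
    resid <- pr$residual_matrix
    rankdef <- pr$rank_deficient
  } else {
    nch <- length(design)
    ns <- ncol(design[[1]])
    spectra <- matrix(0, ns, nch)
    offsets <- if (problem$offset_enabled) numeric(nch) else NULL
    resid <- matrix(0, nrow(problem$data$values), nch)
    rankdef <- FALSE
    for (j in seq_len(nch)) {
      pr <- suppressWarnings(
        project_linear(design[[j]],
                       problem$data$values[, j, drop = FALSE],
                       problem$offset_enabled))
      spectra[, j] <- pr$spectra
      if (problem$offset_enabled) offsets[j] <- pr$offsets
      resid[, j] <- pr$residual_matrix
      rankdef <- rankdef || pr$rank_deficient
    }
  }
  rownames(spectra) <- up$scheme$species
  ss <- sum(resid^2)

  dof <- max(length(resid) - length(theta), 1)
  cov_theta <- tryCatch(solve(JtJ) * ss / dof,
                        error = function(e) matrix(NA_real_,
                                                   length(theta),
                                                   length(theta)))
  se_theta <- sqrt(pmax(diag(cov_theta), 0))

  nk <- length(packing$free_rates)
  k_fit <- up$scheme$reactions$k[packing$free_rates]
  k_se <- k_fit * se_theta[seq_len(nk)]     # delta method from log space
  at_floor <- k_fit <= problem$lower * (1 + 1e-8)

  # lifetimes: fitted rates plus the scheme's non-decaying components
  # (species with zero total outgoing rate, the "Infinite" legends)
  n_fixed_zero <- sum(diag(rate_matrix(up$scheme)) == 0)
  tau <- ifelse(at_floor, Inf, 1 / k_fit)
  tau_se <- ifelse(at_floor, NA_real_, k_se / k_fit^2)
  if (n_fixed_zero > 0) {
    tau <- c(tau, rep(Inf, n_fixed_zero))
    tau_se <- c(tau_se, rep(NA_real_, n_fixed_zero))
  }
  ord <- order(tau)

  irf_est <- NULL
  if (!is.null(up$irf) && length(problem$irf_free)) irf_est <- up$irf

  structure(list(
    rates = stats::setNames(k_fit, names(theta0)[seq_len(nk)]),
    rate_se = stats::setNames(k_se, names(theta0)[seq_len(nk)]),
    lifetimes = tau[ord], lifetime_se = tau_se[ord],
    long_lived = is.infinite(tau[ord]),
    spectra = spectra, offsets = offsets,
    residual_matrix = resid, sum_of_squares = ss,
    rank_deficient = rankdef,
    irf = irf_est, theta = theta,
    engine_report = report), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> SS =", format(x$sum_of_squares, digits = 7),
      if (!x$engine_report$converged) " (NOT converged)" else "", "\n")
  tau <- ifelse(x$long_lived, "Infinite/long-lived",
                sprintf("%.4g +/- %.2g", x$lifetimes, x$lifetime_se))
  cat("  lifetimes:", paste(tau, collapse = ", "), "\n")
  invisible(x)
}

#' Fit SVD time traces with a shared kinetic model
#'
#' Fits the first `n_keep` (optionally singular-value-weighted) left
#' singular vectors of the data simultaneously with shared rate
#' constants. This condenses the data to a few noise-filtered traces;
#' the resulting basis amplitudes have no enforced physical meaning, but
#' the recovered time constants do. Weighted and unweighted traces give
#' identical rates (the scaling is absorbed by the linear amplitudes).
#'
#' @param problem a [fit_problem()] with an SVD `fit_target`
#'   (`"svd-traces"` or `"weighted-svd-traces"`).
#' @param n_keep number of traces; defaults to the problem's `n_keep`.
#'   If smaller than the number of free rates, a warning is issued.
#' @return a `fit_result` (see [fit_global()]); its `spectra` are basis
#'   amplitudes over traces, not physical spectra.
#' @export
fit_svd_traces <- function(problem, n_keep = problem$n_keep) {
  stopifnot(inherits(problem, "fit_problem"))
  if (is.null(n_keep))
    stop("n_keep is required for SVD-trace fitting", call. = FALSE)
  n_free <- sum(problem$scheme$reactions$k > 0)
  if (n_keep < n_free)
    warning("n_keep (", n_keep, ") is smaller than the number of free ",
            "rates (", n_free, ")", call. = FALSE)
  dec <- svd_decompose(problem$data)
  traces <- if (problem$fit_target == "weighted-svd-traces")
    weight_left_vectors(dec, n_keep)
  else dec$left_vectors[, seq_len(n_keep), drop = FALSE]
  tr_data <- data_matrix(problem$data$times, seq_len(n_keep), traces,
                         metadata = list(content = "left singular vectors"))
  sub <- problem
  sub$data <- tr_data
  sub$fit_target <- "full-data"
  class(sub) <- "fit_problem"
  out <- fit_global(sub)
  out$svd <- dec
  out
}

#' Compare fits with increasing component counts
#'
#' Tabulates the sum of squares of a series of fits of the same data,
#' the fold and relative improvement of each over the previous, and
#' flags compensating-amplitude pairs: channel-wise strongly
#' anticorrelated spectra of comparable magnitude between two
#' components, the classic signature of an inadequate (e.g. parallel
#' instead of sequential) model. Anticorrelation is measured by the
#' uncentred cosine similarity of the two spectra, which is strongly
#' negative only when one spectrum mirrors the other with opposite sign
#' at the same channels (mere non-overlap of positive bands scores near
#' zero).
#'
#' @param results list of two or more `fit_result` objects fitted to
#'   identical data.
#' @param cor_threshold cosine similarity below which a pair is
#'   flagged (default -0.5).
#' @param norm_ratio_min minimum smaller/larger spectrum norm ratio for
#'   a pair to count (default 0.1, ignores negligible components).
#' @return list with `table` (data frame: components, sum_of_squares,
#'   fold_improvement, rel_improvement) and `compensating` (per result,
#'   a data frame of flagged component pairs and their correlation).
#' @export
model_comparison <- function(results, cor_threshold = -0.5,
                             norm_ratio_min = 0.1) {
  if (length(results) < 2L)
    stop("need at least two fit results", call. = FALSE)
  dims <- vapply(results, function(r) dim(r$residual_matrix),
                 integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("fit results are not on identical data shapes", call. = FALSE)
  ncomp <- vapply(results, function(r) nrow(r$spectra), integer(1))
  ss <- vapply(results, function(r) r$sum_of_squares, numeric(1))
  tab <- data.frame(components = ncomp, sum_of_squares = ss,
                    fold_improvement = c(NA, ss[-length(ss)] / ss[-1]),
                    rel_improvement = c(NA, (ss[-length(ss)] - ss[-1]) /
                                          ss[-length(ss)]))
  compensating <- lapply(results, function(r) {
    S <- r$spectra
    norms <- sqrt(rowSums(S^2))
    pairs <- utils::combn(nrow(S), 2)
    flagged <- data.frame(i = integer(), j = integer(), cor = numeric())
    for (c_i in seq_len(ncol(pairs))) {
      i <- pairs[1, c_i]; j <- pairs[2, c_i]
      if (norms[i] == 0 || norms[j] == 0) next
      if (min(norms[i], norms[j]) / max(norms[i], norms[j]) < norm_ratio_min)
        next
      rho <- sum(S[i, ] * S[j, ]) / (norms[i] * norms[j])
      if (is.finite(rho) && rho < cor_threshold)
        flagged <- rbind(flagged, data.frame(i = i, j = j, cor = rho))
    }
    flagged
  })
  list(table = tab, compensating = compensating)
}
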