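test_that("projection recovers exact spectra from consistent data", {
  times <- seq(0, 10, length.out = 30)
  C <- cbind(exp(-times), exp(-times / 5))
  S <- matrix(c(1, 0.5, 0.2, 2, 1, 0.1), 2, 3)
  pr <- project_linear(C, C %*% S, offset_enabled = FALSE)
  expect_equal(pr$spectra, S, tolerance = 1e-12)
  expect_lt(max(abs(pr$residual_matrix)), 1e-12)
  expect_equal(pr$sum_of_squares, sum(pr$residual_matrix^2))
})

test_that("orthonormal designs project as C'D and match normal equations", {
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(40), 10, 4)))[, 1:3]
  D <- matrix(rnorm(50), 10, 5)
  pr <- project_linear(Q, D, offset_enabled = FALSE)
  expect_equal(pr$spectra, crossprod(Q, D), tolerance = 1e-12)
  C <- matrix(rnorm(30), 10, 3)
  pr2 <- project_linear(C, D, offset_enabled = FALSE)
  expect_equal(pr2$spectra, normal_eq_oracle(C, D), tolerance = 1e-10)
})

test_that("duplicated-rate designs warn and flag rank deficiency", {
  times <- seq(0, 5, length.out = 20)
  C <- cbind(exp(-times), exp(-times))
  D <- matrix(rnorm(40), 20, 2)
  expect_warning(pr <- project_linear(C, D, offset_enabled = FALSE),
                 "rank-deficient")
  expect_true(pr$rank_deficient)
})

test_that("the noiseless benchmark fit recovers 1.87 s and 34.8 s within 0.1%", {
  bench <- make_benchmark(benchmark_spec())
  sch <- build_sequential_scheme(c(2 / 1.87, 2 / 34.8, 0))
  fit <- fit_global(fit_problem(bench, sch, offset_enabled = FALSE))
  expect_true(fit$engine_report$converged)
  expect_equal(fit$lifetimes[1], 1.87, tolerance = 1e-3)
  expect_equal(fit$lifetimes[2], 34.8, tolerance = 1e-3)
  expect_true(fit$long_lived[3])
  expect_lt(max(abs(fit$residual_matrix)) / max(abs(bench$values)), 1e-6)
})

test_that("parallel and sequential fits share rates and SS; spectra differ", {
  bench <- make_benchmark(benchmark_spec())
  seq_fit <- fit_global(fit_problem(bench,
    build_sequential_scheme(c(2 / 1.87, 2 / 34.8, 0)),
    offset_enabled = FALSE))
  par_fit <- fit_global(fit_problem(bench,
    build_parallel_scheme(c(2 / 1.87, 2 / 34.8, 0)),
    offset_enabled = FALSE))
  expect_equal(sort(par_fit$rates), sort(seq_fit$rates),
               tolerance = 1e-8, ignore_attr = TRUE)
  denom <- max(seq_fit$sum_of_squares, 1e-20)
  expect_lt(abs(par_fit$sum_of_squares - seq_fit$sum_of_squares) / denom, 1)
  expect_gt(max(abs(par_fit$spectra - seq_fit$spectra)), 0.1)
})

test_that("pattern search reaches the gradient optimum on a single exponential", {
  bench <- make_benchmark(benchmark_spec(lifetimes = 2, n_channels = 10))
  pg <- fit_global(fit_problem(bench, build_parallel_scheme(1)))
  pp <- fit_global(fit_problem(bench, build_parallel_scheme(1),
                               engine = "pattern-search"))
  expect_equal(unname(pp$rates), unname(pg$rates), tolerance = 1e-6)
  expect_identical(pp$engine_report$engine, "pattern-search")
})

test_that("variable projection reaches the jointly optimised minimum", {
  set.seed(42)
  times <- seq(0, 10, length.out = 25)
  Ctrue <- cbind(exp(-0.8 * times), exp(-0.15 * times))
  S <- matrix(runif(10), 2, 5)
  D <- Ctrue %*% S
  fit <- fit_global(fit_problem(data_matrix(times, 1:5, D),
                                build_parallel_scheme(c(1.2, 0.1)),
                                offset_enabled = FALSE))
  joint <- optim(c(log(c(1.2, 0.1)), rep(0.5, 10)), function(par) {
    k <- exp(par[1:2])
    sum((D - cbind(exp(-k[1] * times), exp(-k[2] * times)) %*%
           matrix(par[3:12], 2, 5))^2)
  }, method = "BFGS", control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(abs(fit$sum_of_squares - joint$value), 1e-8)
})

test_that("permuted starting guesses land on the same sorted rate set", {
  bench <- make_benchmark(benchmark_spec(n_channels = 30))
  starts <- list(c(2 / 1.87, 2 / 34.8), c(2 / 34.8, 2 / 1.87),
                 c(0.05, 1.5))
  sols <- lapply(starts, function(s0)
    sort(fit_global(fit_problem(bench,
      build_parallel_scheme(c(s0, 0)), offset_enabled = FALSE))$rates))
  for (s in sols[-1])
    expect_equal(unname(s), unname(sols[[1]]), tolerance = 1e-6)
})

test_that("a very narrow IRF leaves the fitted rates unchanged", {
  bench <- make_benchmark(benchmark_spec(lifetimes = c(2, 20, Inf),
                                         n_channels = 15))
  sch <- build_sequential_scheme(c(1, 1 / 15, 0))
  free_fit <- fit_global(fit_problem(bench, sch, offset_enabled = FALSE))
  irf_fit <- fit_global(fit_problem(bench, sch,
                                    irf = irf_model(0, 2 / 500),
                                    offset_enabled = FALSE))
  expect_equal(sort(irf_fit$rates), sort(free_fit$rates),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("fitting with IRF and free parameters recovers a planted IRF", {
  sch <- build_sequential_scheme(c(1 / 0.5, 1 / 5, 0))
  irf_true <- irf_model(0.2, 0.15)
  times <- seq(-1, 20, length.out = 120)
  d <- make_chirped_irf_dataset(scheme = sch, irf = irf_true,
                                times = times, channels = 1:10,
                                spectra = benchmark_spectra(10, 3))
  fit <- fit_global(fit_problem(d, build_sequential_scheme(
    c(1.5 / 0.5, 1.5 / 5, 0)),
    irf = irf_model(0.1, 0.2), irf_free = c("t0", "fwhm"),
    offset_enabled = FALSE))
  expect_equal(fit$irf$t0, 0.2, tolerance = 1e-3)
  expect_equal(fit$irf$fwhm, 0.15, tolerance = 1e-3)
  expect_equal(fit$lifetimes[1], 0.5, tolerance = 1e-3)
})

test_that("SVD-trace fits recover the benchmark lifetimes; weighting is immaterial", {
  bench <- make_benchmark(benchmark_spec())
  sch <- build_sequential_scheme(c(2 / 1.87, 2 / 34.8, 0))
  fu <- fit_svd_traces(fit_problem(bench, sch, fit_target = "svd-traces",
                                   n_keep = 3, offset_enabled = FALSE))
  fw <- fit_svd_traces(fit_problem(bench, sch,
                                   fit_target = "weighted-svd-traces",
                                   n_keep = 3, offset_enabled = FALSE))
  expect_equal(fu$lifetimes[1], 1.87, tolerance = 0.02)
  expect_equal(fu$lifetimes[2], 34.8, tolerance = 0.02)
  expect_equal(sort(fw$rates), sort(fu$rates), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_warning(fit_svd_traces(fit_problem(bench, sch,
                                            fit_target = "svd-traces",
                                            n_keep = 1,
                                            offset_enabled = FALSE)),
                 "smaller than the number of free rates")
})

test_that("weighted and unweighted trace fits match full-data rates on noiseless data", {
  bench <- make_benchmark(benchmark_spec(n_channels = 40))
  sch <- build_sequential_scheme(c(2 / 1.87, 2 / 34.8, 0))
  full <- fit_global(fit_problem(bench, sch, offset_enabled = FALSE))
  traces <- fit_svd_traces(fit_problem(bench, sch,
                                       fit_target = "weighted-svd-traces",
                                       n_keep = 3, offset_enabled = FALSE))
  expect_equal(sort(traces$rates), sort(full$rates), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("model comparison tabulates SS gains and flags compensating amplitudes", {
  bench <- make_benchmark(benchmark_spec())
  seq_fit <- fit_global(fit_problem(bench,
    build_sequential_scheme(c(2 / 1.87, 2 / 34.8, 0)),
    offset_enabled = FALSE))
  par_fit <- fit_global(fit_problem(bench,
    build_parallel_scheme(c(2 / 1.87, 2 / 34.8, 0)),
    offset_enabled = FALSE))
  mc <- model_comparison(list(seq_fit, par_fit))
  expect_equal(nrow(mc$compensating[[1]]), 0L)   # correct model: no flag
  expect_gt(nrow(mc$compensating[[2]]), 0L)      # parallel model: flagged
  # identical results show zero improvement
  mc2 <- model_comparison(list(seq_fit, seq_fit))
  expect_equal(mc2$table$rel_improvement[2], 0)
  expect_error(model_comparison(list(seq_fit)), "at least two")
})

test_that("unresolvably slow components surface as long-lived or off-scale lifetimes", {
  # a free third rate on a 300 s time base either hits the lower bound
  # (flagged Infinite) or fits far beyond the observation window
  bench <- make_benchmark(benchmark_spec(noise_fraction = 0.1, seed = 2))
  fit <- fit_global(fit_problem(bench,
    build_parallel_scheme(c(1 / 2, 1 / 30, 1e-6)),
    offset_enabled = FALSE))
  expect_true(any(fit$long_lived) || max(fit$lifetimes) > 1e3)
  # a rate fixed at zero is always reported as Infinite/long-lived
  fit0 <- fit_global(fit_problem(bench,
    build_parallel_scheme(c(1 / 2, 1 / 30, 0)),
    offset_enabled = FALSE))
  expect_true(fit0$long_lived[3])
  expect_true(is.infinite(fit0$lifetimes[3]))
})

test_that("sum of squares equals the summed squared residuals", {
  bench <- make_benchmark(benchmark_spec(n_channels = 12))
  fit <- fit_global(fit_problem(bench,
    build_sequential_scheme(c(1, 0.05, 0)), offset_enabled = FALSE))
  expect_equal(fit$sum_of_squares, sum(fit$residual_matrix^2),
               tolerance = 1e-10)
  expect_equal(dim(fit$spectra),
               c(3L, length(bench$channels)))
})
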