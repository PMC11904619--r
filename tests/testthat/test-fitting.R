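test_that("objective is zero at the generating parameters and scales with noise", {
  m <- build_model("coi")
  p <- short_staircase(sample_interval = 10)
  sim <- simulate_current(m, m$default_params, p, E_Kr = E_NERNST)
  expect_lt(objective(m, m$default_params, p, sim$trace$current_pA,
                      E_Kr = E_NERNST), 1e-8)
  # with noise sigma, SSE/n at truth estimates sigma^2
  z <- sim$trace$current_pA +
    withr::with_seed(1, rnorm(nrow(sim$trace), 0, 20))
  sse <- objective(m, m$default_params, p, z, E_Kr = E_NERNST)
  expect_lt(abs(sse / length(z) - 400) / 400, 0.15)
  # invariant to observation order (sum of squares)
  ord <- withr::with_seed(2, sample(length(z)))
  y <- sim$trace$current_pA
  expect_equal(sum((y - z)^2), sum((y[ord] - z[ord])^2))
})

test_that("rate bounds use the maximum over the voltage range", {
  cfg <- fit_config()
  expect_false(check_rate_bounds("pos_exp", A = 1e-7, b = 0, cfg))
  expect_true(check_rate_bounds("pos_exp", A = 1, b = 0.1, cfg))   # e^6
  expect_false(check_rate_bounds("neg_exp", A = 1e3, b = 0.04, cfg)) # 1.22e5
  expect_true(check_rate_bounds("constant", A = 0.02, cfg))
  expect_false(check_rate_bounds("constant", A = 1e6, cfg))
})

test_that("conductance bounds scale with the trace and bracket the truth", {
  m <- build_model("beattie")
  p <- short_staircase(sample_interval = 10)
  ok <- 0
  for (s in 1:10) {
    tr_truth <- well_truth("W", m$default_params, g_L = 0, noise_sd = 15)
    sweep <- generate_sweep(tr_truth, m, p, "pre", seed = s,
                            E_Kr = E_NERNST)
    gb <- conductance_bounds(sweep, p, E_Kr = E_NERNST)
    g_true <- m$default_params[m$conductance_index]
    ok <- ok + (g_true >= gb[1] && g_true <= gb[2])
    doubled <- sweep
    doubled$current_pA <- 2 * doubled$current_pA
    expect_equal(conductance_bounds(doubled, p, E_Kr = E_NERNST), 2 * gb)
  }
  expect_equal(ok, 10)
  zero <- leak_trace(p, 0, 0)
  expect_warning(gb0 <- conductance_bounds(zero, p), "degenerate")
  expect_equal(gb0, c(0, Inf))
})

test_that("population size follows floor(4 + 3 log n) with the Wang override", {
  expect_equal(population_size(1), 4L)
  expect_equal(population_size(9), floor(4 + 3 * log(9)))
  expect_equal(population_size(9), 10L)
  expect_equal(population_size(15, override = 50), 50L)
})

test_that("initial guesses are log-uniform, seeded, and respect all bounds", {
  m <- build_model("coi")
  cfg <- fit_config()
  draws <- lapply(1:200, function(s)
    sample_initial_guess(m, cfg, g_bounds = c(1e-6, 1e3), seed = s))
  for (d in draws[1:20]) {
    expect_true(ikrfit:::rate_bounds_ok(m, d[1:8], cfg))
    expect_true(d[9] >= 1e-6 && d[9] <= 1e3)
  }
  expect_identical(sample_initial_guess(m, cfg, seed = 77),
                   sample_initial_guess(m, cfg, seed = 77))
  # with a rate check that cannot reject, log10 draws are uniform on [-7, 1]
  loose <- fit_config(rate_bound_lo = 1e-300, rate_bound_hi = 1e300,
                      v_range = c(-1e-9, 1e-9))
  vals <- unlist(lapply(1:1200, function(s)
    sample_initial_guess(m, loose, seed = s)))
  ks <- suppressWarnings(ks.test(log10(vals), "punif", -7, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("a small fit beats the truth on its own training objective", {
  m <- build_model("coi")
  p <- assemble_protocol(
    tibble::tibble(section_tag = "main", kind = "step",
                   duration_ms = rep(150, 6),
                   v_start_mV = c(-40, 20, -60, 40, -20, -100),
                   v_end_mV = c(-40, 20, -60, 40, -20, -100)),
    name = "mini", sample_interval = 10)
  tr_truth <- well_truth("W", m$default_params, g_L = 0, noise_sd = 20,
                         V_off = 0)
  sweep <- generate_sweep(tr_truth, m, p, "pre", seed = 5, E_Kr = E_NERNST)
  cfg <- fit_config(n_repeats = 2, max_evals = 1200, seed = 31)
  fit <- fit_sweep(m, sweep, p, cfg, E_Kr = E_NERNST, V_off = 0)
  sse_truth <- objective(m, m$default_params, p, sweep$current_pA,
                         E_Kr = E_NERNST)
  expect_lte(fit$sse, sse_truth * 1.0001)
  # the estimate satisfies the rate and conductance bounds
  expect_true(ikrfit:::rate_bounds_ok(m, fit$theta[1:8], cfg))
  expect_true(fit$theta[9] >= fit$g_bounds[1] &&
                fit$theta[9] <= fit$g_bounds[2])
  # tidiers and the repeat table
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  gl <- glance(fit)
  expect_equal(gl$n_repeats, 2)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("the CMA-ES minimiser solves standard smooth problems", {
  sphere <- function(x) sum((x - 1:4)^2)
  res <- cma_es(sphere, x0 = rep(0, 4), sigma0 = 0.5, max_evals = 4000,
                seed = 1)
  expect_lt(res$value, 1e-6)
  expect_equal(res$par, 1:4, tolerance = 1e-3)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  res2 <- cma_es(rosen, x0 = c(-1, 1), sigma0 = 0.3, max_evals = 6000,
                 seed = 2)
  expect_lt(res2$value, 1e-5)
})
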