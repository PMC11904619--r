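test_that("leak fitting recovers a noiseless linear leak exactly", {
  p <- small_battery()$d2
  tr <- leak_trace(p, g_L = 1, E_L = -10)
  lk <- fit_leak(tr, p)
  expect_lt(abs(lk$g_L - 1), 1e-9)
  expect_lt(abs(lk$E_L - (-10)), 1e-6)
  expect_false(lk$degenerate)
  # identically zero current is reported as the degenerate convention
  z <- tr
  z$current_pA <- 0
  lk0 <- fit_leak(z, p)
  expect_equal(lk0$g_L, 0)
  expect_equal(lk0$E_L, 0)
  expect_true(lk0$degenerate)
})

test_that("noisy leak estimates scatter within Monte-Carlo error", {
  p <- small_battery()$d2
  n_in_window <- 40                      # 400 ms ramp at 10 ms sampling
  v_sd <- sd(seq(-120, -80, length.out = n_in_window))
  se_gL <- 20 / (v_sd * sqrt(n_in_window))
  ests <- vapply(1:100, function(s) {
    fit_leak(leak_trace(p, g_L = 1, E_L = -10, sigma = 20, seed = s), p)$g_L
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1), 3 * se_gL / sqrt(100))
  expect_lt(abs(sd(ests) - se_gL) / se_gL, 0.35)
})

test_that("leak subtraction removes the fitted line", {
  p <- small_battery()$d2
  tr <- leak_trace(p, g_L = 1.4, E_L = 3)
  lk <- fit_leak(tr, p)
  corr <- leak_subtract(tr, lk, p)
  expect_lt(max(abs(corr$current_pA)), 1e-6)
  # subtracting a zero leak is the identity
  same <- leak_subtract(tr, list(g_L = 0, E_L = 0), p)
  expect_equal(same$current_pA, tr$current_pA)
})

test_that("drug subtraction is exact pointwise difference", {
  p <- small_battery()$d1
  a <- leak_trace(p, 1, 0, sigma = 5, seed = 1)
  expect_true(all(drug_subtract(a, a)$current_pA == 0))
  b <- leak_trace(p, 1, 0, sigma = 5, seed = 2)
  d <- drug_subtract(a, b)
  expect_equal(d$current_pA, a$current_pA - b$current_pA)
  # variance of the difference of two independent noises is about 2 sigma^2
  expect_lt(abs(var(d$current_pA - mean(d$current_pA)) - 2 * 25) / 50, 0.25)
  short <- a[-1, ]
  expect_error(drug_subtract(a, short), "grid")
})

test_that("reversal inference finds the zero crossing within 0.5 mV", {
  m <- build_model("beattie")
  p <- small_battery()$d2
  for (ek in c(-95, -90.5, -85)) {
    sim <- simulate_current(m, m$default_params, p, E_Kr = ek)
    tr <- tibble::tibble(time_ms = sim$trace$time_ms,
                         current_pA = sim$trace$current_pA)
    expect_lt(abs(infer_reversal(tr, p) - ek), 0.5)
  }
  # strictly positive current over the ramp has no root
  flat <- leak_trace(p, 0, 0)
  flat$current_pA <- flat$current_pA + 50
  expect_error(infer_reversal(flat, p), "zero-crossing")
})

test_that("a +5 mV generator offset shifts E_obs by -5 mV", {
  m <- build_model("beattie")
  p <- small_battery()$d2
  e0 <- infer_reversal(
    simulate_current(m, m$default_params, p, E_Kr = E_NERNST,
                     V_off = 0)$trace, p)
  e5 <- infer_reversal(
    simulate_current(m, m$default_params, p, E_Kr = E_NERNST,
                     V_off = 5)$trace, p)
  expect_lt(abs((e5 - e0) - (-5)), 0.5)
  # and the printed estimator then recovers the +5 offset
  expect_lt(abs(compute_voltage_offset(e5, E_NERNST) - 5), 0.5)
})

test_that("voltage offset is the printed difference", {
  expect_equal(compute_voltage_offset(-90, -90), 0)
  expect_equal(compute_voltage_offset(-85, -90), -5)
})

test_that("noise estimation uses the initial hold", {
  p <- small_battery()$d1
  quiet <- leak_trace(p, 0, 0)
  expect_equal(estimate_noise_sd(quiet, p), 0)
  noisy <- leak_trace(p, 0, 0, sigma = 20, seed = 8)
  s1 <- estimate_noise_sd(noisy, p)
  shifted <- noisy
  shifted$current_pA <- shifted$current_pA + 123
  expect_equal(estimate_noise_sd(shifted, p), s1)
  # 25 hold samples at 10 ms: wide chi band; at 1 ms sampling it tightens
  p1 <- small_battery(sample_interval = 1)$d1
  hits <- vapply(1:40, function(s) {
    est <- estimate_noise_sd(leak_trace(p1, 0, 0, sigma = 20, seed = s), p1)
    est >= 18 && est <= 22
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("postprocessing a noiseless artefact-free sweep returns IKr up to the leak-window bias", {
  m <- build_model("beattie")
  cfg <- dataset_config(m, protocols = small_battery(), wells = "W",
                        noise_sd = 0, g_L_range = c(0, 1e-12), E_L_sd = 0,
                        V_off_sd = 0)
  ds <- generate_dataset(cfg, seed = 5)
  pp <- postprocess_dataset(ds, E_Nernst = cfg$E_Kr)
  ikr <- simulate_current(m, ds$well_params$params$params[[1]],
                          cfg$protocols$d1, E_Kr = cfg$E_Kr)$trace$current_pA
  err <- max(abs(pp$traces[["W|d1|1|pre"]]$current_pA - ikr))
  # the pre-drug leak fit absorbs the (small) channel current over the
  # [-120,-80] window; the residual bias is bounded by a fraction of it
  window_ikr <- max(abs(ikr[voltage_at(cfg$protocols$d1,
                                       pp$traces[[1]]$time_ms) <= -80]))
  expect_lt(err, max(2 * window_ikr, 1e-6))
  expect_lt(err / max(abs(ikr)), 2e-3)
  # the operations themselves are exact: correcting with the true leak and
  # subtracting the true post-drug trace returns IKr to machine precision
  pre <- get_trace(ds, "W", "d1", 1, "pre")
  post <- get_trace(ds, "W", "d1", 1, "post")
  exact <- drug_subtract(leak_subtract(pre, list(g_L = 0, E_L = 0),
                                       cfg$protocols$d1),
                         leak_subtract(post, list(g_L = 0, E_L = 0),
                                       cfg$protocols$d1))
  expect_lt(max(abs(exact$current_pA - ikr)), 1e-9)
})

test_that("QC passes clean wells and flags injected defects specifically", {
  m <- build_model("coi")
  cfg <- dataset_config(m, protocols = small_battery(),
                        wells = c("A01", "B02", "C03"), noise_sd = 15)
  ds <- generate_dataset(cfg, seed = 42)
  clean <- qc_filter(postprocess_dataset(ds, E_Nernst = cfg$E_Kr))
  expect_setequal(clean$passing, c("A01", "B02", "C03"))

  drifted <- inject_qc_failure(ds, "B02", "rundown")
  qc_d <- qc_filter(postprocess_dataset(drifted, E_Nernst = cfg$E_Kr))
  row <- qc_d$flags[qc_d$flags$well == "B02", ]
  expect_false(row$pass)
  expect_false(row$drift_ok)

  shifted <- inject_qc_failure(ds, "C03", "bad_reversal")
  qc_e <- qc_filter(postprocess_dataset(shifted, E_Nernst = cfg$E_Kr))
  row <- qc_e$flags[qc_e$flags$well == "C03", ]
  expect_false(row$pass)
  expect_false(row$eobs_ok)
  expect_true(row$sigma_ok)

  noisy <- inject_qc_failure(ds, "A01", "noisy")
  qc_n <- qc_filter(postprocess_dataset(noisy, E_Nernst = cfg$E_Kr))
  expect_false(qc_n$flags$sigma_ok[qc_n$flags$well == "A01"])
})

test_that("QC is monotone in its thresholds", {
  m <- build_model("coi")
  cfg <- dataset_config(m, protocols = small_battery(),
                        wells = c("A01", "B02"), noise_sd = 25)
  pp <- postprocess_dataset(generate_dataset(cfg, seed = 17),
                            E_Nernst = cfg$E_Kr)
  tight <- qc_filter(pp, qc_criteria(max_sigma = 40,
                                     max_staircase_drift = 0.3,
                                     max_Eobs_deviation = 5,
                                     max_postdrug_ratio = 0.3))
  loose <- qc_filter(pp, qc_criteria(max_sigma = 80,
                                     max_staircase_drift = 0.6,
                                     max_Eobs_deviation = 10,
                                     max_postdrug_ratio = 0.6))
  expect_true(all(tight$passing %in% loose$passing))
})
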