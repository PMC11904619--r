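test_that("zero effect SDs reproduce the base parameters exactly", {
  m <- build_model("beattie")
  wp <- generate_well_params(m, wells = c("A", "B"), protocols = c("d1", "d2"),
                             well_effect_sd = 0, protocol_effect_sd = 0,
                             g_cv = 0, seed = 4)
  for (p in wp$params$params) {
    expect_equal(unname(p), unname(m$default_params))
  }
  expect_true(all(wp$beta_w == 0) && all(wp$beta_d == 0))
})

test_that("effect matrices are centred and have the requested spread", {
  m <- build_model("beattie")
  wp <- generate_well_params(m, wells = sprintf("W%03d", 1:100),
                             protocols = paste0("d", 1:12),
                             well_effect_sd = 0.2, protocol_effect_sd = 0.1,
                             seed = 9)
  expect_lt(max(abs(colSums(wp$beta_w))), 1e-10)
  expect_lt(max(abs(colSums(wp$beta_d))), 1e-10)
  a_cols <- startsWith(colnames(wp$beta_w), "A_")
  sds <- apply(wp$beta_w[, a_cols], 2, sd)
  expect_true(all(abs(sds - 0.2) / 0.2 < 0.2))   # within 20% at 100 wells
})

test_that("sweep generation follows I_out = IKr + leak + noise", {
  m <- build_model("coi")
  p <- short_staircase(sample_interval = 10)
  tr_truth <- well_truth("W", m$default_params, g_L = 0.8, E_L = -4,
                         V_off = 0, noise_sd = 0)
  pre <- generate_sweep(tr_truth, m, p, "pre", E_Kr = E_NERNST)
  post <- generate_sweep(tr_truth, m, p, "post", E_Kr = E_NERNST)
  ikr <- simulate_current(m, m$default_params, p,
                          E_Kr = E_NERNST)$trace$current_pA
  expect_equal(pre$current_pA - post$current_pA, ikr)
  # post-drug with no leak or noise is identically zero
  tr0 <- well_truth("W", m$default_params, g_L = 0, noise_sd = 0)
  expect_true(all(generate_sweep(tr0, m, p, "post")$current_pA == 0))
})

test_that("noise has the configured standard deviation", {
  m <- build_model("coi")
  p <- staircase_like(sample_interval = 0.5)   # > 1e4 samples
  tr_truth <- well_truth("W", m$default_params, g_L = 0, noise_sd = 20,
                         V_off = 0)
  noiseless <- simulate_current(m, m$default_params, p,
                                E_Kr = E_NERNST)$trace$current_pA
  sweep <- generate_sweep(tr_truth, m, p, "pre", seed = 3, E_Kr = E_NERNST,
                          ikr_noiseless = noiseless)
  resid <- sweep$current_pA - noiseless
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 20) / 20, 0.05)
})

test_that("dataset realises the full design deterministically", {
  m <- build_model("coi")
  cfg <- dataset_config(m, protocols = small_battery(), wells = "A01",
                        noise_sd = 10)
  ds <- generate_dataset(cfg, seed = 2)
  des <- ds$design
  expect_equal(nrow(des), 2 * (4 + 2))   # 3-protocol battery: 4x d1 + d2 + d6
  expect_equal(length(ds$traces), nrow(des))
  # with the full 12-protocol battery the design gives 14 fitting sweeps
  full <- experiment_design(paste0("d", 1:12), wells = "A01")
  expect_equal(sum(full$fitting & full$drug_state == "pre"), 14)
  expect_equal(sum(full$drug_state == "pre"), 15)
  ds2 <- generate_dataset(cfg, seed = 2)
  expect_identical(
    lapply(ds$traces, function(t) t$current_pA),
    lapply(ds2$traces, function(t) t$current_pA))
  ds3 <- generate_dataset(cfg, seed = 3)
  expect_false(identical(ds$traces[[1]]$current_pA,
                         ds3$traces[[1]]$current_pA))
  # ground truth is carried with the dataset for every well
  expect_named(ds$truth, "A01")
  expect_true(is.finite(ds$truth$A01$g_L))
})

test_that("datasets and traces round-trip through plain-text files", {
  m <- build_model("coi")
  cfg <- dataset_config(m, protocols = small_battery(), wells = "A01",
                        noise_sd = 5)
  ds <- generate_dataset(cfg, seed = 12)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "design.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_equal(nrow(manifest), nrow(ds$design))
  one <- read_trace_csv(file.path(dir, manifest$path[1]))
  orig <- ds$traces[[1]]
  expect_equal(one$current_pA, orig$current_pA, tolerance = 1e-12)
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$wells$A01$g_L, ds$truth$A01$g_L, tolerance = 1e-12)
})
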