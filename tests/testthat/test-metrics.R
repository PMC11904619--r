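make_cv_table <- function(m, fit_names, val_names = fit_names) {
  tb <- tibble::tibble(
    fit_protocol = sub("\\..*", "", fit_names),
    fit_sweep = as.integer(sub(".*\\.", "", fit_names)))
  for (j in seq_along(val_names)) tb[[val_names[j]]] <- m[, j]
  attr(tb, "diag_keys") <- fit_names
  class(tb) <- c("crossval_table", class(tb))
  tb
}

test_that("nrmse follows the RMS-over-RMS convention", {
  z <- c(1, 3)
  expect_equal(nrmse(z, z), 0)
  expect_equal(nrmse(rep(0, 2), z), 1)
  expect_equal(nrmse(c(1, 1), z), sqrt(4) / sqrt(10))
  expect_equal(nrmse(3 * c(1, 1), 3 * z), nrmse(c(1, 1), z))  # scale-invariant
  expect_error(nrmse(c(1, 2), c(0, 0)), "zero")
})

test_that("E_fit averages the diagonal, E_predict the off-diagonal", {
  m <- matrix(0.5, 3, 3)
  diag(m) <- c(0.1, 0.2, 0.3)
  keys <- c("a.1", "b.1", "c.1")
  tb <- make_cv_table(m, keys)
  expect_equal(e_fit(tb), 0.2)
  # all off-diagonals 0.5 with N_d = 3: sum 3 over (N_d-1)^2 = 4
  expect_equal(e_predict(tb), 0.75)
  # invariance: E_fit ignores off-diagonals, E_predict ignores the diagonal
  m2 <- m
  m2[1, 2] <- 9
  expect_equal(e_fit(make_cv_table(m2, keys)), 0.2)
  m3 <- m
  diag(m3) <- 99
  expect_equal(e_predict(make_cv_table(m3, keys)), 0.75)
  zero <- make_cv_table(matrix(0, 3, 3), keys)
  expect_equal(e_fit(zero), 0)
  expect_equal(e_predict(zero), 0)
})

test_that("weighted residuals average across wells and clip at 100", {
  r1 <- c(0, 10, -10)
  r2 <- c(0, 10, 3000)
  out <- weighted_residuals(list(r1, r2), sigma_hat = c(10, 10))
  expect_equal(out[1], 0)
  expect_equal(out[2], 1)          # overestimate -> positive
  expect_equal(out[3], 100)        # mean(-1, 300) clipped? no: clip after mean
  one <- weighted_residuals(list(c(300 * 7)), sigma_hat = 7)
  expect_equal(one, 100)
  expect_error(weighted_residuals(list(r1), sigma_hat = 0), "positive")
})

test_that("consistency T is scaled by noise plus ensemble standard error", {
  z <- c(0, 0, 0)
  preds <- cbind(z, z, z)
  expect_equal(consistency_T(preds, z, sigma_hat = 5), c(0, 0, 0))
  # ybar - z = sigma with zero spread gives T = 1
  preds2 <- cbind(rep(5, 3), rep(5, 3))
  expect_equal(consistency_T(preds2, z, sigma_hat = 5), rep(1, 3))
  # sqrt(N) versus N denominator switch
  preds3 <- cbind(c(10, 0, 0), c(0, 0, 0))
  t_se <- consistency_T(preds3, z, sigma_hat = 1, se = TRUE)
  t_n <- consistency_T(preds3, z, sigma_hat = 1, se = FALSE)
  expect_gt(t_n[1], t_se[1])   # smaller denominator spread term
  expect_error(consistency_T(matrix(1, 3, 1), z, 1), "2 ensemble")
  big <- cbind(rep(1e4, 3), rep(1e4, 3))
  expect_equal(consistency_T(big, z, sigma_hat = 1), rep(100, 3))
})

test_that("an unbiased ensemble has small T, a biased one sustained large T", {
  set.seed(4)
  n_t <- 200
  truth <- sin(seq(0, 3, length.out = n_t)) * 50
  sigma <- 5
  z <- truth + rnorm(n_t, 0, sigma)
  unbiased <- sapply(1:8, function(i) truth + rnorm(n_t, 0, sigma))
  biased <- sapply(1:8, function(i) truth + 30 + rnorm(n_t, 0, sigma))
  t_ok <- consistency_T(unbiased, z, sigma_hat = sigma)
  t_bad <- consistency_T(biased, z, sigma_hat = sigma)
  expect_lt(abs(mean(t_ok)), 1)
  expect_gt(mean(t_bad), 3)
})

test_that("cross-validation rows are zero when data come from the fitted parameters", {
  m <- build_model("coi")
  cfg <- dataset_config(m, protocols = small_battery(), wells = "W",
                        noise_sd = 0, g_L_range = c(0, 1e-12), E_L_sd = 0,
                        V_off_sd = 0)
  ds <- generate_dataset(cfg, seed = 8)
  pp <- postprocess_dataset(ds, E_Nernst = cfg$E_Kr)
  # fabricate fits at the exact generating parameters
  theta <- ds$well_params$params$params[[1]]
  fits <- lapply(list(c("d1", 1L), c("d2", 1L)), function(id) {
    structure(list(theta = theta, model = "coi", well = "W",
                   protocol = id[1], sweep = as.integer(id[2])),
              class = "ikr_fit")
  })
  # force exact zero voltage offset in validation (truth had none)
  for (k in names(pp$traces)) attr(pp$traces[[k]], "meta")$V_off <- 0
  tb <- cross_validation_table(fits, pp, m, well = "W")
  vals <- as.matrix(tb[, setdiff(names(tb), c("fit_protocol", "fit_sweep"))])
  # entries are NRMSE against data generated from theta: only the leak-fit
  # bias survives, a small fraction of the signal
  expect_lt(max(vals), 5e-3)
  expect_equal(dim(vals), c(2, 6))      # 2 fits x (4 d1 + d2 + d6) sweeps
  expect_s3_class(ggplot2::autoplot(tb), "ggplot")
})
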