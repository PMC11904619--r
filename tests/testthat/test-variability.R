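# direct generator for estimate tables: mu + well + protocol effects + noise
sim_table <- function(wells = 8, protocols = 14, n_par = 4,
                      well_sd = 0, prot_sd = 0, noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    w_lev <- sprintf("w%02d", seq_len(wells))
    d_lev <- sprintf("d%02d", seq_len(protocols))
    bw <- matrix(rnorm(wells * n_par, 0, well_sd), wells)
    bw <- sweep(bw, 2, colMeans(bw))
    bd <- matrix(rnorm(protocols * n_par, 0, prot_sd), protocols)
    bd <- sweep(bd, 2, colMeans(bd))
    grid <- expand.grid(well = w_lev, protocol = d_lev,
                        stringsAsFactors = FALSE)
    mu <- seq_len(n_par)
    Y <- matrix(mu, nrow(grid), n_par, byrow = TRUE) +
      bw[match(grid$well, w_lev), ] + bd[match(grid$protocol, d_lev), ] +
      matrix(rnorm(nrow(grid) * n_par, 0, noise_sd), nrow(grid))
    colnames(Y) <- paste0("a_p", seq_len(n_par))
    out <- tibble::as_tibble(Y)
    out$well <- grid$well
    out$protocol <- grid$protocol
    out$sweep <- 1L
    list(table = out[, c("well", "protocol", "sweep", colnames(Y))],
         beta_w = bw, beta_d = bd)
  })
}

test_that("estimate tables log-transform A and drop the conductance", {
  m <- build_model("beattie")
  mk_fit <- function(well, protocol, sweep, theta) {
    structure(list(theta = theta, model = "beattie", well = well,
                   protocol = protocol, sweep = sweep), class = "ikr_fit")
  }
  theta <- m$default_params
  theta[1] <- 1                      # A = 1 -> a = 0
  fits <- list(mk_fit("w1", "d1", 1L, theta),
               mk_fit("w1", "d2", 1L, m$default_params))
  tab <- transform_estimates(fits, m)
  expect_equal(ncol(tab) - 3, 8)     # 9 params minus g
  expect_equal(tab[[4]][1], 0)       # ln 1
  expect_equal(exp(tab[[4]][2]), m$default_params[1])  # round trip
  expect_true(all(startsWith(setdiff(names(tab), c("well", "protocol",
                                                   "sweep")), c("a_", "b_"))))
  bad <- mk_fit("w1", "d1", 1L, replace(theta, 1, -2))
  expect_error(transform_estimates(list(bad), m), "positive")
})

test_that("sum-to-zero design matrices have the expected rank and coding", {
  wells <- rep(c("a", "b", "c"), each = 4)
  prots <- rep(c("p", "q", "r", "s"), 3)
  dm <- build_design_matrices(wells, prots)
  expect_equal(ncol(dm$X_w), 2)
  expect_equal(ncol(dm$X_d), 3)
  X <- cbind(1, dm$X_d, dm$X_w)
  expect_equal(qr(X)$rank, 1 + 2 + 3)
  # dropped level is -1 across columns; expansion sums to zero over levels
  expect_true(all(dm$X_w[wells == "c", ] == -1))
  # a single well yields an empty well design
  dm1 <- build_design_matrices(rep("a", 4), c("p", "q", "p", "q"))
  expect_equal(ncol(dm1$X_w), 0)
})

test_that("noiseless tables are recovered exactly with zero residuals", {
  sim <- sim_table(wells = 4, protocols = 5, well_sd = 0.3, prot_sd = 0.2,
                   noise_sd = 0, seed = 3)
  fit <- fit_linear_model(sim$table, "Mwd")
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_lt(max(abs(fit$beta_w - sim$beta_w)), 1e-9)
  expect_lt(max(abs(fit$beta_d - sim$beta_d)), 1e-9)
  expect_lt(max(abs(colSums(fit$beta_w))), 1e-10)
  expect_lt(max(abs(colSums(fit$beta_d))), 1e-10)
})

test_that("nested variants satisfy likelihood monotonicity on any table", {
  for (s in 1:5) {
    sim <- sim_table(wells = 5, protocols = 6, well_sd = 0.1, prot_sd = 0.1,
                     noise_sd = 0.2, seed = s)
    ll <- vapply(c("M0", "Mw", "Md", "Mwd"),
                 function(v) fit_linear_model(sim$table, v)$loglik,
                 numeric(1))
    expect_gte(ll["Mwd"], ll["Mw"])
    expect_gte(ll["Mwd"], ll["Md"])
    expect_gte(ll["Mw"], ll["M0"])
    expect_gte(ll["Md"], ll["M0"])
  }
})

test_that("loglik is invariant to row permutation", {
  sim <- sim_table(wells = 4, protocols = 4, well_sd = 0.2, noise_sd = 0.1,
                   seed = 11)
  f1 <- fit_linear_model(sim$table, "Mwd")
  shuffled <- sim$table[withr::with_seed(1, sample(nrow(sim$table))), ]
  f2 <- fit_linear_model(shuffled, "Mwd")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
})

test_that("well effects are recovered within Monte-Carlo error at study shape", {
  # 8 wells x 14 sweeps, matching the study's estimate-table shape
  sim <- sim_table(wells = 8, protocols = 14, well_sd = 0.25, prot_sd = 0.1,
                   noise_sd = 0.1, seed = 21)
  fit <- fit_linear_model(sim$table, "Mwd")
  se <- 0.1 / sqrt(14)               # residual sd / sqrt(reps per well)
  expect_lt(max(abs(fit$beta_w - sim$beta_w)), 4 * se)
})

test_that("LLDs are nonnegative, zero for identical fits, and detect well effects", {
  sim <- sim_table(wells = 6, protocols = 8, well_sd = 0.2, prot_sd = 0.1,
                   noise_sd = 0.1, seed = 2)
  full <- fit_linear_model(sim$table, "Mwd")
  red_w <- fit_linear_model(sim$table, "Md")
  red_d <- fit_linear_model(sim$table, "Mw")
  expect_equal(lld(full, full), 0)
  expect_gte(lld(full, red_w), 0)
  expect_gte(lld(full, red_d), 0)
  expect_error(lld(red_w, red_d), "nested")

  strong <- vapply(1:10, function(s) {
    tb <- sim_table(wells = 8, protocols = 14, well_sd = 0.3,
                    noise_sd = 0.05, seed = 100 + s)$table
    variability_analysis(tb)$lld_w
  }, numeric(1))
  null <- vapply(1:10, function(s) {
    tb <- sim_table(wells = 8, protocols = 14, well_sd = 0,
                    noise_sd = 0.05, seed = 200 + s)$table
    variability_analysis(tb)$lld_w
  }, numeric(1))
  expect_gte(median(strong), 10 * median(null))
})

test_that("variability summary has the standard table shape and tidiers work", {
  sim <- sim_table(wells = 4, protocols = 5, well_sd = 0.2, prot_sd = 0.2,
                   noise_sd = 0.1, seed = 6)
  row <- variability_analysis(sim$table, model_name = "beattie")
  expect_named(row, c("model", "loglik_M0", "loglik_Mw", "loglik_Md",
                      "loglik_Mwd", "lld_w", "lld_d"))
  fit <- fit_linear_model(sim$table, "Mwd")
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("intercept", "well", "protocol"))
  expect_equal(nrow(glance(fit)), 1)
})
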