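test_that("intercept-only fit reduces to the mean with textbook quantities", {
  f <- ols_solve(matrix(1, 3, 1), c(1, 2, 3))
  expect_equal(unname(f$beta), 2)
  expect_equal(f$rss, 2)
  expect_equal(f$df_resid, 2)
  expect_equal(f$hat_diag, rep(1 / 3, 3))
  # RSS = n collapses the Gaussian log-likelihood closed form
  f2 <- ols_solve(matrix(1, 2, 1), c(0, 2))
  expect_equal(f2$loglik, -(log(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(f2$loglik, -2.8378770664, tolerance = 1e-9)
})

test_that("Cook's distance equals the leave-one-out refit definition", {
  f <- ols_solve(matrix(1, 3, 1), c(0, 0, 3))
  expect_equal(unname(f$cooks_d), c(0.25, 0.25, 1.0))
  set.seed(13)
  X <- cbind(1, rnorm(15), runif(15))
  y <- rnorm(15)
  expect_equal(ols_solve(X, y)$cooks_d, oracle_cooks_loo(X, y),
               tolerance = 1e-10)
})

test_that("every statistic matches lm/summary.lm on a random instance", {
  set.seed(20)
  n <- 20
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = runif(n))
  y <- rnorm(n)
  X <- model.matrix(~ x1 + x2 + x3, dat)
  ours <- ols_solve(X, y)
  ref <- lm(y ~ x1 + x2 + x3, dat)
  s <- summary(ref)
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(ours$se), unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(ours$tvalues), unname(s$coefficients[, 3]),
               tolerance = 1e-10)
  expect_equal(unname(ours$pvalues), unname(s$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(ours$aic, AIC(ref), tolerance = 1e-10)
  expect_equal(ours$bic, BIC(ref), tolerance = 1e-10)
  expect_equal(ours$r2, s$r.squared, tolerance = 1e-10)
  expect_equal(ours$r2_adj, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(unname(ours$hat_diag), unname(hatvalues(ref)),
               tolerance = 1e-10)
  expect_equal(unname(ours$cooks_d), unname(cooks.distance(ref)),
               tolerance = 1e-10)
  expect_equal(unname(ours$residuals), unname(residuals(ref)),
               tolerance = 1e-10)
})

test_that("algebraic invariants hold on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    p <- sample(1:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rnorm(n)
    f <- ols_solve(X, y)
    expect_equal(f$rss, sum(f$residuals^2), tolerance = 1e-12)
    expect_lt(max(abs(crossprod(X, f$residuals))), 1e-8)
    expect_true(all(f$hat_diag >= -1e-12 & f$hat_diag <= 1 + 1e-12))
    expect_equal(sum(f$hat_diag), f$p, tolerance = 1e-10)
    expect_true(f$r2_adj <= f$r2 + 1e-12 && f$r2 <= 1 + 1e-12)
  }
})

test_that("rank-deficient and undersized problems are rejected or pinv-solved", {
  X <- cbind(1, 1:5, 2 * (1:5))
  expect_error(ols_solve(X, rnorm(5)), "rank-deficient")
  f <- ols_solve(X, rnorm(5), rank_policy = "pinv")
  expect_equal(f$p, 2)
  expect_equal(f$df_resid, 3)
  expect_error(ols_solve(matrix(rnorm(4), 2, 2), c(1, 2)),
               "not enough observations")
  expect_error(ols_solve(matrix(1, 3, 1), c(1, NA, 3)), "finite")
})

test_that("intercept-only grid fit equals the average ERP at every cell", {
  ep <- simulate_epochs(recovery_spec(n_epochs = 30, seed = 5))
  g <- fit_grid(ep, "~ 1")
  sc <- attr(ep, "schema")
  df <- as.data.frame(ep)
  for (ci in seq_along(g$channels)) {
    means <- tapply(df[[g$channels[ci]]], df[[sc$time]], mean)
    b0 <- vapply(seq_along(g$times), function(ti)
      unname(g$cells[[ti, ci]]$beta[1]), 0)
    expect_lt(max(abs(b0 - unname(means[as.character(g$times)]))), 1e-12)
  }
})

test_that("noiseless synthetic data is fit exactly", {
  spec <- recovery_spec(n_epochs = 24, seed = 8, noise_sd = 0)
  ep <- simulate_epochs(spec)
  g <- fit_grid(ep, "~ 1 + a")
  truth <- true_beta_waveforms(spec)
  for (ci in seq_along(g$channels)) {
    for (ti in seq_along(g$times)) {
      cell <- g$cells[[ti, ci]]
      expect_lt(max(abs(cell$residuals)), 1e-10)
      expect_equal(unname(cell$beta),
                   c(truth[["(Intercept)"]][ti, ci],
                     truth[["a[target]"]][ti, ci]),
                   tolerance = 1e-9)
    }
  }
})

test_that("shared-design fast path equals per-cell standalone fits exactly", {
  ep <- simulate_epochs(recovery_spec(n_epochs = 16, seed = 2))
  g <- fit_grid(ep, "~ 1 + a")
  expect_true(g$shared_design)
  sc <- attr(ep, "schema")
  df <- as.data.frame(ep)
  pred <- df[!duplicated(df$epoch_id), "a", drop = FALSE]
  X <- build_design_matrix("~ 1 + a", pred)
  set.seed(77)
  for (k in 1:8) {
    ti <- sample(length(g$times), 1)
    ci <- sample(length(g$channels), 1)
    y <- df[[g$channels[ci]]][df$time == g$times[ti]]
    standalone <- ols_solve(X, y)
    expect_identical(g$cells[[ti, ci]]$beta, standalone$beta)
    expect_identical(g$cells[[ti, ci]]$aic, standalone$aic)
    expect_identical(g$cells[[ti, ci]]$cooks_d, standalone$cooks_d)
  }
})

test_that("results do not depend on the worker count", {
  ep <- simulate_epochs(recovery_spec(n_epochs = 12, seed = 6,
                                      channels = paste0("ch", 1:4)))
  g1 <- fit_grid(ep, "~ 1 + a", workers = 1)
  g4 <- fit_grid(ep, "~ 1 + a", workers = 4)
  expect_identical(g1$cells, g4$cells)
})

test_that("time-varying predictors take the general path and match per-time fits", {
  set.seed(9)
  n_ep <- 12; times <- c(0, 1, 2, 3)
  df <- expand.grid(time = times, epoch_id = seq_len(n_ep))
  df$x <- rnorm(nrow(df))  # varies within epoch
  df$ch1 <- rnorm(nrow(df))
  ep <- epochs_table(df, channels = "ch1", predictors = "x")
  g <- fit_grid(ep, "~ 1 + x")
  expect_false(g$shared_design)
  for (ti in seq_along(times)) {
    rows <- df[df$time == times[ti], ]
    rows <- rows[order(rows$epoch_id), ]
    ref <- ols_solve(build_design_matrix("~ 1 + x", rows["x"]), rows$ch1)
    expect_equal(g$cells[[ti, 1]]$beta, ref$beta, tolerance = 1e-12)
  }
})

test_that("estimation error shrinks with the square-root law in epochs", {
  err_at <- function(n_epochs) {
    errs <- vapply(1:6, function(s) {
      spec <- recovery_spec(n_epochs = n_epochs, seed = 100 + s)
      ep <- simulate_epochs(spec)
      g <- fit_grid(ep, "~ 1 + a")
      truth <- true_beta_waveforms(spec)[["a[target]"]]
      est <- vapply(seq_along(g$channels), function(ci)
        mean(abs(vapply(seq_along(g$times), function(ti)
          unname(g$cells[[ti, ci]]$beta[2]), 0) - truth[, ci])), 0)
      mean(est)
    }, 0)
    mean(errs)
  }
  ratio <- err_at(50) / err_at(200)
  expect_gt(ratio, 2 * 0.75)
  expect_lt(ratio, 2 * 1.25)
})
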