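# Independent oracles and fixture builders, used only by the tests.

# Moore-Penrose pseudo-inverse via SVD (brute-force reference path).
pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- .Machine$double.eps * max(dim(X)) * s$d[1]
  keep <- s$d > tol
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Full OLS statistics recomputed from definitional formulas through the
# pseudo-inverse (independent of the package's QR path).
oracle_ols <- function(X, y) {
  n <- nrow(X)
  s <- svd(X)
  tol <- .Machine$double.eps * max(dim(X)) * s$d[1]
  p <- sum(s$d > tol)
  Xp <- pinv(X)
  beta <- drop(Xp %*% y)
  H <- X %*% Xp
  hat <- diag(H)
  fitted <- drop(X %*% beta)
  residuals <- y - fitted
  rss <- sum(residuals^2)
  df_resid <- n - p
  sigma2 <- rss / df_resid
  xtxinv <- Xp %*% t(Xp)  # pinv(X'X) = pinv(X) pinv(X)'
  se <- sqrt(sigma2 * diag(xtxinv))
  tvalues <- beta / se
  pvalues <- 2 * stats::pt(-abs(tvalues), df = df_resid)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  K <- p + 1
  has_int <- any(apply(X, 2, function(v) all(v == v[1]) && v[1] != 0))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - as.integer(has_int)) / df_resid
  list(beta = beta, se = se, tvalues = tvalues, pvalues = pvalues,
       residuals = residuals, rss = rss, sigma2 = sigma2, loglik = loglik,
       aic = 2 * K - 2 * loglik, bic = K * log(n) - 2 * loglik,
       r2 = r2, r2_adj = r2_adj, df_resid = df_resid, n = n, p = p,
       hat_diag = hat,
       cooks_d = residuals^2 / (p * sigma2) * hat / (1 - hat)^2)
}

# Cook's distance by literal leave-one-out refitting:
# D_i = (beta - beta_(i))' X'X (beta - beta_(i)) / (p * s^2)
oracle_cooks_loo <- function(X, y) {
  n <- nrow(X)
  p <- qr(X)$rank
  beta <- drop(pinv(X) %*% y)
  s2 <- sum((y - X %*% beta)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    bi <- drop(pinv(X[-i, , drop = FALSE]) %*% y[-i])
    d <- beta - bi
    drop(t(d) %*% crossprod(X) %*% d) / (p * s2)
  }, 0)
}

# Textbook Cox-de Boor recursion, scalar and recursive (independent of the
# package's iterative implementation). Right-open intervals: valid strictly
# inside the knot span.
oracle_bspline_point <- function(x, i, d, knots) {
  if (d == 0) {
    return(as.numeric(x >= knots[i] && x < knots[i + 1]))
  }
  den1 <- knots[i + d] - knots[i]
  den2 <- knots[i + d + 1] - knots[i + 1]
  a <- if (den1 > 0)
    (x - knots[i]) / den1 * oracle_bspline_point(x, i, d - 1, knots) else 0
  b <- if (den2 > 0)
    (knots[i + d + 1] - x) / den2 *
      oracle_bspline_point(x, i + 1, d - 1, knots) else 0
  a + b
}

# Naive index-by-index wide-design constructor (double loop).
oracle_wide_design <- function(Xep, L) {
  n_ep <- nrow(Xep)
  P <- ncol(Xep)
  W <- matrix(0, n_ep * L, L * P)
  for (e in seq_len(n_ep)) {
    for (l in seq_len(L)) {
      row <- (e - 1) * L + l
      for (p in seq_len(P)) {
        W[row, (l - 1) * P + p] <- Xep[e, p]
      }
    }
  }
  W
}

# Small random epochs table with one categorical and one numeric predictor.
random_epochs <- function(n_epochs = 6, n_times = 5, n_channels = 3,
                          seed = 42) {
  set.seed(seed)
  times <- seq(0, by = 0.01, length.out = n_times)
  df <- expand.grid(time = times, epoch_id = seq_len(n_epochs))
  cond <- sample(rep_len(c("lo", "hi"), n_epochs))
  df$cond <- cond[df$epoch_id]
  xval <- rnorm(n_epochs)
  df$x <- xval[df$epoch_id]
  chans <- paste0("ch", seq_len(n_channels))
  for (ch in chans) df[[ch]] <- rnorm(nrow(df))
  epochs_table(df, channels = chans, predictors = c("cond", "x"))
}

# Simulation spec used across tests: compact two-channel montage, balanced
# binary stimulus factor, a 3-unit effect bump on unit noise.
recovery_spec <- function(n_epochs = 200, seed = 1, noise_sd = 1,
                          channels = c("cz", "pz")) {
  simulation_spec(
    n_epochs = n_epochs,
    time_start = 0, time_stop = 0.6, time_step = 0.01,
    channels = channels,
    predictors = list(a = c("standard", "target")),
    formula = "~ 1 + a",
    beta_waveforms = list(
      "(Intercept)" = list(component_spec(0.1, 0.04, 2,
                                          rep(1, length(channels)))),
      "a[target]" = list(component_spec(0.35, 0.08, 3,
                                     rep(1, length(channels))))),
    noise_sd = noise_sd, seed = seed)
}
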