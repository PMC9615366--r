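#' Ordinary least squares with the full statistics catalogue
#'
#' Solves `min ||y - X beta||^2` by column-pivoted orthogonal (QR)
#' decomposition -- never via an explicit normal-equations inverse -- and
#' returns every per-fit quantity the grid machinery broadcasts: coefficients,
#' standard errors, t and two-sided p values, residuals, RSS, the Gaussian
#' maximum-likelihood log-likelihood, AIC/BIC, R-squared, leverages and
#' Cook's distances.
#'
#' Conventions (stated because they differ across ecosystems):
#' * `loglik = -n/2 * (log(2*pi) + log(RSS/n) + 1)` (Gaussian MLE);
#' * `AIC = 2K - 2*loglik` with `K = p + 1`, counting the error variance as an
#'   estimated parameter; `BIC = K*log(n) - 2*loglik`;
#' * `sigma2 = RSS / (n - p)` with `p` the design rank;
#' * p-values are two-sided from the t distribution on `n - p` df;
#' * `cooks_d_i = e_i^2 / (p * sigma2) * h_ii / (1 - h_ii)^2`.
#'
#' Numerical rank is decided by the singular-value threshold
#' `eps * max(n, p) * sigma_max`. Under the default `rank_policy = "error"` a
#' rank-deficient design is rejected; `"pinv"` instead returns the minimum-norm
#' solution from the SVD pseudo-inverse, with `p` equal to the numerical rank.
#'
#' @param X A `design_matrix` (from [build_design_matrix()]) or a plain
#'   numeric matrix.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param rank_policy `"error"` or `"pinv"`.
#' @return A `cell_fit` list; see Details for the fields.
#' @examples
#' X <- cbind(1, c(-1, 0, 1, 2))
#' fit <- ols_solve(X, c(0.1, 0.2, 0.8, 1.1))
#' fit$beta
#' @export
ols_solve <- function(X, y, rank_policy = c("error", "pinv")) {
  rank_policy <- match.arg(rank_policy)
  ctx <- ols_context(X, rank_policy = rank_policy)
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("response must be finite numeric", call. = FALSE)
  }
  if (length(y) != ctx$n) {
    stop("length(y) = ", length(y), " does not match nrow(X) = ", ctx$n,
         call. = FALSE)
  }
  ols_cell(ctx, y)
}

# Precompute everything that depends on X alone, so a shared design pays the
# decomposition cost once for all (time, channel) cells.
ols_context <- function(X, rank_policy = "error") {
  if (inherits(X, "design_matrix")) {
    has_intercept <- X$has_intercept
    X <- X$matrix
  } else {
    X <- as.matrix(X)
    # intercept detection for R^2 centering: any constant non-zero column
    has_intercept <- any(apply(X, 2, function(v)
      all(v == v[1]) && v[1] != 0))
  }
  storage.mode(X) <- "double"
  n <- nrow(X)
  pc <- ncol(X)
  if (n < 1 || pc < 1) stop("empty design matrix", call. = FALSE)
  rk <- matrix_rank(X)
  if (rk < pc && rank_policy == "error") {
    stop("rank-deficient design (rank ", rk, " < ", pc, " columns); ",
         "aliased column(s): ",
         paste(aliased_columns(X, rk), collapse = ", "), call. = FALSE)
  }
  if (n - rk < 1) {
    stop("not enough observations: n = ", n, " <= rank = ", rk, call. = FALSE)
  }
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(pc))

  if (rk == pc) {
    qrX <- qr(X, LAPACK = TRUE)
    Q1 <- qr.Q(qrX)
    hat <- rowSums(Q1^2)
    R <- qr.R(qrX)
    Rinv <- backsolve(R, diag(pc))
    xtxinv <- tcrossprod(Rinv)
    piv <- qrX$pivot
    unpiv <- order(piv)
    xtxinv_diag <- diag(xtxinv)[unpiv]
    solve_fun <- function(y) {
      b <- qr.coef(qrX, y)
      names(b) <- cn
      b
    }
  } else {
    s <- svd(X)
    tol <- .Machine$double.eps * max(n, pc) * s$d[1]
    keep <- s$d > tol
    U1 <- s$u[, keep, drop = FALSE]
    V1 <- s$v[, keep, drop = FALSE]
    d1 <- s$d[keep]
    hat <- rowSums(U1^2)
    xtxinv_diag <- rowSums(sweep(V1, 2, d1^2, "/") * V1)
    solve_fun <- function(y) {
      b <- drop(V1 %*% (crossprod(U1, y) / d1))
      names(b) <- cn
      b
    }
  }
  list(X = X, n = n, p = rk, n_columns = pc, coef_names = cn,
       has_intercept = has_intercept, hat = hat,
       xtxinv_diag = xtxinv_diag, solve_fun = solve_fun)
}

# One cell's complete statistics given a precomputed context.
ols_cell <- function(ctx, y) {
  n <- ctx$n
  p <- ctx$p
  beta <- ctx$solve_fun(y)
  fitted <- drop(ctx$X %*% beta)
  residuals <- y - fitted
  rss <- sum(residuals^2)
  df_resid <- n - p
  sigma2 <- rss / df_resid
  se <- sqrt(sigma2 * ctx$xtxinv_diag)
  tvalues <- beta / se
  pvalues <- 2 * stats::pt(-abs(tvalues), df = df_resid)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  K <- p + 1
  aic <- 2 * K - 2 * loglik
  bic <- K * log(n) - 2 * loglik
  tss <- if (ctx$has_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - rss / tss
  df_int <- if (ctx$has_intercept) 1 else 0
  r2_adj <- 1 - (1 - r2) * (n - df_int) / df_resid
  hat <- ctx$hat
  cooks_d <- residuals^2 / (p * sigma2) * hat / (1 - hat)^2
  structure(list(
    beta = beta, se = se, tvalues = tvalues, pvalues = pvalues,
    residuals = residuals, fitted = fitted, rss = rss, sigma2 = sigma2,
    loglik = loglik, aic = aic, bic = bic, r2 = r2, r2_adj = r2_adj,
    df_resid = df_resid, n = n, p = p, hat_diag = hat, cooks_d = cooks_d
  ), class = "cell_fit")
}

#' @export
print.cell_fit <- function(x, ...) {
  cat(sprintf("<cell_fit> n = %d, p = %d, rss = %.6g, aic = %.6g\n",
              x$n, x$p, x$rss, x$aic))
  print(cbind(beta = x$beta, se = x$se, t = x$tvalues, p = x$pvalues))
  invisible(x)
}

#' Fit a regression model at every (time, channel) cell
#'
#' The workhorse: for each time point and channel of an epochs table, fits the
#' model given by `formula` to the across-epoch observations at that cell and
#' collects the complete [ols_solve()] statistics into a [fit_grid] container.
#' With an intercept-only formula `"~ 1"` the estimated constant at each cell
#' is exactly the across-epoch mean -- the classical average ERP -- so the
#' average ERP is the simplest regression ERP.
#'
#' When every predictor is constant within each epoch (the shared-design case,
#' detected automatically, never assumed), the design matrix is compiled and
#' decomposed once and reused for every cell; results are identical to the
#' general per-time-point path and to any worker count.
#'
#' @param epochs An `epochs_table`.
#' @param formula Formula string or `rerp_formula`.
#' @param channels Optional subset of channel names (default: all, in schema
#'   order).
#' @param times Optional closed interval `c(lo, hi)` restricting time values.
#' @param coding A [coding_scheme()].
#' @param rank_policy `"error"` or `"pinv"`.
#' @param workers Number of parallel workers (forked, split by channel;
#'   results are gathered into canonical time-by-channel order, so the output
#'   does not depend on the worker count).
#' @param model_label Label recorded on the grid (defaults to the formula
#'   text).
#' @return A `fit_grid`.
#' @export
fit_grid <- function(epochs, formula, channels = NULL, times = NULL,
                     coding = coding_scheme(),
                     rank_policy = c("error", "pinv"),
                     workers = 1L, model_label = NULL) {
  rank_policy <- match.arg(rank_policy)
  sc <- epochs_schema(epochs)
  report <- validate_epochs(epochs)
  if (!report$ok) {
    stop("epochs table failed validation:\n",
         paste0("  - ", report$issues$message, collapse = "\n"), call. = FALSE)
  }
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(model_label)) model_label <- formula$text

  all_channels <- sc$channels
  if (is.null(channels)) channels <- all_channels
  bad <- setdiff(channels, all_channels)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tvals <- epoch_times(epochs)
  if (!is.null(times)) {
    stopifnot(length(times) == 2)
    tvals <- tvals[tvals >= times[1] & tvals <= times[2]]
    if (length(tvals) == 0) stop("empty time selection", call. = FALSE)
  }
  if (length(channels) == 0) stop("empty channel selection", call. = FALSE)

  df <- as.data.frame(epochs)
  df <- df[df[[sc$time]] %in% tvals, , drop = FALSE]
  df <- df[order(df[[sc$epoch]], df[[sc$time]]), , drop = FALSE]
  ep_ids <- sort(unique(df[[sc$epoch]]))
  n_epochs <- length(ep_ids)
  n_times <- length(tvals)

  shared <- is_shared_design(df, sc)

  if (shared) {
    first_rows <- !duplicated(df[[sc$epoch]])
    pred_df <- df[first_rows, sc$predictors, drop = FALSE]
    design <- build_design_matrix(formula, pred_df, coding = coding,
                                  rank_policy = rank_policy)
    ctx <- ols_context(design, rank_policy = rank_policy)
    # channel column in (epoch, time) order -> n_epochs x n_times matrix
    y_mats <- lapply(channels, function(ch)
      t(matrix(df[[ch]], nrow = n_times, ncol = n_epochs)))
    names(y_mats) <- channels
    fit_channel <- function(ch) {
      Y <- y_mats[[ch]]
      lapply(seq_len(n_times), function(ti) ols_cell(ctx, Y[, ti]))
    }
    per_channel <- run_by_channel(channels, fit_channel, workers)
    designs <- design
  } else {
    # general path: one design per time point (predictors may vary over time)
    rows_by_time <- lapply(tvals, function(tv) which(df[[sc$time]] == tv))
    ctxs <- lapply(rows_by_time, function(idx) {
      d <- build_design_matrix(formula, df[idx, sc$predictors, drop = FALSE],
                               coding = coding, rank_policy = rank_policy)
      list(design = d, ctx = ols_context(d, rank_policy = rank_policy))
    })
    fit_channel <- function(ch) {
      v <- df[[ch]]
      lapply(seq_len(n_times), function(ti)
        ols_cell(ctxs[[ti]]$ctx, v[rows_by_time[[ti]]]))
    }
    per_channel <- run_by_channel(channels, fit_channel, workers)
    designs <- lapply(ctxs, `[[`, "design")
  }

  cells <- matrix(vector("list", n_times * length(channels)),
                  nrow = n_times, ncol = length(channels),
                  dimnames = list(NULL, channels))
  for (ci in seq_along(channels)) {
    cells[, ci] <- per_channel[[ci]]
  }

  p <- cells[[1, 1]]$p
  structure(list(
    times = tvals, channels = channels, cells = cells,
    model_label = model_label, formula = formula,
    formula_text = formula$text,
    n = n_epochs, p = p, coef_names = names(cells[[1, 1]]$beta),
    epoch_ids = ep_ids, shared_design = shared, design = designs
  ), class = "fit_grid")
}

# gather per-channel results deterministically regardless of worker count
run_by_channel <- function(channels, fit_channel, workers) {
  workers <- max(1L, as.integer(workers))
  if (workers > 1 && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(channels, fit_channel, mc.cores = workers,
                              mc.preschedule = TRUE)
    err <- vapply(res, inherits, TRUE, what = "try-error")
    if (any(err)) stop(attr(res[[which(err)[1]]], "condition"))
    res
  } else {
    lapply(channels, fit_channel)
  }
}

is_shared_design <- function(df, sc) {
  if (length(sc$predictors) == 0) return(TRUE)
  ep <- df[[sc$epoch]]
  all(vapply(sc$predictors, function(p) {
    all(vapply(split(df[[p]], ep),
               function(v) length(unique(v)) == 1, TRUE))
  }, TRUE))
}
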