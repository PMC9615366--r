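#' Mass model comparison across candidate grids
#'
#' Compares two or more candidate models fitted on the same epochs (same
#' times, channels, and per-cell observation count) cell by cell: per
#' (time, channel, model) the AIC, its delta to the per-cell minimum, the
#' log-likelihood and rank, and a selection flag. Selection picks the
#' smallest AIC; exact ties break toward fewer parameters, then earlier
#' position in `grids`. With `criterion = "aicc"` the small-sample corrected
#' criterion `AICc = AIC + 2K(K+1)/(n-K-1)` is used instead.
#'
#' @param grids List of `fit_grid` objects (length >= 2). Names, or the grids'
#'   `model_label`s, label the models.
#' @param criterion `"aic"` (default) or `"aicc"`.
#' @return A `comparison_grid`: tibble with columns `time`, `channel`,
#'   `model`, `aic`, `delta_aic`, `loglik`, `p`, `selected`, carrying the
#'   model labels in attribute `models`.
#' @export
compare_models <- function(grids, criterion = c("aic", "aicc")) {
  criterion <- match.arg(criterion)
  stopifnot(is.list(grids), length(grids) >= 2)
  lapply(grids, function(g) stopifnot(inherits(g, "fit_grid")))
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g$times, g1$times) ||
        !identical(g$channels, g1$channels)) {
      stop("grids have mismatched times or channels", call. = FALSE)
    }
    if (g$n != g1$n) {
      stop("grids were fit on different numbers of epochs (",
           g$n, " vs ", g1$n, ")", call. = FALSE)
    }
  }
  labels <- names(grids)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(grids, function(g) g$model_label, "")
  }
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels)
  }

  nt <- length(g1$times)
  nc <- length(g1$channels)
  nm <- length(grids)
  rows <- vector("list", nm)
  for (m in seq_len(nm)) {
    g <- grids[[m]]
    aic <- vapply(seq_len(nt * nc), function(k) g$cells[[k]]$aic, 0)
    ll <- vapply(seq_len(nt * nc), function(k) g$cells[[k]]$loglik, 0)
    if (criterion == "aicc") {
      K <- g$p + 1
      aic <- aic + 2 * K * (K + 1) / (g$n - K - 1)
    }
    # cells matrix is (time x channel), column-major over k
    rows[[m]] <- tibble::tibble(
      time = rep(g1$times, times = nc),
      channel = rep(g1$channels, each = nt),
      model = labels[m],
      aic = aic, loglik = ll, p = g$p, model_index = m
    )
  }
  long <- dplyr::bind_rows(rows)
  long <- dplyr::arrange(long, .data$time,
                         match(.data$channel, g1$channels),
                         .data$model_index)
  long <- dplyr::group_by(long, .data$time, .data$channel)
  long <- dplyr::mutate(long,
    delta_aic = .data$aic - min(.data$aic),
    selected = seq_along(.data$aic) ==
      order(.data$aic, .data$p, .data$model_index)[1]
  )
  long <- dplyr::ungroup(long)
  out <- long[, c("time", "channel", "model", "aic", "delta_aic",
                  "loglik", "p", "selected")]
  attr(out, "models") <- labels
  attr(out, "criterion") <- criterion
  class(out) <- c("comparison_grid", class(out))
  out
}

#' @export
print.comparison_grid <- function(x, ...) {
  counts <- table(x$model[x$selected])
  cat("<comparison_grid>", length(unique(x$time)), "times x",
      length(unique(x$channel)), "channels x",
      length(attr(x, "models")), "models\n")
  cat("selected per model:\n")
  print(counts)
  invisible(x)
}

#' Per-cell likelihood-ratio tests between nested models
#'
#' For each grid cell computes the likelihood-ratio statistic
#' `2 * (loglik_full - loglik_nested)`, its degrees of freedom
#' `p_full - p_nested`, and the upper-tail chi-squared p-value. Nesting is
#' verified numerically: every design column of the nested model must lie in
#' the column space of the full model (projection residual below `tol`),
#' which stays decidable in the presence of column transforms where symbolic
#' checks are not.
#'
#' @param nested,full `fit_grid` objects fitted on the same epochs.
#' @param tol Tolerance for the nesting (projection-residual) check.
#' @param p_adjust Optional p-value adjustment across cells (any method of
#'   [stats::p.adjust()], e.g. `"BH"`); default `"none"`.
#' @return Tibble with `time`, `channel`, `lr_statistic`, `lr_df`,
#'   `lr_pvalue` (plus `lr_pvalue_adj` when adjusted).
#' @export
likelihood_ratio <- function(nested, full, tol = 1e-8, p_adjust = "none") {
  stopifnot(inherits(nested, "fit_grid"), inherits(full, "fit_grid"))
  if (!identical(nested$times, full$times) ||
      !identical(nested$channels, full$channels) || nested$n != full$n) {
    stop("grids have mismatched shape or epoch count", call. = FALSE)
  }
  df_lr <- full$p - nested$p
  if (df_lr < 0) {
    stop("'full' model has fewer parameters than 'nested'", call. = FALSE)
  }
  check_nested_designs(nested, full, tol)

  nt <- length(full$times)
  nc <- length(full$channels)
  stat <- numeric(nt * nc)
  for (k in seq_len(nt * nc)) {
    stat[k] <- 2 * (full$cells[[k]]$loglik - nested$cells[[k]]$loglik)
  }
  # clip tiny negative round-off (identical models give exactly 0 up to fp)
  stat[stat < 0 & stat > -1e-10] <- 0
  if (any(stat < 0)) {
    stop("negative likelihood-ratio statistic beyond round-off: ",
         "models do not appear nested on the same data", call. = FALSE)
  }
  pval <- if (df_lr == 0) as.numeric(stat <= 0) * 0 + 1 else
    stats::pchisq(stat, df = df_lr, lower.tail = FALSE)
  out <- tibble::tibble(
    time = rep(full$times, times = nc),
    channel = rep(full$channels, each = nt),
    lr_statistic = stat, lr_df = df_lr, lr_pvalue = pval
  )
  out <- dplyr::arrange(out, .data$time, match(.data$channel, full$channels))
  if (!identical(p_adjust, "none")) {
    out$lr_pvalue_adj <- stats::p.adjust(out$lr_pvalue, method = p_adjust)
  }
  out
}

# every nested design column must project onto the full design's column space
check_nested_designs <- function(nested, full, tol) {
  pairs <- if (nested$shared_design && full$shared_design) {
    list(list(nested$design$matrix, full$design$matrix))
  } else {
    dn <- if (nested$shared_design)
      rep(list(nested$design), length(nested$times)) else nested$design
    dfu <- if (full$shared_design)
      rep(list(full$design), length(full$times)) else full$design
    Map(function(a, b) list(a$matrix, b$matrix), dn, dfu)
  }
  for (pr in pairs) {
    Xn <- pr[[1]]; Xf <- pr[[2]]
    qf <- qr(Xf)
    resid <- qr.resid(qf, Xn)
    rel <- max(abs(resid)) / max(1, max(abs(Xn)))
    if (rel > tol) {
      stop("models are not nested: projection residual ",
           format(rel, digits = 3), " exceeds tolerance ", tol,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
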