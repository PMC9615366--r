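#' Wide L-by-P continuous-data design
#'
#' Recodes a rectangular, shared-design epochs table for a single stacked OLS
#' fit: the `L` time points of each epoch are unstacked into `L * P`
#' predictor columns (`P` = columns of the per-epoch design). The stacked
#' data has one row per (epoch, time) observation; the row for epoch `e` at
#' latency `l` carries that epoch's design row in latency block `l` and zeros
#' everywhere else. One OLS fit on this wide matrix recovers, coefficient for
#' coefficient, the per-time-point estimates of the segmented grid fits --
#' the two formulations are mathematically identical because the wide normal
#' equations are block-diagonal by latency.
#'
#' This module exists as a verification device for that identity, not as a
#' performance path: the grid formulation is the natural one for tracking all
#' fit attributes over time, and the wide matrix is built dense.
#'
#' @param epochs A shared-design `epochs_table` (predictors constant within
#'   epoch).
#' @param formula Formula string or `rerp_formula`.
#' @param coding A [coding_scheme()].
#' @return A `wide_design`: list with `matrix` (`n_epochs*L` rows,
#'   `L*P` columns), `column_labels` (tibble of `time`, `predictor` per
#'   column), `times`, `L`, `P`, `epoch_ids`, `responses` (named list of
#'   stacked response vectors per channel, in (epoch, time) row order).
#' @export
build_wide_design <- function(epochs, formula, coding = coding_scheme()) {
  sc <- epochs_schema(epochs)
  report <- validate_epochs(epochs)
  if (!report$ok) {
    stop("epochs table failed validation (wide design needs a rectangular ",
         "panel)", call. = FALSE)
  }
  if (is.character(formula)) formula <- parse_formula(formula)
  df <- as.data.frame(epochs)
  df <- df[order(df[[sc$epoch]], df[[sc$time]]), , drop = FALSE]
  if (!is_shared_design(df, sc)) {
    stop("wide formulation requires predictors constant within epoch",
         call. = FALSE)
  }
  tvals <- epoch_times(epochs)
  L <- length(tvals)
  ep_ids <- sort(unique(df[[sc$epoch]]))
  n_ep <- length(ep_ids)

  pred_df <- df[!duplicated(df[[sc$epoch]]), sc$predictors, drop = FALSE]
  design <- build_design_matrix(formula, pred_df, coding = coding)
  Xep <- design$matrix
  P <- ncol(Xep)

  # rows in (epoch, time) order; column block l holds the epoch design row
  W <- matrix(0, nrow = n_ep * L, ncol = L * P)
  for (l in seq_len(L)) {
    rows <- (seq_len(n_ep) - 1) * L + l
    cols <- (l - 1) * P + seq_len(P)
    W[rows, cols] <- Xep
  }
  labels <- tibble::tibble(
    time = rep(tvals, each = P),
    predictor = rep(design$column_names, times = L)
  )
  colnames(W) <- paste0("t", rep(seq_len(L), each = P), ":",
                        labels$predictor)
  responses <- lapply(sc$channels, function(ch) df[[ch]])
  names(responses) <- sc$channels

  structure(list(matrix = W, column_labels = labels, times = tvals,
                 L = L, P = P, epoch_ids = ep_ids,
                 predictor_names = design$column_names,
                 responses = responses),
            class = "wide_design")
}

#' @export
print.wide_design <- function(x, ...) {
  cat(sprintf("<wide_design> %d x %d (L = %d latencies x P = %d predictors)\n",
              nrow(x$matrix), ncol(x$matrix), x$L, x$P))
  invisible(x)
}

#' Fit the wide continuous formulation
#'
#' Single OLS fit of a stacked response on the wide L-by-P design; the
#' coefficient vector is reshaped to an L x P matrix of per-latency
#' coefficients. Only coefficients are reported: residual-variance pooling
#' differs between the wide and segmented formulations, so standard errors
#' are deliberately not compared.
#'
#' @param wide A `wide_design`.
#' @param y Stacked response vector in (epoch, time) order, e.g. one entry of
#'   `wide$responses`.
#' @return Tibble with columns `time`, one column per predictor coefficient.
#' @export
fit_continuous <- function(wide, y) {
  stopifnot(inherits(wide, "wide_design"))
  if (length(y) != nrow(wide$matrix)) {
    stop("stacked response length ", length(y), " != ", nrow(wide$matrix),
         " rows", call. = FALSE)
  }
  rk <- matrix_rank(wide$matrix)
  if (rk < ncol(wide$matrix)) {
    stop("wide design is rank deficient (e.g. an empty latency cell)",
         call. = FALSE)
  }
  beta <- qr.coef(qr(wide$matrix, LAPACK = TRUE), y)
  B <- matrix(beta, nrow = wide$L, ncol = wide$P, byrow = TRUE)
  out <- tibble::as_tibble(B, .name_repair = "minimal")
  names(out) <- wide$predictor_names
  dplyr::bind_cols(tibble::tibble(time = wide$times), out)
}

#' Verify segmented/continuous coefficient identity
#'
#' Runs both formulations on the same epochs -- the per-time-point grid fits
#' and the single wide stacked fit -- and reports the maximum absolute
#' coefficient discrepancy over all latencies, predictors and channels. By
#' the block-diagonal structure of the wide normal equations this should be
#' at numerical round-off (well below 1e-8 on well-conditioned data).
#'
#' @param epochs A shared-design `epochs_table`.
#' @param formula Formula string or `rerp_formula`.
#' @param coding A [coding_scheme()].
#' @return List with `max_abs_diff` and a tibble `by_channel` of per-channel
#'   maxima.
#' @export
verify_continuous <- function(epochs, formula, coding = coding_scheme()) {
  wide <- build_wide_design(epochs, formula, coding = coding)
  grid <- fit_grid(epochs, formula, coding = coding)
  per_channel <- vapply(grid$channels, function(ch) {
    cw <- fit_continuous(wide, wide$responses[[ch]])
    ci <- match(ch, grid$channels)
    seg <- do.call(rbind, lapply(seq_along(grid$times),
                                 function(ti) grid$cells[[ti, ci]]$beta))
    max(abs(as.matrix(cw[, grid$coef_names]) - seg))
  }, 0)
  list(max_abs_diff = max(per_channel),
       by_channel = tibble::tibble(channel = grid$channels,
                                   max_abs_diff = unname(per_channel)))
}
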