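#' The fit grid container
#'
#' A `fit_grid` holds one complete OLS fit per (time, channel) cell, plus the
#' time index, channel order (schema order, i.e. montage order -- never
#' alphabetized), the model formula, and the design matrix (or per-time
#' designs on the general path). All cells share the same number of
#' observations, rank, and coefficient labels. Attribute access is broadcast
#' over the whole grid by [get_attribute()]; sub-grids are taken with
#' [slice_grid()].
#'
#' @name fit_grid
NULL

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf("<fit_grid> %d times x %d channels | model: %s\n",
              length(x$times), length(x$channels), x$model_label))
  cat(sprintf("  n = %d epochs, p = %d (%s)\n", x$n, x$p,
              paste(x$coef_names, collapse = ", ")))
  cat(sprintf("  time range [%g, %g], channels: %s\n",
              min(x$times), max(x$times),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# attribute name -> shape class
grid_attribute_shapes <- function() {
  list(
    scalar = c("rss", "sigma2", "loglik", "aic", "bic", "r2", "r2_adj",
               "df_resid", "n", "p"),
    coefficient = c("beta", "se", "tvalues", "pvalues"),
    observation = c("residuals", "fitted", "hat_diag", "cooks_d")
  )
}

#' Broadcast one fit attribute over the grid as a tidy table
#'
#' Extracts a per-cell fit statistic from every cell of the grid and returns
#' it as a long-format tibble in canonical order (time, then channel, then any
#' inner key). Scalar statistics (`aic`, `rss`, `loglik`, ...) key by
#' `(time, channel)`; per-coefficient statistics (`beta`, `se`, `tvalues`,
#' `pvalues`) add a `coefficient` key; per-observation statistics
#' (`residuals`, `fitted`, `hat_diag`, `cooks_d`) add an `epoch_id` key.
#'
#' @param grid A `fit_grid`.
#' @param name Attribute name; unknown names raise an error listing the
#'   available ones.
#' @return A tibble with attribute `rerp_attribute` = `name`.
#' @export
get_attribute <- function(grid, name) {
  stopifnot(inherits(grid, "fit_grid"))
  shapes <- grid_attribute_shapes()
  all_names <- unlist(shapes, use.names = FALSE)
  if (!name %in% all_names) {
    stop("unknown attribute '", name, "'; available: ",
         paste(sort(all_names), collapse = ", "), call. = FALSE)
  }
  nt <- length(grid$times)
  nc <- length(grid$channels)
  shape <- if (name %in% shapes$scalar) "scalar" else
    if (name %in% shapes$coefficient) "coefficient" else "observation"
  inner <- switch(shape,
    scalar = 1L,
    coefficient = length(grid$coef_names),
    observation = grid$n)

  # cell (ti, ci) values, inner fastest; cells iterated channel-within-time
  vals <- numeric(nt * nc * inner)
  k <- 0L
  for (ti in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      v <- grid$cells[[ti, ci]][[name]]
      vals[k + seq_len(inner)] <- v
      k <- k + inner
    }
  }
  out <- tibble::tibble(
    time = rep(grid$times, each = nc * inner),
    channel = rep(rep(grid$channels, each = inner), times = nt)
  )
  if (shape == "coefficient") {
    out$coefficient <- rep(grid$coef_names, times = nt * nc)
  } else if (shape == "observation") {
    out$epoch_id <- rep(grid$epoch_ids, times = nt * nc)
  }
  out$value <- vals
  attr(out, "rerp_attribute") <- name
  out
}

#' Slice a fit grid by time interval and channel subset
#'
#' Time slicing is by closed interval on time values (robust to sampling
#' rate), not by positional index; channels are selected by name and returned
#' in the grid's canonical (montage) order. Slicing commutes with
#' [get_attribute()], and composed slices equal a single slice with the
#' intersected selections.
#'
#' @param grid A `fit_grid`.
#' @param time_range `c(lo, hi)` closed interval, or `NULL` for all times.
#' @param channels Character vector of channel names, or `NULL` for all.
#' @return A `fit_grid` over the selected cells.
#' @export
slice_grid <- function(grid, time_range = NULL, channels = NULL) {
  stopifnot(inherits(grid, "fit_grid"))
  ti <- seq_along(grid$times)
  if (!is.null(time_range)) {
    stopifnot(length(time_range) == 2)
    ti <- which(grid$times >= time_range[1] & grid$times <= time_range[2])
    if (length(ti) == 0) stop("empty time selection", call. = FALSE)
  }
  ci <- seq_along(grid$channels)
  if (!is.null(channels)) {
    bad <- setdiff(channels, grid$channels)
    if (length(bad)) stop("unknown channel(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    ci <- which(grid$channels %in% channels)
    if (length(ci) == 0) stop("empty channel selection", call. = FALSE)
  }
  out <- grid
  out$times <- grid$times[ti]
  out$channels <- grid$channels[ci]
  out$cells <- grid$cells[ti, ci, drop = FALSE]
  if (!grid$shared_design) out$design <- grid$design[ti]
  out
}

#' Export tidy attribute tables to CSV
#'
#' Writes each requested attribute as its own `<attribute>.csv` in `path`
#' (created if needed), or -- with `stacked = TRUE` -- one long CSV at `path`
#' with an `attribute` column and a character `key` column holding the inner
#' key (coefficient label or epoch id) where one exists. Row order is
#' canonical and deterministic, and the files round-trip through
#' [readr::read_csv()] at full precision.
#'
#' @param grid A `fit_grid`.
#' @param attributes Non-empty character vector of attribute names.
#' @param path Output directory (default) or file path (`stacked = TRUE`).
#' @param stacked Write one stacked CSV instead of one file per attribute.
#' @return Invisibly, the written file path(s).
#' @export
export_tidy <- function(grid, attributes, path, stacked = FALSE) {
  stopifnot(inherits(grid, "fit_grid"))
  if (length(attributes) == 0) {
    stop("no attributes requested: pass at least one attribute name",
         call. = FALSE)
  }
  tables <- lapply(attributes, function(a) get_attribute(grid, a))
  names(tables) <- attributes
  if (stacked) {
    long <- dplyr::bind_rows(lapply(attributes, function(a) {
      tb <- tables[[a]]
      key <- if ("coefficient" %in% names(tb)) as.character(tb$coefficient)
             else if ("epoch_id" %in% names(tb)) as.character(tb$epoch_id)
             else ""
      tibble::tibble(attribute = a, time = tb$time, channel = tb$channel,
                     key = key, value = tb$value)
    }))
    readr::write_csv(long, path, progress = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- vapply(attributes, function(a) {
    f <- file.path(path, paste0(a, ".csv"))
    readr::write_csv(tables[[a]], f, progress = FALSE)
    f
  }, "")
  invisible(files)
}

#' Plot coefficient waveforms with standard-error envelopes
#'
#' Renders the rERP waveforms: one panel per channel, the estimated
#' coefficient time series with a +/- `se_mult` standard-error ribbon, one
#' colour per coefficient. Requires ggplot2.
#'
#' @param grid A `fit_grid`.
#' @param coefficients Subset of coefficient labels (default all).
#' @param se_mult Half-width of the ribbon in standard errors.
#' @return A ggplot object.
#' @export
plot_rerp <- function(grid, coefficients = NULL, se_mult = 1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rerp() requires ggplot2", call. = FALSE)
  }
  b <- get_attribute(grid, "beta")
  s <- get_attribute(grid, "se")
  b$se <- s$value
  if (!is.null(coefficients)) {
    b <- b[b$coefficient %in% coefficients, , drop = FALSE]
  }
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$coefficient,
                                  fill = .data$coefficient)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - se_mult * .data$se,
                                      ymax = .data$value + se_mult * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time", y = "estimate")
}
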