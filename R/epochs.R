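#' Event-locked epochs tables
#'
#' An `epochs_table` is the long-format container every fitting routine in
#' rerpgrid consumes: one row per (epoch, time sample), with an integer epoch
#' identifier column, a numeric time column, zero or more predictor columns
#' (numeric or categorical, one value per row), and one or more numeric
#' channel columns holding the recorded response (e.g. microvolts).
#'
#' The table is a rectangular panel by contract: every epoch contains exactly
#' the same ordered set of time values, `(epoch, time)` pairs are unique, and
#' channel values are finite. Rows are stored in canonical order (epoch
#' ascending, then time ascending) so that file round trips and output hashes
#' are reproducible.
#'
#' @param data A data frame in long format.
#' @param epoch Name of the epoch identifier column.
#' @param time Name of the time column (numeric sample latency; units are the
#'   user's semantics -- milliseconds, seconds and sample counts are all fine).
#' @param channels Character vector of channel (response) column names.
#' @param predictors Character vector of predictor column names. Defaults to
#'   every remaining column, so the roles of all columns are always explicit.
#'
#' @return An `epochs_table` (a tibble with a `schema` attribute recording the
#'   column roles).
#' @examples
#' df <- expand.grid(epoch_id = 1:2, time = c(0, 10, 20))
#' df$ch1 <- rnorm(nrow(df))
#' ep <- epochs_table(df, channels = "ch1")
#' epoch_times(ep)
#' @export
epochs_table <- function(data, epoch = "epoch_id", time = "time",
                         channels, predictors = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(epoch, time, channels, predictors), names(data))
  if (length(missing_cols) > 0) {
    stop("schema error: column(s) not present in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(data), c(epoch, time, channels))
  }
  if (length(channels) < 1) {
    stop("schema error: at least one channel column is required", call. = FALSE)
  }
  # factors are stored as character so that file round trips are lossless
  for (p in predictors) {
    if (is.factor(data[[p]])) data[[p]] <- as.character(data[[p]])
  }
  data <- data[, c(epoch, time, predictors, channels)]
  data <- data[order(data[[epoch]], data[[time]]), , drop = FALSE]
  # rebuild from columns: sheds stray attributes (e.g. expand.grid's
  # out.attrs) so file round trips compare clean
  data <- tibble::as_tibble(lapply(stats::setNames(names(data), names(data)),
                                   function(nm) as.vector(data[[nm]])))
  out <- structure(
    data,
    schema = list(epoch = epoch, time = time,
                  predictors = predictors, channels = channels),
    class = c("epochs_table", class(data))
  )
  report <- validate_epochs(out)
  if (!report$ok) {
    stop("invalid epochs table:\n",
         paste0("  - ", report$issues$message, collapse = "\n"), call. = FALSE)
  }
  out
}

epochs_schema <- function(table) {
  sc <- attr(table, "schema")
  if (is.null(sc)) stop("not an epochs_table: no schema attribute", call. = FALSE)
  sc
}

#' @rdname epochs_table
#' @param table An `epochs_table`.
#' @export
epoch_times <- function(table) {
  sc <- epochs_schema(table)
  sort(unique(table[[sc$time]]))
}

#' @rdname epochs_table
#' @export
epoch_channels <- function(table) epochs_schema(table)$channels

#' @rdname epochs_table
#' @export
epoch_predictors <- function(table) epochs_schema(table)$predictors

#' @rdname epochs_table
#' @export
epoch_ids <- function(table) {
  sc <- epochs_schema(table)
  sort(unique(table[[sc$epoch]]))
}

#' @export
print.epochs_table <- function(x, ...) {
  sc <- epochs_schema(x)
  cat(sprintf("<epochs_table> %d epochs x %d times x %d channels\n",
              length(epoch_ids(x)), length(epoch_times(x)),
              length(sc$channels)))
  cat("predictors:",
      if (length(sc$predictors)) paste(sc$predictors, collapse = ", ") else "(none)",
      "\n")
  NextMethod()
  invisible(x)
}

#' Validate an epochs table
#'
#' Checks every structural invariant of the epochs contract -- rectangular
#' panel, unique `(epoch, time)` keys, finite channel values, non-empty
#' dimensions -- and reports all violations rather than stopping at the first.
#' Any table that validates cleanly is guaranteed to fit without structural
#' errors.
#'
#' @param table An `epochs_table` (or a data frame carrying a schema
#'   attribute).
#' @return A `validation_report`: a list with logical `ok` and an `issues`
#'   tibble with columns `severity`, `message`, `key`. `ok` is `TRUE` iff no
#'   issue has severity `"error"`.
#' @export
validate_epochs <- function(table) {
  sc <- epochs_schema(table)
  issues <- list()
  add <- function(message, key = "") {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = "error", message = message, key = key)
  }

  ep <- table[[sc$epoch]]
  tm <- table[[sc$time]]
  if (nrow(table) == 0) {
    add("table has zero rows; at least 1 epoch x 1 time x 1 channel required")
  }
  if (!is.numeric(tm)) add(sprintf("time column '%s' is not numeric", sc$time))

  if (nrow(table) > 0 && is.numeric(tm)) {
    key <- paste(ep, tm, sep = "\r")
    dup <- unique(key[duplicated(key)])
    for (d in dup) {
      parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
      add(sprintf("duplicated (epoch_id, time) pair: (%s, %s)",
                  parts[1], parts[2]),
          key = d)
    }
    # rectangularity: every epoch must carry the identical ordered time set
    times_by_epoch <- split(tm, ep)
    all_times <- sort(unique(tm))
    for (e in names(times_by_epoch)) {
      got <- sort(unique(times_by_epoch[[e]]))
      if (length(got) != length(all_times) || any(got != all_times)) {
        add(sprintf(
          "epoch %s is not rectangular: has %d of %d time points (missing: %s)",
          e, length(got), length(all_times),
          paste(utils::head(setdiff(all_times, got), 5), collapse = ", ")),
          key = e)
      }
    }
  }

  for (ch in sc$channels) {
    v <- table[[ch]]
    if (!is.numeric(v)) {
      add(sprintf("channel column '%s' is not numeric", ch), key = ch)
      next
    }
    bad <- which(!is.finite(v))
    for (i in utils::head(bad, 20)) {
      add(sprintf("non-finite value in channel '%s' at (epoch %s, time %s)",
                  ch, ep[i], tm[i]),
          key = paste(ep[i], tm[i], ch, sep = "\r"))
    }
    if (length(bad) > 20) {
      add(sprintf("channel '%s': %d further non-finite values", ch,
                  length(bad) - 20), key = ch)
    }
  }

  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(severity = character(), message = character(),
                   key = character())
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ok:", x$ok, "\n")
  if (nrow(x$issues)) {
    cat(paste0("  [", x$issues$severity, "] ", x$issues$message,
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read and write epochs files
#'
#' Epochs travel as delimited text (CSV or TSV) with a header row; the schema
#' maps column names to roles. `write_epochs` followed by `load_epochs` is the
#' identity on content to full numeric precision (values are serialized with
#' round-trip-exact formatting), and writing the reloaded table again yields a
#' byte-identical file.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param schema Named list with entries `epoch` (or `epoch_id`), `time`,
#'   `channels`, and optionally `predictors` mapping roles to column names.
#'   Omitted `predictors` means every remaining column.
#' @return `load_epochs` returns a validated `epochs_table`; `write_epochs`
#'   returns `path` invisibly.
#' @export
load_epochs <- function(path, dialect = c("csv", "tsv"), schema) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base parser: correctly-rounded double parsing, so written files reload
  # to full precision
  data <- utils::read.table(path, header = TRUE,
                            sep = if (dialect == "csv") "," else "\t",
                            quote = "\"", stringsAsFactors = FALSE,
                            check.names = FALSE)
  data <- tibble::as_tibble(data)
  epoch <- schema$epoch %||% schema$epoch_id %||% "epoch_id"
  time <- schema$time %||% "time"
  if (is.null(schema$channels)) {
    stop("schema error: schema must name at least one channel column",
         call. = FALSE)
  }
  epochs_table(data, epoch = epoch, time = time,
               channels = schema$channels, predictors = schema$predictors)
}

#' @rdname load_epochs
#' @param table An `epochs_table`.
#' @export
write_epochs <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  epochs_schema(table)  # assert it is an epochs table
  df <- tibble::as_tibble(as.data.frame(table))
  if (dialect == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Grid-size accounting
#'
#' The combinatorial load of mass univariate modeling: an epochs table with
#' `n_times` time points and `n_channels` channels yields
#' `n_cells = n_times * n_channels` per-cell datasets, and fitting `n_models`
#' candidate models requires `n_fits = n_cells * n_models` separate fits.
#' For example, 3 s of 32-channel data sampled at 250 Hz gives 750 x 32 =
#' 24,000 cells, and three candidate models then require 72,000 fits.
#'
#' @param table An `epochs_table`.
#' @param n_models Number of candidate models (positive integer).
#' @return Named list with `n_times`, `n_channels`, `n_cells`, `n_fits`.
#' @export
grid_dimensions <- function(table, n_models = 1L) {
  stopifnot(length(n_models) == 1, n_models >= 1)
  n_models <- as.integer(n_models)
  n_times <- length(epoch_times(table))
  n_channels <- length(epoch_channels(table))
  list(n_times = n_times, n_channels = n_channels,
       n_cells = n_times * n_channels,
       n_fits = n_times * n_channels * n_models)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
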