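#' Parse a Wilkinson-style model formula
#'
#' Compiles a formula string such as `"~ 1 + a + b + a:b"` into an explicit
#' term list. The grammar is deliberately small and closed:
#'
#' * `1` / `0` (or `- 1`) add / remove the intercept; the intercept is present
#'   by default,
#' * `+` separates terms,
#' * `a:b` is the pure interaction of `a` and `b`,
#' * `a*b` expands to `a + b + a:b` (crossing),
#' * a whitelist of column transforms may wrap a variable:
#'   `pow(x, k)`, `bspline(x, df, degree)`, `center(x)`, `scale(x)`, `log(x)`.
#'
#' No other function calls are accepted (no arbitrary code execution), and
#' random-effects terms such as `(a | s)` are recognized only to be rejected:
#' mixed-effects models are out of scope for this package. Duplicate terms
#' collapse, so expansion is idempotent: parsing the rendered form of a parsed
#' formula reproduces it exactly.
#'
#' @param text A formula string beginning with `~` (the response side is
#'   implicit: every fit applies to all selected channels).
#' @return An `rerp_formula`: list with `terms` (each term a list of factor
#'   specs), `has_intercept`, and the normalized `text`.
#' @examples
#' f <- parse_formula("~ a * b")
#' format(f)  # "~ 1 + a + b + a:b"
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  src <- text
  if (!grepl("^\\s*~", src)) {
    stop("formula must begin with '~' (got: ", src, ")", call. = FALSE)
  }
  if (grepl("\\|", src)) {
    stop("random-effects terms like '(a | s)' are not supported: ",
         "mixed models are out of scope", call. = FALSE)
  }
  toks <- tokenize_formula(sub("^\\s*~", "", src), src)
  st <- list(toks = toks, pos = 1L)

  peek <- function() if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
  advance <- function() st$pos <<- st$pos + 1L

  # factor := IDENT | TRANSFORM "(" IDENT ["," NUM]* ")"
  parse_factor <- function() {
    tk <- peek()
    if (is.null(tk)) stop_parse(src, NA, "unexpected end of formula")
    if (tk$type == "num") {
      advance()
      if (tk$text == "1") return(list(kind = "intercept"))
      if (tk$text == "0") return(list(kind = "nointercept"))
      stop_parse(src, tk$at, paste0("unexpected number '", tk$text, "'"))
    }
    if (tk$type != "ident") {
      stop_parse(src, tk$at, paste0("expected a variable name, got '", tk$text, "'"))
    }
    advance()
    nxt <- peek()
    if (!is.null(nxt) && nxt$type == "lparen") {
      fun <- tk$text
      allowed <- c("pow", "bspline", "center", "scale", "log")
      if (!fun %in% allowed) {
        stop_parse(src, tk$at, paste0(
          "unknown transform '", fun, "' (allowed: ",
          paste(allowed, collapse = ", "), ")"))
      }
      advance()  # consume "("
      vtk <- peek()
      if (is.null(vtk) || vtk$type != "ident") {
        stop_parse(src, if (is.null(vtk)) NA else vtk$at,
                   paste0("transform ", fun, "() needs a variable name argument"))
      }
      advance()
      args <- numeric()
      repeat {
        tk2 <- peek()
        if (is.null(tk2)) stop_parse(src, NA, "unclosed transform call")
        if (tk2$type == "rparen") { advance(); break }
        if (tk2$type == "comma") {
          advance()
          atk <- peek()
          if (is.null(atk) || atk$type != "num") {
            stop_parse(src, if (is.null(atk)) NA else atk$at,
                       "transform arguments after the variable must be numbers")
          }
          args <- c(args, as.numeric(atk$text))
          advance()
          next
        }
        stop_parse(src, tk2$at, paste0("unexpected '", tk2$text, "' in transform call"))
      }
      check_transform_args(fun, args, src)
      lbl <- if (length(args)) {
        paste0(fun, "(", vtk$text, ", ", paste(format_num(args), collapse = ", "), ")")
      } else paste0(fun, "(", vtk$text, ")")
      return(list(kind = "factor", var = vtk$text, transform = fun,
                  args = args, label = lbl))
    }
    list(kind = "factor", var = tk$text, transform = "identity",
         args = numeric(), label = tk$text)
  }

  # product := factor ( (":" | "*") factor )*
  # returns list(terms = list of factor-lists, intercept_flag)
  parse_product <- function() {
    f <- parse_factor()
    if (f$kind %in% c("intercept", "nointercept")) {
      tk <- peek()
      if (!is.null(tk) && tk$type %in% c("colon", "star")) {
        stop_parse(src, tk$at, "'1'/'0' cannot enter interactions")
      }
      return(list(marker = f$kind, terms = list()))
    }
    terms <- list(list(f))  # each term = list of factors
    repeat {
      tk <- peek()
      if (is.null(tk) || !(tk$type %in% c("colon", "star"))) break
      op <- tk$type
      advance()
      g <- parse_factor()
      if (g$kind != "factor") {
        stop_parse(src, tk$at, "'1'/'0' cannot enter interactions")
      }
      if (op == "colon") {
        # append g to every existing term (pure interaction)
        terms <- lapply(terms, function(tt) c(tt, list(g)))
      } else {
        # crossing: existing terms, the new main effect, and all products
        crossed <- lapply(terms, function(tt) c(tt, list(g)))
        terms <- c(terms, list(list(g)), crossed)
      }
    }
    list(marker = NULL, terms = terms)
  }

  has_intercept <- TRUE
  all_terms <- list()
  sign <- "+"
  expect_operand <- TRUE
  saw_operator <- FALSE
  repeat {
    tk <- peek()
    if (is.null(tk)) break
    if (tk$type %in% c("plus", "minus")) {
      if (expect_operand) stop_parse(src, tk$at, "two operators in a row")
      sign <- if (tk$type == "plus") "+" else "-"
      advance()
      expect_operand <- TRUE
      saw_operator <- TRUE
      next
    }
    if (!expect_operand) {
      stop_parse(src, tk$at, paste0("expected '+' before '", tk$text, "'"))
    }
    if (sign == "-") {
      if (tk$type == "num" && tk$text == "1") {
        has_intercept <- FALSE
        advance()
      } else {
        stop_parse(src, tk$at, "only '- 1' (intercept removal) may follow '-'")
      }
    } else {
      p <- parse_product()
      if (!is.null(p$marker)) {
        has_intercept <- (p$marker == "intercept")
      }
      all_terms <- c(all_terms, p$terms)
    }
    sign <- "+"
    expect_operand <- FALSE
    saw_operator <- FALSE
  }
  if (saw_operator) {
    stop_parse(src, NA, "dangling operator at end of formula")
  }

  # within a term, a repeated factor collapses (a:a == a); across terms,
  # duplicates (by canonical key) collapse keeping first appearance
  all_terms <- lapply(all_terms, function(tt) {
    tt[!duplicated(vapply(tt, function(f) f$label, ""))]
  })
  keys <- vapply(all_terms, term_key, "")
  all_terms <- all_terms[!duplicated(keys)]

  f <- structure(list(terms = all_terms, has_intercept = has_intercept),
                 class = "rerp_formula")
  f$text <- render_formula(f)
  f
}

check_transform_args <- function(fun, args, src) {
  if (fun == "pow") {
    if (length(args) != 1 || args[1] < 1 || args[1] != round(args[1])) {
      stop("pow(x, k) needs a single integer exponent k >= 1 in: ", src,
           call. = FALSE)
    }
  } else if (fun == "bspline") {
    if (length(args) != 2) {
      stop("bspline(x, df, degree) needs df and degree in: ", src,
           call. = FALSE)
    }
  } else if (length(args) != 0) {
    stop(fun, "(x) takes no extra arguments in: ", src, call. = FALSE)
  }
}

format_num <- function(x) {
  ifelse(x == round(x), format(as.integer(round(x))), format(x))
}

term_key <- function(tt) {
  paste(sort(vapply(tt, function(f) f$label, "")), collapse = ":")
}

term_label <- function(tt) {
  paste(vapply(tt, function(f) f$label, ""), collapse = ":")
}

tokenize_formula <- function(body, src) {
  toks <- list()
  i <- 1L
  n <- nchar(body)
  offset <- nchar(src) - n  # character position of body start within src
  while (i <= n) {
    ch <- substr(body, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    at <- i + offset
    if (grepl("^[A-Za-z._]$", ch)) {
      m <- regmatches(substr(body, i, n),
                      regexpr("^[A-Za-z._][A-Za-z0-9._]*", substr(body, i, n)))
      toks[[length(toks) + 1]] <- list(type = "ident", text = m, at = at)
      i <- i + nchar(m)
    } else if (grepl("^[0-9]$", ch)) {
      m <- regmatches(substr(body, i, n),
                      regexpr("^[0-9]+(\\.[0-9]+)?", substr(body, i, n)))
      toks[[length(toks) + 1]] <- list(type = "num", text = m, at = at)
      i <- i + nchar(m)
    } else {
      type <- switch(ch, "+" = "plus", "-" = "minus", ":" = "colon",
                     "*" = "star", "(" = "lparen", ")" = "rparen",
                     "," = "comma", NULL)
      if (is.null(type)) {
        stop_parse(src, at, paste0("unexpected character '", ch, "'"))
      }
      toks[[length(toks) + 1]] <- list(type = type, text = ch, at = at)
      i <- i + 1L
    }
  }
  toks
}

stop_parse <- function(src, at, msg) {
  where <- if (is.na(at)) "end of input" else paste0("character ", at)
  stop("formula syntax error at ", where, " in '", src, "': ", msg,
       call. = FALSE)
}

render_formula <- function(f) {
  parts <- c(if (f$has_intercept) "1" else "0",
             vapply(f$terms, term_label, ""))
  paste("~", paste(parts, collapse = " + "))
}

#' @export
format.rerp_formula <- function(x, ...) x$text

#' @export
print.rerp_formula <- function(x, ...) {
  cat("<rerp_formula>", x$text, "\n")
  invisible(x)
}

#' Treatment coding scheme for categorical predictors
#'
#' Categorical predictors (character, factor, or logical columns, or columns
#' named in `categorical`) are coded by treatment contrasts: a k-level
#' variable contributes k - 1 indicator columns relative to a reference level
#' when the model has an intercept, and k indicator columns (in main-effect
#' terms) when it does not. The reference level defaults to the
#' lexicographically smallest observed level.
#'
#' @param reference Named character vector mapping variable names to reference
#'   levels, overriding the lexicographic default.
#' @param categorical Character vector of numeric columns to force-treat as
#'   categorical (numeric columns are never silently coerced).
#' @return A `coding_scheme` object.
#' @export
coding_scheme <- function(reference = character(), categorical = character()) {
  structure(list(kind = "treatment", reference = reference,
                 categorical = categorical),
            class = "coding_scheme")
}

#' Compile a design matrix from a formula and per-epoch predictors
#'
#' Produces the numeric X of `y = X beta + e`. Categorical variables are
#' treatment-coded (see [coding_scheme()]); interaction columns are exact
#' elementwise products of the constituent coded columns; column order follows
#' term order, then level/basis order within a term. Transforms in the formula
#' (`pow`, `bspline`, `center`, `scale`, `log`) are applied to numeric
#' columns; `bspline` contributes `df` columns.
#'
#' Rank is decided by a singular-value threshold
#' `eps * max(n, p) * sigma_max`. A rank-deficient design is a hard error
#' naming the aliased columns unless `rank_policy = "pinv"`, which leaves
#' resolution to the minimum-norm solver downstream.
#'
#' @param formula An `rerp_formula` or formula string.
#' @param predictors Data frame of predictor values, one row per epoch (or per
#'   observation in the general case).
#' @param coding A [coding_scheme()].
#' @param rank_policy `"error"` (default) or `"pinv"`.
#' @return A `design_matrix`: list with `matrix`, `column_names`, `rank`,
#'   `term_slices` (term label -> column indices), `has_intercept`.
#' @export
build_design_matrix <- function(formula, predictors,
                                coding = coding_scheme(),
                                rank_policy = c("error", "pinv")) {
  rank_policy <- match.arg(rank_policy)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "rerp_formula"), is.data.frame(predictors))

  n <- nrow(predictors)
  vars <- unique(unlist(lapply(formula$terms, function(tt)
    vapply(tt, function(f) f$var, ""))))
  unknown <- setdiff(vars, names(predictors))
  if (length(unknown)) {
    stop("unknown variable(s) in formula: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  is_cat <- function(v) {
    col <- predictors[[v]]
    is.character(col) || is.factor(col) || is.logical(col) ||
      v %in% coding$categorical
  }

  # code one factor spec into a column block
  code_factor <- function(f, main_effect) {
    col <- predictors[[f$var]]
    if (is_cat(f$var)) {
      if (f$transform != "identity") {
        stop("transform ", f$transform, "() cannot apply to categorical '",
             f$var, "'", call. = FALSE)
      }
      lev <- sort(unique(as.character(col)))
      if (any(is.na(col))) {
        stop("missing values in categorical predictor '", f$var, "'",
             call. = FALSE)
      }
      if (length(lev) < 2) {
        stop("categorical predictor '", f$var,
             "' has a single observed level", call. = FALSE)
      }
      ref <- coding$reference[f$var]
      ref <- if (!is.na(ref)) ref else lev[1]
      if (!ref %in% lev) {
        stop("reference level '", ref, "' not observed in '", f$var, "'",
             call. = FALSE)
      }
      full <- !formula$has_intercept && main_effect
      keep <- if (full) lev else setdiff(lev, ref)
      m <- vapply(keep, function(l) as.numeric(col == l), numeric(n))
      m <- matrix(m, nrow = n)
      colnames(m) <- paste0(f$var, "[", keep, "]")
      return(m)
    }
    if (!is.numeric(col)) {
      stop("predictor '", f$var, "' is neither numeric nor categorical",
           call. = FALSE)
    }
    if (any(!is.finite(col))) {
      stop("non-finite values in numeric predictor '", f$var, "'",
           call. = FALSE)
    }
    m <- switch(f$transform,
      identity = matrix(col, ncol = 1),
      pow = matrix(pow_transform(col, f$args[1]), ncol = 1),
      center = matrix(col - mean(col), ncol = 1),
      scale = matrix((col - mean(col)) / stats::sd(col), ncol = 1),
      log = {
        if (any(col <= 0)) stop("log(", f$var, "): non-positive values",
                                call. = FALSE)
        matrix(log(col), ncol = 1)
      },
      bspline = bspline_basis(col, df = as.integer(f$args[1]),
                              degree = as.integer(f$args[2]))
    )
    colnames(m) <- if (ncol(m) == 1) f$label else
      paste0(f$label, "[", seq_len(ncol(m)), "]")
    m
  }

  blocks <- list()
  term_slices <- list()
  col_at <- 0L
  if (formula$has_intercept) {
    blocks[["(Intercept)"]] <- matrix(1, nrow = n, ncol = 1,
                                      dimnames = list(NULL, "(Intercept)"))
    term_slices[["(Intercept)"]] <- 1L
    col_at <- 1L
  }
  for (tt in formula$terms) {
    main_effect <- length(tt) == 1
    coded <- lapply(tt, code_factor, main_effect = main_effect)
    # interaction block: all products, earlier factor varying fastest
    block <- coded[[1]]
    if (length(coded) > 1) {
      for (k in 2:length(coded)) {
        right <- coded[[k]]
        cols <- list()
        nm <- character()
        for (j in seq_len(ncol(right))) {
          for (i in seq_len(ncol(block))) {
            cols[[length(cols) + 1]] <- block[, i] * right[, j]
            nm <- c(nm, paste0(colnames(block)[i], ":", colnames(right)[j]))
          }
        }
        block <- matrix(unlist(cols), nrow = n)
        colnames(block) <- nm
      }
    }
    lbl <- term_label(tt)
    blocks[[lbl]] <- block
    term_slices[[lbl]] <- col_at + seq_len(ncol(block))
    col_at <- col_at + ncol(block)
  }

  X <- do.call(cbind, blocks)
  if (is.null(X)) {
    stop("formula produces an empty design (no intercept and no terms)",
         call. = FALSE)
  }
  cn <- colnames(X)
  if (anyDuplicated(cn)) {
    stop("duplicate design columns: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  }

  rk <- matrix_rank(X)
  if (rk < ncol(X) && rank_policy == "error") {
    aliased <- aliased_columns(X, rk)
    stop("rank-deficient design (rank ", rk, " < ", ncol(X),
         " columns); aliased column(s): ",
         paste(aliased, collapse = ", "),
         ". Use rank_policy = \"pinv\" to fit anyway.", call. = FALSE)
  }

  structure(list(matrix = X, column_names = cn, rank = rk,
                 term_slices = term_slices,
                 has_intercept = formula$has_intercept,
                 formula_text = formula$text,
                 rank_policy = rank_policy),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d, rank %d: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$rank, x$formula_text))
  invisible(x)
}

# numerical rank via SVD threshold eps * max(n, p) * sigma_max
matrix_rank <- function(X) {
  if (nrow(X) == 0 || ncol(X) == 0) return(0L)
  sv <- svd(X, nu = 0, nv = 0)$d
  tol <- .Machine$double.eps * max(dim(X)) * sv[1]
  sum(sv > tol)
}

# names of columns aliased with earlier ones (pivoted QR ordering)
aliased_columns <- function(X, rank) {
  qrx <- qr(X, LAPACK = TRUE)
  colnames(X)[qrx$pivot[(rank + 1):ncol(X)]]
}

#' Polynomial power transform
#'
#' Elementwise `x^k` for polynomial (curvilinear) regression ERPs, e.g.
#' `"~ x + pow(x, 2)"` for a U-shaped relation. `k = 1` is the identity.
#'
#' @param x Numeric vector.
#' @param k Positive integer exponent.
#' @return `x^k`.
#' @export
pow_transform <- function(x, k) {
  if (!is.numeric(x)) stop("pow() needs a numeric vector", call. = FALSE)
  stopifnot(length(k) == 1, k >= 1, k == round(k))
  x^k
}

#' B-spline basis (Cox-de Boor)
#'
#' Evaluates a B-spline basis for spline regression ERPs. Interior knots are
#' placed at quantiles of `x`; boundary knots are clamped at `min(x)` and
#' `max(x)` with multiplicity `degree + 1`. The full basis (with `df + 1`
#' functions built from `df - degree` interior knots) satisfies partition of
#' unity -- rows sum to 1 everywhere on the span. The returned matrix drops
#' the first basis function so that the remaining `df` columns are full rank
#' alongside an intercept; pass `drop_first = FALSE` to get the full basis.
#'
#' @param x Numeric vector of evaluation points.
#' @param df Number of returned basis columns; requires `df >= degree + 1`.
#' @param degree Spline degree (0 = step functions, 3 = cubic).
#' @param knots Optional full knot vector (overrides quantile placement); must
#'   be non-decreasing and span `x`.
#' @param drop_first Drop the intercept-confounded first basis function
#'   (default `TRUE`).
#' @return Matrix with `length(x)` rows.
#' @export
bspline_basis <- function(x, df, degree = 3L, knots = NULL,
                          drop_first = TRUE) {
  if (!is.numeric(x)) stop("bspline() needs a numeric vector", call. = FALSE)
  degree <- as.integer(degree)
  stopifnot(degree >= 0)
  if (is.null(knots)) {
    df <- as.integer(df)
    if (df < degree + 1) {
      stop("bspline: df must be >= degree + 1 (got df = ", df,
           ", degree = ", degree, ")", call. = FALSE)
    }
    if (diff(range(x)) == 0) {
      stop("bspline: x is degenerate (all values equal)", call. = FALSE)
    }
    n_interior <- df - degree
    probs <- seq_len(n_interior) / (n_interior + 1)
    interior <- stats::quantile(x, probs = probs, names = FALSE, type = 7)
    knots <- c(rep(min(x), degree + 1), interior, rep(max(x), degree + 1))
  } else {
    if (is.unsorted(knots)) stop("bspline: knots must be non-decreasing",
                                 call. = FALSE)
    if (min(x) < knots[1] || max(x) > knots[length(knots)]) {
      stop("bspline: x outside the knot span", call. = FALSE)
    }
  }
  B <- cox_de_boor(x, knots, degree)
  if (drop_first) B <- B[, -1, drop = FALSE]
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  B
}

# Cox-de Boor recursion over a full (possibly clamped) knot vector.
# Basis count = length(knots) - degree - 1. The right boundary is closed:
# x equal to the last knot is assigned to the last non-degenerate interval.
cox_de_boor <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1
  if (nb < 1) stop("bspline: too few knots for this degree", call. = FALSE)
  n <- length(x)
  # degree-0 indicators on [t_i, t_{i+1}), closing the final interval
  B <- matrix(0, n, length(knots) - 1)
  right_end <- knots[length(knots)]
  for (i in seq_len(ncol(B))) {
    lo <- knots[i]; hi <- knots[i + 1]
    inb <- (x >= lo & x < hi)
    if (hi == right_end && lo < hi) inb <- inb | (x == right_end)
    B[, i] <- as.numeric(inb)
  }
  if (degree == 0) return(B[, seq_len(nb), drop = FALSE])
  for (d in seq_len(degree)) {
    nb_d <- length(knots) - d - 1
    Bn <- matrix(0, n, nb_d)
    for (i in seq_len(nb_d)) {
      den1 <- knots[i + d] - knots[i]
      den2 <- knots[i + d + 1] - knots[i + 1]
      a <- if (den1 > 0) (x - knots[i]) / den1 * B[, i] else 0
      b <- if (den2 > 0) (knots[i + d + 1] - x) / den2 * B[, i + 1] else 0
      Bn[, i] <- a + b
    }
    B <- Bn
  }
  B
}

#' Export a design matrix to CSV for audit
#'
#' @param design A `design_matrix`.
#' @param path Output CSV path.
#' @export
write_design_matrix <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- tibble::as_tibble(design$matrix, .name_repair = "minimal")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
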