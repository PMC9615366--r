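test_that("formula parsing handles intercept control, crossing and idempotence", {
  f <- parse_formula("~ 1 + a + b + a:b")
  expect_true(f$has_intercept)
  expect_equal(format(f), "~ 1 + a + b + a:b")
  expect_equal(format(parse_formula("~ a*b")), "~ 1 + a + b + a:b")
  expect_equal(format(parse_formula("~ 1")), "~ 1")
  expect_false(parse_formula("~ 0 + a")$has_intercept)
  expect_false(parse_formula("~ a - 1")$has_intercept)
  # idempotence: parse(render(parse(f))) == parse(f)
  for (txt in c("~ 1", "~ a*b", "~ 0 + a + a:b", "~ x + pow(x, 2)",
                "~ a*b*c", "~ 1 + bspline(x, 5, 3)")) {
    f1 <- parse_formula(txt)
    f2 <- parse_formula(format(f1))
    expect_identical(f1, f2)
  }
  # duplicate terms collapse
  expect_equal(format(parse_formula("~ a + a + b:a")), "~ 1 + a + b:a")
})

test_that("formula errors are specific: position, transforms, mixed models", {
  expect_error(parse_formula("a + b"), "must begin with '~'")
  expect_error(parse_formula("~ a + (b | s)"), "mixed models")
  expect_error(parse_formula("~ sqrt(x)"), "unknown transform")
  expect_error(parse_formula("~ a +"), "dangling")
  expect_error(parse_formula("~ a ++ b"), "two operators")
  expect_error(parse_formula("~ a @ b"), "character 5")
  expect_error(parse_formula("~ pow(x)"), "integer exponent")
})

test_that("treatment coding matches the documented layout", {
  preds <- data.frame(a = c("c", "c", "t", "t"))
  d <- build_design_matrix("~ 1 + a", preds)
  expect_equal(d$column_names, c("(Intercept)", "a[t]"))
  expect_equal(unname(d$matrix),
               cbind(c(1, 1, 1, 1), c(0, 0, 1, 1)))
  d0 <- build_design_matrix("~ 0 + a", preds)
  expect_equal(d0$column_names, c("a[c]", "a[t]"))
  expect_equal(unname(d0$matrix), cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  # configurable reference level
  dr <- build_design_matrix("~ 1 + a", preds,
                            coding = coding_scheme(reference = c(a = "t")))
  expect_equal(dr$column_names, c("(Intercept)", "a[c]"))
})

test_that("compiled designs match the reference formula compiler", {
  set.seed(7)
  n <- 40
  preds <- data.frame(
    a = sample(c("one", "two", "three"), n, replace = TRUE),
    b = sample(c("p", "q"), n, replace = TRUE),
    x = rnorm(n), z = rnorm(n),
    stringsAsFactors = FALSE)
  cases <- list(
    list(ours = "~ 1 + a", ref = ~ a),
    list(ours = "~ 1 + a + b + a:b", ref = ~ a + b + a:b),
    list(ours = "~ a*b", ref = ~ a * b),
    list(ours = "~ 1 + x + pow(x, 2)", ref = ~ x + I(x^2)),
    list(ours = "~ 1 + x + z + x:z", ref = ~ x * z),
    list(ours = "~ 1 + b + x + b:x", ref = ~ b + x + b:x),
    list(ours = "~ 0 + a", ref = ~ 0 + a))
  for (cs in cases) {
    ours <- build_design_matrix(cs$ours, preds)$matrix
    ref <- model.matrix(cs$ref, preds)
    expect_equal(ncol(ours), ncol(ref), info = cs$ours)
    # match each reference column to exactly one of ours, value for value
    used <- integer()
    for (j in seq_len(ncol(ref))) {
      hit <- which(vapply(seq_len(ncol(ours)), function(k)
        max(abs(ours[, k] - ref[, j])) < 1e-12, TRUE))
      hit <- setdiff(hit, used)
      expect_length(hit, 1)
      used <- c(used, hit[1])
    }
  }
})

test_that("interaction columns are exact products of coded main effects", {
  set.seed(3)
  preds <- data.frame(a = sample(c("u", "v"), 20, replace = TRUE),
                      x = rnorm(20))
  d <- build_design_matrix("~ 1 + a + x + a:x", preds)
  M <- d$matrix
  expect_identical(M[, "a[v]:x"], M[, "a[v]"] * M[, "x"])
})

test_that("fitted values are invariant to the reference level", {
  set.seed(11)
  preds <- data.frame(a = sample(c("A", "B", "C"), 30, replace = TRUE))
  y <- rnorm(30)
  f1 <- ols_solve(build_design_matrix("~ 1 + a", preds), y)
  f2 <- ols_solve(build_design_matrix(
    "~ 1 + a", preds, coding = coding_scheme(reference = c(a = "C"))), y)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-12)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-12)
})

test_that("rank deficiency is a hard error naming aliased columns", {
  preds <- data.frame(x = rnorm(10))
  preds$y <- 2 * preds$x
  expect_error(build_design_matrix("~ 1 + x + y", preds),
               "rank-deficient.*aliased")
  d <- build_design_matrix("~ 1 + x + y", preds, rank_policy = "pinv")
  expect_lt(d$rank, ncol(d$matrix))
  # unknown variable and single-level categorical
  expect_error(build_design_matrix("~ 1 + w", preds), "unknown variable")
  expect_error(
    build_design_matrix("~ 1 + g", data.frame(g = rep("only", 5))),
    "single observed level")
})

test_that("pow and the other numeric transforms behave elementwise", {
  expect_equal(pow_transform(c(1, 2, 3), 2), c(1, 4, 9))
  x <- rnorm(10)
  expect_identical(pow_transform(x, 1), x)
  expect_error(pow_transform(letters, 2), "numeric")
  d <- build_design_matrix("~ 1 + x + pow(x, 2)", data.frame(x = c(1, 2, 3)))
  expect_equal(unname(d$matrix), cbind(1, c(1, 2, 3), c(1, 4, 9)))
  dc <- build_design_matrix("~ 1 + center(x)", data.frame(x = c(1, 2, 6)))
  expect_equal(unname(dc$matrix[, 2]), c(-2, -1, 3))
})

test_that("the full B-spline basis is a partition of unity", {
  set.seed(21)
  for (i in 1:10) {
    degree <- sample(0:3, 1)
    df <- degree + 1 + sample(1:4, 1)
    x <- runif(50)
    B <- bspline_basis(x, df = df, degree = degree, drop_first = FALSE)
    expect_equal(ncol(B), df + 1)
    expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
    expect_equal(ncol(bspline_basis(x, df = df, degree = degree)), df)
  }
})

test_that("degree-0 spline with explicit knots gives interval indicators", {
  B <- bspline_basis(0.25, degree = 0, knots = c(0, 0.5, 1),
                     drop_first = FALSE)
  expect_equal(unname(B[1, ]), c(1, 0))
})

test_that("spline values match an independent Cox-de Boor recursion", {
  knots <- c(0, 0, 0, 0.25, 0.5, 0.75, 1, 1, 1)  # clamped, degree 2
  degree <- 2
  xs <- c(0.125, 0.375, 0.51, 0.874)             # knot-interval midpoints etc.
  B <- bspline_basis(xs, degree = degree, knots = knots, drop_first = FALSE)
  nb <- length(knots) - degree - 1
  for (r in seq_along(xs)) {
    ora <- vapply(seq_len(nb), function(i)
      oracle_bspline_point(xs[r], i, degree, knots), 0)
    expect_equal(unname(B[r, ]), ora, tolerance = 1e-14)
  }
  # and the base splines evaluator agrees on interior points
  ref <- splines::splineDesign(knots, xs, ord = degree + 1)
  expect_equal(unname(B), unname(ref), tolerance = 1e-14)
})

test_that("spline guards: df too small, degenerate x, off-span values", {
  expect_error(bspline_basis(runif(10), df = 2, degree = 3), "df must be")
  expect_error(bspline_basis(rep(1, 5), df = 4, degree = 2), "degenerate")
  expect_error(bspline_basis(2, degree = 1, knots = c(0, 0, 1, 1)),
               "outside the knot span")
})

test_that("bspline terms compile inside formulas with full design rank", {
  set.seed(5)
  preds <- data.frame(x = runif(40))
  d <- build_design_matrix("~ 1 + bspline(x, 5, 3)", preds)
  expect_equal(ncol(d$matrix), 6)
  expect_equal(d$rank, 6)
})
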