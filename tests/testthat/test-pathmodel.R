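test_that("path specifications are validated structurally", {
  spec <- path_spec(data.frame(from = c("x", "m"), to = c("m", "y")))
  expect_equal(spec$outcome, "y")
  expect_equal(spec$order[1], "x")
  expect_error(path_spec(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cycle")
  expect_error(path_spec(data.frame(from = "a", to = c("b", "c"))),
               "terminal")
})

test_that("a single edge recovers the Pearson correlation", {
  set.seed(31)
  x <- rnorm(500)
  y <- 0.6 * x + rnorm(500)
  fit <- fit_path_model(path_spec(data.frame(from = "x", to = "y")),
                        list(x = x, y = y))
  expect_equal(fit$coefficients$coef[1], cor(x, y), tolerance = 1e-10)
  expect_equal(variance_explained(fit), cor(x, y)^2, tolerance = 1e-10)
})

test_that("a mediation chain recovers the product of path coefficients", {
  set.seed(32)
  n <- 2000
  x <- rnorm(n)
  m <- 0.6 * x + rnorm(n) * sqrt(1 - 0.36)
  y <- 0.5 * m + rnorm(n) * sqrt(1 - 0.25)
  fit <- fit_path_model(path_spec(data.frame(from = c("x", "m"),
                                             to = c("m", "y"))),
                        list(x = x, m = m, y = y))
  ind <- fit$effects$indirect[fit$effects$variable == "x"]
  expect_gt(ind, 0.25)
  expect_lt(ind, 0.35)
  # x has no direct edge to y
  expect_equal(fit$effects$direct[fit$effects$variable == "x"], 0)
})

test_that("total = direct + sum of indirect paths on a 5-variable DAG", {
  set.seed(33)
  n <- 300
  d <- data.frame(a = rnorm(n))
  d$b <- 0.5 * d$a + rnorm(n)
  d$c <- -0.4 * d$a + 0.3 * d$b + rnorm(n)
  d$e <- 0.2 * d$b + rnorm(n)
  d$y <- 0.3 * d$c + 0.4 * d$e + 0.1 * d$a + rnorm(n)
  spec <- path_spec(data.frame(
    from = c("a", "a", "b", "b", "c", "e", "a"),
    to = c("b", "c", "c", "e", "y", "y", "y")))
  fit <- fit_path_model(spec, d)
  eff <- fit$effects
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-10)
  # manual path tracing for variable b: b->c->y plus b->e->y
  co <- fit$coefficients
  getc <- function(f, t) co$coef[co$from == f & co$to == t]
  expect_equal(eff$indirect[eff$variable == "b"],
               getc("b", "c") * getc("c", "y") + getc("b", "e") * getc("e", "y"),
               tolerance = 1e-12)
})

test_that("an outcome built exactly from its parents gives R2 = 1, noise gives ~0", {
  set.seed(34)
  n <- 2000
  x <- rnorm(n); z <- rnorm(n)
  y_exact <- 2 * x - 3 * z
  spec <- path_spec(data.frame(from = c("x", "z"), to = c("y", "y")))
  expect_equal(suppressWarnings(
    fit_path_model(spec, list(x = x, z = z, y = y_exact)))$r2_outcome,
    1, tolerance = 1e-10)
  y_noise <- rnorm(n)
  expect_lt(fit_path_model(spec, list(x = x, z = z, y = y_noise))$r2_outcome,
            0.02)
  # R2 is invariant to rescaling any variable
  f1 <- suppressWarnings(fit_path_model(spec, list(x = x * 1000, z = z, y = y_exact)))
  expect_equal(f1$r2_outcome, 1, tolerance = 1e-10)
})

test_that("standardized coefficients are recovered within 0.05 at n = 2000", {
  set.seed(35)
  spec <- path_spec(data.frame(from = c("x", "x", "m"), to = c("m", "y", "y")))
  errs <- replicate(10, {
    x <- rnorm(2000)
    m <- 0.6 * x + rnorm(2000) * sqrt(1 - 0.36)
    y <- 0.4 * m + 0.3 * x + rnorm(2000) * sqrt(1 - 0.37)
    fit <- fit_path_model(spec, list(x = x, m = m, y = y))
    co <- fit$coefficients
    c(co$coef[co$from == "x" & co$to == "m"] - 0.6,
      co$coef[co$from == "m" & co$to == "y"] - 0.4,
      co$coef[co$from == "x" & co$to == "y"] - 0.3)
  })
  expect_lt(max(abs(errs)), 0.05)
})
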