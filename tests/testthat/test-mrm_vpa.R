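test_that("unfold/refold are exact inverses with the documented pair order", {
  d <- random_dist(3, seed = 1, labels = c("a", "b", "c"))
  v <- unfold(d)
  expect_length(v, 3)
  expect_equal(as.numeric(v), c(d["b", "a"], d["c", "a"], d["c", "b"]))
  expect_equal(refold(v), d)
  d8 <- random_dist(8, seed = 2)
  expect_length(unfold(d8), 8 * 7 / 2)
  expect_equal(refold(unfold(d8)), d8)
})

test_that("MRM coefficients match a direct normal-equations solve", {
  set.seed(21)
  n <- 15
  preds <- list(p1 = random_dist(n, seed = 31), p2 = random_dist(n, seed = 32))
  resp <- 0.4 * preds$p1 - 0.2 * preds$p2 + random_dist(n, seed = 33) * 0.3
  diag(resp) <- 0
  rownames(resp) <- colnames(resp) <- rownames(preds$p1)
  fit <- mrm_fit(resp, preds, permutations = 99, seed = 1)
  lt <- lower.tri(resp)
  X <- cbind(1, preds$p1[lt], preds$p2[lt])
  beta <- solve(t(X) %*% X, t(X) %*% resp[lt])   # independent solve
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("a response identical to a predictor gives a saturated, significant fit", {
  d <- random_dist(12, seed = 3)
  fit <- mrm_fit(d, list(x = d), permutations = 999, seed = 1)
  expect_equal(unname(fit$coefficients["x"]), 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lte(fit$pvals[["x"]], 0.001)
})

test_that("rank-deficient designs are refused with the offender named", {
  d <- random_dist(10, seed = 4)
  x <- random_dist(10, seed = 5)
  expect_error(mrm_fit(d, list(a = x, a_copy = x), permutations = 99),
               "a_copy|collinear")
})

test_that("forward selection finds the true predictor and respects alpha = 1", {
  set.seed(77)
  n <- 20
  true_pred <- random_dist(n, seed = 41)
  resp <- 0.8 * true_pred + 0.15 * random_dist(n, seed = 42)
  diag(resp) <- 0; rownames(resp) <- colnames(resp) <- rownames(true_pred)
  cands <- c(list(signal = true_pred),
             setNames(lapply(43:46, function(s) random_dist(n, seed = s)),
                      paste0("noise", 1:4)))
  sel <- forward_select(resp, cands, alpha = 0.05, permutations = 199, seed = 2)
  expect_true("signal" %in% sel$selected)
  # alpha = 1 admits every candidate, ordered by R2 gain
  all_in <- forward_select(resp, cands, alpha = 1, permutations = 49, seed = 2)
  expect_setequal(all_in$selected, names(cands))
  expect_equal(all_in$selected[1], "signal")
})

test_that("VPA fractions obey their algebraic identities", {
  n <- 14
  resp <- random_dist(n, seed = 51)
  space <- list(geo = random_dist(n, seed = 52))
  env <- list(e1 = random_dist(n, seed = 53), e2 = random_dist(n, seed = 54))
  v <- vpa_two_sets(resp, space, env)
  expect_equal(v$pure_space + v$pure_env + v$shared, v$r2_full, tolerance = 1e-10)
  expect_equal(v$unexplained, 1 - v$r2_full, tolerance = 1e-12)
  # identical sets: everything is shared
  v2 <- vpa_two_sets(resp, env, env)
  expect_equal(v2$pure_space, 0, tolerance = 1e-10)
  expect_equal(v2$pure_env, 0, tolerance = 1e-10)
  expect_equal(v2$shared, v2$r2_full, tolerance = 1e-10)
})

test_that("orthogonal predictor sets split the variance additively", {
  # build response from two exactly orthogonal pairwise predictors
  n <- 16
  set.seed(61)
  a <- random_dist(n, seed = 62)
  b <- random_dist(n, seed = 63)
  lt <- lower.tri(a)
  # orthogonalize b against a (and the intercept) in pair space
  bres <- residuals(lm(b[lt] ~ a[lt]))
  bm <- matrix(0, n, n, dimnames = dimnames(a))
  bm[lt] <- bres; bm <- bm + t(bm)
  resp <- matrix(0, n, n, dimnames = dimnames(a))
  resp[lt] <- scale(a[lt]) * sqrt(0.3) + scale(bm[lt]) * sqrt(0.1) +
    rnorm(sum(lt)) * sqrt(0.6)
  resp <- resp + t(resp)
  v <- vpa_two_sets(resp, list(a = a), list(b = bm))
  expect_lt(abs(v$shared), 0.02)
  expect_equal(v$pure_space, v$r2_space, tolerance = 0.02)
  expect_equal(v$pure_env, v$r2_env, tolerance = 0.02)
})

test_that("hierarchical partitioning is exact, additive, and order-free", {
  n <- 14
  resp <- random_dist(n, seed = 71)
  g <- list(g1 = list(x1 = random_dist(n, seed = 72)),
            g2 = list(x2 = random_dist(n, seed = 73),
                      x3 = random_dist(n, seed = 74)),
            g3 = list(x4 = random_dist(n, seed = 75)))
  hp <- hierarchical_partition(resp, g)
  expect_equal(sum(hp$contributions), hp$r2_full, tolerance = 1e-10)
  # single group: contribution equals its own R2
  hp1 <- hierarchical_partition(resp, g[1])
  lt <- lower.tri(resp)
  r2_direct <- summary(lm(resp[lt] ~ g$g1$x1[lt]))$r.squared
  expect_equal(unname(hp1$contributions), r2_direct, tolerance = 1e-10)
  expect_error(hierarchical_partition(resp, rep(g, 2)), "5 groups")
})
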