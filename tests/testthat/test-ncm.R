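test_that("expected frequency matches independent numerical quadrature", {
  N <- 9080; m <- 0.45; d <- 1 / 9080
  # oracle: integrate the beta density of local relative abundance above
  # the detection limit
  dens <- function(x, p) dbeta(x, N * m * p, N * m * (1 - p))
  for (p in c(1e-3, 1e-4, 5e-3)) {
    quad <- stats::integrate(dens, lower = d, upper = 1, p = p,
                             rel.tol = 1e-10)$value
    expect_equal(sloan_expected_frequency(p, N, m, d), quad, tolerance = 1e-6)
  }
})

test_that("expected frequency is monotone in abundance and hits its limits", {
  N <- 9080; m <- 0.3; d <- 1 / N
  grid <- exp(seq(log(1e-6), log(0.999), length.out = 100))
  f <- sloan_expected_frequency(grid, N, m, d)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f >= 0 & f <= 1))
  expect_gt(sloan_expected_frequency(1 - 1e-9, N, m, d), 1 - 1e-6)
  expect_error(sloan_expected_frequency(0, N, m, d), "p")
  expect_error(sloan_expected_frequency(0.5, N, 1.5, d), "m")
})

test_that("the migration rate is recovered from model-generated communities", {
  fits <- lapply(1:5, function(i)
    fit_ncm(simulate_sloan_community(90, 1000, 9080, m = 0.3, seed = 100 + i),
            N = 9080))
  m_hat <- vapply(fits, `[[`, numeric(1), "m")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  expect_lt(abs(mean(m_hat) - 0.3), 0.05)
  expect_true(all(r2 >= 0.8))
})

test_that("the fit is invariant to sample and taxon order", {
  ct <- simulate_sloan_community(40, 300, 2000, m = 0.2, seed = 9)
  f1 <- fit_ncm(ct, N = 2000)
  perm <- community_table(ct$counts[sample(nrow(ct$counts)),
                                    sample(ncol(ct$counts))])
  f2 <- fit_ncm(perm, N = 2000)
  expect_equal(f1$m, f2$m, tolerance = 1e-8)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("degenerate and adversarial occupancy structures are handled", {
  # every taxon everywhere: no interior frequencies
  full <- community_table(matrix(5, 12, 12,
                                 dimnames = list(paste0("s", 1:12),
                                                 paste0("t", 1:12))))
  expect_error(fit_ncm(full), "degenerate occupancy")
  # frequencies anti-monotone in abundance: fit can be worse than the mean
  n_s <- 30; n_t <- 40
  p_target <- exp(seq(log(2e-4), log(5e-2), length.out = n_t))
  freq_target <- seq(0.95, 0.05, length.out = n_t)  # high p -> low occupancy
  cnt <- sapply(seq_len(n_t), function(j) {
    present <- seq_len(n_s) <= round(freq_target[j] * n_s)
    reads <- round(p_target[j] * 1000 * n_s / max(1, sum(present)))
    ifelse(present, pmax(1, reads), 0)
  })
  dimnames(cnt) <- list(paste0("s", 1:n_s), paste0("t", 1:n_t))
  # the collapse of fit quality also trips the unreliable-m warning
  expect_warning(fit <- fit_ncm(community_table(cnt), N = 1000), "unreliable")
  expect_lt(fit$r2, 0)
  # unequal depths are refused without an explicit N
  expect_error(fit_ncm(community_table(cnt)), "unequal")
})
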