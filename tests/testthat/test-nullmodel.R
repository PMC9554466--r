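test_that("null replicates preserve per-sample richness and totals exactly", {
  ct <- random_table(n_samples = 10, n_taxa = 30, depth = 400, seed = 6)
  for (r in 1:20) {
    nt <- generate_null_community(ct, seed = r)
    expect_equal(rowSums(nt$counts > 0), rowSums(ct$counts > 0))
    expect_equal(rowSums(nt$counts), rowSums(ct$counts))
  }
  # rejection mode satisfies the same constraints
  nt <- generate_null_community(ct, seed = 1, method = "rejection")
  expect_equal(rowSums(nt$counts > 0), rowSums(ct$counts > 0))
  expect_equal(rowSums(nt$counts), rowSums(ct$counts))
})

test_that("a one-taxon pool forces the null community to equal the observed one", {
  m <- matrix(c(5, 9), 2, 1, dimnames = list(c("s1", "s2"), "only"))
  ct <- community_table(m)
  nt <- generate_null_community(ct, seed = 3)
  expect_identical(nt$counts, ct$counts)
})

test_that("taxon inclusion frequencies match brute-force enumeration of ordered draws", {
  # pool of 5 taxa; each sample draws S = 3 distinct taxa with
  # probability proportional to pool abundance, sequentially without
  # replacement. The exact inclusion probabilities come from enumerating
  # all 5*4*3 ordered draws.
  pool <- c(50, 25, 12, 8, 5)
  W <- sum(pool)
  incl <- numeric(5)
  for (i in 1:5) for (j in setdiff(1:5, i)) for (k in setdiff(1:5, c(i, j))) {
    pr <- (pool[i] / W) * (pool[j] / (W - pool[i])) *
      (pool[k] / (W - pool[i] - pool[j]))
    incl[c(i, j, k)] <- incl[c(i, j, k)] + pr
  }
  expect_equal(sum(incl), 3, tolerance = 1e-12)  # three slots per draw

  # one observed sample with richness 3; the pool is supplied explicitly
  obs <- community_table(matrix(c(10, 5, 5, 0, 0), 1, 5,
                                dimnames = list("s1", paste0("t", 1:5))))
  draws <- 10000
  set.seed(2024)
  counts <- numeric(5)
  for (i in seq_len(draws)) {
    nt <- generate_null_community(obs, pool = pool)
    counts <- counts + (nt$counts[1, ] > 0)
  }
  gof <- suppressWarnings(chisq.test(counts, p = incl / 3))
  expect_gt(gof$p.value, 0.01)
})

test_that("null column totals are pool-proportional in expectation", {
  # all-taxa-present fixture so allocation (not taxon draw) drives totals
  set.seed(8)
  cnt <- matrix(rmultinom(3, 1000, c(0.4, 0.3, 0.2, 0.1)), ncol = 4, byrow = TRUE)
  cnt[cnt == 0] <- 1
  dimnames(cnt) <- list(paste0("s", 1:3), paste0("t", 1:4))
  ct <- community_table(cnt)
  pool_share <- colSums(ct$counts) / sum(ct$counts)
  reps <- 3000
  tot <- numeric(4)
  set.seed(99)
  for (i in seq_len(reps)) tot <- tot + colSums(generate_null_community(ct)$counts)
  expect_equal(unname(tot / sum(tot)), unname(pool_share), tolerance = 0.01)
})

test_that("beta-deviation output is deterministic and internally consistent", {
  ct <- random_table(n_samples = 8, n_taxa = 25, depth = 300, seed = 4)
  bd1 <- beta_deviation(ct, reps = 99, seed = 7)
  bd2 <- beta_deviation(ct, reps = 99, seed = 7)
  expect_identical(bd1, bd2)
  expect_equal(nrow(bd1), 8 * 7 / 2)
  # the reported deviation is exactly (obs - null mean) / null sd
  expect_equal(bd1$deviation,
               (bd1$beta_obs - bd1$null_mean) / bd1$null_sd)
  expect_true(all(is.finite(bd1$deviation)))
  expect_identical(attr(bd1, "reps"), 99)
  # refolding recovers a symmetric matrix aligned with the table
  m <- deviation_matrix(bd1)
  expect_identical(rownames(m), rownames(ct$counts))
  expect_equal(m, t(m))
})

test_that("degenerate null ensembles yield NA deviations with a warning", {
  m <- matrix(c(5, 9), 2, 1, dimnames = list(c("s1", "s2"), "only"))
  ct <- community_table(m)
  expect_warning(bd <- beta_deviation(ct, reps = 99, seed = 1), "zero null SD")
  expect_true(is.na(bd$deviation))
})
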