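test_that("TSV community tables round-trip and validate", {
  ct <- toy_table()
  path <- tempfile(fileext = ".tsv")
  write_community_table(ct, path)
  back <- read_community_table(path)
  expect_identical(back$counts, ct$counts)
  expect_equal(unname(sample_depths(back)), c(10, 7))

  # duplicated taxon ID named in the error
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("#ASV ID\ts1\ts2", "tA\t1\t2", "tA\t3\t4"), bad)
  expect_error(read_community_table(bad), "tA")

  # zero-taxon table refused
  expect_error(community_table(matrix(numeric(0), nrow = 2, ncol = 0,
                                      dimnames = list(c("a", "b"), NULL))),
               "no taxa")
})

test_that("low-count filter drops taxa below the total-read threshold", {
  m <- matrix(c(3, 4, 50,
                4, 4, 50), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("low", "edge", "high")))
  ct <- community_table(m)  # totals 7, 8, 100
  kept <- filter_low_count_taxa(ct, min_reads = 8)
  expect_identical(kept$taxon_ids, c("edge", "high"))  # < 8 discarded, 8 kept
  expect_identical(filter_low_count_taxa(ct, min_reads = 0)$counts, ct$counts)
  expect_warning(out <- filter_low_count_taxa(ct, min_reads = 1000), "below")
  expect_identical(ncol(out$counts), 0L)
})

test_that("rarefaction subsamples exactly, deterministically, and errors on shallow samples", {
  ct <- random_table(n_samples = 6, n_taxa = 30, depth = 800, seed = 3)
  r1 <- rarefy_table(ct, depth = 500, seed = 11)
  r2 <- rarefy_table(ct, depth = 500, seed = 11)
  r3 <- rarefy_table(ct, depth = 500, seed = 12)
  expect_true(all(sample_depths(r1) == 500))
  expect_identical(r1$counts, r2$counts)
  expect_false(identical(r1$counts, r3$counts))
  expect_true(all(sample_depths(r3) == 500))
  # subsample never exceeds the original counts
  expect_true(all(r1$counts <= ct$counts))
  # sample already at depth is left untouched
  same <- rarefy_table(ct, depth = 800, seed = 1)
  expect_identical(same$counts, ct$counts)
  expect_error(rarefy_table(ct, depth = 801), "shallower")
})

test_that("relative abundances are row-normalized proportions", {
  m <- matrix(c(6, 2, 0), nrow = 1, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(as.vector(relative_abundance(community_table(m))),
               c(0.75, 0.25, 0))
  rel <- relative_abundance(random_table(seed = 7))
  expect_true(all(abs(rowSums(rel) - 1) < 1e-12))
  zero <- community_table(matrix(c(1, 0), 2, 1,
                                 dimnames = list(c("a", "b"), "t")))
  expect_error(relative_abundance(zero), "zero-depth")
})

test_that("aridity is one minus MAP/PET with valid range handling", {
  expect_equal(derive_aridity(100, 1000), 0.9)
  expect_equal(derive_aridity(500, 500), 0)
  # the study's aridity-index range maps to aridity without complaint
  ai <- c(0.03, 0.32)
  expect_silent(a <- derive_aridity(ai * 1000, 1000))
  expect_equal(a, 1 - ai)
  expect_error(derive_aridity(100, 0), "PET")
})

test_that("collinearity pruning enforces the |r| threshold", {
  set.seed(42)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, dup = x[, "a"])  # r = 1 pair
  pr <- collinearity_prune(x, threshold = 0.6)
  expect_length(pr$dropped, 1)
  expect_true(pr$steps$r[1] > 0.99)
  # all remaining pairwise correlations below the threshold (recomputed)
  C <- abs(cor(x[, pr$retained])); diag(C) <- 0
  expect_true(max(C) <= 0.6)

  # orthogonalized columns survive untouched
  z <- qr.Q(qr(matrix(rnorm(80), 20, 4)))
  colnames(z) <- letters[1:4]
  expect_length(collinearity_prune(z, 0.6)$dropped, 0)

  expect_error(collinearity_prune(cbind(x, const = 1), 0.6), "constant")
})
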