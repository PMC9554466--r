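test_that("Bray-Curtis matches the formula and its invariances", {
  m <- matrix(c(6, 2, 0,
                2, 4, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("x", "y"), c("a", "b", "c")))
  bc <- bray_curtis(community_table(m))
  expect_equal(bc["x", "y"], 1 - 2 * 4 / 14, tolerance = 1e-10)
  # identical samples -> 0; disjoint -> 1
  m2 <- matrix(c(3, 0, 3, 0, 0, 5, 0, 5), 4, 2,
               dimnames = list(c("p", "q", "r", "s"), c("a", "b")))
  bc2 <- bray_curtis(community_table(m2))
  expect_equal(bc2["p", "r"], 0)   # identical composition
  expect_equal(bc2["p", "q"], 1)   # disjoint taxa
  # adding an all-zero taxon changes nothing
  m3 <- cbind(m, z = c(0, 0))
  expect_equal(unname(bray_curtis(community_table(m3))), unname(bc))
})

test_that("geographic distances are great-circle km on a 6371 km sphere", {
  meta <- data.frame(sample_id = c("o", "deg1", "anti"),
                     lat = c(0, 0, 0), lon = c(0, 1, 180))
  g <- geographic_distance(meta)
  expect_equal(g["o", "deg1"], 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(g["o", "anti"], 6371 * pi, tolerance = 1e-6)
  expect_equal(g["o", "o"], 0)
  meta$lat[2] <- NA
  expect_error(geographic_distance(meta), "deg1")
})

test_that("environmental distance is standardized and unit-invariant", {
  x <- data.frame(a = c(0, 1, 2, 5), b = c(3, 1, 4, 2))
  rownames(x) <- paste0("s", 1:4)
  d1 <- env_distance(x)
  x2 <- x; x2$a <- x2$a * 1000
  expect_equal(unname(d1), unname(env_distance(x2)), tolerance = 1e-10)
  one <- data.frame(a = c(0, 1, 2)); rownames(one) <- paste0("s", 1:3)
  d <- env_distance(one)
  expect_equal(d["s1", "s3"] / d["s1", "s2"], 2, tolerance = 1e-10)
  expect_error(env_distance(data.frame(a = c(1, 1, 1))), "zero-variance")
})

test_that("Mantel statistic hits the exact bounds and agrees with vegan", {
  a <- random_dist(10, seed = 1)
  m_same <- mantel_test(a, a, permutations = 99, seed = 1)
  expect_equal(m_same$r, 1)
  anti <- max(a) - a; diag(anti) <- 0
  expect_equal(mantel_test(a, anti, permutations = 99, seed = 1)$r, -1)
  # statistic is symmetric in its arguments and matches vegan's r
  b <- random_dist(10, seed = 2)
  r_ab <- mantel_test(a, b, permutations = 99, seed = 1)$r
  r_ba <- mantel_test(b, a, permutations = 99, seed = 1)$r
  expect_equal(r_ab, r_ba, tolerance = 1e-12)
  expect_equal(r_ab, unname(vegan::mantel(as.dist(a), as.dist(b),
                                          permutations = 0)$statistic),
               tolerance = 1e-10)
})

test_that("PERMANOVA flags separated clusters and returns valid ranges", {
  set.seed(9)
  grp <- rep(c("A", "B"), each = 8)
  x <- matrix(rpois(16 * 20, 10), 16, 20,
              dimnames = list(sprintf("s%02d", 1:16), sprintf("t%02d", 1:20)))
  x[grp == "B", 1:10] <- x[grp == "B", 1:10] + 60  # strong group signal
  d <- bray_curtis(community_table(x))
  res <- permanova(d, grp, permutations = 999, seed = 1)
  expect_lte(res$p, 0.001)
  expect_gt(res$pseudo_F, 0)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  expect_error(permanova(d, c("A", rep("B", 15)), permutations = 99),
               "singleton")
})

test_that("distance-decay regression recovers an exact linear relationship", {
  set.seed(3)
  pos <- sort(runif(12, 0, 800))
  geo <- dist_from_values(pos, labels = sprintf("s%02d", 1:12))
  beta <- 1 - (0.8 - 0.001 * geo)   # similarity = 0.8 - 0.001 * km exactly
  diag(beta) <- 0
  fit <- suppressWarnings(ddr_fit(beta, geo, permutations = 99, seed = 1))
  expect_equal(fit$slope, -0.001, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 12 * 11 / 2)
  # similarity unrelated to distance: slope within 2 SE of zero
  noise <- random_dist(12, seed = 4, labels = rownames(geo))
  fit0 <- ddr_fit(noise, geo, permutations = 99, seed = 1)
  se <- abs(fit0$slope / qt(1 - fit0$p_ols / 2, fit0$n_pairs - 2))
  expect_lt(abs(fit0$slope), 2 * se + 1e-12)
  expect_gt(fit0$p_perm, 0.05)
})

test_that("dispersal-limited communities show a significant negative distance decay", {
  cfg <- sim_config(seed = 3, selection_strength = 0,
                    dispersal_decay_km = 300, m_immigration = 1)
  sim <- simulate_metacommunity(cfg)
  bc <- bray_curtis(sim$table)
  geo <- geographic_distance(sim$meta)
  fit <- ddr_fit(bc, geo, permutations = 199, seed = 1)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_perm, 0.05)
})
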