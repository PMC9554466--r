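# small community tables built in code, shared across test files

toy_table <- function() {
  m <- matrix(c(6, 2, 2,
                2, 4, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  community_table(m)
}

# lognormal pool + multinomial reads: a generic random fixture
random_table <- function(n_samples = 20, n_taxa = 50, depth = 500,
                         sdlog = 1.5, seed = 1) {
  set.seed(seed)
  pool <- rlnorm(n_taxa, 0, sdlog)
  cnt <- t(rmultinom(n_samples, depth, pool / sum(pool)))
  dimnames(cnt) <- list(sprintf("s%02d", seq_len(n_samples)),
                        sprintf("t%02d", seq_len(n_taxa)))
  community_table(cnt)
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n = 10, seed = 1, labels = sprintf("s%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# distance matrix from a latent per-sample variable (|x_i - x_j|)
dist_from_values <- function(x, labels = names(x)) {
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(labels, labels)
  m
}
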