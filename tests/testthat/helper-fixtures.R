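# Shared fixtures, all generated in code.

# Random connected weighted graph as a screened edge set: a random spanning
# tree plus extra random edges, weights in (0.1, 1). Node "t" is the target.
random_connected_edges <- function(n_nodes, extra = 2) {
  nodes <- c("t", paste0("v", seq_len(n_nodes - 1)))
  parent <- vapply(2:n_nodes, function(i) sample.int(i - 1, 1), integer(1))
  edges <- data.frame(var_a = nodes[parent], var_b = nodes[2:n_nodes],
                      stringsAsFactors = FALSE)
  for (k in seq_len(extra)) {
    ij <- sample.int(n_nodes, 2)
    a <- nodes[min(ij)]
    b <- nodes[max(ij)]
    dup <- any((edges$var_a == a & edges$var_b == b) |
                 (edges$var_a == b & edges$var_b == a))
    if (!dup) {
      edges <- rbind(edges, data.frame(var_a = a, var_b = b))
    }
  }
  edges$r <- stats::runif(nrow(edges), 0.1, 1) *
    sample(c(-1, 1), nrow(edges), replace = TRUE)
  edges$p <- stats::runif(nrow(edges), 0, 0.04)
  edges$method <- "pearson"
  edges$n <- 100L
  edges
}

# Dense-solver oracle: principal eigenvector of the attenuated adjacency,
# sign-aligned to be non-negative and L2-normalised.
dense_eigen_oracle <- function(net) {
  A <- targnet:::adjacency_of(net)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), rownames(A))
}

# Small Gaussian cohort spec with a given correlation matrix, for screening
# and calibration tests: near-untruncated normal marginals.
gaussian_spec <- function(k, n, R = diag(k)) {
  marg <- lapply(seq_len(k), function(i) {
    list(mean = 0, sd = 1, min = -8, max = 8, family = "truncnorm",
         resolution = NA_real_, floor = NA_real_)
  })
  names(marg) <- paste0("v", seq_len(k))
  cohort_spec(marg, R, n = n)
}
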