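test_that("normality gating picks Pearson for Gaussian pairs at the nominal rate", {
  # Two independent Gaussian variables: each passes Shapiro-Wilk with
  # probability 1 - alpha, so both pass with probability ~0.95^2 = 0.9025.
  set.seed(51)
  picks <- replicate(400, {
    choose_method(rnorm(411), rnorm(411)) == "pearson"
  })
  expect_gt(mean(picks), 0.9025 - 0.05)
  expect_lt(mean(picks), 0.9025 + 0.05)
})

test_that("a heavily skewed variable forces Spearman", {
  set.seed(52)
  picks <- replicate(100, {
    choose_method(rnorm(411), rlnorm(411, 0, 1)) == "spearman"
  })
  expect_gte(mean(picks), 0.99)
})

test_that("constant vectors are non-normal and their pairs are excluded", {
  expect_equal(choose_method(rep(1, 50), rnorm(50)), "spearman")
  set.seed(53)
  tab <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(2, 50))
  edges <- screen_edges(tab, alpha = 1)
  excl <- attr(edges, "excluded")
  expect_true(all(excl$var_a == "c" | excl$var_b == "c"))
  expect_match(excl$reason[1], "constant")
  expect_false(any(edges$var_a == "c" | edges$var_b == "c"))
})

test_that("screening retains a strongly planted correlation and respects alpha", {
  R <- diag(2)
  R[1, 2] <- R[2, 1] <- 0.52
  for (s in 1:5) {
    co <- generate_cohort(gaussian_spec(2, 411, R), seed = s)
    edges <- screen_edges(co[, c("v1", "v2")])
    expect_equal(nrow(edges), 1)
    expect_lt(abs(edges$r - 0.52), 0.12) # ~3 sampling SDs at n = 411
  }
  # single variable: nothing to test
  co <- generate_cohort(gaussian_spec(1, 50), seed = 1)
  expect_equal(nrow(screen_edges(co[, "v1", drop = FALSE])), 0)
  expect_error(screen_edges(data.frame(a = numeric(0))), "non-empty")
})

test_that("missing values are dropped case-wise or handled pairwise", {
  set.seed(54)
  tab <- data.frame(a = rnorm(60), b = rnorm(60))
  tab$b <- tab$b + tab$a # make the pair correlated
  tab$a[1:5] <- NA
  cc <- screen_edges(tab, alpha = 1)
  expect_equal(attr(cc, "n_dropped"), 5L)
  expect_equal(cc$n, 55L)
  pw <- screen_edges(tab, alpha = 1, use = "pairwise")
  expect_equal(attr(pw, "n_dropped"), 0L)
  expect_equal(pw$n, 55L)
})

test_that("edge orders and attenuated weights follow the hop-distance law", {
  edges <- data.frame(
    var_a = c("beck", "A", "B", "C"),
    var_b = c("A", "B", "C", "D"),
    r = c(0.52, 0.13, -0.40, 0.30),
    p = rep(0.001, 4), method = "pearson", n = 411L,
    stringsAsFactors = FALSE)
  net <- assign_orders(edges, "beck")
  expect_s3_class(net, "targeted_network")
  expect_equal(net$hop[c("beck", "A", "B", "C", "D")],
               c(beck = 0L, A = 1L, B = 2L, C = 3L, D = 4L))
  expect_identical(net$edges$order, c(1L, 2L, 3L, 4L))
  # binary-exact attenuation: 0.13 * 0.5 = 0.065 etc.
  expect_identical(net$edges$weight[2], 0.065)
  expect_identical(net$edges$weight / abs(net$edges$r), c(1, 0.5, 0.25, 0.125))
  # weight is based on |r|: the negative correlation keeps magnitude
  expect_identical(net$edges$weight[3], 0.40 * 0.25)
})

test_that("a lateral edge between two first-hop nodes is second order", {
  edges <- data.frame(var_a = c("t", "t", "a"), var_b = c("a", "b", "b"),
                      r = c(0.5, 0.5, 0.3), p = 0.001,
                      stringsAsFactors = FALSE)
  net <- assign_orders(edges, "t")
  lateral <- net$edges[net$edges$var_a == "a" & net$edges$var_b == "b", ]
  expect_equal(lateral$order, 2L)
  expect_identical(lateral$weight, 0.15)
})

test_that("nodes unreachable from the target are dropped with their edges", {
  edges <- data.frame(var_a = c("t", "x"), var_b = c("a", "y"),
                      r = c(0.5, 0.6), p = 0.001, stringsAsFactors = FALSE)
  net <- assign_orders(edges, "t", nodes = c("t", "a", "x", "y", "z"))
  expect_setequal(net$nodes, c("t", "a"))
  expect_setequal(net$dropped, c("x", "y", "z"))
  expect_equal(nrow(net$edges), 1)
})

test_that("an absent target errors and an isolated target warns", {
  edges <- data.frame(var_a = "a", var_b = "b", r = 0.5, p = 0.001,
                      stringsAsFactors = FALSE)
  expect_error(assign_orders(edges, "nope", nodes = c("a", "b")),
               "not among")
  expect_warning(net <- assign_orders(edges, "t", nodes = c("t", "a", "b")),
                 "target alone")
  expect_equal(net$nodes, "t")
  expect_equal(eigenvector_centrality(net)$scores, c(t = 1))
})

test_that("weight law and attenuation monotonicity hold on random graphs", {
  set.seed(61)
  for (i in 1:25) {
    edges <- random_connected_edges(sample(4:10, 1), extra = sample(0:4, 1))
    net <- assign_orders(edges, "t")
    expect_identical(net$edges$weight / abs(net$edges$r),
                     2^-(net$edges$order - 1))
    expect_true(all(net$edges$order >= 1))
    # equal |r| at lower order always outweighs higher order
    if (nrow(net$edges) >= 2) {
      o <- net$edges$order
      att <- 2^-(o - 1)
      expect_true(all(outer(o, o, "<") == outer(att, att, ">")))
    }
  }
})

test_that("removing a node at hop h leaves orders of edges nearer the target alone", {
  set.seed(62)
  for (i in 1:10) {
    edges <- random_connected_edges(8, extra = 3)
    net <- assign_orders(edges, "t")
    far <- names(net$hop)[net$hop == max(net$hop)][1]
    if (net$hop[[far]] < 1) next
    keep <- !(edges$var_a == far | edges$var_b == far)
    net2 <- suppressWarnings(assign_orders(edges[keep, ], "t"))
    h <- max(net$hop)
    inner <- net$edges[net$hop[net$edges$var_a] < h &
                         net$hop[net$edges$var_b] < h, ]
    for (k in seq_len(nrow(inner))) {
      m <- net2$edges$var_a == inner$var_a[k] &
        net2$edges$var_b == inner$var_b[k]
      expect_equal(net2$edges$order[m], inner$order[k])
    }
  }
})

test_that("power iteration matches closed forms on symmetric graphs", {
  # two nodes: both scores 1/sqrt(2)
  edges <- data.frame(var_a = "t", var_b = "v", r = 0.3, p = 0.001,
                      stringsAsFactors = FALSE)
  rep2 <- eigenvector_centrality(assign_orders(edges, "t"))
  expect_equal(unname(rep2$scores), rep(1 / sqrt(2), 2), tolerance = 1e-8)

  # star with k leaves and equal weights: leaf/center ratio 1/sqrt(k)
  for (k in c(3, 6, 9)) {
    star <- data.frame(var_a = "t", var_b = paste0("v", 1:k), r = 0.4,
                       p = 0.001, stringsAsFactors = FALSE)
    rep_k <- eigenvector_centrality(assign_orders(star, "t"))
    leaves <- rep_k$scores[paste0("v", 1:k)]
    expect_equal(unname(leaves / rep_k$scores[["t"]]), rep(1 / sqrt(k), k),
                 tolerance = 1e-8)
    expect_equal(max(abs(leaves - leaves[1])), 0, tolerance = 1e-10)
  }
})

test_that("power iteration agrees with the dense eigen-decomposition oracle", {
  set.seed(63)
  for (i in 1:30) {
    edges <- random_connected_edges(sample(3:10, 1), extra = sample(0:5, 1))
    net <- assign_orders(edges, "t")
    got <- eigenvector_centrality(net)
    want <- dense_eigen_oracle(net)
    expect_equal(got$scores[net$nodes], want[net$nodes], tolerance = 1e-8)
    expect_equal(sum(got$scores^2), 1, tolerance = 1e-12)
    expect_true(all(got$scores >= 0))
  }
})

test_that("centrality agrees with igraph's eigenvector centrality", {
  set.seed(64)
  edges <- random_connected_edges(9, extra = 4)
  net <- assign_orders(edges, "t")
  got <- eigenvector_centrality(net)
  g <- igraph::graph_from_data_frame(net$edges[, c("var_a", "var_b")],
                                     directed = FALSE)
  ig <- igraph::eigen_centrality(g, weights = net$edges$weight)$vector
  ig <- ig / sqrt(sum(ig^2))
  expect_equal(unname(got$scores[names(ig)]), unname(ig), tolerance = 1e-6)
})

test_that("centrality is invariant to rescaling all weights", {
  set.seed(65)
  edges <- random_connected_edges(8, extra = 3)
  net <- assign_orders(edges, "t")
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 37.5
  a <- eigenvector_centrality(net)$scores
  b <- eigenvector_centrality(scaled)$scores
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("bipartite graphs converge and non-convergence is reported", {
  # even cycle (bipartite): plain power iteration would oscillate
  edges <- data.frame(var_a = c("t", "a", "b", "c"),
                      var_b = c("a", "b", "c", "t"),
                      r = 0.5, p = 0.001, stringsAsFactors = FALSE)
  net <- assign_orders(edges, "t")
  rep4 <- eigenvector_centrality(net)
  want <- dense_eigen_oracle(net)
  expect_equal(rep4$scores[net$nodes], want[net$nodes], tolerance = 1e-8)
  expect_error(eigenvector_centrality(net, tol = 1e-16, max_iter = 2),
               "did not converge")
})

test_that("the composed pipeline is deterministic and ranks a sole partner first", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.6
  co <- generate_cohort(gaussian_spec(3, 300, R), seed = 71)
  fit <- build_targeted_network(co[, paste0("v", 1:3)], target = "v1")
  non_target <- setdiff(fit$centrality$ranking, "v1")
  expect_equal(non_target[1], "v2")
  fit2 <- build_targeted_network(co[, paste0("v", 1:3)], target = "v1")
  expect_identical(fit$centrality$scores, fit2$centrality$scores)
  expect_error(build_targeted_network(co, target = "nope"), "not a numeric")
})

test_that("a planted chain ranks the near node above the far node", {
  # t -- a -- b with equal latent link strength: attenuation plus adjacency
  # to the target must rank a over b.
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.5
  hits <- 0
  for (s in 1:10) {
    co <- generate_cohort(gaussian_spec(3, 411, R), seed = 80 + s)
    fit <- suppressWarnings(
      build_targeted_network(co[, paste0("v", 1:3)], target = "v1"))
    sc <- fit$centrality$scores
    if (all(c("v2", "v3") %in% names(sc)) && sc[["v2"]] > sc[["v3"]]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
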