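# Correlation screening, target-anchored edge weighting and eigenvector
# centrality. The graph is built from all significantly correlated variable
# pairs; each edge is then attenuated by its hop distance from the target
# node and node importance is read off the principal eigenvector of the
# weighted adjacency matrix.

# Per-variable normality decision used to gate Pearson vs Spearman.
# Shapiro-Wilk accepts 3..5000 observations; larger samples are thinned
# evenly (deterministically) to 5000 before testing. Constant vectors are
# treated as non-normal.
is_normal <- function(x, alpha_norm = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(unique(x)) == 1) {
    return(FALSE)
  }
  if (length(x) > 5000) {
    x <- x[round(seq(1, length(x), length.out = 5000))]
  }
  stats::shapiro.test(x)$p.value >= alpha_norm
}

#' Choose the correlation method for a pair of variables
#'
#' Returns `"pearson"` when both variables pass a Shapiro-Wilk normality
#' test at `alpha_norm`, and `"spearman"` otherwise. Normality is assessed
#' per variable, so a pair uses Pearson only when both marginals look
#' Gaussian.
#'
#' @param x,y Numeric sample vectors (length >= 3).
#' @param alpha_norm Significance level of the normality test; default 0.05.
#' @return `"pearson"` or `"spearman"`.
#' @export
choose_method <- function(x, y, alpha_norm = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("choose_method needs at least 3 observations per variable",
         call. = FALSE)
  }
  if (is_normal(x, alpha_norm) && is_normal(y, alpha_norm)) {
    "pearson"
  } else {
    "spearman"
  }
}

#' Screen all variable pairs for significant correlation
#'
#' Tests every unordered pair of variables in a scored table and retains
#' those with two-sided p-value below `alpha`. The coefficient for each pair
#' is Pearson's r when both variables pass the Shapiro-Wilk normality gate
#' at `alpha_norm`, otherwise Spearman's rho (see [choose_method()]).
#' Constant variables cannot be correlated; pairs involving them are
#' excluded and reported in the `excluded` attribute with a reason.
#'
#' @param scored Data frame of numeric variables (non-numeric columns such
#'   as `id`/`sex` are ignored).
#' @param alpha Two-sided significance level for edge inclusion; default
#'   0.05.
#' @param alpha_norm Level of the per-variable normality gate; default 0.05.
#' @param use `"complete"` (default) drops rows with any missing value
#'   before testing; `"pairwise"` uses pairwise-complete observations, with
#'   the per-pair n reported in the result.
#' @return Data frame of retained edges with columns `var_a`, `var_b`, `r`,
#'   `p`, `method`, `n`. Attribute `excluded` lists degenerate pairs and
#'   reasons; attribute `n_dropped` counts rows removed by complete-case
#'   filtering.
#' @export
screen_edges <- function(scored, alpha = 0.05, alpha_norm = 0.05,
                         use = c("complete", "pairwise")) {
  use <- match.arg(use)
  num <- scored[, vapply(scored, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 1 || nrow(num) == 0) {
    stop("screen_edges needs a non-empty table with numeric variables",
         call. = FALSE)
  }
  n_dropped <- 0L
  if (use == "complete") {
    keep <- stats::complete.cases(num)
    n_dropped <- sum(!keep)
    num <- num[keep, , drop = FALSE]
  }
  if (nrow(num) < 4) {
    stop("screen_edges needs at least 4 complete observations", call. = FALSE)
  }
  vars <- names(num)
  normal <- vapply(vars, function(v) is_normal(num[[v]], alpha_norm),
                   logical(1))
  constant <- vapply(vars, function(v) {
    x <- num[[v]][is.finite(num[[v]])]
    length(unique(x)) <= 1
  }, logical(1))

  edges <- list()
  excluded <- list()
  if (length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) {
      for (j in seq((i + 1), length(vars))) {
        a <- vars[i]
        b <- vars[j]
        x <- num[[a]]
        y <- num[[b]]
        ok <- is.finite(x) & is.finite(y)
        if (constant[i] || constant[j]) {
          excluded[[length(excluded) + 1]] <- data.frame(
            var_a = a, var_b = b,
            reason = sprintf("constant variable: %s",
                             paste(c(a, b)[c(constant[i], constant[j])],
                                   collapse = ", ")),
            stringsAsFactors = FALSE)
          next
        }
        if (sum(ok) < 4) {
          excluded[[length(excluded) + 1]] <- data.frame(
            var_a = a, var_b = b, reason = "fewer than 4 complete pairs",
            stringsAsFactors = FALSE)
          next
        }
        method <- if (normal[i] && normal[j]) "pearson" else "spearman"
        ct <- suppressWarnings(stats::cor.test(
          x[ok], y[ok], method = method, exact = FALSE,
          alternative = "two.sided"))
        if (is.finite(ct$estimate) && ct$p.value < alpha) {
          edges[[length(edges) + 1]] <- data.frame(
            var_a = a, var_b = b, r = unname(ct$estimate),
            p = ct$p.value, method = method, n = sum(ok),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(edges) > 0) {
    do.call(rbind, edges)
  } else {
    data.frame(var_a = character(), var_b = character(), r = numeric(),
               p = numeric(), method = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  attr(out, "excluded") <- if (length(excluded) > 0) {
    do.call(rbind, excluded)
  } else {
    data.frame(var_a = character(), var_b = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Anchor a screened edge set at a target node and attenuate weights
#'
#' Computes hop distances from the target node by breadth-first search on
#' the unweighted significance graph, assigns each edge an order equal to
#' `min(hop(u), hop(v)) + 1`, and attenuates its weight geometrically with
#' order:
#'
#' \deqn{w = |r| \times 0.5^{order - 1}}
#'
#' so edges touching the target (order 1) keep their full correlation
#' magnitude, second-degree edges keep half of it, third- and fourth-degree
#' edges a quarter and an eighth, and so on. Nodes with no path to the
#' target are dropped from the network (their variables are absent from
#' that network's report), along with any edges touching them.
#'
#' @param edges Data frame of screened edges as returned by
#'   [screen_edges()] (columns `var_a`, `var_b`, `r`; `p`, `method`, `n`
#'   carried through when present).
#' @param target Name of the target variable; must appear in the edge set
#'   unless it is isolated, in which case a single-node network is returned
#'   with a warning.
#' @param nodes Optional character vector of all variables that were
#'   screened; used to recognise an isolated target and to report dropped
#'   nodes. Defaults to the variables present in `edges` plus the target.
#' @return An object of class `targeted_network`: a list with `target`,
#'   `nodes`, `hop` (named integer vector of hop distances, target = 0),
#'   `edges` (with added `order` and `weight` columns) and `dropped`
#'   (unreachable variables).
#' @export
assign_orders <- function(edges, target, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- union(unique(c(edges$var_a, edges$var_b)), target)
  }
  if (!target %in% nodes) {
    stop(sprintf("target '%s' is not among the screened variables", target),
         call. = FALSE)
  }
  if (nrow(edges) == 0 || !any(edges$var_a == target | edges$var_b == target)) {
    warning(sprintf(
      "target '%s' has no significant correlations; network is the target alone",
      target), call. = FALSE)
    net <- list(
      target = target, nodes = target,
      hop = stats::setNames(0L, target),
      edges = cbind(edges[0, , drop = FALSE],
                    data.frame(order = integer(), weight = numeric())),
      dropped = setdiff(nodes, target))
    class(net) <- "targeted_network"
    return(net)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("var_a", "var_b")], directed = FALSE,
    vertices = data.frame(name = nodes))
  hops <- igraph::distances(g, v = target, weights = NA)[1, ]
  reachable <- names(hops)[is.finite(hops)]
  dropped <- setdiff(nodes, reachable)
  hop <- stats::setNames(as.integer(hops[reachable]), reachable)

  keep <- edges$var_a %in% reachable & edges$var_b %in% reachable
  edges <- edges[keep, , drop = FALSE]
  ord <- pmin(hop[edges$var_a], hop[edges$var_b]) + 1L
  edges$order <- as.integer(ord)
  # 0.5^(order-1) is a power of two, so the attenuation is binary-exact.
  edges$weight <- abs(edges$r) * 2^-(edges$order - 1L)
  rownames(edges) <- NULL

  net <- list(target = target, nodes = reachable, hop = hop,
              edges = edges, dropped = dropped)
  class(net) <- "targeted_network"
  net
}

#' @export
print.targeted_network <- function(x, ...) {
  cat(sprintf("Targeted correlation network: target '%s'\n", x$target))
  cat(sprintf("  %d nodes, %d edges (orders %s)\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges) > 0) {
                paste(range(x$edges$order), collapse = "..")
              } else "-"))
  if (length(x$dropped) > 0) {
    cat("  dropped (unreachable):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# Symmetric weighted adjacency matrix of a targeted network.
adjacency_of <- function(net) {
  k <- length(net$nodes)
  A <- matrix(0, k, k, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    ia <- match(net$edges$var_a, net$nodes)
    ib <- match(net$edges$var_b, net$nodes)
    A[cbind(ia, ib)] <- net$edges$weight
    A[cbind(ib, ia)] <- net$edges$weight
  }
  A
}

#' Eigenvector centrality of a targeted network by power iteration
#'
#' Computes the principal eigenvector of the symmetric attenuated-weight
#' adjacency matrix by power iteration from a uniform positive start. A
#' small positive diagonal shift (proportional to the largest row sum, so
#' centralities are invariant to rescaling all weights) removes the
#' period-2 oscillation a bipartite graph would otherwise induce without
#' changing the eigenvectors. Scores are non-negative and L2-normalised to
#' 1 over all nodes; under Perron-Frobenius theory on a connected
#' non-negative matrix the limit is unique.
#'
#' @param net A `targeted_network` from [assign_orders()].
#' @param tol Convergence bound on the L1 difference between successive
#'   normalised iterates; default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual. Default 1000.
#' @return Object of class `centrality_report`: list with `scores` (named,
#'   L2-normalised, descending), `ranking` (node names, target included),
#'   `iterations` and `residual`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(net, "targeted_network"))
  k <- length(net$nodes)
  if (k == 1) {
    rep <- list(scores = stats::setNames(1, net$nodes), ranking = net$nodes,
                iterations = 0L, residual = 0)
    class(rep) <- "centrality_report"
    return(rep)
  }
  A <- adjacency_of(net)
  if (any(A < 0)) {
    stop("edge weights must be non-negative", call. = FALSE)
  }
  # Shift scales with the matrix so results are invariant under w -> c * w.
  shift <- 0.05 * max(rowSums(A))
  M <- A + diag(shift, k)
  v <- rep(1 / sqrt(k), k)
  residual <- Inf
  for (it in seq_len(max_iter)) {
    w <- M %*% v
    w <- as.numeric(w) / sqrt(sum(w^2))
    residual <- sum(abs(w - v))
    v <- w
    if (residual < tol) {
      scores <- stats::setNames(pmax(v, 0), net$nodes)
      scores <- scores / sqrt(sum(scores^2))
      ord <- order(scores, decreasing = TRUE)
      rep <- list(scores = scores[ord], ranking = net$nodes[ord],
                  iterations = it, residual = residual)
      class(rep) <- "centrality_report"
      return(rep)
    }
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (residual %.3e)",
    max_iter, residual), call. = FALSE)
}

#' @export
print.centrality_report <- function(x, ...) {
  cat(sprintf("Eigenvector centrality (%d nodes, %d iterations)\n",
              length(x$scores), x$iterations))
  print(round(x$scores, 4))
  invisible(x)
}

#' Build a target-anchored correlation network from a scored cohort
#'
#' Runs the full network pipeline on a scored table: significance screening
#' of all variable pairs ([screen_edges()]), hop-distance weight
#' attenuation anchored at the target ([assign_orders()]) and eigenvector
#' centrality ([eigenvector_centrality()]). Deterministic given the table.
#'
#' @param scored Scored cohort data frame (see [analysis_variables()]).
#' @param target Target variable name; default `"beck"`, the depression
#'   score.
#' @param alpha Edge-inclusion significance level; default 0.05.
#' @param alpha_norm Normality-gate level; default 0.05.
#' @param tol,max_iter Power-iteration controls, see
#'   [eigenvector_centrality()].
#' @param use Missing-data handling passed to [screen_edges()].
#' @return List with elements `network` (`targeted_network`) and
#'   `centrality` (`centrality_report`).
#' @export
#' @examples
#' cohort <- generate_cohort(default_spec(n = 150), seed = 1)
#' fit <- build_targeted_network(cohort)
#' fit$centrality
build_targeted_network <- function(scored, target = "beck", alpha = 0.05,
                                   alpha_norm = 0.05, tol = 1e-10,
                                   max_iter = 1000,
                                   use = c("complete", "pairwise")) {
  num_vars <- names(scored)[vapply(scored, is.numeric, logical(1))]
  if (!target %in% num_vars) {
    stop(sprintf("target '%s' is not a numeric column of the table", target),
         call. = FALSE)
  }
  edges <- screen_edges(scored, alpha = alpha, alpha_norm = alpha_norm,
                        use = use)
  net <- assign_orders(edges, target, nodes = num_vars)
  list(network = net, centrality = eigenvector_centrality(net, tol, max_iter))
}
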