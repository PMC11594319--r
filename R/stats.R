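# Companion descriptive and inferential statistics: rank-based two-group
# and k-group comparisons, internal consistency, and t-based confidence
# intervals, plus writers for the descriptive and comparison tables.

#' Mann-Whitney comparison of two independent samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test using the normal
#' approximation with tie correction and continuity correction, reporting
#' the standardised statistic Z alongside U and the p-value. This is the
#' approximation appropriate at cohort-scale sample sizes; for tiny
#' samples an exact enumeration is available via [stats::wilcox.test()]
#' and is used as the test oracle.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List with `design = "two_sample"`, `u`, `z`, `p`, and the group
#'   sizes.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (sigma2 <= 0) {
    warning("all pooled values tied; p set to 1", call. = FALSE)
    return(list(design = "two_sample", u = u, z = 0, p = 1, n1 = n1, n2 = n2))
  }
  # Continuity correction of 0.5 toward the null mean.
  num <- u - mu
  z <- (num - sign(num) * 0.5) / sqrt(sigma2)
  if (num == 0) z <- 0
  p <- 2 * stats::pnorm(-abs(z))
  list(design = "two_sample", u = u, z = z, p = min(p, 1), n1 = n1, n2 = n2)
}

#' Kruskal-Wallis comparison across k groups with Dunn post hoc tests
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p-value (via
#' [stats::kruskal.test()]). When the omnibus test is significant at 0.05,
#' Dunn's rank-based pairwise comparisons are run with the configured
#' multiple-testing adjustment (Bonferroni by default) and the pairwise
#' significance flags are populated.
#'
#' @param groups Named list of numeric samples (k >= 2, each of length >=
#'   2).
#' @param p_adjust Adjustment method for the pairwise p-values, any method
#'   of [stats::p.adjust()]; default `"bonferroni"`.
#' @return List with `design = "k_sample"`, `h`, `df`, `p`, and `pairwise`
#'   (data frame of group pairs, Dunn z, adjusted p, significance flag;
#'   `NULL` when the omnibus test is not significant).
#' @export
kruskal_wallis <- function(groups, p_adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes), levels = names(groups))
  kt <- stats::kruskal.test(values, labels)
  res <- list(design = "k_sample", h = unname(kt$statistic),
              df = unname(kt$parameter), p = kt$p.value, pairwise = NULL)
  if (is.finite(kt$p.value) && kt$p.value < 0.05) {
    res$pairwise <- dunn_pairwise(values, labels, p_adjust)
  }
  res
}

# Dunn's test: pairwise z statistics on mean ranks with the pooled
# tie-corrected variance.
dunn_pairwise <- function(values, labels, p_adjust = "bonferroni") {
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(rk, labels, mean)
  sizes <- table(labels)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
             p_adjusted = pmin(p_adj, 1), significant = p_adj < 0.05,
             stringsAsFactors = FALSE)
}

#' Cronbach's alpha internal consistency
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#'
#' where \eqn{s_i^2} are the sample item variances and \eqn{s_T^2} the
#' variance of the item sums (n-1 denominators).
#'
#' @param items Numeric matrix or data frame, respondents in rows and
#'   scale items in columns (n >= 2, k >= 2).
#' @return List with `k`, `n` and `alpha` (<= 1).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (!is.numeric(items) || nrow(items) < 2 || ncol(items) < 2) {
    stop("cronbach_alpha needs a numeric matrix with n >= 2 and k >= 2",
         call. = FALSE)
  }
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (!is.finite(total_var) || total_var <= 0) {
    stop("total-score variance is zero; alpha is undefined", call. = FALSE)
  }
  item_var <- sum(apply(items, 2, stats::var))
  list(k = k, n = nrow(items), alpha = k / (k - 1) * (1 - item_var / total_var))
}

#' t-based confidence interval for the mean
#'
#' @param x Numeric sample (n >= 2).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return List with `mean`, `lower`, `upper`, `level`, `n`.
#' @export
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("mean_ci needs at least 2 observations", call. = FALSE)
  stopifnot(level > 0, level < 1)
  m <- mean(x)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, level = level, n = n)
}

#' Descriptive summary of a scored cohort
#'
#' Mean, SD, observed range and t-based confidence interval for every
#' analysis variable, in the layout of a cohort descriptive table.
#'
#' @param scored Scored cohort data frame.
#' @param level Confidence level; default 0.95.
#' @param variables Variables to summarise; default [analysis_variables()]
#'   intersected with the table's columns.
#' @return Data frame with one row per variable.
#' @export
describe_cohort <- function(scored, level = 0.95,
                            variables = intersect(analysis_variables(),
                                                  names(scored))) {
  rows <- lapply(variables, function(v) {
    x <- scored[[v]][is.finite(scored[[v]])]
    ci <- mean_ci(x, level)
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x),
               ci_lower = ci$lower, ci_upper = ci$upper, n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare every analysis variable between the sexes
#'
#' Mann-Whitney tests of each variable between females and males, with
#' group means and SDs, in the layout of a sex-comparison table.
#'
#' @param scored Scored cohort data frame with a `sex` column.
#' @param variables Variables to compare.
#' @return Data frame, one row per variable, with group summaries, Z and p.
#' @export
compare_by_sex <- function(scored,
                           variables = intersect(analysis_variables(),
                                                 names(scored))) {
  rows <- lapply(variables, function(v) {
    f <- scored[[v]][scored$sex == "female"]
    m <- scored[[v]][scored$sex == "male"]
    mw <- mann_whitney(f, m)
    data.frame(variable = v,
               female_mean = mean(f), female_sd = stats::sd(f),
               male_mean = mean(m), male_sd = stats::sd(m),
               z = abs(mw$z), p = mw$p, significant = mw$p < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare every analysis variable across the age bands
#'
#' Kruskal-Wallis tests of each variable across the G1-G4 age bands, with
#' Dunn post hoc flags where the omnibus test is significant.
#'
#' @param scored Scored cohort data frame with an `age` column.
#' @param variables Variables to compare.
#' @param p_adjust Pairwise adjustment method; default `"bonferroni"`.
#' @return List with `omnibus` (data frame of per-variable group means, H
#'   and p) and `pairwise` (data frame of significant-variable pairwise
#'   results).
#' @export
compare_by_age <- function(scored,
                           variables = intersect(analysis_variables(),
                                                 names(scored)),
                           p_adjust = "bonferroni") {
  bands <- list(G1 = c(18, 28), G2 = c(29, 39), G3 = c(40, 50),
                G4 = c(51, Inf))
  split_groups <- function(v) {
    lapply(bands, function(b) {
      scored[[v]][scored$age >= b[1] & scored$age <= b[2]]
    })
  }
  omnibus <- list()
  pairwise <- list()
  for (v in variables) {
    groups <- split_groups(v)
    kw <- kruskal_wallis(groups, p_adjust = p_adjust)
    means <- vapply(groups, mean, numeric(1))
    omnibus[[v]] <- data.frame(
      variable = v, g1_mean = means[["G1"]], g2_mean = means[["G2"]],
      g3_mean = means[["G3"]], g4_mean = means[["G4"]],
      h = kw$h, p = kw$p, significant = kw$p < 0.05,
      stringsAsFactors = FALSE)
    if (!is.null(kw$pairwise)) {
      pw <- kw$pairwise
      pw$variable <- v
      pairwise[[v]] <- pw[, c("variable", setdiff(names(pw), "variable"))]
    }
  }
  list(omnibus = do.call(rbind, c(omnibus, list(make.row.names = FALSE))),
       pairwise = if (length(pairwise) > 0) {
         do.call(rbind, c(pairwise, list(make.row.names = FALSE)))
       })
}
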