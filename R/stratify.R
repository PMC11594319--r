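# Subgroup stratification: the full network analysis is rebuilt
# independently inside each stratum (screening, hop orders and centrality
# are all recomputed on the subgroup's rows), so a variable can be central
# in one subgroup and absent from another.

#' Default strata: general, sex, and four age bands
#'
#' The seven strata of the study design: the unfiltered cohort
#' (`general`), the two sexes, and four age bands covering 18..74 --
#' G1 (18-28), G2 (29-39), G3 (40-50) and G4 (51 and over). Bin edges are
#' inclusive integers; the bands are disjoint and exhaustive.
#'
#' @return Named list of predicate functions on a scored data frame, each
#'   returning a logical row filter.
#' @export
default_strata <- function() {
  list(
    general = function(d) rep(TRUE, nrow(d)),
    female = function(d) d$sex == "female",
    male = function(d) d$sex == "male",
    G1 = function(d) d$age >= 18 & d$age <= 28,
    G2 = function(d) d$age >= 29 & d$age <= 39,
    G3 = function(d) d$age >= 40 & d$age <= 50,
    G4 = function(d) d$age >= 51
  )
}

#' Rebuild the targeted network within each stratum
#'
#' Filters the scored cohort by each stratum predicate and reruns
#' [build_targeted_network()] on the subgroup. Strata smaller than `min_n`
#' are skipped with a warning, since correlation screening and centrality
#' are unreliable at very small n. When the stratum predicate removes the
#' `age` column's informative variation (e.g. within a narrow band), the
#' network simply reflects that: no special-casing is applied.
#'
#' @param scored Scored cohort data frame with `sex` and `age` columns.
#' @param strata Named list of predicate functions; default
#'   [default_strata()].
#' @param min_n Minimum subgroup size; default 30.
#' @param ... Network configuration passed to [build_targeted_network()]
#'   (`target`, `alpha`, `alpha_norm`, `tol`, `max_iter`, `use`).
#' @return Named list; one element per retained stratum, each a list with
#'   `n`, `network` and `centrality`. Skipped strata are absent.
#' @export
#' @examples
#' cohort <- generate_cohort(default_spec(n = 200), seed = 2)
#' fits <- run_stratified(cohort, min_n = 30)
#' names(fits)
run_stratified <- function(scored, strata = default_strata(), min_n = 30,
                           ...) {
  stopifnot(is.list(strata), !is.null(names(strata)))
  out <- list()
  for (s in names(strata)) {
    keep <- strata[[s]](scored)
    keep[is.na(keep)] <- FALSE
    sub <- scored[keep, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning(sprintf("stratum '%s' has n = %d < %d; skipped",
                      s, nrow(sub), min_n), call. = FALSE)
      next
    }
    fit <- build_targeted_network(sub, ...)
    out[[s]] <- list(n = nrow(sub), network = fit$network,
                     centrality = fit$centrality)
  }
  out
}

#' Combine per-stratum centrality scores into one table
#'
#' @param fits Result of [run_stratified()].
#' @return Data frame of eigenvector scores, variables in rows and strata
#'   in columns; `NA` where a variable was absent from a stratum's
#'   network.
#' @export
centrality_table <- function(fits) {
  vars <- sort(unique(unlist(lapply(fits, function(f) names(f$centrality$scores)))))
  tab <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (s in names(fits)) {
    sc <- fits[[s]]$centrality$scores
    tab[[s]] <- unname(sc[vars])
  }
  tab
}
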