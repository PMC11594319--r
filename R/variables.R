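#' Canonical analysis variables
#'
#' The eighteen variables used as network nodes: the depression score (the
#' usual target), demographic and physical measures, the six mood domains
#' plus total mood disturbance, four sleep measures and four nutrition
#' measures. All scored tables produced or consumed by this package use these
#' column names.
#'
#' @return Character vector of the eighteen variable names, in canonical
#'   order.
#' @export
#' @examples
#' analysis_variables()
analysis_variables <- function() {
  c(
    "beck", "age", "physical_activity",
    "tension", "depression", "hostility", "vigor", "fatigue", "confusion",
    "tmd",
    "sleep_quality", "sleep_latency", "sleep_duration", "drowsiness",
    "energy", "carbohydrates", "proteins", "fat"
  )
}

#' @keywords internal
mood_domains <- function() {
  c("tension", "depression", "hostility", "vigor", "fatigue", "confusion")
}

# Shared validation: integer-valued items within [lo, hi], exact count.
# Errors name the first offending index so malformed questionnaire exports
# are easy to locate.
check_items <- function(items, n_items, lo, hi, what) {
  items <- as.numeric(items)
  if (length(items) != n_items) {
    stop(sprintf("%s: expected %d items, got %d", what, n_items, length(items)),
         call. = FALSE)
  }
  bad <- which(!is.finite(items) | items < lo | items > hi |
                 items != round(items))
  if (length(bad) > 0) {
    stop(sprintf("%s: item %d has value %s, outside integers %d..%d",
                 what, bad[1], format(items[bad[1]]), lo, hi),
         call. = FALSE)
  }
  as.integer(round(items))
}
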