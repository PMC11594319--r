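#' Score the Beck Depression Inventory
#'
#' Sums the 21 items of the Beck Depression Inventory, each rated 0--3, into
#' a single symptom score in 0--63. This score is the target node of the
#' correlation networks built by [build_targeted_network()].
#'
#' @param items Numeric vector of exactly 21 integer item responses, each in
#'   0..3.
#' @return Integer depression score in 0..63.
#' @export
#' @examples
#' score_beck(rep(0, 21))
#' score_beck(c(3, 2, 1, rep(0, 18)))
score_beck <- function(items) {
  items <- check_items(items, 21L, 0L, 3L, "beck")
  sum(items)
}

#' Score the Profile of Mood States and total mood disturbance
#'
#' Scores a 42-item mood-states questionnaire into six domain scores --
#' tension, depression, hostility, vigor, fatigue and confusion, six items
#' each, item range 0--4 so each domain spans 0--24 -- and the total mood
#' disturbance (TMD) composite:
#'
#' \deqn{TMD = T + D + H + F + C - V + 100}
#'
#' i.e. the sum of the five negative domains minus vigor, plus a constant of
#' 100 that keeps the composite positive. The attainable TMD range under
#' this formula is 76 (all vigor, nothing else) to 220 (all negative domains
#' maximal, zero vigor).
#'
#' @param items Numeric vector of exactly 42 integer responses, each in 0..4.
#' @param domains Character vector of length 42 mapping each item to its
#'   domain; must contain exactly six items per scored domain. Items mapped
#'   to any other label (e.g. `"filler"`) are validated but not scored --
#'   the 42-item instrument carries six items per mood domain plus six
#'   unscored items. The default assigns consecutive blocks of six in the
#'   order tension, depression, hostility, vigor, fatigue, confusion, then
#'   filler.
#' @return Named list with the six domain scores and `tmd`.
#' @export
#' @examples
#' score_poms(rep(0, 42))$tmd # 100
score_poms <- function(items,
                       domains = rep(c(mood_domains(), "filler"), each = 6)) {
  items <- check_items(items, 42L, 0L, 4L, "poms")
  domains <- as.character(domains)
  if (length(domains) != 42L) {
    stop("poms: domain map must have length 42", call. = FALSE)
  }
  counts <- table(factor(domains, levels = mood_domains()))
  if (any(counts != 6L)) {
    off <- names(counts)[counts != 6L][1]
    stop(sprintf("poms: domain '%s' has %d items, expected 6",
                 off, counts[[off]]), call. = FALSE)
  }
  scores <- vapply(mood_domains(), function(d) sum(items[domains == d]),
                   numeric(1))
  negative <- sum(scores[c("tension", "depression", "hostility",
                           "fatigue", "confusion")])
  c(as.list(scores), list(tmd = negative - scores[["vigor"]] + 100))
}

#' Score IPAQ short-form physical activity in MET-minutes per week
#'
#' Computes weekly physical-activity volume from the short-form
#' International Physical Activity Questionnaire as
#' \eqn{\sum_i MET_i \times days_i \times minutes_i} over walking, moderate
#' and vigorous activity, using the standard short-form multipliers 3.3, 4.0
#' and 8.0 METs. Bouts shorter than 10 continuous minutes do not count
#' toward activity, so any intensity reported with a daily duration below 10
#' minutes contributes zero. Sitting time is accepted for completeness but
#' does not enter the score.
#'
#' @param walking_days,moderate_days,vigorous_days Days per week (0..7) on
#'   which each intensity was performed.
#' @param walking_minutes,moderate_minutes,vigorous_minutes Minutes per day
#'   of each intensity (non-negative).
#' @param sitting_minutes Optional daily sitting minutes; parsed, validated
#'   and ignored.
#' @return Physical-activity volume in MET-minutes/week (non-negative).
#' @export
#' @examples
#' score_ipaq(vigorous_days = 3, vigorous_minutes = 30) # 8.0 * 3 * 30 = 720
#' score_ipaq(walking_days = 5, walking_minutes = 9)    # sub-bout, 0
score_ipaq <- function(walking_days = 0, walking_minutes = 0,
                       moderate_days = 0, moderate_minutes = 0,
                       vigorous_days = 0, vigorous_minutes = 0,
                       sitting_minutes = NA_real_) {
  days <- c(walking = walking_days, moderate = moderate_days,
            vigorous = vigorous_days)
  mins <- c(walking = walking_minutes, moderate = moderate_minutes,
            vigorous = vigorous_minutes)
  if (any(!is.finite(days) | days < 0 | days > 7 | days != round(days))) {
    stop("ipaq: weekly frequencies must be integers in 0..7", call. = FALSE)
  }
  if (any(!is.finite(mins) | mins < 0)) {
    stop("ipaq: daily durations must be non-negative minutes", call. = FALSE)
  }
  if (!is.na(sitting_minutes) && sitting_minutes < 0) {
    stop("ipaq: sitting minutes must be non-negative", call. = FALSE)
  }
  met <- c(walking = 3.3, moderate = 4.0, vigorous = 8.0)
  mins[mins < 10] <- 0 # below the 10-minute continuous-bout threshold
  sum(met * days * mins)
}

#' Score sleep variables from PSQI components and the Epworth scale
#'
#' Derives the four sleep variables of the analysis: sleep quality as the
#' Pittsburgh Sleep Quality Index global score (sum of seven 0--3
#' components, range 0--21, higher = poorer sleep), self-reported sleep
#' latency (minutes) and sleep duration (hours) passed through unchanged,
#' and daytime drowsiness as the Epworth Sleepiness Scale total (sum of
#' eight 0--3 items, range 0--24).
#'
#' @param psqi_components Numeric vector of exactly 7 integer component
#'   scores, each 0..3.
#' @param sleep_latency Reported sleep-onset latency in minutes
#'   (non-negative).
#' @param sleep_duration Reported sleep duration in hours (non-negative).
#' @param ess_items Numeric vector of exactly 8 integer items, each 0..3.
#' @return Named list with `sleep_quality`, `sleep_latency`,
#'   `sleep_duration` and `drowsiness`.
#' @export
#' @examples
#' score_sleep(rep(3, 7), 20, 7.5, rep(1, 8))
score_sleep <- function(psqi_components, sleep_latency, sleep_duration,
                        ess_items) {
  psqi <- check_items(psqi_components, 7L, 0L, 3L, "psqi")
  ess <- check_items(ess_items, 8L, 0L, 3L, "ess")
  if (!is.finite(sleep_latency) || sleep_latency < 0) {
    stop("sleep latency must be non-negative minutes", call. = FALSE)
  }
  if (!is.finite(sleep_duration) || sleep_duration < 0) {
    stop("sleep duration must be non-negative hours", call. = FALSE)
  }
  list(
    sleep_quality = sum(psqi),
    sleep_latency = as.numeric(sleep_latency),
    sleep_duration = as.numeric(sleep_duration),
    drowsiness = sum(ess)
  )
}

# Raw-table column schema ----------------------------------------------------

#' Column schema for raw participant tables
#'
#' A raw cohort table has one row per participant with demographics followed
#' by questionnaire item responses. Nutrition variables (energy,
#' carbohydrates, proteins, fat) appear pre-quantified in g/day and kcal/day
#' because food-frequency-to-macronutrient conversion requires an external
#' food-composition database and is outside the scope of this package.
#'
#' @return Character vector of required column names for a raw table.
#' @export
raw_schema <- function() {
  c("id", "sex", "age",
    paste0("beck_", sprintf("%02d", 1:21)),
    paste0("poms_", sprintf("%02d", 1:42)),
    "ipaq_walk_days", "ipaq_walk_min", "ipaq_mod_days", "ipaq_mod_min",
    "ipaq_vig_days", "ipaq_vig_min", "ipaq_sit_min",
    paste0("psqi_c", 1:7), "psqi_latency_min", "psqi_duration_h",
    paste0("ess_", sprintf("%02d", 1:8)),
    "energy", "carbohydrates", "proteins", "fat")
}

#' Score a raw participant table into the analysis variables
#'
#' Applies [score_beck()], [score_poms()], [score_ipaq()] and
#' [score_sleep()] row-wise to a raw table following [raw_schema()],
#' returning a scored table with `id`, `sex`, `age` and the eighteen
#' [analysis_variables()].
#'
#' @param raw Data frame with the columns of [raw_schema()].
#' @return Scored data frame, one row per participant.
#' @export
score_participants <- function(raw) {
  missing_cols <- setdiff(raw_schema(), names(raw))
  if (length(missing_cols) > 0) {
    stop("raw table is missing columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) ", ...", call. = FALSE)
  }
  sex <- as.character(raw$sex)
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  age <- as.numeric(raw$age)
  if (any(!is.finite(age) | age < 18 | age > 74 | age != round(age))) {
    stop("age must be an integer in 18..74", call. = FALSE)
  }
  beck_cols <- paste0("beck_", sprintf("%02d", 1:21))
  poms_cols <- paste0("poms_", sprintf("%02d", 1:42))
  psqi_cols <- paste0("psqi_c", 1:7)
  ess_cols <- paste0("ess_", sprintf("%02d", 1:8))

  # Vectorised item validation: integer values within bounds, errors naming
  # the first offending row and item.
  item_block <- function(cols, lo, hi, what) {
    m <- as.matrix(raw[, cols])
    storage.mode(m) <- "numeric"
    bad <- which(!is.finite(m) | m < lo | m > hi | m != round(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("%s: row %d item %d has value %s, outside integers %d..%d",
                   what, bad[1, 1], bad[1, 2], format(m[bad[1, , drop = FALSE]]),
                   lo, hi), call. = FALSE)
    }
    m
  }
  beck_m <- item_block(beck_cols, 0, 3, "beck")
  poms_m <- item_block(poms_cols, 0, 4, "poms")
  psqi_m <- item_block(psqi_cols, 0, 3, "psqi")
  ess_m <- item_block(ess_cols, 0, 3, "ess")
  poms_dom <- rep(c(mood_domains(), "filler"), each = 6)
  dom_sum <- function(d) rowSums(poms_m[, poms_dom == d, drop = FALSE])

  freq <- as.matrix(raw[, c("ipaq_walk_days", "ipaq_mod_days",
                            "ipaq_vig_days")])
  mins <- as.matrix(raw[, c("ipaq_walk_min", "ipaq_mod_min",
                            "ipaq_vig_min")])
  if (any(!is.finite(freq) | freq < 0 | freq > 7 | freq != round(freq))) {
    stop("ipaq: weekly frequencies must be integers in 0..7", call. = FALSE)
  }
  if (any(!is.finite(mins) | mins < 0)) {
    stop("ipaq: daily durations must be non-negative minutes", call. = FALSE)
  }
  mins[mins < 10] <- 0 # sub-bout durations do not count
  met <- rowSums(freq * mins * matrix(c(3.3, 4.0, 8.0), nrow(raw), 3,
                                      byrow = TRUE))
  latency <- as.numeric(raw$psqi_latency_min)
  duration <- as.numeric(raw$psqi_duration_h)
  if (any(!is.finite(latency) | latency < 0)) {
    stop("sleep latency must be non-negative minutes", call. = FALSE)
  }
  if (any(!is.finite(duration) | duration < 0)) {
    stop("sleep duration must be non-negative hours", call. = FALSE)
  }

  tension <- dom_sum("tension")
  depression <- dom_sum("depression")
  hostility <- dom_sum("hostility")
  vigor <- dom_sum("vigor")
  fatigue <- dom_sum("fatigue")
  confusion <- dom_sum("confusion")
  scored <- data.frame(
    id = as.character(raw$id), sex = sex,
    beck = rowSums(beck_m), age = age, physical_activity = met,
    tension = tension, depression = depression, hostility = hostility,
    vigor = vigor, fatigue = fatigue, confusion = confusion,
    tmd = tension + depression + hostility + fatigue + confusion -
      vigor + 100,
    sleep_quality = rowSums(psqi_m), sleep_latency = latency,
    sleep_duration = duration, drowsiness = rowSums(ess_m),
    energy = as.numeric(raw$energy),
    carbohydrates = as.numeric(raw$carbohydrates),
    proteins = as.numeric(raw$proteins), fat = as.numeric(raw$fat),
    stringsAsFactors = FALSE)
  rownames(scored) <- NULL
  scored[, c("id", "sex", analysis_variables())]
}

#' Read a cohort table from delimited text
#'
#' Accepts either a raw item-level table (columns of [raw_schema()], scored
#' on read) or an already-scored table containing `sex`, `age` and the
#' eighteen [analysis_variables()], which is validated and returned as is.
#'
#' @param path Path to a CSV file.
#' @return Scored data frame with `sex`, `age` and the analysis variables.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  scored_cols <- c("sex", analysis_variables())
  if (all(scored_cols %in% names(tab))) {
    validate_scored(tab)
    return(tab)
  }
  if (all(raw_schema() %in% names(tab))) {
    return(score_participants(tab))
  }
  stop("file matches neither the raw item schema nor the scored schema; ",
       "see raw_schema() and analysis_variables()", call. = FALSE)
}

# Checks the score-level invariants a scored table must satisfy.
validate_scored <- function(scored) {
  needed <- c("sex", analysis_variables())
  missing_cols <- setdiff(needed, names(scored))
  if (length(missing_cols) > 0) {
    stop("scored table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  neg <- scored$tension + scored$depression + scored$hostility +
    scored$fatigue + scored$confusion
  if (any(abs(scored$tmd - (neg - scored$vigor + 100)) > 1e-8)) {
    stop("tmd violates tmd = T + D + H + F + C - V + 100", call. = FALSE)
  }
  if (any(scored$beck < 0 | scored$beck > 63)) {
    stop("beck score outside 0..63", call. = FALSE)
  }
  invisible(scored)
}
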