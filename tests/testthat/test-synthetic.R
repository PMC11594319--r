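test_that("the default spec encodes the study conditions", {
  spec <- default_spec()
  expect_equal(spec$n, 411)
  expect_equal(spec$marginals$energy$mean, 3187.0)
  expect_equal(spec$marginals$sleep_quality$mean, 6.2)
  expect_equal(spec$marginals$sleep_quality$sd, 2.9)
  expect_equal(spec$correlation["beck", "sleep_quality"], 0.52)
  expect_equal(spec$correlation["sleep_quality", "carbohydrates"], 0.13)
  expect_equal(spec$sex_proportion_female, 322 / 411)
  expect_equal(spec$age_bins$weight, c(241, 70, 60, 40) / 411)
  expect_equal(spec$sex_shifts[["vigor"]], -2.5)
  ev <- eigen(spec$correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("generation is bit-identical under the same spec and seed", {
  spec <- default_spec(n = 120)
  a <- generate_cohort(spec, seed = 9)
  b <- generate_cohort(spec, seed = 9)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 10)
  expect_false(identical(a, c))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(301)
  before <- .Random.seed
  invisible(generate_cohort(default_spec(n = 20), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("identity correlation yields near-zero sample correlations", {
  co <- generate_cohort(gaussian_spec(6, 100000), seed = 302)
  cm <- cor(co[, paste0("v", 1:6)])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.015)
})

test_that("the planted direct correlation survives the marginal transforms", {
  co <- generate_cohort(default_spec(n = 100000), seed = 303)
  # +-0.02 absolute: copula preserves the latent value up to truncation and
  # discretisation attenuation
  expect_lt(abs(cor(co$beck, co$sleep_quality) - 0.52), 0.02)
  expect_lt(abs(cor(co$sleep_quality, co$carbohydrates) - 0.13), 0.02)
})

test_that("generated profiles satisfy the instrument invariants", {
  co <- generate_cohort(default_spec(n = 2000), seed = 304)
  validate_scored <- function(v, lo, hi, int = TRUE) {
    x <- co[[v]]
    expect_true(all(x >= lo & x <= hi), label = v)
    if (int) expect_true(all(x == round(x)), label = v)
  }
  validate_scored("beck", 0, 63)
  for (d in c("tension", "depression", "hostility", "vigor", "fatigue",
              "confusion")) {
    validate_scored(d, 0, 24)
  }
  validate_scored("sleep_quality", 0, 21)
  validate_scored("drowsiness", 0, 24)
  validate_scored("age", 18, 74)
  expect_true(all(co$tmd == co$tension + co$depression + co$hostility +
                    co$fatigue + co$confusion - co$vigor + 100))
  expect_true(all(co$physical_activity == 0 |
                    (co$physical_activity >= 80 &
                       co$physical_activity %% 8 == 0)))
  expect_true(all(co$energy >= 0))
  # energy is coherent with the macronutrients up to the noise term
  pred <- 4 * co$carbohydrates + 4 * co$proteins + 9 * co$fat
  expect_lt(sd(co$energy - pred), 200)
  expect_gt(cor(co$energy, pred), 0.98)
})

test_that("marginal moments track the configured targets", {
  co <- generate_cohort(default_spec(n = 50000), seed = 305)
  spec <- default_spec()
  for (v in c("beck", "tension", "sleep_quality", "carbohydrates",
              "proteins", "fat", "sleep_duration")) {
    m <- spec$marginals[[v]]
    # truncation and discretisation shift moments; allow a coarse band
    expect_equal(mean(co[[v]]), m$mean, tolerance = 0.15 * m$mean + 0.5,
                 label = v)
    expect_gt(sd(co[[v]]), 0.6 * m$sd)
  }
})

test_that("quota composition is deterministic; bernoulli is seeded", {
  spec <- default_spec()
  co <- generate_cohort(spec, seed = 306)
  expect_equal(sum(co$sex == "female"), 322)
  expect_equal(sum(co$sex == "male"), 89)
  expect_equal(as.vector(table(cut(co$age, c(17, 28, 39, 50, 74)))),
               c(241, 70, 60, 40))
  bern <- generate_cohort(spec, seed = 306, composition = "bernoulli")
  expect_equal(mean(bern$sex == "female"), 322 / 411, tolerance = 0.08)
  expect_identical(bern,
                   generate_cohort(spec, seed = 306,
                                   composition = "bernoulli"))
})

test_that("sex contrasts shift the configured variables and preserve the pooled mean", {
  spec <- default_spec(n = 60000)
  co <- generate_cohort(spec, seed = 307)
  f <- co[co$sex == "female", ]
  m <- co[co$sex == "male", ]
  expect_equal(mean(f$tension) - mean(m$tension), 2.9, tolerance = 0.4)
  expect_equal(mean(f$vigor) - mean(m$vigor), -2.5, tolerance = 0.4)
  expect_equal(mean(f$beck) - mean(m$beck), 2.8, tolerance = 0.5)
  # unshifted variables show no contrast
  expect_equal(mean(f$carbohydrates) - mean(m$carbohydrates), 0,
               tolerance = 4)
})

test_that("a non-PSD correlation matrix is repaired with a warning", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_warning(co <- generate_cohort(gaussian_spec(3, 500, R), seed = 308),
                 "nearest-PSD")
  expect_equal(nrow(co), 500)
})

test_that("backfilled items re-score to the generated profiles exactly", {
  co <- generate_cohort(default_spec(n = 800), seed = 309)
  raw <- backfill_items(co)
  expect_true(all(raw[, paste0("beck_", sprintf("%02d", 1:21))] <= 3))
  expect_true(all(raw[, paste0("poms_", sprintf("%02d", 1:42))] <= 4))
  rescored <- score_participants(raw)
  for (v in analysis_variables()) {
    expect_identical(as.numeric(rescored[[v]]), as.numeric(co[[v]]),
                     label = v)
  }
  # boundary scores
  one <- co[1, ]
  one$beck <- 0
  expect_equal(sum(backfill_items(one)[, paste0("beck_", sprintf("%02d", 1:21))]), 0)
  one$beck <- 63
  expect_true(all(backfill_items(one)[, paste0("beck_", sprintf("%02d", 1:21))] == 3))
  one$beck <- 64
  expect_error(backfill_items(one), "not attainable")
  one$beck <- 5
  one$physical_activity <- 12 # not a multiple of 8 above the bout floor
  expect_error(backfill_items(one), "vigorous bout")
})

test_that("planted edges are recovered at their hop orders", {
  direct <- 0
  both <- 0
  second_order_ok <- TRUE
  for (s in 1:40) {
    co <- generate_cohort(default_spec(), seed = 400 + s)
    fit <- suppressWarnings(build_targeted_network(co))
    e <- fit$network$edges
    d <- e[(e$var_a == "beck" & e$var_b == "sleep_quality") |
             (e$var_b == "beck" & e$var_a == "sleep_quality"), ]
    sc <- e[(e$var_a == "sleep_quality" & e$var_b == "carbohydrates") |
              (e$var_b == "sleep_quality" & e$var_a == "carbohydrates"), ]
    if (nrow(d) == 1 && d$order == 1) direct <- direct + 1
    if (nrow(d) == 1 && nrow(sc) == 1) {
      both <- both + 1
      if (sc$order != 2) second_order_ok <- FALSE
    }
  }
  expect_equal(direct, 40)
  expect_gt(both, 0)
  expect_true(second_order_ok)
})

test_that("a cohort spec survives a YAML round trip", {
  spec <- default_spec(n = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec(spec, path)
  back <- read_spec(path)
  expect_equal(back$n, spec$n)
  expect_equal(back$correlation, spec$correlation)
  expect_equal(back$sex_shifts, spec$sex_shifts)
  expect_equal(back$marginals$energy$mean, 3187.0)
  expect_identical(generate_cohort(back, seed = 5),
                   generate_cohort(spec, seed = 5))
})
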