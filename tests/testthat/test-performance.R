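test_that("rsd follows the sample-SD definition", {
  expect_equal(rsd(c(100, 100, 100)), 0)
  expect_equal(rsd(c(90, 100, 110)), 10)
  expect_equal(rsd(c(10, 20, 30)), 50)
  expect_error(rsd(5), class = "ddplexr_invalid")
  expect_error(rsd(c(-1, 1)), class = "ddplexr_invalid")
})

test_that("1.5 x IQR outlier rule uses interpolated quartiles", {
  expect_identical(iqr_outliers(c(1, 2, 3, 4, 100)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(c(1, 2, 3, 4, 5))))
  expect_false(any(iqr_outliers(rep(7, 6)))) # zero IQR, fences collapse
  expect_error(iqr_outliers(c(1, 2, 3)), class = "ddplexr_invalid")
})

test_that("aLOQ is the lowest mean passing the RSD rule", {
  lv <- list(
    dilution_level("A", 100, c(90, 100, 110)),  # RSD 10%
    dilution_level("B", 20, c(10, 20, 30))      # RSD 50%
  )
  res <- determine_aloq(lv)
  expect_equal(res$aloq, 100)
  expect_equal(res$levels$rsd, c(10, 50))

  # both levels passing -> the smaller mean wins
  lv2 <- list(
    dilution_level("A", 100, c(90, 100, 110)),
    dilution_level("B", 20, c(19, 20, 21))
  )
  expect_equal(determine_aloq(lv2)$aloq, 20)

  # no level passing -> undefined, with per-level diagnostics
  res3 <- determine_aloq(lv, max_rsd = 5)
  expect_true(is.na(res3$aloq))
  expect_equal(nrow(res3$levels), 2)
})

test_that("aLOQ outlier removal can rescue a level", {
  # one wild replicate pushes RSD over 25%; dropping it brings it back
  vals <- c(100, 104, 96, 101, 99, 103, 97, 100, 102, 98, 100, 101, 99, 100, 220)
  lv <- list(dilution_level("A", 100, vals))
  expect_true(is.na(determine_aloq(lv)$aloq))
  res <- determine_aloq(lv, remove_outliers = TRUE)
  expect_false(is.na(res$aloq))
  expect_equal(res$levels$n_outliers, 1L)
})

test_that("aLOQ is monotone in the RSD threshold", {
  set.seed(13)
  lv <- lapply(1:6, function(i) {
    mu <- 10 * 2^i
    dilution_level(paste0("L", i), mu, rnorm(10, mu, mu * (7 - i) / 12))
  })
  thresholds <- c(10, 15, 20, 25, 30, 40, 60)
  aloqs <- vapply(thresholds,
                  function(t) determine_aloq(lv, max_rsd = t)$aloq,
                  numeric(1))
  aloqs <- aloqs[!is.na(aloqs)]
  expect_true(all(diff(aloqs) <= 0))
})

test_that("aLOD applies the 14-of-15 positive-replicate rule", {
  mk <- function(droplets) {
    dilution_level("L", 15, replicate_values = rep(15, 15),
                   replicate_positive_droplets = droplets)
  }
  detects <- function(lv) determine_alod(list(lv))$levels$detects
  expect_true(detects(mk(c(rep(10, 14), 2))))   # 14/15 positive
  expect_false(detects(mk(c(rep(10, 13), 2, 2)))) # 13/15 positive
  expect_true(detects(mk(rep(3, 15))))          # exactly 3 droplets counts

  # stricter setting: zero negatives allowed
  lv <- mk(c(rep(10, 14), 2))
  strict <- determine_alod(list(lv), max_negative_replicates = 0)
  expect_false(strict$levels$detects)
  expect_error(determine_alod(list(
    dilution_level("L", 15, rep(15, 15))
  )), class = "ddplexr_invalid")
})

test_that("aLOD is never laxer with fewer allowed negatives", {
  set.seed(17)
  lv <- lapply(1:5, function(i) {
    mu <- 4 * 2^i
    dilution_level(paste0("L", i), mu, rnorm(15, mu, mu / 5),
                   replicate_positive_droplets = rpois(15, mu / 3))
  })
  a0 <- determine_alod(lv, max_negative_replicates = 0)$alod
  a1 <- determine_alod(lv, max_negative_replicates = 1)$alod
  if (!is.na(a0) && !is.na(a1)) expect_gte(a0, a1)
})

test_that("percent bias is signed and anchored to the published comparison", {
  expect_equal(round(percent_bias(67576, 62109), 1), -8.1)
  expect_equal(round(percent_bias(1237, 1119), 1), -9.5)
  expect_equal(percent_bias(500, 500), 0)
  expect_error(percent_bias(0, 10), class = "ddplexr_invalid")
  # not antisymmetric under swapping: the denominator changes
  expect_false(isTRUE(all.equal(percent_bias(100, 80),
                                -percent_bias(80, 100))))
})

test_that("z-scores pass strictly below |z| = 2", {
  expect_equal(z_score(1.0, 1.0, 0.1)$z, 0)
  expect_true(z_score(1.0, 1.0, 0.1)$pass)
  at_boundary <- z_score(1.2, 1.0, 0.1)
  expect_equal(at_boundary$z, 2)
  expect_false(at_boundary$pass)
  near <- z_score(1.19, 1.0, 0.1)
  expect_equal(near$z, 1.9)
  expect_true(near$pass)
  expect_error(z_score(1, 1, 0), class = "ddplexr_invalid")
})

test_that("linearity recovers identity and scaling exactly", {
  x <- c(10, 100, 1000, 10000)
  fit <- linearity(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  fit2 <- linearity(x, 2 * x)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r_squared, 1)
  fit3 <- linearity(x, 2 * x, log10 = TRUE)
  expect_equal(fit3$slope, 1)
  expect_error(linearity(c(1, 1, 1), c(1, 2, 3)), class = "ddplexr_invalid")
})

test_that("simulated dilution series are linear over the dynamic range", {
  layout <- quad_layout()
  base <- quad_sim(copies = 10000, seed = 41)
  ser <- simulate_dilution_series(
    base, layout,
    dilution_factors = c(1, 0.4, 0.16, 0.064, 0.0256, 0.001),
    replicates_per_level = 3
  )
  df <- ser$results[ser$results$target == "hmgA", ]
  fit <- linearity(df$assigned_copies, df$measured_copies)
  expect_gte(fit$r_squared, 0.98)
  expect_equal(fit$slope, 1, tolerance = 0.1)
})

test_that("unit conversion is directional and exactly invertible", {
  expect_equal(convert_units(1.0, conversion_factor("consensus"),
                             "mass_to_copies"), 0.5)
  expect_equal(convert_units(1.0, conversion_factor("male_parent"),
                             "mass_to_copies"), 0.4)
  expect_equal(convert_units(1.0, conversion_factor("female_parent"),
                             "mass_to_copies"), 0.6)
  for (origin in c("consensus", "male_parent", "female_parent")) {
    f <- conversion_factor(origin)
    expect_identical(
      convert_units(convert_units(2.5, f, "mass_to_copies"), f,
                    "copies_to_mass"),
      2.5
    )
  }
  expect_equal(conversion_factor("custom", 0.45)$value, 0.45)
  expect_error(conversion_factor("custom", 1.5), class = "ddplexr_invalid")
})

test_that("false-positive rate is a percentage of the paired high-target positives", {
  expect_equal(false_positive_rate(5, 2000), 0.25)
  expect_equal(false_positive_rate(0, 1500), 0)
  expect_error(false_positive_rate(5, 0), class = "ddplexr_invalid")
})

test_that("GM labelling flags mark the 0.9% and 0.1% thresholds inclusively", {
  flags <- gm_labelling_flags(c(0.05, 0.1, 0.5, 0.9, 2))
  expect_equal(flags$exceeds_0_9, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(flags$exceeds_0_1, c(FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("performance_report assembles all rule blocks from a replicate table", {
  set.seed(19)
  reps <- do.call(rbind, lapply(c(1000, 100, 5), function(mu) {
    data.frame(
      level_id = paste0("L", mu), target = "tgt",
      assigned_copies = mu,
      measured_copies = rnorm(15, mu, mu * ifelse(mu > 50, 0.05, 0.6)),
      positive_droplets = rpois(15, mu / 2)
    )
  }))
  rep_bias <- data.frame(target = "tgt", reference = 1000, measured = 900)
  rep_z <- data.frame(sample = "pt1", measured = 1.1, assigned = 1.0,
                      sigma = 0.2)
  rep_gm <- data.frame(sample = "pt1", gm_percent = 1.1)
  report <- performance_report(reps, bias = rep_bias, z = rep_z, gm = rep_gm)
  expect_s3_class(report, "performance_report")
  expect_equal(nrow(report$limits), 1)
  expect_false(is.na(report$limits$aloq))
  expect_false(is.na(report$limits$alod))
  expect_lte(report$limits$alod, report$limits$aloq)
  expect_equal(round(report$bias$bias_percent, 1), -10)
  expect_equal(report$z$z, 0.5)
  expect_true(report$gm$exceeds_0_9)

  f <- tempfile(fileext = ".tsv")
  write_performance_report(report, f)
  txt <- readLines(f)
  expect_true(any(grepl("^# limits$", txt)))
  expect_true(any(grepl("^# z_scores$", txt)))
})
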