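test_that("internal validation is exact for deterministic margins", {
  cfg <- world_config(n_truth = 20000)
  truth <- withr::with_seed(3, make_ground_truth(cfg))
  census <- derive_census_crosstab(truth, suppression_threshold = 1L)
  pop <- withr::with_seed(4, expand_strata(census, "deterministic"))
  src <- truth |>
    dplyr::mutate(age_band = age_band(age)) |>
    dplyr::group_by(age_band, sex) |>
    dplyr::summarise(reference_value = mean(ethnicity == "Maori"),
                     .groups = "drop")
  cmp <- internal_compare(pop, src, "ethnicity", c("age_band", "sex"),
                          level = "Maori")
  expect_equal(max(cmp$abs_diff), 0)
  expect_true(all(cmp$pass))
})

test_that("internal validation bounds Monte Carlo stages by 4 SE", {
  cfg <- world_config(n_truth = 60000)
  truth <- withr::with_seed(5, make_ground_truth(cfg))
  census <- derive_census_crosstab(truth, suppression_threshold = 1L)
  pop <- withr::with_seed(6, expand_strata(census, "monte_carlo"))
  src <- truth |>
    dplyr::mutate(age_band = age_band(age)) |>
    dplyr::group_by(age_band) |>
    dplyr::summarise(reference_value = mean(smoking == "current"),
                     .groups = "drop")
  cmp <- internal_compare(pop, src, "smoking", "age_band", level = "current")
  expect_true(all(cmp$pass))
  expect_gt(max(cmp$abs_diff), 0)  # stochastic, not copied
})

test_that("strata missing from the population are flagged, not dropped", {
  pop <- make_pop(500, seed = 9)
  pop <- pop[pop$age < 75, ]
  src <- tibble::tibble(age_band = age_band_levels,
                        reference_value = 0.1)
  cmp <- internal_compare(pop, src, "diabetes", "age_band")
  expect_equal(nrow(cmp), 5L)
  expect_equal(cmp$n[cmp$age_band == "75-84"], 0L)
  expect_false(cmp$pass[cmp$age_band == "75-84"])
  expect_error(
    internal_compare(pop, src[1:2, ], "diabetes", "age_band"),
    "stratum mismatch")
})

test_that("external comparison flags interval membership per stratum", {
  pop <- make_pop(3000, seed = 12)
  ref <- tibble::tibble(
    variable = "diabetes",
    age_low = c(30, 30), age_high = c(85, 85), sex = "all",
    ethnicity = "all",
    estimate = c(0.045, 0.045), ci_low = c(0.03, 0.03),
    ci_high = c(0.30, 0.06))
  got <- external_compare(pop, ref, "diabetes", level = NULL)
  prev <- mean(pop$diabetes)
  expect_equal(got$synthetic_value, c(prev, prev))
  expect_true(got$within_ci[1])   # wide interval contains the prevalence
  expect_false(got$within_ci[2])  # narrow one does not (prev ~ 0.11)
  expect_equal(attr(got, "summary")[["within"]], 1L)
})

test_that("ethnic re-aggregation maps Asian onto its member groups", {
  pop <- make_pop(4000, seed = 14)
  ref <- tibble::tibble(variable = "diabetes", age_low = 30, age_high = 85,
                        sex = "all", ethnicity = "Asian",
                        estimate = 0.1, ci_low = 0, ci_high = 1)
  got <- external_compare(pop, ref, "diabetes")
  inside <- pop$ethnicity %in% c("Chinese", "OtherAsian")
  expect_equal(got$n, sum(inside))
  expect_equal(got$synthetic_value, mean(pop$diabetes[inside]))
  bad <- ref
  bad$ethnicity <- "Atlantean"
  expect_error(external_compare(pop, bad, "diabetes"), "unmappable")
})

test_that("survey intervals from the same truth attain nominal coverage", {
  cfg <- world_config(n_truth = 40000, survey_n = 2500)
  truth <- withr::with_seed(20, make_ground_truth(cfg))
  truth$band <- age_band(truth$age)
  true_prev <- tapply(truth$diabetes, truth$band, mean)
  hits <- 0L; total <- 0L
  withr::with_seed(21, {
    for (i in 1:30) {
      ref <- suppressWarnings(
        derive_reference_survey(truth, cfg$survey_n, "diabetes"))
      cover <- true_prev[paste0(ref$age_low, "-", ref$age_high - 1)] >=
        ref$ci_low & true_prev[paste0(ref$age_low, "-", ref$age_high - 1)] <=
        ref$ci_high
      hits <- hits + sum(cover); total <- total + length(cover)
    }
  })
  expect_gt(hits / total, 0.90)
})

test_that("the adjusted odds ratio reduces to the 2x2 cross-product", {
  pop <- make_pop(20000, seed = 25)
  pop$maori <- pop$ethnicity == "Maori"
  t22 <- table(pop$maori, pop$prior_cvd)
  closed_form <- (t22[1, 1] * t22[2, 2]) / (t22[1, 2] * t22[2, 1])
  fit <- adjusted_odds_ratio(pop, "prior_cvd", "maori", adjusters = NULL)
  expect_equal(fit$or, closed_form, tolerance = 1e-6)
})

test_that("embedded ethnicity effects are recovered and nulls stay null", {
  cfg <- world_config(cvd_eth_logor = c(Maori = log(1.58)))
  pop <- withr::with_seed(26, make_ground_truth(cfg, n = 80000))
  pop$maori <- pop$ethnicity == "Maori"
  fit <- adjusted_odds_ratio(pop, "prior_cvd", "maori")
  expect_true(fit$ci_low <= 1.58 && 1.58 <= fit$ci_high)

  cfg0 <- world_config(cvd_eth_logor = c(Maori = 0))
  pop0 <- withr::with_seed(27, make_ground_truth(cfg0, n = 80000))
  pop0$maori <- pop0$ethnicity == "Maori"
  fit0 <- adjusted_odds_ratio(pop0, "prior_cvd", "maori")
  expect_true(fit0$ci_low <= 1 && 1 <= fit0$ci_high)
})

test_that("replicate variability uses n-1 and scales like binomial error", {
  pops <- lapply(1:6, function(r) make_pop(20000, seed = 100 + r))
  out <- replicate_variability(pops, "diabetes")
  # n-1 definition, checked on a two-replicate pair
  two <- replicate_variability(pops[1:2], "diabetes")
  band1 <- vapply(pops[1:2],
                  function(p) mean(p$diabetes[age_band(p$age) == "30-44"]),
                  numeric(1))
  expect_equal(two$sd[two$age_band == "30-44"], stats::sd(band1))
  # binomial oracle within factor 3 (6 replicates is a noisy sd estimate)
  for (i in seq_len(nrow(out))) {
    oracle <- sqrt(out$mean[i] * (1 - out$mean[i]) / out$n_mean[i])
    expect_lt(out$sd[i], 3 * oracle)
    expect_gt(out$sd[i], oracle / 3)
  }
})

test_that("larger strata show smaller relative replicate variability", {
  pops <- lapply(1:8, function(r) make_pop(30000, seed = 200 + r))
  out <- dplyr::bind_rows(lapply(pops, function(p) {
    p$band <- age_band(p$age)
    tibble::tibble(big = mean(p$diabetes[p$ethnicity == "European"]),
                   small = mean(p$diabetes[p$ethnicity == "Pacific"]))
  }))
  rel <- function(x) stats::sd(x) / mean(x)
  expect_lt(rel(out$big), rel(out$small))
})
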