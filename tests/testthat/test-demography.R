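test_that("ethnic prioritisation follows the national priority order", {
  expect_equal(prioritize_ethnicity(c("European", "Maori")), "Maori")
  expect_equal(prioritize_ethnicity(c("Chinese", "Indian")), "Indian")
  expect_equal(prioritize_ethnicity("European"), "European")
  expect_equal(prioritize_ethnicity(c("Other", "OtherAsian", "Pacific")),
               "Pacific")
  expect_error(prioritize_ethnicity(character()), "empty")
  expect_error(prioritize_ethnicity("Klingon"), "unknown")
})

test_that("suppressed cells resolve to integers in [1, 5]", {
  strata <- tiny_census()
  withr::with_seed(1, {
    for (i in 1:20) {
      res <- resolve_suppressed_cells(strata)
      expect_false(anyNA(res[smoking_levels]))
      expect_true(res$ex[4] %in% 1:5)
      # untouched cells identical
      expect_identical(res$never, strata$never)
    }
  })
  no_supp <- strata[1:2, ]
  expect_identical(resolve_suppressed_cells(no_supp), no_supp)
})

test_that("total-constrained resolution matches known row totals", {
  strata <- tibble::tibble(
    age_band_low = 50L, sex = "male", ethnicity = "European",
    nzdep_quintile = "2", never = 40L, ex = NA_integer_,
    current = NA_integer_)
  # brute-force oracle: feasible (ex, current) fills with sum 7
  feasible <- subset(expand.grid(ex = 1:5, current = 1:5),
                     ex + current == 7)
  withr::with_seed(3, {
    seen <- replicate(50, {
      res <- resolve_suppressed_cells(strata, "total_constrained",
                                      row_totals = 47L)
      expect_equal(res$ex + res$current, 7L)
      paste(res$ex, res$current)
    })
  })
  expect_true(all(seen %in% paste(feasible$ex, feasible$current)))
  expect_error(
    resolve_suppressed_cells(strata, "total_constrained", row_totals = 60L),
    "infeasible")
})

test_that("unknown categories are redistributed proportionally and conserved", {
  strata <- tibble::tibble(
    age_band_low = 40L, sex = "female",
    ethnicity = c("Maori", "European", "Unknown"),
    nzdep_quintile = "3",
    never = c(60L, 40L, 10L), ex = c(0L, 0L, 0L), current = c(3L, 4L, 7L))
  out <- redistribute_unknowns(strata)
  expect_equal(nrow(out), 2L)
  # 10 unknowns split 60/40 exactly
  expect_equal(out$never, c(66L, 44L))
  # 7 unknowns over the 3/4 split conserve the total
  expect_equal(sum(out$current), 14L)
  expect_equal(sum(as.matrix(out[smoking_levels])),
               sum(as.matrix(strata[smoking_levels])))
  # no unknowns: identity
  expect_identical(redistribute_unknowns(out), out)
})

test_that("redistribution falls back when the matching margin is empty", {
  strata <- tibble::tibble(
    age_band_low = c(40L, 40L, 50L),
    sex = "female",
    ethnicity = c("Unknown", "European", "European"),
    nzdep_quintile = c("1", "2", "1"),
    never = c(5L, 10L, 10L), ex = 0L, current = 0L)
  expect_message(out <- redistribute_unknowns(strata), "fallback")
  expect_equal(sum(out$never), 25L)
})

test_that("strata expansion conserves counts and draws ages in-band", {
  cfg <- world_config(n_truth = 60000)
  truth <- withr::with_seed(5, make_ground_truth(cfg))
  census <- derive_census_crosstab(truth, suppression_threshold = 1L)
  total <- sum(as.matrix(census[smoking_levels]))
  for (seed in c(1, 2)) {
    pop <- withr::with_seed(seed, expand_strata(census))
    expect_equal(nrow(pop), total)
    expect_true(all(pop$age >= 30 & pop$age < 85))
  }
  # within-band uniformity: KS test at alpha = 0.001 for large bands
  pop <- withr::with_seed(9, expand_strata(census))
  frac <- pop$age - floor(pop$age)
  year <- floor(pop$age)
  for (y in as.integer(names(which(table(year) >= 1000)))[1:5]) {
    p <- suppressWarnings(stats::ks.test(frac[year == y], "punif")$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("deterministic expansion reproduces the cross-tab cell-for-cell", {
  cfg <- world_config(n_truth = 20000)
  truth <- withr::with_seed(7, make_ground_truth(cfg))
  census <- derive_census_crosstab(truth, suppression_threshold = 1L)
  pop <- withr::with_seed(11, expand_strata(census, "deterministic"))
  got <- derive_census_crosstab(
    dplyr::mutate(pop, sbp = 120, tc_hdl = 4, fam_hx = FALSE,
                  diabetes = FALSE, prior_cvd = FALSE,
                  ll_med = FALSE, bpl_med = FALSE),
    suppression_threshold = 1L)
  key <- function(x) do.call(paste, x[c("age_band_low", "sex", "ethnicity",
                                        "nzdep_quintile")])
  got <- got[match(key(census), key(got)), ]
  expect_equal(as.matrix(got[smoking_levels]),
               as.matrix(census[smoking_levels]))
})

test_that("expansion is byte-for-byte deterministic given the seed", {
  census <- derive_census_crosstab(
    withr::with_seed(2, make_ground_truth(world_config(n_truth = 5000))),
    suppression_threshold = 1L)
  a <- withr::with_seed(123, expand_strata(census))
  b <- withr::with_seed(123, expand_strata(census))
  expect_identical(a, b)
  c <- withr::with_seed(124, expand_strata(census))
  expect_false(identical(a$age, c$age))
})

test_that("expansion rejects unresolved or unknown inputs", {
  expect_error(expand_strata(tiny_census()), "suppressed|Unknown")
  strata <- tiny_census()[2, ]
  strata$never <- -1L
  expect_error(expand_strata(strata), "negative")
})
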