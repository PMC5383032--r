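test_that("CPT rows are observed relative frequencies and sum to one", {
  records <- tibble::tibble(
    age_band = "30-44", sex = "female", ethnicity = "Maori",
    disease_state = c(rep("diabetes_only", 3), rep("neither", 6), "cvd_only",
                      rep("both", 0)))
  expect_error(estimate_cpt(records, c("age_band", "sex"), "disease_state"),
               "absent")
  records$disease_state[1] <- "both"  # make all four categories present
  cpt <- estimate_cpt(records, c("age_band", "sex"), "disease_state",
                      min_cell = 1L)
  expect_s3_class(cpt, "cvdsynth_cpt")
  expect_equal(cpt$p_diabetes_only, 0.2)
  expect_equal(cpt$p_neither, 0.6)
  probs <- as.matrix(cpt[paste0("p_", disease_levels)])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-12)
  expect_error(estimate_cpt(records[0, ], "age_band", "disease_state"),
               "no records")
})

test_that("sparse strata pool to the parent distribution", {
  withr::with_seed(4, {
    records <- tibble::tibble(
      age_band = rep(c("30-44", "45-54"), c(100, 5)),
      sex = "male",
      smoking = c(sample(smoking_levels, 100, TRUE, prob = c(.5, .3, .2)),
                  c("never", "never", "ex", "current", "never")))
  })
  cpt <- estimate_cpt(records, c("sex", "age_band"), "smoking",
                      min_cell = 20L)
  sparse <- cpt[cpt$age_band == "45-54", ]
  expect_equal(sparse$pooling_level, 1L)
  # brute-force oracle: pooled frequencies over ALL records (the parent
  # stratum after dropping age_band)
  expect_equal(sparse$p_never, mean(records$smoking == "never"))
  expect_equal(sparse$p_current, mean(records$smoking == "current"))
  expect_equal(cpt$pooling_level[cpt$age_band == "30-44"], 0L)
})

test_that("unseen conditioning combinations resolve via pooled levels", {
  records <- tibble::tibble(
    age_band = rep(age_band_levels, each = 40), sex = "male",
    smoking = rep(rep(smoking_levels, c(20, 12, 8)), 5))
  cpt <- estimate_cpt(records, c("age_band", "sex"), "smoking")
  pop <- make_pop(50)
  pop$sex <- "female"  # not in the records: must pool up to age_band-only
  withr::with_seed(1, expect_silent(s <- assign_categorical(pop, cpt)))
  expect_true(all(s %in% smoking_levels))
  # a manual CPT without pooled levels errors on unseen combinations
  bare <- new_cpt(tibble::tibble(age_band = "30-44", p_never = 1, p_ex = 0,
                                 p_current = 0),
                  "age_band", "smoking", smoking_levels)
  old <- make_pop(30)
  old$age <- 80.5
  expect_error(assign_smoking(old, bare), "unresolvable")
})

test_that("Monte Carlo assignment matches row probabilities", {
  n <- 50000L
  pop <- tibble::tibble(
    person_id = sprintf("p%06d", 1:n), age = 35, sex = "female",
    ethnicity = "European", nzdep_quintile = "1", smoking = "never",
    diabetes = FALSE, prior_cvd = FALSE, ll_med = FALSE, bpl_med = FALSE,
    sbp = NA_real_, tc_hdl = NA_real_, fam_hx = NA)
  probs <- c(neither = 0.55, diabetes_only = 0.25, cvd_only = 0.15,
             both = 0.05)
  cpt <- new_cpt(tibble::tibble(age_band = "30-44", p_neither = probs[1],
                                p_diabetes_only = probs[2],
                                p_cvd_only = probs[3], p_both = probs[4]),
                 "age_band", "disease_state", disease_levels)
  out <- withr::with_seed(8, assign_disease_state(pop, cpt))
  state <- encode_disease_state(out$diabetes, out$prior_cvd)
  counts <- table(factor(state, disease_levels))
  # chi-square goodness of fit against the multinomial expected counts
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
  # every category within 4 binomial standard errors
  for (k in disease_levels) {
    se <- sqrt(probs[[k]] * (1 - probs[[k]]) / n)
    expect_lt(abs(mean(state == k) - probs[[k]]), 4 * se)
  }
})

test_that("degenerate and zero-probability categories behave exactly", {
  pop <- make_pop(200)
  cpt1 <- new_cpt(tibble::tibble(sex = sex_levels, p_never = 0, p_ex = 1,
                                 p_current = 0),
                  "sex", "smoking", smoking_levels)
  out <- withr::with_seed(2, assign_smoking(pop, cpt1))
  expect_true(all(out$smoking == "ex"))

  cpt2 <- new_cpt(tibble::tibble(sex = sex_levels, p_neither = 0.5,
                                 p_diabetes_only = 0.3, p_cvd_only = 0.2,
                                 p_both = 0),
                  "sex", "disease_state", disease_levels)
  out2 <- withr::with_seed(2, assign_disease_state(pop, cpt2))
  expect_false(any(out2$diabetes & out2$prior_cvd))
})

test_that("joint decoding always reconstructs the sampled category", {
  pop <- make_pop(2000, seed = 6)
  cpt <- disease_cpt_from_margins()
  out <- withr::with_seed(3, assign_disease_state(pop, cpt))
  state <- encode_disease_state(out$diabetes, out$prior_cvd)
  redec <- decode_disease_state(state)
  expect_identical(redec$diabetes, out$diabetes)
  expect_identical(redec$prior_cvd, out$prior_cvd)
  med <- withr::with_seed(4, assign_medication_state(out,
                                                     medication_cpt_from_margins()))
  mstate <- encode_medication_state(med$ll_med, med$bpl_med)
  expect_identical(decode_medication_state(mstate)$ll_med, med$ll_med)
})

test_that("medication assignment enforces stage ordering and CVD conditioning", {
  pop <- make_pop(4000, seed = 10)
  admin <- make_admin(20000, seed = 12)
  admin$medication_state <- encode_medication_state(admin$ll_med,
                                                    admin$bpl_med)
  cpt <- estimate_cpt(admin, c("age_band", "prior_cvd"), "medication_state",
                      min_cell = 20L)
  bare <- pop
  bare$prior_cvd <- NA
  expect_error(assign_medication_state(bare, cpt), "disease state")
  out <- withr::with_seed(5, assign_medication_state(pop, cpt))
  # CVD-positive persons are treated more often, as in the estimation source
  src <- tapply(admin$bpl_med, admin$prior_cvd, mean)
  got <- tapply(out$bpl_med, out$prior_cvd, mean)
  expect_gt(src[["TRUE"]], src[["FALSE"]])
  expect_gt(got[["TRUE"]], got[["FALSE"]])
})

test_that("estimated joint disease CPT preserves the embedded association", {
  admin <- make_admin(60000, seed = 21)
  admin$disease_state <- encode_disease_state(admin$diabetes, admin$prior_cvd)
  cpt <- estimate_cpt(admin, c("age_band", "sex", "ethnicity"),
                      "disease_state")
  pop <- make_pop(60000, seed = 22)
  out <- withr::with_seed(23, assign_disease_state(pop, cpt))
  # 2x2 cross-product oracle on the source records vs the generated persons
  or_of <- function(d) {
    t <- table(d$diabetes, d$prior_cvd)
    (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  }
  lo <- log(or_of(admin)); lg <- log(or_of(out))
  expect_lt(abs(lg - lo), 0.35)
  expect_gt(lg, 0)  # positive association survives the pipeline
})
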