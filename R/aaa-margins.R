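# Canonical category vocabulary and the packaged reference marginal
# distributions of the 2013 New Zealand usually-resident population aged
# 30-84, by five age bands. These marginals are the default parameters of
# the ground-truth world generator (see world_config()).

#' Canonical ethnicity categories in prioritisation order
#'
#' Ethnicity is collapsed to a single category by a fixed priority order
#' (first match wins): Maori, Pacific, Indian, Chinese, OtherAsian, Other,
#' European. "Unknown" is accepted on input but must be redistributed before
#' a population is expanded.
#'
#' @format Character vector of length 7 (highest priority first).
#' @export
eth_levels <- c("Maori", "Pacific", "Indian", "Chinese",
                "OtherAsian", "Other", "European")

#' Canonical smoking categories
#'
#' Never / ex / current smoker, in the fixed order used for inverse-CDF
#' sampling (coded 0, 1, 2 in integer form).
#'
#' @format Character vector of length 3.
#' @export
smoking_levels <- c("never", "ex", "current")

#' Joint disease-state categories
#' @format Character vector of length 4.
#' @export
disease_levels <- c("neither", "diabetes_only", "cvd_only", "both")

#' Joint medication-state categories
#' @format Character vector of length 4.
#' @export
medication_levels <- c("neither", "ll_only", "bpl_only", "both")

#' Sex categories
#' @format Character vector of length 2.
#' @export
sex_levels <- c("female", "male")

#' Age-band boundaries used for conditional probability tables
#'
#' Closed-open bands: 30-44, 45-54, 55-64, 65-74, 75-84 (top band ends at 85).
#'
#' @format Numeric vector of break points.
#' @export
age_band_breaks <- c(30, 45, 55, 65, 75, 85)

#' Age-band labels
#' @format Character vector of length 5.
#' @export
age_band_levels <- c("30-44", "45-54", "55-64", "65-74", "75-84")

#' Column order of a serialised population file
#' @format Character vector of column names.
#' @export
person_columns <- c("person_id", "age", "sex", "ethnicity", "nzdep_quintile",
                    "smoking", "diabetes", "prior_cvd", "ll_med", "bpl_med",
                    "sbp", "tc_hdl", "fam_hx")

#' Reference marginal distributions, NZ adults 30-84, 2013
#'
#' Published age-band marginal summaries of the 2013 New Zealand
#' usually-resident adult population (ages 30-84): band sizes, percent male,
#' ethnicity and deprivation-quintile composition, smoking, diabetes,
#' prior-CVD, lipid-lowering (LL) and blood-pressure-lowering (BPL)
#' medication prevalences, systolic blood pressure (SBP) and total:HDL
#' cholesterol ratio means/SDs, and family history of premature CVD. These
#' values seed the defaults of [world_config()] so that parameter-recovery
#' experiments target realistic national conditions.
#'
#' Percentages are on the 0-100 scale; SBP in mmHg; TC:HDL dimensionless.
#' `or_prior_cvd` holds age- and sex-adjusted prior-CVD odds ratios for
#' ethnic groups versus the rest of the population.
#'
#' @format A list with one element per quantity; matrix elements have one
#'   column per age band (`30-44` ... `75-84`).
#' @export
nz_margins_2013 <- local({
  bands <- c("30-44", "45-54", "55-64", "65-74", "75-84")
  bm <- function(x, nm) matrix(x, nrow = length(nm), byrow = TRUE,
                               dimnames = list(nm, bands))
  list(
    bands = bands,
    n_band = stats::setNames(
      c(828518L, 600532L, 491463L, 344559L, 186206L), bands),
    total = 2451278L,
    pct_male = stats::setNames(c(47.3, 48.0, 48.7, 48.4, 45.3), bands),
    pct_ethnicity = bm(c(13.9, 12.0,  9.5,  6.8,  4.5,
                          6.1,  4.8,  3.6,  2.7,  1.9,
                          5.0,  3.1,  2.4,  1.6,  0.9,
                          4.6,  3.6,  3.6,  2.6,  2.2,
                          4.9,  3.5,  2.0,  0.8,  0.4,
                          1.6,  0.8,  0.5,  0.2,  0.1,
                         63.9, 72.3, 78.5, 85.2, 90.0), eth_levels),
    pct_nzdep = bm(c(20.9, 25.1, 24.5, 22.5, 19.2,
                     21.2, 22.0, 21.9, 21.6, 20.5,
                     20.7, 19.6, 19.9, 20.4, 20.9,
                     19.5, 17.4, 18.1, 19.3, 22.2,
                     17.6, 15.9, 15.7, 16.2, 17.2), as.character(1:5)),
    pct_smoking = bm(c(58.9, 57.0, 56.0, 55.0, 58.5,
                       22.3, 25.3, 30.1, 35.1, 35.0,
                       18.9, 17.7, 13.8,  9.9,  6.6), smoking_levels),
    pct_diabetes = stats::setNames(c(4.1, 8.2, 13.8, 19.4, 22.6), bands),
    pct_prior_cvd = stats::setNames(c(0.6, 2.5, 6.1, 12.6, 22.4), bands),
    pct_ll = stats::setNames(c(1.6, 8.2, 20.5, 34.8, 41.3), bands),
    pct_bpl = stats::setNames(c(3.1, 12.7, 28.5, 47.4, 60.6), bands),
    sbp_mean = stats::setNames(c(122.7, 127.9, 132.5, 136.9, 140.4), bands),
    sbp_sd = stats::setNames(c(17.3, 17.2, 17.3, 17.4, 17.5), bands),
    tc_hdl_mean = stats::setNames(c(4.0, 4.2, 4.1, 4.0, 3.8), bands),
    tc_hdl_sd = stats::setNames(c(1.4, 1.2, 1.2, 1.1, 1.1), bands),
    pct_fam_hx = stats::setNames(c(16.5, 13.5, 12.1, 10.6, 8.5), bands),
    or_prior_cvd = c(Maori = 1.58, Pacific = 1.85, Asian = 0.43)
  )
})

#' Assign an age-band label to continuous ages
#'
#' @param age Numeric vector of ages in years (must lie in [30, 85)).
#' @param breaks Band break points (closed-open bands).
#' @param labels Band labels, one fewer than breaks.
#' @return Character vector of band labels.
#' @export
age_band <- function(age, breaks = age_band_breaks,
                     labels = age_band_levels) {
  stopifnot(length(labels) == length(breaks) - 1L)
  if (any(age < breaks[1] | age >= breaks[length(breaks)], na.rm = TRUE)) {
    stop("ages outside [", breaks[1], ", ", breaks[length(breaks)], ")")
  }
  labels[findInterval(age, breaks)]
}
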