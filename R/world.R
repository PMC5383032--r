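# Ground-truth world generator: a configurable "true" population from
# which every pipeline input (census cross-tab with suppression, linked
# administrative records, biased donor cohort with digit preference,
# reference surveys) is derived. Because the truth is known, end-to-end
# runs become parameter-recovery experiments.

#' Configure a ground-truth world
#'
#' Defaults are the packaged national reference marginals
#' ([nz_margins_2013]): age-band weights, percent male, ethnicity and
#' deprivation composition, smoking, diabetes, prior-CVD, medication
#' prevalences, SBP and TC:HDL means/SDs and family-history prevalence per
#' band, plus the ethnicity prior-CVD odds ratios. Joint structure not
#' identified by marginal tables is set by association parameters:
#' `or_diabetes_cvd` (diabetes x prior-CVD odds ratio), `or_ll_bpl`
#' (lipid- x blood-pressure-lowering), and `or_cvd_ll` / `or_cvd_bpl`
#' (odds multipliers for treatment given prior CVD). Baseline logits are
#' solved so the configured band marginals still hold exactly in
#' expectation after the offsets are mixed in.
#'
#' @param n_truth Number of true individuals (default 200000).
#' @param margins Reference marginal list (shape of [nz_margins_2013]).
#' @param or_diabetes_cvd,or_ll_bpl,or_cvd_ll,or_cvd_bpl Association
#'   odds ratios (defaults 3, 4, 6, 6).
#' @param cvd_eth_logor Named log-odds offsets on prior CVD by ethnicity
#'   (default: the reference adjusted odds ratios — Maori ln(1.58),
#'   Pacific ln(1.85), Chinese/OtherAsian ln(0.43); others 0).
#' @param sbp_sex_gap Male-minus-female SBP gap in mmHg (default 0: the
#'   marginal tables carry no sex split).
#' @param bias_age Cohort sampling weight per age band (older bands
#'   up-weighted by default).
#' @param bias_diabetes,bias_eth Cohort weight multipliers for diabetes
#'   and for Maori/Pacific/Indian ethnicity.
#' @param p_round Probability a cohort SBP reading is rounded to the
#'   nearest 10 mmHg (digit preference; default 0.3).
#' @param survey_n Reference-survey sample size (default 5000).
#' @param seed Master seed.
#' @return A `world_config` list.
#' @export
world_config <- function(n_truth = 200000L, margins = nz_margins_2013,
                         or_diabetes_cvd = 3, or_ll_bpl = 4,
                         or_cvd_ll = 6, or_cvd_bpl = 6,
                         cvd_eth_logor = NULL, sbp_sex_gap = 0,
                         bias_age = c(0.4, 0.8, 1.2, 1.6, 2.0),
                         bias_diabetes = 2, bias_eth = 1.5,
                         p_round = 0.3, survey_n = 5000L, seed = 1L) {
  stopifnot(n_truth >= 1L, p_round >= 0, p_round <= 1)
  if (is.null(cvd_eth_logor)) {
    cvd_eth_logor <- stats::setNames(rep(0, length(eth_levels)), eth_levels)
    cvd_eth_logor["Maori"] <- log(margins$or_prior_cvd[["Maori"]])
    cvd_eth_logor["Pacific"] <- log(margins$or_prior_cvd[["Pacific"]])
    cvd_eth_logor[c("Chinese", "OtherAsian")] <-
      log(margins$or_prior_cvd[["Asian"]])
  } else {
    full <- stats::setNames(rep(0, length(eth_levels)), eth_levels)
    full[names(cvd_eth_logor)] <- cvd_eth_logor
    cvd_eth_logor <- full
  }
  norm <- function(m) sweep(m, 2L, colSums(m), "/")
  cfg <- list(
    n_truth = as.integer(n_truth),
    bands = margins$bands,
    p_band = margins$n_band / sum(margins$n_band),
    p_male = margins$pct_male / 100,
    p_eth = norm(margins$pct_ethnicity),
    p_dep = norm(margins$pct_nzdep),
    p_smoking = norm(margins$pct_smoking),
    p_diabetes = margins$pct_diabetes / 100,
    p_cvd = margins$pct_prior_cvd / 100,
    p_ll = margins$pct_ll / 100,
    p_bpl = margins$pct_bpl / 100,
    sbp_mean = margins$sbp_mean, sbp_sd = margins$sbp_sd,
    tc_hdl_mean = margins$tc_hdl_mean, tc_hdl_sd = margins$tc_hdl_sd,
    p_fam_hx = margins$pct_fam_hx / 100,
    or_diabetes_cvd = or_diabetes_cvd, or_ll_bpl = or_ll_bpl,
    or_cvd_ll = or_cvd_ll, or_cvd_bpl = or_cvd_bpl,
    cvd_eth_logor = cvd_eth_logor, sbp_sex_gap = sbp_sex_gap,
    bias_age = stats::setNames(bias_age, margins$bands),
    bias_diabetes = bias_diabetes, bias_eth = bias_eth,
    p_round = p_round, survey_n = as.integer(survey_n),
    seed = as.integer(seed)
  )
  for (p in cfg[c("p_band", "p_male", "p_diabetes", "p_cvd", "p_ll",
                  "p_bpl", "p_fam_hx")]) {
    stopifnot(all(p >= 0 & p <= 1))
  }
  stopifnot(all(cfg$sbp_sd > 0), all(cfg$tc_hdl_sd > 0))
  structure(cfg, class = "world_config")
}

# Baseline logit b such that sum_i mix_i * plogis(b + offset_i) == target.
solve_base_logit <- function(target, offsets, mix) {
  stats::uniroot(function(b) sum(mix * stats::plogis(b + offsets)) - target,
                 c(-25, 25), tol = 1e-12)$root
}

# Inverse-CDF draw of category indices from a row-wise probability matrix.
sample_rows <- function(probs) {
  cum <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
  u <- stats::runif(nrow(probs))
  1L + rowSums(u >= cum[, -ncol(cum), drop = FALSE])
}

#' Draw a fully observed ground-truth population
#'
#' Samples `cfg$n_truth` individuals exactly from the configured
#' conditional distributions: demographics per band, smoking per band,
#' the joint diabetes/prior-CVD state (band- and ethnicity-conditional
#' prior-CVD logit offsets, band marginals preserved), the joint
#' medication state (conditional on prior CVD, band marginals preserved),
#' truncated-normal SBP and TC:HDL per band (truncation at 70-250 mmHg
#' and 1.5-12 respectively), and family history per band.
#'
#' @param cfg A [world_config()].
#' @param n Override for the number of individuals.
#' @return A fully observed population tibble (the "truth").
#' @export
make_ground_truth <- function(cfg, n = cfg$n_truth) {
  stopifnot(inherits(cfg, "world_config"))
  bands <- cfg$bands
  nb <- length(bands)
  band_idx <- sample.int(nb, n, replace = TRUE, prob = cfg$p_band)
  lo <- age_band_breaks[band_idx]
  hi <- age_band_breaks[band_idx + 1L]
  age <- lo + stats::runif(n) * (hi - lo)
  sex <- ifelse(stats::runif(n) < cfg$p_male[band_idx], "male", "female")
  eth_idx <- sample_rows(t(cfg$p_eth)[band_idx, , drop = FALSE])
  ethnicity <- eth_levels[eth_idx]
  dep <- as.character(sample_rows(t(cfg$p_dep)[band_idx, , drop = FALSE]))
  smoking <- smoking_levels[sample_rows(t(cfg$p_smoking)[band_idx, , drop = FALSE])]

  # joint disease state: ethnicity offsets on the prior-CVD logit, baseline
  # solved per band so the band marginal matches the configured value
  base_cvd <- vapply(seq_len(nb), function(b) {
    solve_base_logit(cfg$p_cvd[b], cfg$cvd_eth_logor, cfg$p_eth[, b])
  }, numeric(1L))
  p_cvd_i <- stats::plogis(base_cvd[band_idx] + cfg$cvd_eth_logor[ethnicity])
  p_diab_i <- cfg$p_diabetes[band_idx]
  disease_probs <- joint_from_margins(p_diab_i, p_cvd_i, cfg$or_diabetes_cvd)
  if (is.null(dim(disease_probs))) disease_probs <- rbind(disease_probs)
  # columns of joint_from_margins: p00, p10 (diab only), p01 (cvd only), p11
  disease <- disease_levels[sample_rows(disease_probs)]
  dec <- decode_disease_state(disease)

  # joint medication state conditional on prior CVD; band marginals solved
  p_ll_i <- p_bpl_i <- numeric(n)
  for (b in seq_len(nb)) {
    in_b <- band_idx == b
    pc <- cfg$p_cvd[b]
    base_ll <- solve_base_logit(cfg$p_ll[b], c(0, log(cfg$or_cvd_ll)),
                                c(1 - pc, pc))
    base_bpl <- solve_base_logit(cfg$p_bpl[b], c(0, log(cfg$or_cvd_bpl)),
                                 c(1 - pc, pc))
    p_ll_i[in_b] <- stats::plogis(base_ll +
      log(cfg$or_cvd_ll) * dec$prior_cvd[in_b])
    p_bpl_i[in_b] <- stats::plogis(base_bpl +
      log(cfg$or_cvd_bpl) * dec$prior_cvd[in_b])
  }
  med_probs <- joint_from_margins(p_ll_i, p_bpl_i, cfg$or_ll_bpl)
  if (is.null(dim(med_probs))) med_probs <- rbind(med_probs)
  meds <- medication_levels[sample_rows(med_probs)]
  dm <- decode_medication_state(meds)

  sex_shift <- ifelse(sex == "male", cfg$sbp_sex_gap / 2, -cfg$sbp_sex_gap / 2)
  tibble::tibble(
    person_id = sprintf("t%08d", seq_len(n)),
    age = age, sex = sex, ethnicity = ethnicity, nzdep_quintile = dep,
    smoking = smoking, diabetes = dec$diabetes, prior_cvd = dec$prior_cvd,
    ll_med = dm$ll_med, bpl_med = dm$bpl_med,
    sbp = rnorm_trunc(n, cfg$sbp_mean[band_idx] + sex_shift,
                      cfg$sbp_sd[band_idx], 70, 250),
    tc_hdl = rnorm_trunc(n, cfg$tc_hdl_mean[band_idx],
                         cfg$tc_hdl_sd[band_idx], 1.5, 12),
    fam_hx = stats::runif(n) < cfg$p_fam_hx[band_idx]
  )
}

#' Derive a suppressed census cross-tabulation from the truth
#'
#' Exact cross-tab of the truth by single-year age band, sex, ethnicity
#' and deprivation quintile with per-smoking-category counts; cells with
#' counts between 1 and `suppression_threshold - 1` are replaced by the
#' suppression marker (`NA`).
#'
#' @param truth Ground-truth population.
#' @param suppression_threshold Counts below this are suppressed
#'   (default 6, i.e. 1-5 suppressed, 0 kept).
#' @return Census cross-tab tibble.
#' @export
derive_census_crosstab <- function(truth, suppression_threshold = 6L) {
  tab <- truth |>
    dplyr::mutate(age_band_low = as.integer(floor(.data$age))) |>
    dplyr::count(.data$age_band_low, .data$sex, .data$ethnicity,
                 .data$nzdep_quintile, .data$smoking) |>
    tidyr::pivot_wider(names_from = "smoking", values_from = "n",
                       values_fill = 0L)
  for (cat in setdiff(smoking_levels, names(tab))) tab[[cat]] <- 0L
  tab <- tab[c("age_band_low", "sex", "ethnicity", "nzdep_quintile",
               smoking_levels)]
  for (cat in smoking_levels) {
    supp <- tab[[cat]] > 0L & tab[[cat]] < suppression_threshold
    tab[[cat]][supp] <- NA_integer_
  }
  dplyr::arrange(tab, .data$age_band_low, .data$sex, .data$ethnicity,
                 .data$nzdep_quintile)
}

#' Derive linked administrative records from the truth
#'
#' The national registries are population-wide, so the derived admin
#' extract is simply the truth's identifier, demographics and
#' disease/medication flags.
#'
#' @param truth Ground-truth population.
#' @return Tibble of admin records.
#' @export
derive_admin_records <- function(truth) {
  truth[c("person_id", "age", "sex", "ethnicity",
          "diabetes", "prior_cvd", "ll_med", "bpl_med")]
}

#' Derive a risk-biased donor cohort with digit preference
#'
#' Samples cohort members without replacement with weights multiplied by
#' the configured factors for older age bands, diabetes, and Maori /
#' Pacific / Indian ethnicity (emulating a primary-care risk-assessment
#' cohort enriched for higher-risk groups). With probability `p_round`
#' each SBP reading is rounded to the nearest 10 mmHg (observer digit
#' preference). All records are complete cases.
#'
#' @param truth Ground-truth population.
#' @param cfg A [world_config()].
#' @param n_cohort Cohort size (must not exceed `nrow(truth)`).
#' @return Tibble of cohort records.
#' @export
derive_biased_cohort <- function(truth, cfg, n_cohort) {
  stopifnot(n_cohort <= nrow(truth))
  band <- age_band(truth$age)
  w <- cfg$bias_age[band] *
    ifelse(truth$diabetes, cfg$bias_diabetes, 1) *
    ifelse(truth$ethnicity %in% c("Maori", "Pacific", "Indian"),
           cfg$bias_eth, 1)
  idx <- sample.int(nrow(truth), n_cohort, replace = FALSE, prob = w)
  cohort <- truth[idx, ]
  round_it <- stats::runif(n_cohort) < cfg$p_round
  cohort$sbp[round_it] <- pmax(round(cohort$sbp[round_it] / 10) * 10, 70)
  cohort$person_id <- sprintf("c%08d", seq_len(n_cohort))
  cohort
}

#' Derive stratum reference estimates from a simple random survey
#'
#' Draws a simple random sample of the truth and summarises `variable`
#' per age-range stratum (optionally split by sex): proportions get
#' Wilson 95% intervals, means get t-based intervals. Strata absent from
#' the sample are omitted with a warning.
#'
#' @param truth Ground-truth population.
#' @param n_sample Survey size (`n_sample == nrow(truth)` is the census
#'   case).
#' @param variable Column to estimate.
#' @param bands Data frame with `age_low`, `age_high` (closed-open);
#'   defaults to the standard five bands.
#' @param by_sex Split strata by sex (default FALSE).
#' @param level Optional category level (proportion of that level).
#' @return Reference-estimate tibble ([read_reference_table()] schema).
#' @export
derive_reference_survey <- function(truth, n_sample, variable,
                                    bands = NULL, by_sex = FALSE,
                                    level = NULL) {
  stopifnot(n_sample >= 1L, n_sample <= nrow(truth))
  if (is.null(bands)) {
    bands <- data.frame(age_low = age_band_breaks[-length(age_band_breaks)],
                        age_high = age_band_breaks[-1L])
  }
  smp <- truth[sample.int(nrow(truth), n_sample, replace = FALSE), ]
  sexes <- if (by_sex) sex_levels else "all"
  rows <- list()
  for (i in seq_len(nrow(bands))) {
    for (s in sexes) {
      inside <- smp$age >= bands$age_low[i] & smp$age < bands$age_high[i]
      if (s != "all") inside <- inside & smp$sex == s
      n_str <- sum(inside)
      if (n_str == 0L) {
        warning("stratum [", bands$age_low[i], ",", bands$age_high[i],
                ") ", s, " absent from sample; omitted", call. = FALSE)
        next
      }
      val <- smp[[variable]][inside]
      if (!is.null(level)) val <- val == level
      if (is.logical(val)) {
        est <- mean(val)
        ci <- wilson_ci(sum(val), n_str)
      } else {
        est <- mean(val)
        half <- stats::qt(0.975, max(n_str - 1L, 1L)) *
          stats::sd(val) / sqrt(n_str)
        if (!is.finite(half)) half <- 0
        ci <- c(low = est - half, high = est + half)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = variable, age_low = bands$age_low[i],
        age_high = bands$age_high[i], sex = s, ethnicity = "all",
        estimate = est, ci_low = ci[["low"]], ci_high = ci[["high"]],
        n = n_str)
    }
  }
  validate_reference_table(dplyr::bind_rows(rows))
}

#' Build exact reference targets from marginal tables
#'
#' Convenience constructor of a reference-estimate table whose per-band
#' targets are taken directly from a marginal summary (default the
#' packaged national marginals), for use as post-hoc adjustment targets.
#'
#' @param variable `"sbp"` or `"tc_hdl"`.
#' @param margins Marginal list (shape of [nz_margins_2013]).
#' @return Reference-estimate tibble with degenerate (point) intervals.
#' @export
make_reference_targets <- function(variable = c("sbp", "tc_hdl"),
                                   margins = nz_margins_2013) {
  variable <- match.arg(variable)
  est <- if (variable == "sbp") margins$sbp_mean else margins$tc_hdl_mean
  tibble::tibble(
    variable = variable,
    age_low = age_band_breaks[-length(age_band_breaks)],
    age_high = age_band_breaks[-1L],
    sex = "all", ethnicity = "all",
    estimate = unname(est), ci_low = unname(est), ci_high = unname(est),
    n = NA_integer_)
}

#' Parameterise CPTs directly from marginal tables
#'
#' Builds age-band-conditional CPTs whose row probabilities come straight
#' from a marginal summary (default the packaged national marginals):
#' the three-category smoking CPT, the joint disease-state CPT (diabetes
#' and prior-CVD band marginals combined through an association odds
#' ratio), and the joint medication-state CPT (LL and BPL band marginals,
#' likewise). These support parameter-recovery runs in which assignment
#' must reproduce printed marginal prevalences.
#'
#' @param margins Marginal list (shape of [nz_margins_2013]).
#' @param or Association odds ratio for the joint constructions.
#' @return A `cvdsynth_cpt` conditioned on `age_band`.
#' @export
smoking_cpt_from_margins <- function(margins = nz_margins_2013) {
  p <- sweep(margins$pct_smoking, 2L, colSums(margins$pct_smoking), "/")
  tab <- tibble::tibble(age_band = margins$bands,
                        p_never = p["never", ], p_ex = p["ex", ],
                        p_current = p["current", ])
  new_cpt(tab, "age_band", "smoking", smoking_levels)
}

#' @rdname smoking_cpt_from_margins
#' @export
disease_cpt_from_margins <- function(margins = nz_margins_2013, or = 3) {
  joint <- joint_from_margins(margins$pct_diabetes / 100,
                              margins$pct_prior_cvd / 100, or)
  tab <- tibble::tibble(age_band = margins$bands,
                        p_neither = joint[, "p00"],
                        p_diabetes_only = joint[, "p10"],
                        p_cvd_only = joint[, "p01"],
                        p_both = joint[, "p11"])
  new_cpt(tab, "age_band", "disease_state", disease_levels)
}

#' @rdname smoking_cpt_from_margins
#' @export
medication_cpt_from_margins <- function(margins = nz_margins_2013, or = 4) {
  joint <- joint_from_margins(margins$pct_ll / 100, margins$pct_bpl / 100, or)
  tab <- tibble::tibble(age_band = margins$bands,
                        p_neither = joint[, "p00"],
                        p_ll_only = joint[, "p10"],
                        p_bpl_only = joint[, "p01"],
                        p_both = joint[, "p11"])
  new_cpt(tab, "age_band", "medication_state", medication_levels)
}
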