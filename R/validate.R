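# Validation: internal comparisons against the generating sources (exact
# for deterministic stages, bounded by Monte Carlo error for stochastic
# ones), external comparisons against independent reference estimates with
# 95% CIs, adjusted odds ratios by logistic regression, and
# replicate-population variability.

# Per-stratum value of `variable` in pop: proportion for logical columns
# (or of `level` for categorical ones), mean for numeric.
stratum_values <- function(pop, variable, strata_vars, level = NULL) {
  val <- pop[[variable]]
  if (!is.null(level)) val <- pop[[variable]] == level
  pop$.val <- val
  pop |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_vars))) |>
    dplyr::summarise(synthetic_value = mean(.data$.val), n = dplyr::n(),
                     .groups = "drop")
}

#' Internal validation against a generating-source summary
#'
#' Compares per-stratum synthetic values (proportions for binary or
#' categorical variables, means for continuous ones) with the equivalent
#' summary of the source dataset the stage was generated from. For
#' deterministically generated variables the absolute difference must be
#' exactly zero; for Monte Carlo variables the standardized difference
#' (absolute difference over the binomial or normal standard error at the
#' synthetic stratum size) is flagged against a 4-standard-error pass
#' criterion. Strata present in the source but empty in the population are
#' reported with `n = 0`, not dropped.
#'
#' @param pop Population tibble.
#' @param source_summary Tibble with the stratum columns and a
#'   `reference_value` column (plus optional `reference_sd` for continuous
#'   variables).
#' @param variable Column of `pop` to compare.
#' @param strata_vars Stratum columns (present in both inputs; `age_band`
#'   is derived from `age` when needed).
#' @param level Optional category for categorical variables (compares the
#'   proportion in that category).
#' @return Comparison tibble with `synthetic_value`, `reference_value`,
#'   `abs_diff`, `std_diff`, `pass`.
#' @export
internal_compare <- function(pop, source_summary, variable, strata_vars,
                             level = NULL) {
  if ("age_band" %in% strata_vars && !"age_band" %in% names(pop)) {
    pop$age_band <- age_band(pop$age)
  }
  missing_cols <- setdiff(strata_vars, names(source_summary))
  if (length(missing_cols)) {
    stop("source summary lacks stratum column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  syn <- stratum_values(pop, variable, strata_vars, level)
  out <- dplyr::full_join(syn, source_summary,
                          by = strata_vars)
  if (anyNA(out$reference_value)) {
    stop("stratum mismatch: population strata without a source summary row")
  }
  out$n[is.na(out$n)] <- 0L
  is_prop <- !"reference_sd" %in% names(out)
  se <- if (is_prop) {
    sqrt(pmax(out$reference_value * (1 - out$reference_value), 1e-12) /
           pmax(out$n, 1L))
  } else {
    out$reference_sd / sqrt(pmax(out$n, 1L))
  }
  out$abs_diff <- abs(out$synthetic_value - out$reference_value)
  out$std_diff <- out$abs_diff / se
  out$pass <- !is.na(out$std_diff) & out$std_diff <= 4
  out
}

# Map reference strata (age range x sex x ethnicity, with "all" margins and
# the Asian aggregation) onto persons; returns a logical membership matrix
# handled row by row.
reference_members <- function(pop, ref_row,
                              agg_map = list(Asian = c("Chinese", "OtherAsian"))) {
  inside <- pop$age >= ref_row$age_low & pop$age < ref_row$age_high
  if (ref_row$sex != "all") inside <- inside & pop$sex == ref_row$sex
  if (ref_row$ethnicity != "all") {
    eths <- agg_map[[ref_row$ethnicity]] %||% ref_row$ethnicity
    bad <- setdiff(eths, eth_levels)
    if (length(bad)) stop("unmappable reference stratum ethnicity: ",
                          ref_row$ethnicity)
    inside <- inside & pop$ethnicity %in% eths
  }
  inside
}

#' External validation against independent reference estimates
#'
#' Computes the synthetic value of `variable` within each reference
#' stratum (re-aggregating ages and ethnic groups as the reference
#' requires, e.g. merging Chinese and OtherAsian into "Asian") and flags
#' whether it falls within the reference 95% confidence interval.
#'
#' @param pop Population tibble.
#' @param reference Reference-estimate tibble ([read_reference_table()]
#'   schema) filtered to one variable, or carrying a `variable` column.
#' @param variable Column of `pop` to compare.
#' @param level Optional category level (proportion comparison).
#' @param agg_map Named list mapping reference ethnicity labels to sets of
#'   canonical categories.
#' @return Comparison tibble with `within_ci`; the counts of strata inside
#'   and outside their intervals are attached as attribute `"summary"`.
#' @export
external_compare <- function(pop, reference, variable, level = NULL,
                             agg_map = list(Asian = c("Chinese", "OtherAsian"))) {
  if ("variable" %in% names(reference)) {
    reference <- reference[reference$variable == variable, ]
  }
  if (nrow(reference) == 0L) stop("no reference rows for ", variable)
  val <- if (is.null(level)) pop[[variable]] else pop[[variable]] == level
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    inside <- reference_members(pop, r, agg_map)
    syn <- if (any(inside)) mean(val[inside]) else NA_real_
    tibble::tibble(
      age_low = r$age_low, age_high = r$age_high, sex = r$sex,
      ethnicity = r$ethnicity, n = sum(inside), synthetic_value = syn,
      reference_value = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high,
      within_ci = !is.na(syn) & syn >= r$ci_low & syn <= r$ci_high,
      abs_diff = abs(syn - r$estimate),
      std_diff = abs(syn - r$estimate) /
        pmax((r$ci_high - r$ci_low) / (2 * stats::qnorm(0.975)), 1e-12))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, summary = c(within = sum(out$within_ci),
                             outside = sum(!out$within_ci)))
}

#' Age- and sex-adjusted odds ratio by logistic regression
#'
#' Fits `outcome ~ exposure + adjusters` with a binomial GLM and returns
#' the exponentiated exposure coefficient with a Wald 95% confidence
#' interval. With no adjusters this reduces (exactly) to the 2x2
#' cross-product ratio. On complete separation the fit falls back to a
#' ridge-penalised estimate, flagged in the result.
#'
#' @param pop Population tibble.
#' @param outcome Name of a logical column (e.g. `"prior_cvd"`).
#' @param exposure Name of a logical column (e.g. a binary ethnicity
#'   indicator created by the caller).
#' @param adjusters Character vector of adjustment covariates (default
#'   `c("age", "sex")`); `NULL` for the unadjusted 2x2 case.
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se`,
#'   `penalized`.
#' @export
adjusted_odds_ratio <- function(pop, outcome, exposure,
                                adjusters = c("age", "sex")) {
  stopifnot(is.logical(pop[[outcome]]), is.logical(pop[[exposure]]))
  df <- data.frame(y = pop[[outcome]], x = as.numeric(pop[[exposure]]))
  for (a in adjusters) {
    df[[a]] <- if (is.character(pop[[a]])) factor(pop[[a]]) else pop[[a]]
  }
  form <- stats::as.formula(paste("y ~ x",
    if (length(adjusters)) paste("+", paste(adjusters, collapse = " + "))
    else ""))
  fit <- suppressWarnings(stats::glm(form, data = df, family = stats::binomial()))
  penalized <- FALSE
  if (!fit$converged || abs(stats::coef(fit)[["x"]]) > 15) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("separation detected and glmnet unavailable for penalised fit")
    }
    message("separation in odds-ratio fit; using penalised estimate")
    x_mat <- stats::model.matrix(form, df)[, -1L, drop = FALSE]
    pen <- glmnet::glmnet(x_mat, df$y, family = "binomial",
                          alpha = 0, lambda = 1e-3)
    log_or <- as.numeric(pen$beta["x", ])
    return(list(or = exp(log_or), ci_low = NA_real_, ci_high = NA_real_,
                log_or = log_or, se = NA_real_, penalized = TRUE))
  }
  log_or <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  list(or = exp(log_or),
       ci_low = exp(log_or - stats::qnorm(0.975) * se),
       ci_high = exp(log_or + stats::qnorm(0.975) * se),
       log_or = log_or, se = se, penalized = penalized)
}

#' Replicate-population variability of stratum summaries
#'
#' Summarises a set of replicate populations (built from distinct seeds)
#' by the across-replicate mean and standard deviation (denominator n-1)
#' of a per-stratum summary, quantifying the Monte Carlo uncertainty of
#' the population development. Larger strata are expected to show smaller
#' relative variability.
#'
#' @param replicates List (length >= 2) of population tibbles.
#' @param variable Column to summarise.
#' @param strata_vars Stratum columns (default `"age_band"`).
#' @param level Optional category level (proportion summaries).
#' @return Tibble with per-stratum `mean`, `sd`, `rel_sd` (sd/mean) and
#'   the mean stratum size `n_mean`.
#' @export
replicate_variability <- function(replicates, variable,
                                  strata_vars = "age_band", level = NULL) {
  stopifnot(is.list(replicates), length(replicates) >= 2L)
  per_rep <- lapply(seq_along(replicates), function(r) {
    pop <- replicates[[r]]
    if ("age_band" %in% strata_vars && !"age_band" %in% names(pop)) {
      pop$age_band <- age_band(pop$age)
    }
    dplyr::mutate(stratum_values(pop, variable, strata_vars, level),
                  .rep = r)
  })
  dplyr::bind_rows(per_rep) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_vars))) |>
    dplyr::summarise(mean = mean(.data$synthetic_value),
                     sd = stats::sd(.data$synthetic_value),
                     n_mean = mean(.data$n), .groups = "drop") |>
    dplyr::mutate(rel_sd = .data$sd / pmax(abs(.data$mean), 1e-12))
}
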