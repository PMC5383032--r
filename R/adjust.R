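# Post-hoc adjustment: shift stratum-specific means of a continuous
# variable onto external reference targets while retaining the variability
# developed during imputation. The shift is additive per stratum (age band
# x sex), which preserves the within-stratum spread exactly; a
# physiological floor clamp prevents impossible values after large
# negative shifts.

default_floor <- c(sbp = 60, tc_hdl = 1)

#' Compute a per-stratum mean-shift adjustment
#'
#' For each age-band x sex stratum, the delta is the reference mean minus
#' the current synthetic mean. Reference rows must cover every stratum
#' present in the population; rows with `sex == "all"` apply to both sexes.
#'
#' @param pop Completed population tibble.
#' @param reference Reference-estimate tibble (see
#'   [read_reference_table()]) for the target variable, with per-band
#'   target means in `estimate`.
#' @param variable `"sbp"` or `"tc_hdl"`.
#' @param floor Lower clamp applied after shifting (default 60 mmHg for
#'   SBP, 1.0 for TC:HDL).
#' @return An `adjustment_spec` tibble (age_band, sex, target_mean,
#'   observed_mean, delta) with the variable and floor as attributes.
#' @export
compute_adjustment <- function(pop, reference, variable = c("sbp", "tc_hdl"),
                               floor = NULL) {
  variable <- match.arg(variable)
  floor <- floor %||% default_floor[[variable]]
  ref <- reference[reference$variable == variable, ]
  if (nrow(ref) == 0L) stop("no reference rows for variable ", variable)
  if (any(ref$sex == "all")) {
    ref <- dplyr::bind_rows(lapply(sex_levels, function(s) {
      r <- ref
      r$sex[r$sex == "all"] <- s
      r[r$sex == s, ]
    }))
  }
  ref$age_band <- paste0(ref$age_low, "-", ref$age_high - 1L)
  cur <- pop |>
    dplyr::mutate(age_band = age_band(.data$age)) |>
    dplyr::group_by(.data$age_band, .data$sex) |>
    dplyr::summarise(observed_mean = mean(.data[[variable]]),
                     n = dplyr::n(), .groups = "drop")
  spec <- dplyr::left_join(cur, ref[c("age_band", "sex", "estimate")],
                           by = c("age_band", "sex"))
  if (anyNA(spec$estimate)) {
    miss <- spec[is.na(spec$estimate), ]
    stop("no reference estimate for strata: ",
         paste(paste(miss$age_band, miss$sex), collapse = "; "))
  }
  spec <- dplyr::transmute(spec,
    age_band = .data$age_band, sex = .data$sex,
    target_mean = .data$estimate,
    observed_mean = .data$observed_mean,
    delta = .data$estimate - .data$observed_mean)
  if (any(!is.finite(spec$delta))) stop("non-finite adjustment delta")
  if (any(floor >= spec$target_mean)) {
    stop("floor ", floor, " is not below every target mean")
  }
  structure(spec, variable = variable, floor = floor,
            class = c("adjustment_spec", class(spec)))
}

#' Apply a mean-shift adjustment to a population
#'
#' Each person's value is incremented by their stratum's delta, then
#' clamped at the physiological floor. For strata where no clamping
#' engages, the post-shift mean equals the target and the standard
#' deviation is unchanged (an additive shift preserves spread). Clamped
#' persons are counted and reported with a message.
#'
#' @param pop Population tibble.
#' @param spec An `adjustment_spec` from [compute_adjustment()].
#' @return `pop` with the named variable shifted; all other columns
#'   untouched.
#' @export
apply_mean_shift <- function(pop, spec) {
  stopifnot(inherits(spec, "adjustment_spec"))
  variable <- attr(spec, "variable")
  floor <- attr(spec, "floor")
  key <- paste(age_band(pop$age), pop$sex)
  idx <- match(key, paste(spec$age_band, spec$sex))
  if (anyNA(idx)) {
    stop("adjustment spec lacks strata: ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  shifted <- pop[[variable]] + spec$delta[idx]
  clamped <- shifted < floor
  if (any(clamped)) {
    message(sum(clamped), " value(s) clamped at floor ", floor,
            " for ", variable)
    shifted[clamped] <- floor
  }
  pop[[variable]] <- shifted
  pop
}
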