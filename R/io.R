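# Reading and writing the pipeline's tabular artifacts: census cross-tabs
# with the small-cell suppression dialect, populations, cohorts, linked
# administrative records, conditional probability tables and reference
# estimate tables. All files are comma-delimited text with a one-line
# header; populations may additionally round-trip through a columnar
# binary format (Parquet) when the 'arrow' package is available.

census_columns <- c("age_band_low", "sex", "ethnicity", "nzdep_quintile",
                    smoking_levels)

#' Read a census cross-tabulation with suppressed small cells
#'
#' Each row is one stratum (single-year age band x sex x ethnicity x
#' deprivation quintile) with one count column per smoking category.
#' Counts below the disclosure threshold are suppressed in the source and
#' appear as a sentinel string; they are parsed to `NA_integer_` (the
#' in-memory SUPPRESSED marker), never to zero.
#'
#' @param path Path to a delimited text file with header columns
#'   `age_band_low, sex, ethnicity, nzdep_quintile, never, ex, current`.
#' @param sentinel Suppression sentinel string (default `"..C"`).
#' @param eth_aliases Optional named character vector mapping alias labels
#'   to canonical ethnicity categories.
#' @return A tibble of strata in file order; suppressed counts are `NA`.
#' @export
read_census_crosstab <- function(path, sentinel = "..C",
                                 eth_aliases = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(census_columns, names(raw))
  if (length(missing_cols)) {
    stop("census file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[census_columns]
  if (!is.null(eth_aliases)) {
    hit <- raw$ethnicity %in% names(eth_aliases)
    raw$ethnicity[hit] <- eth_aliases[raw$ethnicity[hit]]
  }
  bad_eth <- setdiff(unique(raw$ethnicity), c(eth_levels, "Unknown"))
  if (length(bad_eth)) stop("unknown ethnicity label(s): ",
                            paste(bad_eth, collapse = ", "))
  bad_sex <- setdiff(unique(raw$sex), sex_levels)
  if (length(bad_sex)) stop("unknown sex label(s): ",
                            paste(bad_sex, collapse = ", "))
  bad_dep <- setdiff(unique(raw$nzdep_quintile), c(as.character(1:5), "Unknown"))
  if (length(bad_dep)) stop("unknown deprivation label(s): ",
                            paste(bad_dep, collapse = ", "))
  out <- tibble::tibble(
    age_band_low = as.integer(raw$age_band_low),
    sex = raw$sex,
    ethnicity = raw$ethnicity,
    nzdep_quintile = raw$nzdep_quintile
  )
  if (anyNA(out$age_band_low) ||
      any(out$age_band_low < 30L | out$age_band_low > 84L)) {
    stop("age_band_low must be an integer in [30, 84]")
  }
  for (cat in smoking_levels) {
    cell <- raw[[cat]]
    supp <- cell == sentinel
    num <- suppressWarnings(as.integer(cell))
    bad <- !supp & (is.na(num) | num < 0 | cell != as.character(num))
    if (any(bad)) {
      stop("malformed count '", cell[which(bad)[1]], "' in column '", cat,
           "', row ", which(bad)[1])
    }
    num[supp] <- NA_integer_
    out[[cat]] <- num
  }
  out
}

#' Write a census cross-tabulation, restoring the suppression sentinel
#'
#' @param strata Tibble as returned by [read_census_crosstab()].
#' @inheritParams read_census_crosstab
#' @return `path`, invisibly.
#' @export
write_census_crosstab <- function(strata, path, sentinel = "..C") {
  out <- strata[census_columns]
  for (cat in smoking_levels) {
    cell <- as.character(out[[cat]])
    cell[is.na(cell)] <- sentinel
    out[[cat]] <- cell
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_person_invariants <- function(pop, require_complete = TRUE) {
  stopifnot(is.data.frame(pop))
  missing_cols <- setdiff(person_columns, names(pop))
  if (length(missing_cols)) {
    stop("population lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  offender <- function(bad, what) {
    if (any(bad)) {
      stop("invalid ", what, " for person_id ",
           pop$person_id[which(bad)[1]])
    }
  }
  offender(is.na(pop$age) | pop$age < 30 | pop$age >= 85, "age")
  offender(!pop$sex %in% sex_levels, "sex")
  offender(!pop$ethnicity %in% eth_levels, "ethnicity")
  offender(!pop$nzdep_quintile %in% as.character(1:5), "nzdep_quintile")
  offender(!pop$smoking %in% smoking_levels, "smoking")
  for (v in c("diabetes", "prior_cvd", "ll_med", "bpl_med")) {
    offender(!is.logical(pop[[v]]) | is.na(pop[[v]]), v)
  }
  if (require_complete) {
    offender(!is.finite(pop$sbp) | pop$sbp <= 0, "sbp")
    offender(!is.finite(pop$tc_hdl) | pop$tc_hdl <= 0, "tc_hdl")
    offender(!is.logical(pop$fam_hx) | is.na(pop$fam_hx), "fam_hx")
  }
  invisible(pop)
}

#' Write a synthetic population
#'
#' Refuses to write a population violating the person invariants (age in
#' [30, 85), canonical categories, finite positive SBP and TC:HDL, boolean
#' flags), naming the first offending `person_id`. Column order is fixed so
#' files are byte-stable across runs.
#'
#' @param pop Population tibble (one row per person).
#' @param path Output path; `.parquet` suffix (with `format = "parquet"`)
#'   selects the columnar binary format via the arrow package.
#' @param format `"csv"` (default) or `"parquet"`.
#' @param complete If `FALSE`, allow missing sbp/tc_hdl/fam_hx (a
#'   pre-imputation population).
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, format = c("csv", "parquet"),
                             complete = TRUE) {
  format <- match.arg(format)
  check_person_invariants(pop, require_complete = complete)
  out <- pop[person_columns]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for parquet output")
    }
    arrow::write_parquet(out, path)
  }
  invisible(path)
}

#' Read a synthetic population
#'
#' @inheritParams write_population
#' @return Population tibble with canonical column order and types.
#' @export
read_population <- function(path, format = c("csv", "parquet"),
                            complete = TRUE) {
  format <- match.arg(format)
  if (format == "csv") {
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = c(person_id = "character",
                                          nzdep_quintile = "character"))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for parquet input")
    }
    raw <- as.data.frame(arrow::read_parquet(path))
  }
  pop <- tibble::as_tibble(raw[person_columns])
  for (v in c("diabetes", "prior_cvd", "ll_med", "bpl_med", "fam_hx")) {
    pop[[v]] <- as.logical(pop[[v]])
  }
  pop$nzdep_quintile <- as.character(pop$nzdep_quintile)
  check_person_invariants(pop, require_complete = complete)
  pop
}

#' Read a donor-cohort file
#'
#' Cohort records are complete cases: the same fields as a population, all
#' observed (including sbp, tc_hdl and fam_hx).
#'
#' @param path Delimited text file with the population schema.
#' @return Tibble of cohort records.
#' @export
read_cohort <- function(path) read_population(path, complete = TRUE)

#' Read linked administrative records
#'
#' Individual-level records carrying demographics plus disease and
#' medication flags, used to estimate conditional probability tables.
#'
#' @param path Delimited text file with header `person_id, age, sex,
#'   ethnicity, diabetes, prior_cvd, ll_med, bpl_med`.
#' @return Tibble of records.
#' @export
read_admin_records <- function(path) {
  cols <- c("person_id", "age", "sex", "ethnicity",
            "diabetes", "prior_cvd", "ll_med", "bpl_med")
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(person_id = "character"))
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("admin file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(raw[cols])
  for (v in c("diabetes", "prior_cvd", "ll_med", "bpl_med")) {
    out[[v]] <- as.logical(out[[v]])
  }
  stopifnot(all(out$sex %in% sex_levels),
            all(out$ethnicity %in% eth_levels))
  out
}

#' Read a table of external reference estimates
#'
#' Reference estimates are stratum-level point estimates with 95%
#' confidence intervals from sources independent of the generating data
#' (surveys, laboratory databases). Strata are age ranges (closed-open
#' `[age_low, age_high)`), optionally split by sex and/or ethnicity
#' (`"all"` marks a margin over that variable).
#'
#' @param path Delimited text file with header `variable, age_low,
#'   age_high, sex, ethnicity, estimate, ci_low, ci_high` and optionally `n`.
#' @return Tibble of reference estimates; errors if any interval fails
#'   `ci_low <= estimate <= ci_high`.
#' @export
read_reference_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("variable", "age_low", "age_high", "sex", "ethnicity",
            "estimate", "ci_low", "ci_high")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("reference file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"n" %in% names(raw)) raw$n <- NA_integer_
  out <- tibble::as_tibble(raw[c(need, "n")])
  validate_reference_table(out)
}

validate_reference_table <- function(ref) {
  bad <- ref$ci_low > ref$estimate | ref$estimate > ref$ci_high
  if (any(bad)) {
    stop("reference interval does not bracket its estimate in row(s) ",
         paste(which(bad), collapse = ", "))
  }
  stopifnot(all(ref$sex %in% c(sex_levels, "all")),
            all(ref$ethnicity %in% c(eth_levels, "Asian", "all")))
  ref
}

#' Serialise / read a conditional probability table
#'
#' One row per conditioning combination; one probability column per outcome
#' category (prefixed `p_`), plus the supporting record count `n` and the
#' `pooling_level` (how many trailing conditioning variables were dropped
#' to estimate the row).
#'
#' @param cpt A `cvdsynth_cpt` object.
#' @param path File path.
#' @return `write_cpt()`: `path` invisibly; `read_cpt()`: a `cvdsynth_cpt`.
#' @export
write_cpt <- function(cpt, path) {
  stopifnot(inherits(cpt, "cvdsynth_cpt"))
  header <- sprintf("# outcome=%s conditioning=%s categories=%s",
                    attr(cpt, "outcome_var"),
                    paste(attr(cpt, "conditioning_vars"), collapse = ","),
                    paste(attr(cpt, "outcome_categories"), collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(cpt), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cpt
#' @export
read_cpt <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
    regexec("outcome=(\\S+) conditioning=(\\S+) categories=(\\S+)", header))[[1]]
  if (length(meta) != 4L) stop("malformed CPT header line")
  tab <- tibble::as_tibble(utils::read.csv(path, skip = 1L,
                                           check.names = FALSE))
  conditioning <- strsplit(meta[3], ",")[[1]]
  for (v in intersect(conditioning, c("nzdep_quintile", "prior_cvd", "diabetes"))) {
    if (v %in% c("prior_cvd", "diabetes")) tab[[v]] <- as.logical(tab[[v]])
    else tab[[v]] <- as.character(tab[[v]])
  }
  new_cpt(tab, conditioning_vars = conditioning, outcome_var = meta[2],
          outcome_categories = strsplit(meta[4], ",")[[1]])
}
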