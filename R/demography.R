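# Demographic framework: resolve suppressed census cells and unknown
# categories, then expand strata into individual synthetic persons whose
# demographic margins match the census cross-tab exactly.

#' Collapse multiple reported ethnicities to a single prioritised category
#'
#' Ethnic prioritisation uses the fixed national order (Maori, Pacific,
#' Indian, Chinese, OtherAsian, Other, European): a person reporting several
#' ethnicities is assigned the highest-priority one.
#'
#' @param reported Non-empty character vector (a set) of reported
#'   ethnicities, a subset of [eth_levels].
#' @return The single highest-priority category.
#' @export
prioritize_ethnicity <- function(reported) {
  if (length(reported) == 0L) stop("empty ethnicity set")
  bad <- setdiff(reported, eth_levels)
  if (length(bad)) stop("unknown ethnicity: ", paste(bad, collapse = ", "))
  eth_levels[min(match(reported, eth_levels))]
}

#' Resolve suppressed cross-tab cells
#'
#' Census disclosure control suppresses counts of 1-5, so a suppressed cell
#' is known to lie in that range. Two resolution strategies:
#' `"uniform_1_5"` draws each suppressed cell independently and uniformly
#' from {1,...,5}; `"total_constrained"` additionally conditions on a known
#' row total, drawing uniformly from the feasible fill combinations whose
#' sum matches the total.
#'
#' @param strata Census cross-tab tibble (suppressed cells are `NA`).
#' @param strategy Resolution strategy.
#' @param row_totals Optional integer vector (length `nrow(strata)`) of
#'   known stratum totals; `NA` where unknown. Required cells for
#'   `"total_constrained"` rows.
#' @return The cross-tab with every suppressed cell replaced by an integer
#'   in [1, 5]. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
resolve_suppressed_cells <- function(strata,
                                     strategy = c("uniform_1_5",
                                                  "total_constrained"),
                                     row_totals = NULL) {
  strategy <- match.arg(strategy)
  counts <- as.matrix(strata[smoking_levels])
  supp <- is.na(counts)
  if (!any(supp)) return(strata)
  if (strategy == "uniform_1_5") {
    counts[supp] <- sample(1:5, sum(supp), replace = TRUE)
  } else {
    stopifnot(!is.null(row_totals), length(row_totals) == nrow(strata))
    for (i in which(rowSums(supp) > 0)) {
      s <- sum(supp[i, ])
      if (is.na(row_totals[i])) {
        counts[i, supp[i, ]] <- sample(1:5, s, replace = TRUE)
        next
      }
      need <- row_totals[i] - sum(counts[i, ], na.rm = TRUE)
      if (need < s || need > 5L * s) {
        stop("infeasible total ", row_totals[i], " for row ", i,
             ": ", s, " suppressed cell(s) must sum to ", need)
      }
      fills <- as.matrix(expand.grid(rep(list(1:5), s)))
      fills <- fills[rowSums(fills) == need, , drop = FALSE]
      counts[i, supp[i, ]] <- fills[sample.int(nrow(fills), 1L), ]
    }
  }
  strata[smoking_levels] <- counts
  strata
}

# Reallocate `amount` across target rows proportional to their current
# counts in column `col`, by largest remainder. Returns updated counts.
reallocate <- function(counts, targets, amount, fallbacks) {
  for (idx in c(list(targets), fallbacks)) {
    if (length(idx) && sum(counts[idx]) > 0) {
      counts[idx] <- counts[idx] + largest_remainder(amount, counts[idx])
      return(list(counts = counts, fallback = !identical(idx, targets)))
    }
  }
  stop("no rows with positive known counts to receive unknowns")
}

#' Redistribute Unknown ethnicity and deprivation counts
#'
#' Strata labelled `Unknown` in ethnicity or deprivation are removed and
#' their counts reallocated to the known-category strata within the same
#' age-band x sex margin (matching deprivation, respectively ethnicity,
#' where possible), proportionally to known counts with largest-remainder
#' rounding so the grand total is conserved exactly. Margins whose known
#' counts are all zero fall back to the age-band x sex margin and then to
#' the overall known distribution, with a message.
#'
#' @param strata Resolved cross-tab tibble (no suppressed cells).
#' @return Cross-tab without Unknown rows; per-smoking-column and grand
#'   totals unchanged.
#' @export
redistribute_unknowns <- function(strata) {
  stopifnot(!anyNA(strata[smoking_levels]))
  for (var in c("ethnicity", "nzdep_quintile")) {
    unk <- strata[[var]] == "Unknown"
    if (!any(unk)) next
    other <- if (var == "ethnicity") "nzdep_quintile" else "ethnicity"
    known <- !unk & strata[[other]] != "Unknown"
    for (i in which(unk)) {
      for (cat in smoking_levels) {
        amount <- strata[[cat]][i]
        if (amount == 0L) next
        in_margin <- known &
          strata$age_band_low == strata$age_band_low[i] &
          strata$sex == strata$sex[i]
        targets <- which(in_margin & strata[[other]] == strata[[other]][i])
        res <- reallocate(strata[[cat]], targets,
                          amount, list(which(in_margin), which(known)))
        if (res$fallback) {
          message("unknown ", var, " redistributed via fallback margin for ",
                  "age ", strata$age_band_low[i], " ", strata$sex[i])
        }
        strata[[cat]] <- res$counts
      }
    }
    strata <- strata[!unk, ]
  }
  strata
}

#' Expand census strata into synthetic persons
#'
#' Walks the resolved cross-tab row by row and emits one person per counted
#' individual. Age is drawn uniformly on the one-year band `[Y, Y+1)`; sex,
#' ethnicity and deprivation are applied deterministically from the
#' stratum. Smoking is assigned either deterministically from the count
#' column the person came from (`"deterministic"`), or by Monte Carlo
#' redraw from the stratum's smoking proportions (`"monte_carlo"`, the
#' default): a per-person uniform draw against the stratum's cumulative
#' smoking distribution, reflecting the greater self-report uncertainty and
#' temporal variability of smoking status relative to the other census
#' variables.
#'
#' @param strata Resolved cross-tab (no suppressed cells, no Unknowns).
#' @param smoking_mode `"monte_carlo"` or `"deterministic"`.
#' @return Population tibble (pre-imputation: sbp, tc_hdl, fam_hx are `NA`)
#'   with exactly `sum(counts)` rows.
#' @export
expand_strata <- function(strata,
                          smoking_mode = c("monte_carlo", "deterministic")) {
  smoking_mode <- match.arg(smoking_mode)
  counts <- as.matrix(strata[smoking_levels])
  if (anyNA(counts)) stop("unresolved suppressed cells")
  if (any(counts < 0)) stop("negative count")
  if (any(strata$ethnicity == "Unknown" | strata$nzdep_quintile == "Unknown")) {
    stop("Unknown categories must be redistributed before expansion")
  }
  row_n <- rowSums(counts)
  total <- sum(row_n)
  stratum <- rep(seq_len(nrow(strata)), times = row_n)
  # smoking by count column, in canonical order within each stratum
  smoking <- rep(rep(smoking_levels, nrow(strata)), times = as.vector(t(counts)))
  if (smoking_mode == "monte_carlo") {
    probs <- counts / pmax(row_n, 1L)
    cum1 <- probs[stratum, 1L]
    cum2 <- cum1 + probs[stratum, 2L]
    u <- stats::runif(total)
    smoking <- smoking_levels[1L + (u >= cum1) + (u >= cum2)]
  }
  tibble::tibble(
    person_id = sprintf("p%08d", seq_len(total)),
    age = strata$age_band_low[stratum] + stats::runif(total),
    sex = strata$sex[stratum],
    ethnicity = strata$ethnicity[stratum],
    nzdep_quintile = as.character(strata$nzdep_quintile[stratum]),
    smoking = smoking,
    diabetes = NA, prior_cvd = NA, ll_med = NA, bpl_med = NA,
    sbp = NA_real_, tc_hdl = NA_real_, fam_hx = NA
  )
}
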