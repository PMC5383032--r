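# Conditional probability tables (CPTs): estimation from individual-level
# records with recursive pooling of sparse strata, and Monte Carlo
# assignment of categorical risk factors to persons by inverse-CDF
# sampling.

cpt_key <- function(df, vars) {
  if (length(vars) == 0L) return(rep("", nrow(df)))
  do.call(paste, c(lapply(df[vars], as.character), sep = "\r"))
}

#' Construct a conditional probability table
#'
#' A CPT maps each combination of conditioning-variable values to a
#' probability distribution over the outcome's categories. Probability
#' columns are named `p_<category>`; `n` records the supporting record
#' count and `pooling_level` how many trailing conditioning variables were
#' dropped to estimate the row (0 = fully stratified).
#'
#' @param tab Data frame with the conditioning columns and one `p_` column
#'   per outcome category.
#' @param conditioning_vars Ordered character vector of conditioning
#'   variable names (pooling drops from the end).
#' @param outcome_var Name of the outcome variable.
#' @param outcome_categories Ordered category labels (fixed order is the
#'   sampling order).
#' @param pooled_levels Optional list of coarser tables used to resolve
#'   combinations unseen at full stratification.
#' @return A `cvdsynth_cpt` tibble.
#' @export
new_cpt <- function(tab, conditioning_vars, outcome_var, outcome_categories,
                    pooled_levels = NULL) {
  tab <- tibble::as_tibble(tab)
  pcols <- paste0("p_", outcome_categories)
  for (pc in intersect(pcols, names(tab))) tab[[pc]] <- unname(tab[[pc]])
  missing_cols <- setdiff(c(conditioning_vars, pcols), names(tab))
  if (length(missing_cols)) {
    stop("CPT lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  probs <- as.matrix(tab[pcols])
  if (any(probs < 0)) stop("negative probability in CPT")
  bad <- abs(rowSums(probs) - 1) > 1e-12
  if (any(bad)) {
    stop("CPT row(s) do not sum to 1: ", paste(which(bad), collapse = ", "))
  }
  if (!"n" %in% names(tab)) tab$n <- NA_integer_
  if (!"pooling_level" %in% names(tab)) tab$pooling_level <- 0L
  structure(tab,
            conditioning_vars = conditioning_vars,
            outcome_var = outcome_var,
            outcome_categories = outcome_categories,
            pooled_levels = pooled_levels,
            class = c("cvdsynth_cpt", class(tab)))
}

freq_table <- function(records, vars, outcome_var, categories) {
  key <- cpt_key(records, vars)
  counts <- table(factor(key, levels = unique(key)),
                  factor(records[[outcome_var]], levels = categories))
  counts <- unclass(counts)
  first <- !duplicated(key)
  out <- tibble::as_tibble(records[first, vars, drop = FALSE])
  out <- out[match(rownames(counts), key[first]), , drop = FALSE]
  n <- rowSums(counts)
  probs <- counts / n
  colnames(probs) <- paste0("p_", categories)
  dplyr::bind_cols(out, tibble::as_tibble(probs),
                   tibble::tibble(n = as.integer(n)))
}

#' Estimate a CPT from individual-level records
#'
#' Row probabilities are observed relative frequencies of the outcome
#' within each conditioning stratum. Strata supported by fewer than
#' `min_cell` records are re-estimated after dropping the last conditioning
#' variable, recursively, and the number of dropped variables is recorded
#' in `pooling_level`. Coarser tables for every pooling level are retained
#' so that conditioning combinations absent from the records can still be
#' resolved at assignment time.
#'
#' @param records Tibble of individual records containing the conditioning
#'   variables and the outcome. If `"age_band"` is a conditioning variable
#'   and absent from `records`, it is derived from `age` via [age_band()].
#' @param conditioning_vars Ordered conditioning variable names.
#' @param outcome_var Outcome variable name (categorical).
#' @param outcome_categories Category labels; defaults to the canonical
#'   list for known outcomes, otherwise the observed values. Every category
#'   must occur at least once in the records.
#' @param min_cell Minimum records per stratum before pooling (default 20).
#' @return A `cvdsynth_cpt`.
#' @export
estimate_cpt <- function(records, conditioning_vars, outcome_var,
                         outcome_categories = NULL, min_cell = 20L) {
  if (nrow(records) == 0L) stop("no records to estimate from")
  if ("age_band" %in% conditioning_vars && !"age_band" %in% names(records)) {
    records$age_band <- age_band(records$age)
  }
  if (is.null(outcome_categories)) {
    outcome_categories <- switch(outcome_var,
      smoking = smoking_levels,
      disease_state = disease_levels,
      medication_state = medication_levels,
      sort(unique(as.character(records[[outcome_var]]))))
  }
  seen <- unique(as.character(records[[outcome_var]]))
  absent <- setdiff(outcome_categories, seen)
  if (length(absent)) {
    stop("outcome categor(ies) absent from all records: ",
         paste(absent, collapse = ", "))
  }
  unseen <- setdiff(seen, outcome_categories)
  if (length(unseen)) {
    stop("records contain unlisted outcome categor(ies): ",
         paste(unseen, collapse = ", "))
  }
  k <- length(conditioning_vars)
  levels_list <- lapply(0:k, function(drop) {
    freq_table(records, conditioning_vars[seq_len(k - drop)],
               outcome_var, outcome_categories)
  })
  names(levels_list) <- as.character(0:k)
  tab <- levels_list[[1L]]
  tab$pooling_level <- 0L
  pcols <- paste0("p_", outcome_categories)
  for (drop in seq_len(k)) {
    sparse <- tab$n < min_cell
    if (!any(sparse)) break
    parent <- levels_list[[drop + 1L]]
    pv <- conditioning_vars[seq_len(k - drop)]
    idx <- match(cpt_key(tab[sparse, , drop = FALSE], pv),
                 cpt_key(parent, pv))
    grow <- parent$n[idx] >= min_cell | drop == k
    rows <- which(sparse)[grow]
    tab[rows, pcols] <- parent[idx[grow], pcols]
    tab$n[rows] <- parent$n[idx[grow]]
    tab$pooling_level[rows] <- drop
  }
  new_cpt(tab, conditioning_vars, outcome_var, outcome_categories,
          pooled_levels = levels_list[-1L])
}

# Resolve the probability matrix for each person; cascades through pooled
# levels for combinations unseen at full stratification.
resolve_rows <- function(pop, cpt) {
  vars <- attr(cpt, "conditioning_vars")
  pcols <- paste0("p_", attr(cpt, "outcome_categories"))
  if ("age_band" %in% vars && !"age_band" %in% names(pop)) {
    pop$age_band <- age_band(pop$age)
  }
  for (v in vars) {
    if (!v %in% names(pop)) stop("population lacks conditioning variable ", v)
    if (anyNA(pop[[v]])) stop("conditioning variable ", v, " has missing values",
                              " (stage ordering violated?)")
  }
  probs <- matrix(NA_real_, nrow(pop), length(pcols))
  idx <- match(cpt_key(pop, vars), cpt_key(cpt, vars))
  hit <- !is.na(idx)
  probs[hit, ] <- as.matrix(cpt[idx[hit], pcols])
  pooled <- attr(cpt, "pooled_levels")
  k <- length(vars)
  for (drop in seq_len(k)) {
    todo <- which(is.na(probs[, 1L]))
    if (!length(todo)) break
    if (is.null(pooled) || length(pooled) < drop) break
    parent <- pooled[[drop]]
    pv <- vars[seq_len(k - drop)]
    idx <- match(cpt_key(pop[todo, , drop = FALSE], pv), cpt_key(parent, pv))
    hit <- !is.na(idx)
    probs[todo[hit], ] <- as.matrix(parent[idx[hit], pcols])
  }
  miss <- which(is.na(probs[, 1L]))
  if (length(miss)) {
    combo <- paste(unlist(pop[miss[1L], vars]), collapse = "/")
    stop("unresolvable conditioning combination: ", combo)
  }
  probs
}

#' Assign a categorical outcome to persons by Monte Carlo sampling
#'
#' Each person's conditioning combination is looked up in the CPT (falling
#' back through pooled levels where needed) and one outcome category is
#' drawn by inverse-CDF sampling of a single uniform draw against the
#' cumulative probabilities in canonical category order.
#'
#' @param pop Population tibble.
#' @param cpt A `cvdsynth_cpt`.
#' @return Character vector of sampled categories (one per person).
#' @export
assign_categorical <- function(pop, cpt) {
  probs <- resolve_rows(pop, cpt)
  cum <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
  u <- stats::runif(nrow(pop))
  cat_idx <- rowSums(u >= cbind(0, cum[, -ncol(cum), drop = FALSE]))
  attr(cpt, "outcome_categories")[cat_idx]
}

#' Assign smoking status from a smoking CPT
#'
#' Specialisation of [assign_categorical()] for the three smoking
#' categories (never/ex/current), conditional on age band, sex, ethnicity
#' and deprivation (or whatever the CPT conditions on).
#'
#' @inheritParams assign_categorical
#' @return `pop` with `smoking` replaced by sampled categories.
#' @export
assign_smoking <- function(pop, cpt) {
  stopifnot(identical(attr(cpt, "outcome_categories"), smoking_levels))
  pop$smoking <- assign_categorical(pop, cpt)
  pop
}

#' Assign the joint diabetes / prior-CVD state
#'
#' Diabetes and prior CVD are strongly associated, so they are sampled
#' jointly from a four-category CPT (neither / diabetes only / CVD only /
#' both) and then decoded into the two boolean fields — never
#' independently.
#'
#' @inheritParams assign_categorical
#' @return `pop` with `diabetes` and `prior_cvd` set.
#' @export
assign_disease_state <- function(pop, cpt) {
  stopifnot(identical(attr(cpt, "outcome_categories"), disease_levels))
  state <- assign_categorical(pop, cpt)
  dec <- decode_disease_state(state)
  pop$diabetes <- dec$diabetes
  pop$prior_cvd <- dec$prior_cvd
  pop
}

#' Assign the joint medication state
#'
#' Lipid-lowering (LL) and blood-pressure-lowering (BPL) treatment are
#' sampled jointly from a four-category CPT, conditional (by default) on
#' age band, sex, ethnicity and prior CVD — so the disease state must be
#' assigned first.
#'
#' @inheritParams assign_categorical
#' @return `pop` with `ll_med` and `bpl_med` set.
#' @export
assign_medication_state <- function(pop, cpt) {
  stopifnot(identical(attr(cpt, "outcome_categories"), medication_levels))
  if ("prior_cvd" %in% attr(cpt, "conditioning_vars") &&
      anyNA(pop$prior_cvd)) {
    stop("disease state must be assigned before medication state")
  }
  state <- assign_categorical(pop, cpt)
  dec <- decode_medication_state(state)
  pop$ll_med <- dec$ll_med
  pop$bpl_med <- dec$bpl_med
  pop
}
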