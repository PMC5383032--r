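# Imputation-as-synthesis: the synthetic population is appended to the
# donor cohort with its continuous/binary biological variables treated as
# missing, and chained-equations imputation fills them. Continuous targets
# (SBP, TC:HDL) use predictive mean matching (PMM) with Bayesian parameter
# draws, so every imputed value is an observed donor value; the binary
# target (family history of premature CVD) uses logistic draws. Models are
# fit on the (fully observed) cohort rows only, so sharding the synthetic
# rows is exact, not an approximation.

imputation_targets <- c("sbp", "tc_hdl", "fam_hx")

#' Stack a donor cohort and a synthetic population for imputation
#'
#' Returns a single table containing both real (cohort) and synthetic
#' rows. The three imputation targets (`sbp`, `tc_hdl`, `fam_hx`) are
#' cleared to missing on the synthetic rows (with a message if values were
#' present); all other fields must be observed. Categories present in the
#' population but absent from the cohort have no possible donors and are
#' reported with a warning.
#'
#' @param cohort Complete-case donor records (population schema).
#' @param pop Synthetic population (pre-imputation).
#' @return Stacked tibble with a `source` column (`"cohort"`/`"synthetic"`).
#' @export
stack_for_imputation <- function(cohort, pop) {
  check_person_invariants(cohort, require_complete = TRUE)
  check_person_invariants(pop, require_complete = FALSE)
  for (v in c("sex", "ethnicity", "nzdep_quintile", "smoking")) {
    orphan <- setdiff(unique(pop[[v]]), unique(cohort[[v]]))
    if (length(orphan)) {
      warning("no cohort donors for ", v, " level(s): ",
              paste(orphan, collapse = ", "), " (",
              sum(pop[[v]] %in% orphan), " persons)", call. = FALSE)
    }
  }
  carried <- !is.na(pop$sbp) | !is.na(pop$tc_hdl) | !is.na(pop$fam_hx)
  if (any(carried)) {
    message(sum(carried), " synthetic row(s) carried target values; ",
            "cleared to missing for imputation")
    pop$sbp <- NA_real_
  }
  pop$sbp <- NA_real_
  pop$tc_hdl <- NA_real_
  pop$fam_hx <- NA
  dplyr::bind_rows(
    dplyr::mutate(cohort[person_columns], source = "cohort"),
    dplyr::mutate(pop[person_columns], source = "synthetic")
  )
}

# Design matrix over predictor columns with canonical factor levels;
# constant columns are dropped with a message (once per call).
impute_design <- function(data, predictors, quiet = FALSE) {
  df <- data.frame(
    age = data$age,
    sex = factor(data$sex, sex_levels),
    ethnicity = factor(data$ethnicity, eth_levels),
    nzdep_quintile = factor(data$nzdep_quintile, as.character(1:5)),
    smoking = factor(data$smoking, smoking_levels),
    diabetes = as.numeric(data$diabetes),
    prior_cvd = as.numeric(data$prior_cvd),
    ll_med = as.numeric(data$ll_med),
    bpl_med = as.numeric(data$bpl_med),
    sbp = data$sbp, tc_hdl = data$tc_hdl,
    fam_hx = as.numeric(data$fam_hx)
  )[predictors]
  x <- stats::model.matrix(~ ., df)
  x
}

drop_constant <- function(x_obs, quiet = FALSE) {
  keep <- c(TRUE, apply(x_obs[, -1L, drop = FALSE], 2L,
                        function(col) stats::var(col) > 0))
  if (!all(keep) && !quiet) {
    message("dropping constant predictor column(s): ",
            paste(colnames(x_obs)[!keep], collapse = ", "))
  }
  which(keep)
}

# Sample one of the k nearest donors (by predicted mean) for each missing
# prediction. Returns indices into yhat_obs.
match_pmm <- function(yhat_obs, yhat_mis, k) {
  n_obs <- length(yhat_obs)
  n_mis <- length(yhat_mis)
  k <- min(k, n_obs)
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  w <- min(2L * k, n_obs)
  start <- pmin(pmax(findInterval(yhat_mis, ys) - k + 1L, 1L), n_obs - w + 1L)
  cand <- outer(start, 0:(w - 1L), `+`)                 # n_mis x w positions
  d <- abs(matrix(ys[cand], n_mis, w) - yhat_mis)
  nearest <- matrix(0L, n_mis, k)
  for (j in seq_len(k)) {
    m <- max.col(-d, ties.method = "first")
    nearest[, j] <- cand[cbind(seq_len(n_mis), m)]
    d[cbind(seq_len(n_mis), m)] <- Inf
  }
  pick <- sample.int(k, n_mis, replace = TRUE)
  ord[nearest[cbind(seq_len(n_mis), pick)]]
}

# Bayesian linear-model draw (normal-inverse-chi-square posterior under the
# reference prior): returns betahat, a posterior draw beta_star, and yhat_obs.
bayes_lm_draw <- function(x, y) {
  qrx <- qr(x)
  betahat <- qr.coef(qrx, y)
  betahat[is.na(betahat)] <- 0
  res <- y - qr.fitted(qrx, y)
  df <- length(y) - qrx$rank
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  r <- qr.R(qrx)[seq_len(qrx$rank), seq_len(qrx$rank), drop = FALSE]
  v <- chol2inv(r)
  piv <- qrx$pivot[seq_len(qrx$rank)]
  beta_star <- betahat
  beta_star[piv] <- beta_star[piv] +
    drop(crossprod(chol(v), stats::rnorm(qrx$rank))) * sqrt(sigma2)
  list(betahat = betahat, beta_star = beta_star)
}

# Logistic fit with posterior draw; falls back to a ridge-penalised fit on
# (quasi-)separation, flagged by a message.
bayes_logit_draw <- function(x, y) {
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15)
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    message("separation in logistic imputation step; using penalised fit")
    pen <- glmnet::glmnet(x[, -1L, drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = 1e-2)
    beta <- c(pen$a0, as.numeric(pen$beta))
    return(list(beta_star = beta))
  }
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  rank <- fit$qr$rank
  piv <- fit$qr$pivot[seq_len(rank)]
  r <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
  v <- chol2inv(r)
  beta_star <- coefs
  beta_star[piv] <- beta_star[piv] +
    drop(crossprod(chol(v), stats::rnorm(rank)))
  list(beta_star = beta_star)
}

#' Run chained-equations imputation on a stacked table
#'
#' Iterates over the targets in fixed order (`sbp`, `tc_hdl`, `fam_hx`) for
#' `n_iterations` passes. Each target is modelled on the cohort rows
#' against all shared variables plus the current values of the other two
#' targets; synthetic rows receive PMM draws (continuous) or Bayesian
#' logistic draws (binary). Cohort cells are never modified. Missing-value
#' initialisation is a random draw from the observed donor values.
#'
#' @param stacked Table from [stack_for_imputation()].
#' @param n_iterations Chained passes (default 10).
#' @param pmm_donors Number of nearest donors sampled from (default 5).
#' @param m Number of independently completed tables to return (default 1;
#'   `m > 1` returns a list).
#' @param predictors Character vector of predictor variables; default all
#'   shared variables plus the other targets.
#' @param shard_size Synthetic rows are predicted/matched in shards of at
#'   most this many rows (models are fit on the cohort only, so sharding is
#'   exact); default 100000.
#' @param seed Optional integer; if given, seeds the RNG locally.
#' @return Completed table(s) with no missing cells.
#' @export
run_chained_imputation <- function(stacked, n_iterations = 10L,
                                   pmm_donors = 5L, m = 1L,
                                   predictors = NULL,
                                   shard_size = 100000L, seed = NULL) {
  stopifnot(n_iterations >= 1L, pmm_donors >= 1L, m >= 1L)
  if (!is.null(seed)) set.seed(seed)
  base_predictors <- c("age", "sex", "ethnicity", "nzdep_quintile", "smoking",
                       "diabetes", "prior_cvd", "ll_med", "bpl_med")
  predictors <- predictors %||% c(base_predictors, imputation_targets)
  mis <- which(stacked$source == "synthetic")
  obs <- which(stacked$source == "cohort")
  bad <- vapply(imputation_targets,
                function(v) anyNA(stacked[[v]][obs]), logical(1L))
  if (any(bad)) stop("cohort rows have missing target values: ",
                     paste(imputation_targets[bad], collapse = ", "))
  if (length(mis) == 0L ||
      !anyNA(stacked[mis, imputation_targets])) {
    return(if (m > 1L) replicate(m, stacked, simplify = FALSE) else stacked)
  }
  if (length(obs) == 0L) stop("no cohort rows to impute from")

  impute_once <- function(tab) {
    for (v in imputation_targets) {
      tab[[v]][mis] <- sample(tab[[v]][obs], length(mis), replace = TRUE)
    }
    shards <- split(mis, ceiling(seq_along(mis) / shard_size))
    for (iter in seq_len(n_iterations)) {
      quiet <- iter > 1L
      for (target in imputation_targets) {
        preds <- setdiff(predictors, target)
        x_obs <- impute_design(tab[obs, ], preds)
        keep <- drop_constant(x_obs, quiet = quiet)
        x_obs <- x_obs[, keep, drop = FALSE]
        y_obs <- if (target == "fam_hx") as.numeric(tab$fam_hx[obs])
                 else tab[[target]][obs]
        if (target == "fam_hx") {
          draw <- bayes_logit_draw(x_obs, y_obs)
          for (sh in shards) {
            x_mis <- impute_design(tab[sh, ], preds)[, keep, drop = FALSE]
            p <- stats::plogis(drop(x_mis %*% draw$beta_star))
            tab$fam_hx[sh] <- stats::runif(length(sh)) < p
          }
        } else {
          draw <- bayes_lm_draw(x_obs, y_obs)
          yhat_obs <- drop(x_obs %*% draw$betahat)
          for (sh in shards) {
            x_mis <- impute_design(tab[sh, ], preds)[, keep, drop = FALSE]
            yhat_mis <- drop(x_mis %*% draw$beta_star)
            donors <- match_pmm(yhat_obs, yhat_mis, pmm_donors)
            tab[[target]][sh] <- y_obs[donors]
          }
        }
      }
    }
    tab
  }

  out <- lapply(seq_len(m), function(i) impute_once(stacked))
  if (m > 1L) out else out[[1L]]
}

#' Extract the completed synthetic persons from a stacked table
#'
#' @param stacked Fully imputed table from [run_chained_imputation()].
#' @return Population tibble of the synthetic rows only, satisfying all
#'   person invariants (errors on residual missingness).
#' @export
extract_synthetic <- function(stacked) {
  out <- stacked[stacked$source == "synthetic", person_columns]
  if (anyNA(out[imputation_targets])) {
    stop("residual missingness in imputation targets")
  }
  out$fam_hx <- as.logical(out$fam_hx)
  check_person_invariants(out, require_complete = TRUE)
  tibble::as_tibble(out)
}
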