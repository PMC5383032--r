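# Small numerical helpers shared across modules.

#' Integer allocation by largest remainder
#'
#' Splits a non-negative integer total across categories proportionally to a
#' weight vector so that the parts are integers and sum exactly to the
#' total. Fractional remainders are resolved largest-first; ties break in
#' favour of earlier positions (canonical category order).
#'
#' @param total Non-negative integer to allocate.
#' @param weights Non-negative weights (not all zero).
#' @return Integer vector of the same length as `weights` summing to `total`.
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, length(weights) >= 1L, all(weights >= 0))
  if (sum(weights) <= 0) stop("all weights are zero")
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order(): earlier index wins ties because sort is stable on -frac
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Joint 2x2 probabilities from margins and an odds ratio
#'
#' Given marginal probabilities of two binary traits and their odds ratio,
#' returns the joint cell probabilities (the Plackett construction: the
#' p11 root of the quadratic consistent with both margins and the OR).
#'
#' @param p_a,p_b Marginal probabilities.
#' @param or Odds ratio of the association (1 = independence).
#' @return Named numeric vector `p00`, `p10`, `p01`, `p11` (a then b).
#' @export
joint_from_margins <- function(p_a, p_b, or = 1) {
  stopifnot(all(p_a >= 0 & p_a <= 1), all(p_b >= 0 & p_b <= 1), or > 0)
  if (abs(or - 1) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    s <- 1 + (p_a + p_b) * (or - 1)
    p11 <- (s - sqrt(s^2 - 4 * or * (or - 1) * p_a * p_b)) / (2 * (or - 1))
  }
  p11 <- pmin(pmax(p11, pmax(0, p_a + p_b - 1)), pmin(p_a, p_b))
  out <- cbind(p00 = 1 - p_a - p_b + p11, p10 = p_a - p11,
               p01 = p_b - p11, p11 = p11)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Encode/decode the joint disease state
#'
#' The four-category joint state maps bijectively onto the
#' (diabetes, prior_cvd) boolean pair.
#'
#' @param diabetes,prior_cvd Logical vectors.
#' @return `encode_disease_state()`: character vector of categories;
#'   `decode_disease_state()`: tibble with columns `diabetes`, `prior_cvd`.
#' @export
encode_disease_state <- function(diabetes, prior_cvd) {
  ifelse(diabetes & prior_cvd, "both",
         ifelse(diabetes, "diabetes_only",
                ifelse(prior_cvd, "cvd_only", "neither")))
}

#' @rdname encode_disease_state
#' @param state Character vector of joint disease categories.
#' @export
decode_disease_state <- function(state) {
  stopifnot(all(state %in% disease_levels))
  tibble::tibble(diabetes = state %in% c("diabetes_only", "both"),
                 prior_cvd = state %in% c("cvd_only", "both"))
}

#' Encode/decode the joint medication state
#'
#' @param ll_med,bpl_med Logical vectors.
#' @return `encode_medication_state()`: character categories;
#'   `decode_medication_state()`: tibble with `ll_med`, `bpl_med`.
#' @export
encode_medication_state <- function(ll_med, bpl_med) {
  ifelse(ll_med & bpl_med, "both",
         ifelse(ll_med, "ll_only",
                ifelse(bpl_med, "bpl_only", "neither")))
}

#' @rdname encode_medication_state
#' @param state Character vector of joint medication categories.
#' @export
decode_medication_state <- function(state) {
  stopifnot(all(state %in% medication_levels))
  tibble::tibble(ll_med = state %in% c("ll_only", "both"),
                 bpl_med = state %in% c("bpl_only", "both"))
}

# Truncated-normal draw by inverse CDF (vectorised over means).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Wilson score 95% interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = centre - half, high = centre + half)
}

# Derive a reproducible child seed from a master seed (kept below 2^31).
child_seed <- function(master, index) {
  (as.integer(master) %% 1000003L) * 2011L + 7L * as.integer(index) %% 2011L +
    as.integer(index)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
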