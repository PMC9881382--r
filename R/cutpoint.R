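# Logrank numerator for a binary split: sum over event times of
# (observed - expected) deaths in the high group, hypergeometric expectation.
.logrank_numerator <- function(high, time, status) {
  et <- sort(unique(time[status == 1]))
  U <- 0
  for (t in et) {
    at_risk <- time >= t
    d <- sum(status == 1 & time == t)
    d1 <- sum(status == 1 & time == t & high)
    r <- sum(at_risk)
    r1 <- sum(at_risk & high)
    U <- U + d1 - d * r1 / r
  }
  U
}

#' Optimal survival cutpoint by the Contal-O'Quigley method
#'
#' Dichotomizes a continuous marker by the cutpoint maximizing the absolute
#' logrank statistic over candidate thresholds, with a p-value from the
#' supremum distribution of a Brownian bridge. Interval-censored
#' observations are first reduced to right-censored form: subjects with a
#' finite `R` become events at the interval midpoint (or right endpoint),
#' right-censored subjects are censored at `L`. Candidate cutpoints are the
#' unique observed marker values between the trim quantiles; the "high"
#' stratum is `covariate >= threshold`.
#'
#' @param covariate Per-subject marker values.
#' @param obs Interval observations (`sample_id`, `L`, `R`).
#' @param trim Quantile window of admissible cutpoints (default `c(0.1, 0.9)`),
#'   which protects against degenerate, near-empty strata.
#' @param event_time `"midpoint"` (default) or `"right_endpoint"` placement
#'   of events when reducing intervals to exact times.
#' @return Object of class `cutpoint_result`: `threshold`, `direction`
#'   (`"high_risk"` if the high stratum has the excess of deaths,
#'   else `"low_risk"`), `q_statistic` (standardized supremum), `p`,
#'   and the `scan` table of per-candidate logrank numerators.
#' @examples
#' d <- validation_design(n_subjects = 80, n_proteins = 1, seed = 2)
#' v <- generate_validation_cohort(d, effect_spec("P0001", log_hr = 1.2))
#' contal_oquigley_cutpoint(log2(v$matrix[, 1]), v$intervals)
#' @export
contal_oquigley_cutpoint <- function(covariate, obs, trim = c(0.1, 0.9),
                                     event_time = c("midpoint",
                                                    "right_endpoint")) {
  event_time <- match.arg(event_time)
  .check_intervals(obs)
  stopifnot(length(covariate) == nrow(obs), all(is.finite(covariate)))
  if (length(unique(covariate)) < 2)
    stop("covariate is constant; no cutpoint exists")

  ev <- is.finite(obs$R)
  time <- ifelse(ev,
                 if (event_time == "midpoint") (obs$L + obs$R) / 2 else obs$R,
                 obs$L)
  status <- as.integer(ev)
  if (sum(status) < 1) stop("no events after right-censored conversion")

  qs <- quantile(covariate, trim, names = FALSE)
  cand <- sort(unique(covariate))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  # a threshold must split the sample: drop candidates with an empty stratum
  cand <- cand[vapply(cand, function(c) {
    h <- covariate >= c
    any(h) && any(!h)
  }, logical(1))]
  if (!length(cand)) stop("no admissible candidate cutpoint after trimming")

  U <- vapply(cand, function(c)
    .logrank_numerator(covariate >= c, time, status), numeric(1))
  best <- which.max(abs(U))

  D <- sum(status)
  if (D < 2) stop("need at least 2 events for the supremum distribution")
  a <- 1 - cumsum(1 / (D - seq_len(D) + 1))
  s2 <- sum(a^2) / (D - 1)
  q <- max(abs(U)) / (sqrt(s2) * sqrt(D - 1))
  k <- seq_len(1000)
  p <- 2 * sum((-1)^(k + 1) * exp(-2 * k^2 * q^2))
  p <- min(max(p, .Machine$double.eps), 1)

  structure(list(threshold = cand[best],
                 direction = if (U[best] > 0) "high_risk" else "low_risk",
                 q_statistic = q, p = p,
                 scan = data.frame(cutpoint = cand, numerator = U)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Contal-O'Quigley cutpoint: %.4g (%s), q = %.3f, p = %.3g\n",
              x$threshold, x$direction, x$q_statistic, x$p))
  invisible(x)
}
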