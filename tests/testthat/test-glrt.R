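test_that("identical groups give a null statistic and p of 1", {
  half <- toy_intervals()
  obs <- rbind(half, transform(half, sample_id = paste0(sample_id, "b")))
  res <- generalized_logrank(obs, group = rep(c(0, 1), each = 8))
  expect_equal(res$score, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
})

test_that("small samples are enumerated exactly", {
  obs <- toy_intervals()
  g <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- generalized_logrank(obs, g)
  expect_equal(res$method, "exact")
  expect_equal(res$n_permutations_used, choose(8, 4))

  # independent enumeration from the pooled NPMLE scores
  fit <- turnbull_npmle(obs)
  SL <- sscprog:::.turnbull_surv_at(fit, obs$L)
  SR <- sscprog:::.turnbull_surv_at(fit, obs$R)
  slogs <- function(s) ifelse(s <= 0, 0, s * log(s))
  xi <- (slogs(SL) - slogs(SR)) / (SL - SR)
  combos <- combn(8, 4)
  stats <- apply(combos, 2, function(ix) sum(xi[ix]) - 4 * mean(xi))
  obs_stat <- sum(xi[g == 1]) - 4 * mean(xi)
  expect_equal(res$score, obs_stat, tolerance = 1e-9)
  expect_equal(res$p, mean(abs(stats) >= abs(obs_stat) - 1e-12),
               tolerance = 1e-12)
})

test_that("the test reduces to the classical logrank on right-censored data", {
  skip_if_not_installed("survival")
  set.seed(15)
  n <- 60
  g <- rep(c(0, 1), each = n / 2)
  t_ev <- rexp(n, 0.25 * exp(0.35 * g))
  cens <- t_ev > 4
  eps <- 1e-9
  obs <- data.frame(sample_id = paste0("s", 1:n),
                    L = ifelse(cens, 4, pmax(t_ev - eps, 0)),
                    R = ifelse(cens, Inf, t_ev))
  res <- generalized_logrank(obs, g, n_permutations = 4000, seed = 2)

  sd <- survival::survdiff(
    survival::Surv(ifelse(cens, 4, t_ev), !cens) ~ g)
  p_classic <- 1 - pchisq(sd$chisq, 1)
  expect_lt(abs(res$p - p_classic), 0.08)
  # scores coincide with the logrank observed-minus-expected count
  expect_equal(res$score, unname(sd$obs[2] - sd$exp[2]), tolerance = 0.05)
})

test_that("a planted group difference is detected", {
  eff <- effect_spec("P0001", log_hr = 1.4)
  v <- generate_validation_cohort(validation_design(n_subjects = 80,
                                                    n_proteins = 1,
                                                    seed = 8), eff)
  high <- v$matrix[, 1] >= median(v$matrix[, 1])
  res <- generalized_logrank(v$intervals, high, n_permutations = 1000,
                             seed = 3)
  expect_lt(res$p, 0.05)
  expect_gt(res$statistic, 3.84)
})

test_that("degenerate group inputs are rejected", {
  obs <- toy_intervals()
  expect_error(generalized_logrank(obs, rep(1, 8)), "nonempty")
  expect_error(generalized_logrank(obs, rep(0, 4)), "length")
})
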