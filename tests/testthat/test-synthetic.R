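test_that("cohort generation is bit-identical under a fixed seed", {
  d <- discovery_design(n_proteins = 25, seed = 123, missing_rate = 0.05)
  a <- generate_discovery_cohort(d)
  b <- generate_discovery_cohort(d)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$meta, b$meta)

  vd <- validation_design(n_proteins = 4, seed = 99, missing_rate = 0.1)
  eff <- effect_spec("P0001", log_hr = 1)
  va <- generate_validation_cohort(vd, eff)
  vb <- generate_validation_cohort(vd, eff)
  expect_identical(va$matrix, vb$matrix)
  expect_identical(va$intervals, vb$intervals)
})

test_that("planted case-control fold change is recovered at large n", {
  d <- discovery_design(n_cases = 10000, n_controls = 10000,
                        n_proteins = 3, n_progressors = 0, seed = 7)
  co <- generate_discovery_cohort(d, effect_spec("P0002", log2_fc = 1.0))
  fc <- log_fold_change(co$matrix, co$meta)
  expect_equal(unname(fc["P0002"]), 1.0, tolerance = 0.05)
  expect_lt(max(abs(fc[c("P0001", "P0003")])), 0.05)
})

test_that("null fold-change exceedance matches the closed-form rate", {
  # FC_p ~ N(0, sigma^2 (1/13 + 1/8)); protein-level means cancel exactly
  sd0 <- 0.5 * sqrt(1 / 13 + 1 / 8)
  p_exceed <- 2 * pnorm(-0.585 / sd0)
  hits <- 0L
  n_prot <- 100
  n_seeds <- 300
  for (s in seq_len(n_seeds)) {
    co <- generate_discovery_cohort(discovery_design(n_proteins = n_prot,
                                                     seed = 1000 + s))
    fc <- log_fold_change(co$matrix, co$meta)
    hits <- hits + length(filter_by_fc(fc, 0.585))
  }
  frac <- hits / (n_prot * n_seeds)
  se <- sqrt(p_exceed * (1 - p_exceed) / (n_prot * n_seeds))
  expect_lt(abs(frac - p_exceed), 4 * se)
})

test_that("null 5-year progression risk matches the exponential closed form", {
  # baseline calibrated so P(T <= 5) = 0.4 with no marker effects
  progressed <- 0L
  total <- 0L
  for (s in seq_len(100)) {
    v <- generate_validation_cohort(validation_design(n_proteins = 1,
                                                      seed = 2000 + s))
    progressed <- progressed + sum(is.finite(v$intervals$R))
    total <- total + nrow(v$intervals)
  }
  expect_equal(progressed / total, 0.4, tolerance = 0.05)
})

test_that("censoring intervals bracket the true event time", {
  for (s in 1:10) {
    v <- generate_validation_cohort(
      validation_design(n_proteins = 2, seed = 300 + s),
      effect_spec("P0001", log_hr = 0.8))
    obs <- v$intervals
    tt <- v$truth$true_time
    ev <- is.finite(obs$R)
    expect_true(all(obs$L[ev] < tt[ev] & tt[ev] <= obs$R[ev]))
    expect_true(all(obs$R[!ev] == Inf))
    expect_true(all(obs$L[!ev] == 5))   # last attended visit
    expect_true(all(tt[!ev] > 5))
  }
})

test_that("missingness control behaves as specified", {
  v0 <- generate_validation_cohort(validation_design(seed = 4,
                                                     missing_rate = 0))
  expect_false(anyNA(v0$matrix))
  v1 <- generate_validation_cohort(validation_design(seed = 4,
                                                     missing_rate = 0.15))
  expect_gt(sum(is.na(v1$matrix)), 0)
  expect_true(all(rowSums(!is.na(v1$matrix)) >= 1))
  expect_true(all(v1$matrix[!is.na(v1$matrix)] > 0))
})

test_that("invalid designs and effects are rejected", {
  expect_error(discovery_design(n_progressors = 20, n_cases = 13))
  expect_error(validation_design(visit_times = c(2, 1)))
  expect_error(validation_design(visit_times = numeric(0)))
  expect_error(validation_design(visit_times = 1:5, horizon = 0.5))
  expect_error(generate_discovery_cohort(
    discovery_design(n_proteins = 5),
    rbind(effect_spec("P0001"), effect_spec("P0001"))),
    "duplicate")
  expect_error(generate_discovery_cohort(discovery_design(n_proteins = 5),
                                         effect_spec("P9999")),
               "not among")
})
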