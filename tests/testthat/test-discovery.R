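test_that("log fold change has its closed-form values", {
  m <- rbind(c1 = c(A = 3, B = 4), c2 = c(A = 3, B = 4), c3 = c(A = 3, B = 4),
             h1 = c(A = 2, B = 4), h2 = c(A = 2, B = 4))
  meta <- data.frame(sample_id = rownames(m),
                     group = c("case", "case", "case", "control", "control"))
  fc <- log_fold_change(m, meta)
  expect_equal(unname(fc["A"]), log2(3 / 2))
  expect_equal(unname(fc["B"]), 0)

  # every case exactly 2x every control -> FC = 1
  m2 <- rbind(c1 = c(A = 8), c2 = c(A = 10), h1 = c(A = 4), h2 = c(A = 5))
  meta2 <- data.frame(sample_id = rownames(m2),
                      group = c("case", "case", "control", "control"))
  expect_equal(unname(log_fold_change(m2, meta2)["A"]), 1)
})

test_that("fold-change filter is two-sided and inclusive at the boundary", {
  fc <- c(a = 0.6, b = -0.7, c = 0.2, d = 0.585, e = -0.3)
  expect_setequal(filter_by_fc(fc, 0.585), c("a", "b", "d"))
  expect_length(filter_by_fc(c(x = 0, y = 0), 0.585), 0)
  # the 0.585 log2 threshold is the 1.5-fold linear-ratio filter
  expect_equal(2^0.585, 1.5, tolerance = 1e-3)
})

test_that("a perfectly separating marker scores near-perfect accuracy", {
  # all 7 progressors strictly above all 6 non-progressors; accuracy is not
  # exactly 1 because the in-bag median is always an actual data value (the
  # 7th order statistic of a 13-draw bootstrap), so out-of-bag subjects at
  # the class boundary can fall on the wrong side of it
  y <- c(rep(1, 7), rep(0, 6))
  vals <- c(10 + 1:7, 1:6)
  cfg <- bagging_config(n_resamples = 500, seed = 3)
  acc <- bagging_accuracy(vals, y, cfg)
  expect_gt(acc, 0.85)

  # and it matches the independent oracle on the same bootstrap draws
  set.seed(cfg$seed)
  boot <- matrix(sample.int(13, 13 * cfg$n_resamples, replace = TRUE),
                 nrow = cfg$n_resamples, byrow = TRUE)
  expect_equal(acc, r_bag_accuracy(vals, y, boot), tolerance = 1e-12)
})

test_that("the bagging kernel agrees with an independent R implementation", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:13, 1)
    y <- integer(n)
    y[sample(n, sample(2:(n - 2), 1))] <- 1L
    vals <- matrix(rlnorm(n * 3), n, 3)
    boot <- matrix(sample.int(n, n * 40, replace = TRUE), nrow = 40)
    got <- sscprog:::bag_accuracy_kernel(vals, cbind(y), boot, 0L, integer(1))
    for (p in 1:3)
      expect_equal(got[1, p], r_bag_accuracy(vals[, p], y, boot),
                   tolerance = 1e-12)
  }
})

test_that("a constant marker scores at the out-of-bag majority-class rate", {
  # all values tie with the median -> everything classified "at/below";
  # the in-bag majority picks the direction, so the OOB accuracy is the
  # OOB frequency of the in-bag majority class
  y <- c(rep(1, 7), rep(0, 6))
  vals <- rep(5, 13)
  acc <- bagging_accuracy(vals, y, bagging_config(n_resamples = 4000, seed = 8))
  set.seed(81)
  oracle <- replicate(20000, {
    idx <- sample.int(13, 13, replace = TRUE)
    oob <- setdiff(1:13, idx)
    if (!length(oob)) return(NA_real_)
    maj <- if (mean(y[idx]) > 0.5) 1L else 0L  # tie -> predict non-progressor
    mean(y[oob] == maj)
  })
  expect_equal(acc, mean(oracle, na.rm = TRUE), tolerance = 0.02)
})

test_that("step-down maxT output satisfies its structural invariants", {
  co <- generate_discovery_cohort(discovery_design(n_proteins = 8, seed = 21))
  cases <- co$meta$group == "case"
  cm <- co$matrix[cases, , drop = FALSE]
  y <- co$meta$outcome[cases]
  cfg <- bagging_config(n_resamples = 50, n_permutations = 300, seed = 5)
  res <- stepdown_maxt(cm, y, cfg)

  P <- cfg$n_permutations
  expect_true(all(res$p_adj >= 1 / (P + 1) & res$p_adj <= 1))
  # monotone nondecreasing along decreasing observed accuracy
  expect_true(all(diff(res$p_adj) >= -1e-12))
  expect_equal(order(res$bag_accuracy, decreasing = TRUE), seq_len(nrow(res)))

  # determinism
  res2 <- stepdown_maxt(cm, y, cfg)
  expect_identical(res, res2)

  # permuting protein columns permutes but does not change the results
  perm <- sample(ncol(cm))
  res3 <- stepdown_maxt(cm[, perm, drop = FALSE], y, cfg)
  expect_equal(res3[order(res3$protein_id), ],
               res[order(res$protein_id), ], ignore_attr = TRUE)
})

test_that("identical protein columns get identical adjusted p-values", {
  set.seed(9)
  v <- rlnorm(10)
  cm <- cbind(A = v, B = v, C = v)
  rownames(cm) <- paste0("s", 1:10)
  y <- c(rep(1, 5), rep(0, 5))
  res <- stepdown_maxt(cm, y, bagging_config(n_resamples = 40,
                                             n_permutations = 200, seed = 2))
  expect_equal(length(unique(res$p_adj)), 1)
  expect_equal(length(unique(res$bag_accuracy)), 1)
})

test_that("a single protein degenerates to its unadjusted permutation p", {
  set.seed(31)
  n <- 10
  y <- c(rep(1, 5), rep(0, 5))
  cm <- cbind(A = rlnorm(n))
  rownames(cm) <- paste0("s", 1:n)
  cfg <- bagging_config(n_resamples = 60, n_permutations = 400, seed = 13)
  res <- stepdown_maxt(cm, y, cfg)

  # replicate the seeded permutation and bootstrap streams and compute the
  # marginal permutation p directly with the independent oracle
  set.seed(cfg$seed)
  perms <- replicate(cfg$n_permutations, sample(y))
  boot <- matrix(sample.int(n, n * cfg$n_resamples, replace = TRUE),
                 nrow = cfg$n_resamples, byrow = TRUE)
  obs <- r_bag_accuracy(cm[, 1], y, boot)
  perm_acc <- apply(perms, 2, function(yy) r_bag_accuracy(cm[, 1], yy, boot))
  p_marg <- (1 + sum(perm_acc >= obs - 1e-12)) / (cfg$n_permutations + 1)
  expect_equal(res$p_adj, p_marg, tolerance = 1e-12)
})

test_that("sampled step-down p-values converge to the exhaustive oracle", {
  set.seed(55)
  n <- 6
  y <- c(1, 1, 1, 0, 0, 0)
  cm <- matrix(rlnorm(n * 3, meanlog = c(0.8, 0, 0)[col(matrix(0, n, 3))]),
               n, 3)
  cm[y == 1, 1] <- cm[y == 1, 1] * 2   # one real-ish marker, two nulls
  dimnames(cm) <- list(paste0("s", 1:n), c("A", "B", "C"))
  cfg <- bagging_config(n_resamples = 25, n_permutations = 4000, seed = 77)
  res <- stepdown_maxt(cm, y, cfg)

  set.seed(cfg$seed)
  replicate(cfg$n_permutations, sample(y))   # advance past the perm stream
  boot <- matrix(sample.int(n, n * cfg$n_resamples, replace = TRUE),
                 nrow = cfg$n_resamples, byrow = TRUE)
  oracle <- wy_stepdown_exact(cm, y, boot)

  for (pid in c("A", "B", "C")) {
    p_hat <- res$p_adj[res$protein_id == pid]
    p_star <- oracle$p_adj[pid]
    se <- sqrt(max(p_star * (1 - p_star), 0.25 / 20) / cfg$n_permutations)
    expect_lt(abs(p_hat - p_star), 3 * se + 2 / cfg$n_permutations)
  }
})

test_that("run_discovery recovers planted markers and handles empty filters", {
  eff <- rbind(effect_spec("P0001", log2_fc = 1.2, log_hr = 3.5),
               effect_spec("P0002", log2_fc = -1.1, log_hr = -3.5),
               effect_spec("P0003", log2_fc = 1.0, log_hr = 3.5))
  co <- generate_discovery_cohort(discovery_design(n_proteins = 100, seed = 61),
                                  eff)
  res <- run_discovery(co$matrix, co$meta,
                       bagging_config(n_permutations = 2000, seed = 6))
  expect_true(all(c("P0001", "P0002", "P0003") %in% res$protein_id[1:3]))
  expect_true(all(res$significant[res$protein_id %in% eff$protein_id]))

  # a global-null cohort with a sky-high threshold -> empty table, no error
  co0 <- generate_discovery_cohort(discovery_design(n_proteins = 10, seed = 3))
  res0 <- run_discovery(co0$matrix, co0$meta,
                        bagging_config(fc_threshold = 50))
  expect_equal(nrow(res0), 0)
  expect_named(res0, c("protein_id", "log2_fc", "bag_accuracy", "p_adj",
                       "significant"))
})

test_that("degenerate discovery inputs are rejected", {
  m <- matrix(rlnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("p", 1:4)))
  expect_error(stepdown_maxt(m, rep(1, 5)), "both classes")
  expect_error(bagging_accuracy(rep(1, 5), rep(1, 5)), "both classes")
  m2 <- m; m2[1, 1] <- -1
  expect_error(log_fold_change(m2, data.frame(sample_id = rownames(m),
                                              group = c("case", "case", "case",
                                                        "control", "control"))),
               "positive")
})
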