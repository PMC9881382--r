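# Independent reference implementations used as oracles. Deliberately
# written in plain R with a different structure from the package paths they
# check.

# mean out-of-bag accuracy of the median-threshold classifier, given an
# explicit bootstrap index matrix (rows = resamples)
r_bag_accuracy <- function(values, y, boot) {
  n <- length(values)
  accs <- numeric(0)
  for (b in seq_len(nrow(boot))) {
    idx <- boot[b, ]
    oob <- setdiff(seq_len(n), idx)
    if (!length(oob)) next
    thr <- stats::median(values[idx])
    acc_above <- mean((values[idx] > thr) == (y[idx] == 1))
    dir_above <- acc_above >= 0.5   # tie -> above-median predicts progressor
    pred <- if (dir_above) values[oob] > thr else values[oob] <= thr
    accs <- c(accs, mean(pred == (y[oob] == 1)))
  }
  mean(accs)
}

# exhaustive Westfall-Young step-down adjusted p-values: enumerate every
# distinct assignment of the progressor labels across cases (uniform under
# label permutation), score each with r_bag_accuracy on the shared bootstrap
# sets, and apply the step-down successive-maxima rule exactly
wy_stepdown_exact <- function(case_matrix, y, boot) {
  n <- length(y)
  n1 <- sum(y == 1)
  combos <- utils::combn(n, n1)
  m <- ncol(case_matrix)
  acc <- matrix(NA_real_, ncol(combos), m)
  for (k in seq_len(ncol(combos))) {
    yk <- integer(n)
    yk[combos[, k]] <- 1L
    for (p in seq_len(m)) acc[k, p] <- r_bag_accuracy(case_matrix[, p], yk, boot)
  }
  obs <- vapply(seq_len(m), function(p) r_bag_accuracy(case_matrix[, p], y, boot),
                numeric(1))
  ord <- order(obs, decreasing = TRUE)
  p_sorted <- numeric(m)
  for (i in seq_len(m)) {
    succ_max <- apply(acc[, ord[i:m], drop = FALSE], 1, max)
    p_sorted[i] <- mean(succ_max >= obs[ord[i]] - 1e-12)
  }
  p_adj <- numeric(m)
  p_adj[ord] <- cummax(p_sorted)
  names(p_adj) <- colnames(case_matrix)
  list(p_adj = p_adj, obs = obs)
}

# brute-force NPMLE for interval-censored data: direct maximization of the
# log-likelihood over the probability simplex on the innermost intervals
# (softmax parameterization, several starts)
simplex_npmle <- function(L, R) {
  inn <- sscprog:::.innermost_intervals(L, R)
  A <- sscprog:::.alpha_matrix(L, R, inn)
  J <- nrow(inn)
  nll <- function(g) {
    w <- exp(c(0, g))
    p <- w / sum(w)
    -sum(log(pmax(drop(A %*% p), 1e-300)))
  }
  best <- NULL
  set.seed(42)
  for (s in 1:6) {
    g0 <- if (s == 1) rep(0, J - 1) else stats::rnorm(J - 1)
    o <- stats::optim(g0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  w <- exp(c(0, best$par))
  list(intervals = inn, mass = w / sum(w), loglik = -best$value)
}

# per-candidate logrank numerators via survival::survdiff (observed minus
# expected deaths in the high group)
survdiff_scan <- function(x, time, status, candidates) {
  vapply(candidates, function(cc) {
    grp <- factor(x >= cc, levels = c(FALSE, TRUE))
    sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
    unname(sd$obs[2] - sd$exp[2])
  }, numeric(1))
}

# small interval-censored toy shared by several tests
toy_intervals <- function() {
  data.frame(sample_id = paste0("s", 1:8),
             L = c(0, 0, 1, 1, 2, 2, 3, 4),
             R = c(1, 2, 2, 3, 4, Inf, Inf, Inf),
             stringsAsFactors = FALSE)
}
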