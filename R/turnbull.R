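# Turnbull innermost intervals of interval-censored observations (L, R].
# Adjacent distinct endpoint pairs (a, b] with a from the L-set and b from
# the R-set; every NPMLE support point lies in one of these.
.innermost_intervals <- function(L, R) {
  pts <- sort(unique(c(L, R)))
  isL <- pts %in% L
  isR <- pts %in% R
  q <- p <- numeric(0)
  for (i in seq_len(length(pts) - 1)) {
    if (isL[i] && isR[i + 1]) {
      q <- c(q, pts[i])
      p <- c(p, pts[i + 1])
    }
  }
  if (!length(q)) stop("no innermost interval; degenerate input")
  data.frame(q = q, p = p)
}

# alpha[i, j] = 1 iff innermost interval j is contained in (L_i, R_i]
.alpha_matrix <- function(L, R, inn) {
  outer(L, inn$q, `<=`) & outer(R, inn$p, `>=`)
}

#' Turnbull nonparametric MLE of the survival function
#'
#' Self-consistency (EM) estimate of the survival distribution from
#' interval-censored observations `(L, R]`, with `R = Inf` encoding right
#' censoring. Probability mass is assigned to the Turnbull innermost
#' intervals; the survival function is uniquely defined outside them and
#' reported as a right-continuous step function at their right endpoints.
#'
#' @param obs Data frame with `sample_id`, `L`, `R` (years; `R = Inf` for
#'   right-censored subjects), or anything [read_intervals_csv()] returns.
#' @param tol EM stopping rule: maximum absolute mass change (default 1e-8).
#' @param maxit Iteration cap (default 10000).
#' @return Object of class `turnbull_npmle`: `intervals` (`q`, `p`, `mass`),
#'   `surv` (`time`, `surv`, starting at (0, 1)), `loglik`, `iterations`,
#'   `converged`.
#' @examples
#' obs <- data.frame(sample_id = letters[1:4],
#'                   L = c(0, 1, 2, 3), R = c(2, 3, 4, Inf))
#' fit <- turnbull_npmle(obs)
#' fit$intervals
#' @export
turnbull_npmle <- function(obs, tol = 1e-8, maxit = 10000) {
  .check_intervals(obs)
  L <- obs$L; R <- obs$R
  inn <- .innermost_intervals(L, R)
  A <- .alpha_matrix(L, R, inn)
  if (any(rowSums(A) == 0))
    stop("an observation contains no innermost interval; check (L, R]")
  J <- nrow(inn)
  m <- rep(1 / J, J)
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    denom <- drop(A %*% m)
    m_new <- colMeans(A * rep(m, each = nrow(A)) / denom)
    if (max(abs(m_new - m)) < tol) {
      m <- m_new
      converged <- TRUE
      break
    }
    m <- m_new
  }
  loglik <- sum(log(drop(A %*% m)))
  surv <- data.frame(time = c(0, inn$p), surv = c(1, 1 - cumsum(m)))
  structure(list(intervals = cbind(inn, mass = m), surv = surv,
                 loglik = loglik, iterations = it, converged = converged),
            class = "turnbull_npmle")
}

#' @export
print.turnbull_npmle <- function(x, ...) {
  cat("Turnbull NPMLE:", nrow(x$intervals), "innermost interval(s),",
      "log-likelihood", format(x$loglik, digits = 6), "\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

# Evaluate a Turnbull survival estimate at arbitrary times outside the
# innermost intervals' interiors: S(t) = 1 - sum of masses with p <= t.
.turnbull_surv_at <- function(fit, t) {
  p <- fit$intervals$p
  m <- fit$intervals$mass
  vapply(t, function(ti) {
    if (!is.finite(ti)) return(0)
    1 - sum(m[p <= ti])
  }, numeric(1))
}
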