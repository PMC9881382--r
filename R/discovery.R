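#' Configuration of the discovery screen
#'
#' Defaults follow the published analysis settings: 100 bootstrap
#' resamples for the bagged accuracy, 10,000 label permutations for the
#' step-down maxT family-wise correction, a log2 fold-change filter at
#' 0.585 (a 1.5-fold change), and a nominal 0.05 family-wise level.
#'
#' @param n_resamples Bootstrap resamples per protein (default 100).
#' @param n_permutations Outcome-label permutations (default 10000).
#' @param fc_threshold Two-sided |log2 FC| filter vs controls (default 0.585).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for bootstrap draws and permutations.
#' @param reuse_bootstrap If `TRUE` (default) the bootstrap index sets are
#'   drawn once and reused for every permutation; if `FALSE`, fresh sets are
#'   drawn per permutation (slower, more Monte-Carlo noise, same target).
#' @param direction `"in_bag"` (default): per resample, the classification
#'   direction (above- vs below-median predicts progression) is the one with
#'   the higher in-bag accuracy, ties going to above-median-predicts-
#'   progressor; `"fc_sign"`: the direction is fixed per protein by the sign
#'   of its case-vs-control log2 fold change.
#' @return A list of class `bagging_config`.
#' @export
bagging_config <- function(n_resamples = 100, n_permutations = 10000,
                           fc_threshold = 0.585, alpha = 0.05, seed = 1L,
                           reuse_bootstrap = TRUE,
                           direction = c("in_bag", "fc_sign")) {
  direction <- match.arg(direction)
  stopifnot(n_resamples >= 1, n_permutations >= 1, fc_threshold > 0,
            alpha > 0, alpha < 1)
  structure(list(n_resamples = as.integer(n_resamples),
                 n_permutations = as.integer(n_permutations),
                 fc_threshold = fc_threshold, alpha = alpha,
                 seed = as.integer(seed),
                 reuse_bootstrap = isTRUE(reuse_bootstrap),
                 direction = direction),
            class = "bagging_config")
}

#' Per-protein log2 fold change of cases versus controls
#'
#' The fold change is the difference of arithmetic means of log2 abundances
#' (equivalently, the log2 ratio of geometric means), the standard summary
#' for positive, right-skewed abundance data.
#'
#' @param matrix Samples x proteins positive matrix.
#' @param meta Metadata with `sample_id`, `group` (case/control).
#' @return Named numeric vector, one log2 FC per protein.
#' @examples
#' m <- rbind(c1 = c(A = 3), c2 = c(A = 3), h1 = c(A = 2))
#' meta <- data.frame(sample_id = c("c1", "c2", "h1"),
#'                    group = c("case", "case", "control"))
#' log_fold_change(m, meta)  # log2(3/2) = 0.585
#' @export
log_fold_change <- function(matrix, meta) {
  .check_protein_matrix(matrix)
  meta <- .align_meta(matrix, meta)
  cases <- meta$sample_id[meta$group == "case"]
  ctrls <- meta$sample_id[meta$group == "control"]
  if (!length(cases) || !length(ctrls))
    stop("need at least one case and one control")
  lv <- log2(matrix)
  colMeans(lv[cases, , drop = FALSE]) - colMeans(lv[ctrls, , drop = FALSE])
}

#' Filter proteins by absolute log2 fold change
#'
#' Keeps proteins with `|FC| >= threshold` (two-sided, inclusive at the
#' boundary). At the default threshold 0.585 this is the classic
#' 1.5-fold-change filter, since `2^0.585 = 1.5` to three decimals.
#'
#' @param fc Named per-protein log2 fold changes.
#' @param threshold Positive log2 threshold (default 0.585).
#' @return Character vector of retained protein ids.
#' @export
filter_by_fc <- function(fc, threshold = 0.585) {
  stopifnot(threshold > 0)
  names(fc)[abs(fc) >= threshold]
}

.align_meta <- function(matrix, meta) {
  need <- c("sample_id", "group")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("meta needs columns sample_id and group")
  if (!all(rownames(matrix) %in% meta$sample_id))
    stop("meta is missing samples present in the matrix")
  meta[match(rownames(matrix), meta$sample_id), , drop = FALSE]
}

.outcome01 <- function(outcome) {
  if (is.logical(outcome)) return(as.integer(outcome))
  if (is.numeric(outcome)) {
    stopifnot(all(outcome %in% c(0, 1)))
    return(as.integer(outcome))
  }
  as.integer(outcome == "progressor")
}

.draw_bootstrap <- function(n, n_resamples) {
  matrix(sample.int(n, n * n_resamples, replace = TRUE),
         nrow = n_resamples, ncol = n, byrow = TRUE)
}

#' Bagged out-of-bag accuracy of a median-threshold classifier
#'
#' For each bootstrap resample of the cases (size = number of cases, with
#' replacement), the in-bag median abundance is used as a classification
#' threshold for progression; its accuracy is scored on the out-of-bag
#' cases from the 2x2 table, and the mean over resamples (skipping the rare
#' empty out-of-bag sets) is returned. Values equal to the median count as
#' "at/below". The classification direction is chosen per resample on the
#' in-bag sample (see [bagging_config()]).
#'
#' @param values Per-case abundance (numeric vector).
#' @param outcome Per-case outcome: `"progressor"`/`"non_progressor"`,
#'   logical, or 0/1.
#' @param cfg A [bagging_config()]; only `n_resamples`, `seed`, `direction`
#'   are used. Seeds the bootstrap draw.
#' @param fc_dir Optional per-protein direction (+1/-1) when
#'   `cfg$direction == "fc_sign"`.
#' @return Mean out-of-bag accuracy in `[0, 1]`.
#' @export
bagging_accuracy <- function(values, outcome, cfg = bagging_config(),
                             fc_dir = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2)
  y <- .outcome01(outcome)
  if (length(y) != length(values))
    stop("values and outcome lengths differ")
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes")
  set.seed(cfg$seed)
  boot <- .draw_bootstrap(length(values), cfg$n_resamples)
  dirmode <- if (cfg$direction == "fc_sign") 1L else 0L
  fd <- if (dirmode == 1L) as.integer(fc_dir) else integer(1)
  acc <- bag_accuracy_kernel(cbind(values), cbind(y), boot, dirmode, fd)
  as.numeric(acc[1, 1])
}

#' Step-down maxT permutation screen over case proteins
#'
#' Computes the bagged out-of-bag accuracy of every protein on the cases,
#' then adjusts for family-wise error with the Westfall-Young step-down maxT
#' procedure: outcome labels are permuted across cases, accuracies are
#' recomputed for every permutation (by default reusing the same bootstrap
#' index sets, a variance-reduction device), and with proteins ordered by
#' observed accuracy the adjusted p at rank i is
#' `(1 + #permutations where max over ranks >= i of permuted accuracy >=
#' observed_i) / (n_permutations + 1)`, followed by monotonicity
#' enforcement along the ordering.
#'
#' @param case_matrix Cases x proteins positive matrix (cases only).
#' @param outcome Per-case outcome labels.
#' @param cfg A [bagging_config()].
#' @param fc_dir Optional named per-protein directions for
#'   `direction = "fc_sign"`.
#' @return `data.frame` with `protein_id`, `bag_accuracy`, `p_adj`,
#'   `significant`, sorted by accuracy descending.
#' @export
stepdown_maxt <- function(case_matrix, outcome, cfg = bagging_config(),
                          fc_dir = NULL) {
  .check_protein_matrix(case_matrix)
  y <- .outcome01(outcome)
  n <- nrow(case_matrix)
  if (length(y) != n) stop("outcome length must match rows of case_matrix")
  if (length(unique(y)) < 2) stop("outcome must contain both classes")

  P <- cfg$n_permutations
  set.seed(cfg$seed)
  perms <- replicate(P, sample(y))
  labmat <- cbind(y, perms)

  dirmode <- if (cfg$direction == "fc_sign") 1L else 0L
  fd <- if (dirmode == 1L) {
    if (is.null(fc_dir)) stop("direction = 'fc_sign' needs fc_dir")
    as.integer(sign(fc_dir[colnames(case_matrix)]))
  } else integer(1)

  if (cfg$reuse_bootstrap) {
    boot <- .draw_bootstrap(n, cfg$n_resamples)
    acc <- bag_accuracy_kernel(case_matrix, labmat, boot, dirmode, fd)
  } else {
    acc <- matrix(NA_real_, nrow = P + 1, ncol = ncol(case_matrix))
    for (k in seq_len(P + 1)) {
      boot <- .draw_bootstrap(n, cfg$n_resamples)
      acc[k, ] <- bag_accuracy_kernel(case_matrix,
                                      labmat[, k, drop = FALSE],
                                      boot, dirmode, fd)[1, ]
    }
  }

  obs <- acc[1, ]
  perm <- acc[-1, , drop = FALSE]
  ord <- order(obs, decreasing = TRUE)
  eps <- 1e-12

  # successive maxima over not-yet-rejected proteins, built right to left
  m <- ncol(case_matrix)
  count <- numeric(m)
  run <- rep(-Inf, nrow(perm))
  for (j in rev(seq_len(m))) {
    run <- pmax(run, perm[, ord[j]])
    count[j] <- sum(run >= obs[ord[j]] - eps)
  }
  p_sorted <- cummax((1 + count) / (P + 1))
  p_adj <- numeric(m)
  p_adj[ord] <- p_sorted

  out <- data.frame(protein_id = colnames(case_matrix),
                    bag_accuracy = obs, p_adj = p_adj,
                    significant = p_adj <= cfg$alpha,
                    stringsAsFactors = FALSE)
  out[order(out$bag_accuracy, decreasing = TRUE), , drop = FALSE]
}

#' Run the full discovery screen
#'
#' Composition of the fold-change filter against healthy controls (which is
#' outcome-blind) and the bagged-accuracy + step-down maxT permutation
#' screen on the cases, yielding the ranked candidate-marker table.
#'
#' @param matrix Samples x proteins positive matrix (cases and controls).
#' @param meta Metadata with `sample_id`, `group`, `outcome`.
#' @param cfg A [bagging_config()].
#' @return `data.frame` with `protein_id`, `log2_fc`, `bag_accuracy`,
#'   `p_adj`, `significant`, sorted by accuracy descending; zero rows if no
#'   protein passes the fold-change filter.
#' @examples
#' cohort <- generate_discovery_cohort(
#'   discovery_design(n_proteins = 30, seed = 11),
#'   effect_spec("P0001", log2_fc = 1.2, log_hr = 3))
#' run_discovery(cohort$matrix, cohort$meta,
#'               bagging_config(n_permutations = 200, seed = 4))
#' @export
run_discovery <- function(matrix, meta, cfg = bagging_config()) {
  .check_protein_matrix(matrix)
  meta <- .align_meta(matrix, meta)
  if (!"outcome" %in% names(meta)) stop("meta needs an outcome column")

  fc <- log_fold_change(matrix, meta)
  keep <- filter_by_fc(fc, cfg$fc_threshold)
  if (!length(keep)) {
    return(data.frame(protein_id = character(), log2_fc = numeric(),
                      bag_accuracy = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }

  cases <- meta$group == "case"
  case_matrix <- matrix[meta$sample_id[cases], keep, drop = FALSE]
  y <- .outcome01(meta$outcome[cases])
  res <- stepdown_maxt(case_matrix, y, cfg, fc_dir = sign(fc[keep]))
  res$log2_fc <- fc[res$protein_id]
  res[, c("protein_id", "log2_fc", "bag_accuracy", "p_adj", "significant")]
}
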