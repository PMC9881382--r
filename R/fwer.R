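#' Family-wise error calibration of the discovery screen under a global null
#'
#' Simulates replicate discovery cohorts with no protein-outcome association
#' (every protein i.i.d. log-normal in both outcome groups), runs the bagged
#' median-threshold screen with the step-down maxT permutation adjustment on
#' the cases, and reports the fraction of replicates in which any protein is
#' declared family-wise significant at `alpha`. For a valid procedure this
#' fraction must not exceed `alpha` up to binomial noise.
#'
#' The fold-change filter is skipped here on purpose: it is outcome-blind,
#' so it cannot affect family-wise validity, and under the global null it
#' would only shrink the tested family.
#'
#' @param n_replicates Replicate cohorts (default 200).
#' @param n_cases,n_progressors,n_proteins Cohort shape (defaults 13, 7, 20).
#' @param cfg A [bagging_config()]; its `seed` seeds the replicate stream.
#' @return List with `fwer` (the empirical rate), `n_replicates`,
#'   `any_significant` (logical per replicate), and `min_p` per replicate.
#' @examples
#' sim <- fwer_simulation(n_replicates = 20,
#'                        cfg = bagging_config(n_permutations = 100, seed = 2))
#' sim$fwer
#' @export
fwer_simulation <- function(n_replicates = 200, n_cases = 13,
                            n_progressors = 7, n_proteins = 20,
                            cfg = bagging_config(n_permutations = 200)) {
  set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  any_sig <- logical(n_replicates)
  min_p <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    design <- discovery_design(n_cases = n_cases, n_controls = 2,
                               n_proteins = n_proteins,
                               n_progressors = n_progressors,
                               seed = rep_seeds[r])
    cohort <- generate_discovery_cohort(design)
    cases <- cohort$meta$group == "case"
    cm <- cohort$matrix[cases, , drop = FALSE]
    y <- cohort$meta$outcome[cases]
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    res <- stepdown_maxt(cm, y, cfg_r)
    any_sig[r] <- any(res$p_adj <= cfg$alpha)
    min_p[r] <- min(res$p_adj)
  }
  list(fwer = mean(any_sig), n_replicates = n_replicates,
       any_significant = any_sig, min_p = min_p)
}
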