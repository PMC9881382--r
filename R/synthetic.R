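#' Planted marker effects for synthetic cohorts
#'
#' Describes how one protein departs from the null in a simulated cohort:
#' a case-vs-control mean shift on the log2 scale (`log2_fc`) and/or an
#' association with progression (`log_hr`). In a discovery cohort `log_hr`
#' acts as a per-SD mean shift of progressors' log2 values (a point-biserial
#' association); in a validation cohort it is the per-SD log hazard ratio of
#' the proportional-hazards event model.
#'
#' @param protein_id Protein identifier the effect applies to.
#' @param log2_fc Case-vs-control mean shift of log2 abundance. Default 0.
#' @param log_hr Log hazard ratio per standard deviation of log2 abundance
#'   (validation), or per-SD progressor shift (discovery). Default 0.
#' @return A one-row `data.frame` with columns `protein_id`, `log2_fc`,
#'   `log_hr`. Combine several with `rbind()`.
#' @examples
#' rbind(effect_spec("P0001", log2_fc = 1, log_hr = 1.4),
#'       effect_spec("P0002", log_hr = -1.4))
#' @export
effect_spec <- function(protein_id, log2_fc = 0, log_hr = 0) {
  stopifnot(length(protein_id) == 1L, is.finite(log2_fc), is.finite(log_hr))
  data.frame(protein_id = as.character(protein_id),
             log2_fc = log2_fc, log_hr = log_hr,
             stringsAsFactors = FALSE)
}

.check_effects <- function(effects) {
  if (is.null(effects)) {
    return(data.frame(protein_id = character(), log2_fc = numeric(),
                      log_hr = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(effects),
            all(c("protein_id", "log2_fc", "log_hr") %in% names(effects)))
  if (anyDuplicated(effects$protein_id))
    stop("duplicate protein_id in effect specification")
  if (!all(is.finite(effects$log2_fc)) || !all(is.finite(effects$log_hr)))
    stop("effect sizes must be finite")
  effects
}

#' Design of a synthetic discovery cohort
#'
#' Defaults reproduce the dimensions of an aptamer discovery study in
#' preclinical systemic sclerosis: 13 cases (7 of whom later progress to
#' definite disease) and 8 matched healthy controls. Null log2 abundances are
#' Normal(mu_p, sigma) with protein-level means mu_p drawn once per cohort,
#' i.e. relative fluorescence units are log-normal.
#'
#' @param n_cases,n_controls,n_proteins,n_progressors Cohort dimensions.
#' @param sigma Within-protein SD of log2 abundance (default 0.5).
#' @param mu_mean,mu_sd Distribution of protein-level log2 means (default
#'   Normal(10, 1), i.e. RFUs of order 1000).
#' @param missing_rate Proportion of cells set missing completely at random.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the design (including the seed) and the effect list.
#' @return A list of class `discovery_design`.
#' @export
discovery_design <- function(n_cases = 13, n_controls = 8, n_proteins = 100,
                             n_progressors = 7, sigma = 0.5,
                             mu_mean = 10, mu_sd = 1,
                             missing_rate = 0, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_proteins >= 1,
            n_progressors >= 0, n_progressors <= n_cases,
            sigma > 0, missing_rate >= 0, missing_rate < 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_proteins = as.integer(n_proteins),
                 n_progressors = as.integer(n_progressors),
                 sigma = sigma, mu_mean = mu_mean, mu_sd = mu_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "discovery_design")
}

#' Design of a synthetic validation cohort
#'
#' Defaults reproduce a 50-subject prospective validation cohort followed on
#' a yearly visit schedule over a 5-year horizon, with the exponential
#' baseline hazard calibrated so that the 5-year cumulative progression risk
#' is 40% when no marker effects are planted (20/50 progressors on average).
#'
#' @param n_subjects Cohort size (default 50).
#' @param n_proteins Number of proteins measured (default 9, an ELISA panel).
#' @param baseline_hazard Baseline hazard scale per year; with
#'   `weibull_shape = 1` the cumulative hazard is `baseline_hazard * t`.
#'   Default `-log(0.6)/5` (5-year risk 0.40).
#' @param weibull_shape Weibull shape of the baseline cumulative hazard
#'   `(baseline_hazard * t)^shape`... shape 1 = exponential (default);
#'   other values support misspecification experiments.
#' @param visit_times Strictly increasing assessment times in years from
#'   blood draw (default yearly, 1:5). Progression is only ascertained at
#'   visits, which is what makes the outcome interval-censored.
#' @param horizon End of follow-up in years (default 5).
#' @param sigma,mu_mean,mu_sd,missing_rate,seed As in [discovery_design()].
#' @return A list of class `validation_design`.
#' @export
validation_design <- function(n_subjects = 50, n_proteins = 9,
                              baseline_hazard = -log(0.6) / 5,
                              weibull_shape = 1,
                              visit_times = 1:5, horizon = 5,
                              sigma = 0.5, mu_mean = 10, mu_sd = 1,
                              missing_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, n_proteins >= 1, baseline_hazard > 0,
            weibull_shape > 0, sigma > 0,
            missing_rate >= 0, missing_rate < 1)
  if (length(visit_times) == 0) stop("empty visit schedule")
  if (any(diff(visit_times) <= 0) || visit_times[1] <= 0)
    stop("visit_times must be strictly increasing with first visit > 0")
  if (horizon < visit_times[1])
    stop("horizon earlier than the first visit")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_proteins = as.integer(n_proteins),
                 baseline_hazard = baseline_hazard,
                 weibull_shape = weibull_shape,
                 visit_times = as.numeric(visit_times), horizon = horizon,
                 sigma = sigma, mu_mean = mu_mean, mu_sd = mu_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "validation_design")
}

.protein_ids <- function(n) sprintf("P%04d", seq_len(n))

# log2 abundance matrix under the null: rows samples, cols proteins
.null_log2 <- function(n_samples, mu, sigma) {
  matrix(rnorm(n_samples * length(mu), mean = rep(mu, each = n_samples),
               sd = sigma),
         nrow = n_samples, ncol = length(mu))
}

.inject_missing <- function(x, rate) {
  if (rate <= 0) return(x)
  drop_mask <- matrix(runif(length(x)) < rate, nrow = nrow(x))
  # keep at least one observed value per row (imputation precondition)
  full_rows <- which(rowSums(!drop_mask) == 0)
  if (length(full_rows)) drop_mask[full_rows, 1] <- FALSE
  x[drop_mask] <- NA_real_
  x
}

#' Simulate a discovery cohort (cases + healthy controls)
#'
#' Null proteins are drawn i.i.d. log-normal, identically in cases and
#' controls. For each planted effect, case log2 values are shifted by
#' `log2_fc`, and progressors' log2 values are additionally shifted by
#' `log_hr * sigma` (so `log_hr` is a standardized progressor/non-progressor
#' effect size). All abundances are strictly positive and the output is a
#' deterministic function of the design.
#'
#' @param design A [discovery_design()].
#' @param effects Effect table from [effect_spec()] / `rbind`, or `NULL`.
#' @return List with `matrix` (samples x proteins, positive values) and
#'   `meta` (`sample_id`, `group` in case/control, `outcome` in
#'   progressor/non_progressor/not_applicable).
#' @examples
#' cohort <- generate_discovery_cohort(discovery_design(n_proteins = 20, seed = 7))
#' dim(cohort$matrix)
#' table(cohort$meta$group, cohort$meta$outcome)
#' @export
generate_discovery_cohort <- function(design, effects = NULL) {
  stopifnot(inherits(design, "discovery_design"))
  effects <- .check_effects(effects)
  prot <- .protein_ids(design$n_proteins)
  if (!all(effects$protein_id %in% prot))
    stop("effect protein_id not among generated proteins: ",
         paste(setdiff(effects$protein_id, prot), collapse = ", "))

  set.seed(design$seed)
  n <- design$n_cases + design$n_controls
  mu <- rnorm(design$n_proteins, design$mu_mean, design$mu_sd)
  log2v <- .null_log2(n, mu, design$sigma)
  case_rows <- seq_len(design$n_cases)
  ctrl_rows <- design$n_cases + seq_len(design$n_controls)
  progressors <- sort(sample(case_rows, design$n_progressors))

  for (i in seq_len(nrow(effects))) {
    j <- match(effects$protein_id[i], prot)
    log2v[case_rows, j] <- log2v[case_rows, j] + effects$log2_fc[i]
    if (effects$log_hr[i] != 0)
      log2v[progressors, j] <- log2v[progressors, j] +
        effects$log_hr[i] * design$sigma
  }

  values <- 2^log2v
  rownames(values) <- c(sprintf("case%02d", case_rows),
                        sprintf("ctrl%02d", seq_len(design$n_controls)))
  colnames(values) <- prot
  values <- .inject_missing(values, design$missing_rate)

  outcome <- rep("not_applicable", n)
  outcome[case_rows] <- "non_progressor"
  outcome[progressors] <- "progressor"
  meta <- data.frame(
    sample_id = rownames(values),
    group = rep(c("case", "control"),
                c(design$n_cases, design$n_controls)),
    outcome = outcome, stringsAsFactors = FALSE)
  list(matrix = values, meta = meta)
}

#' Simulate a validation cohort with interval-censored progression times
#'
#' Event times follow a proportional-hazards model with cumulative hazard
#' `(baseline_hazard * t)^shape * exp(lp)` where the linear predictor is
#' `sum(log_hr * z)` over planted effects and `z` is the marker's exactly
#' standardized log2 abundance. Progression is ascertained only at the visit
#' times, yielding intervals `(L, R]`: `L` the last progression-free visit
#' (0 if progression precedes the first visit), `R` the first visit at or
#' after the event, and `R = Inf` with `L` the last visit when no
#' progression is seen by the horizon. Missing abundance cells are inserted
#' completely at random at `missing_rate` (never emptying a whole row).
#'
#' @param design A [validation_design()].
#' @param effects Effect table (`log2_fc` is ignored here), or `NULL`.
#' @return List with `matrix` (samples x proteins), `intervals`
#'   (`sample_id`, `L`, `R` in years), and `truth` (`sample_id`,
#'   `true_time`, the simulated event time, plus the standardized marker
#'   values used in the linear predictor) for use in tests.
#' @examples
#' eff <- effect_spec("P0001", log_hr = log(2))
#' v <- generate_validation_cohort(validation_design(seed = 3), eff)
#' head(v$intervals)
#' mean(is.finite(v$intervals$R))  # realized progressor fraction
#' @export
generate_validation_cohort <- function(design, effects = NULL) {
  stopifnot(inherits(design, "validation_design"))
  effects <- .check_effects(effects)
  prot <- .protein_ids(design$n_proteins)
  if (!all(effects$protein_id %in% prot))
    stop("effect protein_id not among generated proteins: ",
         paste(setdiff(effects$protein_id, prot), collapse = ", "))

  set.seed(design$seed)
  n <- design$n_subjects
  mu <- rnorm(design$n_proteins, design$mu_mean, design$mu_sd)
  log2v <- .null_log2(n, mu, design$sigma)
  zstd <- sweep(sweep(log2v, 2, mu), 2, design$sigma, `/`)

  lp <- rep(0, n)
  for (i in seq_len(nrow(effects))) {
    j <- match(effects$protein_id[i], prot)
    lp <- lp + effects$log_hr[i] * zstd[, j]
  }

  # inverse-transform sampling from Lambda(t) = (b t)^k exp(lp)
  e <- rexp(n)
  true_time <- (e / exp(lp))^(1 / design$weibull_shape) / design$baseline_hazard

  vs <- design$visit_times[design$visit_times <= design$horizon]
  L <- R <- numeric(n)
  for (i in seq_len(n)) {
    if (true_time[i] <= max(vs)) {
      R[i] <- vs[which(vs >= true_time[i])[1]]
      before <- vs[vs < true_time[i]]
      L[i] <- if (length(before)) max(before) else 0
    } else {
      L[i] <- max(vs)
      R[i] <- Inf
    }
  }

  values <- 2^log2v
  rownames(values) <- sprintf("subj%03d", seq_len(n))
  colnames(values) <- prot
  values <- .inject_missing(values, design$missing_rate)

  truth <- data.frame(sample_id = rownames(values), true_time = true_time,
                      stringsAsFactors = FALSE)
  if (nrow(effects)) {
    zcols <- as.data.frame(zstd[, match(effects$protein_id, prot),
                                drop = FALSE])
    names(zcols) <- paste0("z_", effects$protein_id)
    truth <- cbind(truth, zcols)
  }
  intervals <- data.frame(sample_id = rownames(values), L = L, R = R,
                          stringsAsFactors = FALSE)
  .check_intervals(intervals)
  list(matrix = values, intervals = intervals, truth = truth)
}
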