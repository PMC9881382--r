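#!/usr/bin/env Rscript
# Stage 0: simulate the two study cohorts.
#
# Discovery: 13 preclinical cases (7 later progress to definite disease) and
# 8 matched healthy controls, 1306 proteins on a log-normal RFU scale.
# Twelve proteins are planted as differentially expressed vs controls
# (|log2 FC| >= 0.8); three of those additionally carry a progressor /
# non-progressor shift, emulating prognostic markers of the
# endostatin / bFGF / PAF-AHbeta kind (one harmful-high, two
# protective-high).
#
# Validation: 50 independent subjects measured on a 9-protein panel,
# followed on a yearly visit schedule for 5 years (interval-censored
# progression, 40% baseline 5-year risk), with the same three prognostic
# markers planted and 5% missing cells for the imputation step.

suppressPackageStartupMessages(library(sscprog))

seed <- 20230
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating discovery cohort (13 cases / 8 controls, 1306 proteins)")
disc_effects <- rbind(
  effect_spec("P0001", log2_fc =  1.4, log_hr =  3.5),  # harmful, up vs HC
  effect_spec("P0002", log2_fc = -1.1, log_hr = -3.5),  # protective, down
  effect_spec("P0003", log2_fc = -0.9, log_hr = -3.0),  # protective, down
  effect_spec("P0004", log2_fc =  1.0),                 # DE only
  effect_spec("P0005", log2_fc = -1.2),
  effect_spec("P0006", log2_fc =  0.8),
  effect_spec("P0007", log2_fc =  1.6),
  effect_spec("P0008", log2_fc = -0.7),
  effect_spec("P0009", log2_fc =  0.9),
  effect_spec("P0010", log2_fc = -1.0),
  effect_spec("P0011", log2_fc =  0.7),
  effect_spec("P0012", log2_fc = -1.5))
disc <- generate_discovery_cohort(
  discovery_design(n_proteins = 1306, seed = seed), disc_effects)
write_protein_csv(disc$matrix, file.path(out_dir, "discovery_matrix.csv"))
write_meta_csv(disc$meta, file.path(out_dir, "discovery_meta.csv"))

message("simulating validation cohort (50 subjects, 9-protein panel)")
val_effects <- rbind(
  effect_spec("P0001", log_hr =  1.4),
  effect_spec("P0002", log_hr = -1.4),
  effect_spec("P0003", log_hr = -1.2))
val <- generate_validation_cohort(
  validation_design(n_proteins = 9, missing_rate = 0.05, seed = seed + 1),
  val_effects)
write_protein_csv(val$matrix, file.path(out_dir, "validation_matrix.csv"))
write_intervals_csv(val$intervals, file.path(out_dir, "validation_intervals.csv"))

n_prog <- sum(is.finite(val$intervals$R))
message(sprintf("validation cohort: %d/%d subjects progressed within 5 years",
                n_prog, nrow(val$intervals)))

manifest <- c(
  sprintf("seed: %d", seed),
  sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
  sprintf("sscprog version: %s", as.character(packageVersion("sscprog"))),
  vapply(list.files(out_dir, full.names = TRUE), function(f)
    sprintf("md5 %s: %s", basename(f), tools::md5sum(f)), character(1)))
writeLines(manifest, file.path(out_dir, "manifest.txt"))
message("wrote ", out_dir)
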