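#!/usr/bin/env Rscript
# Analyze the simulated traces: segment cycles, run baseline QC, call
# inhibition per replicate, aggregate to per-chemical calls under the
# majority rule, and estimate the inhibitory dose for positive calls.
# Requires results/traces/ from analysis/01_simulate_traces.R.

suppressPackageStartupMessages(library(cdsurf))

trace_dir <- file.path("results", "traces")
if (!dir.exists(trace_dir))
  stop("run analysis/01_simulate_traces.R first")
panel <- read.csv(file.path("results", "panel.csv"))
criteria <- assay_criteria()

calls <- lapply(seq_len(nrow(panel)), function(i) {
  id <- panel$chemical_id[i]
  files <- list.files(trace_dir, pattern = paste0("^", id, "_rep"),
                      full.names = TRUE)
  traces <- lapply(files, read_trace_csv)
  out <- assay_chemical(traces, criteria)
  dose <- NULL
  if (out$call$inhibitory && panel$deposition_flux[i] > 0) {
    dose <- estimate_inhibitory_dose(panel$deposition_flux[i],
                                     out$replicates[[1]]$call,
                                     mean_drop_area = 18 * (1 - 0.25 / 2))
  }
  list(chemical_id = id,
       deposition_flux_ng_cm2_min = panel$deposition_flux[i],
       inhibitory = out$call$inhibitory,
       agreement = out$call$agreement,
       n_qc_passed = out$n_qc_passed,
       dose = dose)
})

write_result_json(calls, file.path("results", "chemical_calls.json"),
                  seed = 101, config = unclass(criteria))

summary_df <- data.frame(
  chemical_id = vapply(calls, `[[`, character(1), "chemical_id"),
  flux = vapply(calls, `[[`, numeric(1), "deposition_flux_ng_cm2_min"),
  inhibitory = vapply(calls, `[[`, logical(1), "inhibitory"),
  n_qc_passed = vapply(calls, `[[`, numeric(1), "n_qc_passed"))
print(summary_df)
cat("wrote results/chemical_calls.json\n")
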