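#!/usr/bin/env Rscript
# Simulate surface-tension traces for a small chemical panel: inhibitory
# chemicals (aerosol deposition pushes the film past its functional floor
# mid-run) and non-depositing controls, 4 replicates each, written as CSV
# under results/traces/.

suppressPackageStartupMessages(library(cdsurf))

out_dir <- file.path("results", "traces")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

protocol <- cycling_protocol(cycle_rate = 20, frame_rate = 10,
                             baseline_area = 18, relative_amplitude = 0.25,
                             duration = 120)

set.seed(101)
panel <- data.frame(
  chemical_id = sprintf("chem_%02d", 1:10),
  deposition_flux = c(round(runif(5, 40, 58), 1), rep(0, 5)))

for (i in seq_len(nrow(panel))) {
  for (rep_id in 1:4) {
    film <- film_params(deposition_flux = panel$deposition_flux[i],
                        d50 = 100, noise_sd = 0.3,
                        seed = 1000 * i + rep_id)
    tr <- simulate_trace(protocol, film,
                         chemical_id = panel$chemical_id[i],
                         replicate_id = rep_id)
    write_trace_csv(tr, file.path(out_dir, sprintf("%s_rep%d.csv",
                                                   panel$chemical_id[i],
                                                   rep_id)))
  }
}
write.csv(panel, file.path("results", "panel.csv"), row.names = FALSE)
cat("wrote", nrow(panel) * 4, "traces to", out_dir, "\n")
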