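#!/usr/bin/env Rscript
# Two-scenario predictivity evaluation on the margin-exact 26-chemical
# benchmark dataset: in vitro inhibition calls vs (a) GHS acute inhalation
# classification and (b) respiratory clinical signs within the scoring
# window. Writes results/concordance.md and results/concordance.json.

suppressPackageStartupMessages(library(cdsurf))
dir.create("results", showWarnings = FALSE)

records <- make_table1_fixture(seed = 1)
write_records_csv(records, file.path("results", "benchmark_records.csv"))

report <- predictivity_report(records, conf_level = 0.95)

md <- c("# Two-scenario predictivity",
        "",
        "In vitro inhibition call vs GHS classification (cat 3/4 = positive)",
        "and vs respiratory clinical signs within the scoring window.",
        "",
        format_report_table(report))
writeLines(md, file.path("results", "concordance.md"))

to_list <- function(scn) list(
  confusion = unclass(report[[scn]]$confusion),
  metrics = as.data.frame(report[[scn]]$metrics))
write_result_json(list(ghs = to_list("ghs"), clinical = to_list("clinical")),
                  file.path("results", "concordance.json"), seed = 1)

cat(paste(md, collapse = "\n"), "\n")
cat("wrote results/concordance.{md,json} and results/benchmark_records.csv\n")
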