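#!/usr/bin/env Rscript
# Stage 5 — hygiene benchmarks. Rolls the published hospital touch-surface
# survey up from its per-location rows (sample counts, indicator-positive
# rates) and classifies a per-sample table against the ATP (>= 1 RLU/cm2
# dirty) and TPC (>= 2.5 CFU/cm2 benchmark, >= 40 heavy growth) guidelines.

suppressPackageStartupMessages(library(surfstain))

out <- "results/hygiene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

survey <- read_location_summary()
totals <- withCallingHandlers(
  survey_totals(survey),
  warning = function(w) {
    cat("NOTE:", conditionMessage(w), "\n")
    invokeRestart("muffleWarning")
  })
cat(sprintf("survey totals: N(ATP) %d, N(TPC) %d, overall %d samples\n",
            totals$n_atp_total, totals$n_tpc_total, totals$n_samples_total))
cat(sprintf("overall positives: S. aureus %.1f%%, Enterococci %.1f%%, Gram-negatives %.1f%%\n",
            totals$s_aureus_overall_pct, totals$enterococci_overall_pct,
            totals$gram_negatives_overall_pct))

visual <- read.table(system.file("extdata", "hospital_survey_visual.tsv",
                                 package = "surfstain"),
                     sep = "\t", header = TRUE)
cat(sprintf("visual inspection: %d surfaces, %d visibly dirty, %d visually clean\n",
            visual$n_inspected, visual$n_visibly_dirty,
            visual$n_inspected - visual$n_visibly_dirty))

jsonlite::write_json(totals, file.path(out, "survey_totals.json"),
                     auto_unbox = TRUE, digits = 10, pretty = TRUE)

samples <- read_hygiene_samples(
  system.file("extdata", "example_hygiene_samples_synthetic.csv",
              package = "surfstain"))
verdicts <- hygiene_verdicts(samples)
write.csv(verdicts, file.path(out, "sample_verdicts.csv"), row.names = FALSE)
summary_tab <- summarize_hygiene(samples)
write.csv(summary_tab, file.path(out, "sample_summary.csv"),
          row.names = FALSE)

cat(sprintf("synthetic sample table: %d samples, %d ATP-dirty, %d exceed the TPC benchmark (%d heavy growth)\n",
            nrow(verdicts), sum(verdicts$atp_status == "dirty"),
            sum(verdicts$tpc_status %in% c("exceeds_benchmark", "heavy_growth")),
            sum(verdicts$tpc_status == "heavy_growth")))
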