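#!/usr/bin/env Rscript
# Generate the five synthetic study cohorts (named presets) and write
# them out in the interchange formats the pipeline consumes (GCT 1.2,
# CLS, clinical TSV, GMT), so every later step can be re-run from files.

suppressMessages(library(mpdicho))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

for (name in c("crc_like", "gc_like", "null_model", "smp_like", "pr_like")) {
  coh <- generate_cohort(preset(name))
  base <- file.path(out_dir, name)
  write_expression_table(coh$matrix, paste0(base, ".gct"), "gct")
  write_cls(coh$clinical$stage_group, paste0(base, ".cls"))
  write_clinical_table(coh$clinical, paste0(base, "_clinical.tsv"))
  write_gmt(list(coh$prolif_set, coh$migr_set), paste0(base, "_programs.gmt"))
  cat(sprintf("%-11s %4d samples x %3d genes  (rho = %+0.2f, delta = %0.1f)\n",
              name, ncol(coh$matrix), nrow(coh$matrix),
              coh$config$rho, coh$config$delta))
}
cat("cohort files written under", out_dir, "\n")
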