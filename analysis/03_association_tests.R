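#!/usr/bin/env Rscript
# Chi-square association of complexity grade with surgical outcome on the
# reconstructed 88-patient validation cohort: extent of resection and
# major complications (Clavien-Dindo above 3a).

suppressPackageStartupMessages(library(gbmgrade))
dir.create("results", showWarnings = FALSE)

co <- reference_outcome_cohort()

res <- pearson_chi2(crosstab(co, "complexity", "complete_resection"))
cat("Grade vs complete resection: ")
print(res)
write_stats_json(res, "results/chi2_resection.json")

cmp <- pearson_chi2(crosstab(co, "complexity", "major_complication"))
cat("Grade vs major complications: ")
print(cmp)
if (cmp$warning_low_expected)
  cat("  note: expected counts below 5; the asymptotic p is a rough guide\n")
write_stats_json(cmp, "results/chi2_complications.json")
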