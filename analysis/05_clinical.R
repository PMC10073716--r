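#!/usr/bin/env Rscript
# Stage 5 — clinical statistics: group comparison of sperm parameters,
# correlation of the observable hCit burden (per-pool spectral counts
# propagated to pool members) with morphology, motility and age, and the
# lifestyle/age confound screen.

library(upmprofiler)

psms <- filter_psms(read_psm_table("results/data/psm.tsv"))
clinical <- read_clinical("results/data/clinical.csv")
pools <- read.delim("results/data/pools.tsv", comment.char = "#")

vars <- c("vitality", "morphology", "progressive_motility", "count")
gc <- do.call(rbind, lapply(vars, function(v) group_compare(clinical, v)))
write.table(gc, "results/tables/group_compare.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("group comparison (NZ vs nonNZ):\n")
print(gc[, c("variable", "mean_NZ", "mean_nonNZ", "t", "p")])

hc <- cumulative_signal(psms, "hCit", by = "pool")
pool_burden <- setNames(hc$spectral_count, hc$unit)
burden <- unname(pool_burden[pools$pool[match(clinical$subject_id,
                                              pools$subject_id)]])
correlations <- do.call(rbind, lapply(
  c("morphology", "progressive_motility", "age"), function(v) {
    cr <- correlate(burden, clinical[[v]])
    cr$pair <- paste0("hCit_burden~", v)
    cr
  }))
write.table(correlations, "results/tables/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nhCit burden correlations (pool-level burden, subject-level n):\n")
print(correlations[, c("pair", "r", "p", "n")])

confounds <- confound_screen(clinical, burden)
write.table(confounds, "results/tables/confounds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nconfound screen:\n")
print(confounds[, c("variable", "screen", "effect", "p", "significant")])
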