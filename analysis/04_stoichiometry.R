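#!/usr/bin/env Rscript
# Stage 4 — per-site modification stoichiometry (percent modified of the
# protein pool) and its NZ-vs-nonNZ chi-squared comparison. Two
# contingency variants are written: intensity pseudo-counts (the
# table-style default, p-values scale-dependent) and raw spectral counts
# (the calibrated variant).

library(upmprofiler)

psms <- filter_psms(read_psm_table("results/data/psm.tsv"))
sites <- read.delim("results/tables/sites.tsv")
upm_sites <- sites[sites$mod_class %in% c("Cit", "hCit"), ]

for (variant in c("intensity", "count")) {
  st <- stoichiometry_table(psms, upm_sites, input = variant)
  out <- sprintf("results/tables/stoich_%s.tsv", variant)
  write.table(st, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] %d sites -> %s\n", variant, nrow(st), out))
}

st <- read.delim("results/tables/stoich_intensity.tsv")
cit <- merge(st, upm_sites[upm_sites$mod_class == "Cit",
                           c("protein", "position")])
cat(sprintf("Cit sites decreased in the patient group: %d of %d\n",
            sum(cit$direction == "decreased"), nrow(cit)))
print(cit[, c("protein", "position", "pct_control", "pct_patient",
              "direction")])
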