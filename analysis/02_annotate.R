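#!/usr/bin/env Rscript
# Stage 2 — identification filtering and modification-site annotation:
# keep PSMs below the q-value cutoff (q < 0.01), classify every mass
# shift (Cit +0.98402 on R, hCit +43.00581 on K, with deamidation and
# N-terminal carbamylation as isobaric confounds), and aggregate per
# protein site.

library(upmprofiler)

psms <- read_psm_table("results/data/psm.tsv")
fasta <- read_fasta("results/data/proteins.fasta")
kept <- filter_psms(psms, q_max = 0.01)
cat(sprintf("q-value filter: %d of %d PSMs kept\n", nrow(kept), nrow(psms)))

sites <- annotate_sites(kept, fasta)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(sites[, c("protein", "position", "residue", "mod_class",
                      "n_psms", "flagged")],
            "results/tables/sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("site classes found:\n")
print(table(sites$mod_class))
cat(sprintf("%d Cit and %d hCit sites -> results/tables/sites.tsv\n",
            sum(sites$mod_class == "Cit"), sum(sites$mod_class == "hCit")))
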