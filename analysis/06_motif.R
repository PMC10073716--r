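#!/usr/bin/env Rscript
# Stage 6 — sequence and domain context of Cit sites: +/-10-residue
# windows anchored on the modified arginine, BLOSUM62 column scores with
# consensus/conservation, domain colocalization, and a functional
# category summary of the Cit proteins.

library(upmprofiler)

fasta <- read_fasta("results/data/proteins.fasta")
domains <- read_domains("results/data/domains.tsv")
sites <- read.delim("results/tables/sites.tsv")
cit <- sites[sites$mod_class == "Cit", ]

windows <- lapply(seq_len(nrow(cit)), function(i)
  extract_window(fasta[[cit$protein[i]]], cit$position[i],
                 accession = cit$protein[i]))
aln <- align_windows(windows)
cons <- window_consensus(aln)
write.table(cons, "results/tables/consensus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
center <- cons[cons$rel_position == 0, ]
cat(sprintf("center column: %s, agreement %.0f%%, conservation score %d\n",
            center$modal_residue, center$agreement,
            center$conservation_score))
cat(sprintf("columns above 40%% agreement (excluding center): %d of %d\n",
            sum(cons$shade != "none") - 1L, nrow(cons) - 1L))

overlap <- do.call(rbind, lapply(seq_len(nrow(cit)), function(i) {
  d <- domain_overlap(cit$protein[i], cit$position[i], domains)
  if (nrow(d) == 0L) return(NULL)
  cbind(data.frame(protein = cit$protein[i], position = cit$position[i]),
        d[, c("domain_name", "start", "end", "inside")])
}))
write.table(overlap, "results/tables/domain_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCit sites falling inside annotated domains:\n")
print(overlap[overlap$inside, ])

categories <- c(
  SEMG2_HUMAN = "semen viscosity", TGM4_HUMAN = "semen viscosity",
  DPP4_HUMAN = "sperm motility", HSP7C_HUMAN = "protein folding",
  ANXA2_HUMAN = "sperm exocytosis", RAB27A_HUMAN = "sperm exocytosis",
  CBPE_HUMAN = "peptide processing", TMPS2_HUMAN = "proteolysis")
cs <- category_summary(categories[unique(cit$protein)])
write.table(cs, "results/tables/categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nfunctional categories of Cit proteins:\n")
print(cs)
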