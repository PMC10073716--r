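#!/usr/bin/env Rscript
# Stage 3 — cumulative ureido burden by spectral counting, reporter-based
# relative protein quantification with group t-tests, and EV-marker
# summaries.

library(upmprofiler)

psms <- filter_psms(read_psm_table("results/data/psm.tsv"))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

cumulative <- do.call(rbind, lapply(c("Cit", "hCit"), function(cl) {
  cs <- cumulative_signal(psms, cl)
  cs$difference_count <- attr(cs, "difference")[["spectral_count"]]
  cs
}))
write.table(cumulative, "results/tables/cumulative.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hc <- cumulative[cumulative$mod_class == "hCit", ]
cat(sprintf("cumulative hCit spectral counts: NZ = %d, nonNZ = %d (diff %d)\n",
            hc$spectral_count[hc$unit == "NZ"],
            hc$spectral_count[hc$unit == "nonNZ"], hc$difference_count[1]))

pq <- quantify_proteins(psms)
write.table(pq, "results/tables/protein_quant.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d proteins quantified; %d significant at p <= 0.05\n",
            nrow(pq), sum(pq$significant)))

ms <- marker_summary(pq,
                     read_marker_list("results/data/markers.txt"),
                     read_marker_list("results/data/exosome_markers.txt"),
                     read_marker_list("results/data/microvesicle_markers.txt"))
write.table(ms$markers, "results/tables/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("markers detected: %d; not detected: %s\n", nrow(ms$markers),
            paste(ms$not_detected, collapse = ", ")))
if (!is.null(ms$class_comparison)) {
  cat(sprintf("exosome vs microvesicle marker mean relative intensity: %.4f vs %.4f (p = %.3f)\n",
              ms$class_comparison$mean_exosome,
              ms$class_comparison$mean_microvesicle, ms$class_comparison$p))
}
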