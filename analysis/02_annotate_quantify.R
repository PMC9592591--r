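#!/usr/bin/env Rscript
# Annotate the peak lists against the composition library, quantify every
# analyte against the spiked internal standard, apply the >= 3-detection
# filter, and assemble the samples x glycoforms profile matrix with its
# per-class totals and glycoform counts.

library(glycoatlas)

peaks <- read_peaklists("results/peaklists.tsv")
lib <- readLines("results/library.txt")
model <- derivatization_model(tag_delta = 389.2)

annotated <- do.call(rbind, lapply(split(peaks, peaks$sample_id), function(p) {
  annotate_peaklist(p, model, library = lib, tol = 0.01)
}))
cat(sprintf("annotated %d peaks: %d library, %d de novo, %d unassigned\n",
            nrow(annotated), sum(annotated$source == "library"),
            sum(annotated$source == "de_novo"),
            sum(annotated$source == "none")))

quant <- quantify(annotated, is_amount = 10)
filt <- detection_filter(quant, min_detections = 3)
cat(sprintf("detection filter (>= 3 within any class): %d of %d glycoforms retained\n",
            length(filt$retained), nrow(filt$tallies)))

profile <- build_matrix(quant, filt$retained)
write_quant_table(quant, "results/quant_table.tsv")
write_profile_csv(profile, "results/profile_matrix.csv")

summ <- profile_summary(profile)
write.csv(summ$per_class, "results/class_summaries.csv", row.names = FALSE)
cat("per-class median totals (pmol/100 ug) and glycoform counts:\n")
print(summ$per_class, row.names = FALSE, digits = 4)
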