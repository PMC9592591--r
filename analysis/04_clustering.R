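#!/usr/bin/env Rscript
# Profile dissimilarity and clustering: column z-scores for the deviation
# heatmap, pairwise Canberra distances on the raw absolute abundances,
# Ward linkage, an 18-group cut, and the group-purity report under both
# Ward variants.

library(glycoatlas)

profile <- read_profile_csv("results/profile_matrix.csv")

z <- zscore_profile(profile)
write_profile_csv(z, "results/profile_zscores.csv")

for (variant in c("ward.D2", "ward.D")) {
  cl <- ward_cluster(profile, variant = variant)
  cut <- cut_and_purity(cl, k = 18)
  cat(sprintf("%s: %d of 18 groups are single-class\n", variant, cut$n_pure))
  if (variant == "ward.D2") {
    dendrogram_newick(cl, "results/dendrogram.nwk")
    write.csv(cut$groups, "results/groups_k18.csv", row.names = FALSE)
    write.csv(cut$group_summary, "results/group_summary_k18.csv",
              row.names = FALSE)
    print(cut$group_summary, row.names = FALSE)
  }
}

# heatmap exports (absolute and z-scored, grey = not detected)
if (requireNamespace("pheatmap", quietly = TRUE)) {
  png("results/heatmap_zscore.png", width = 1400, height = 900)
  disp <- z$abundance
  disp[!z$mask] <- NA
  pheatmap::pheatmap(t(disp), cluster_cols = FALSE, cluster_rows = FALSE,
                     na_col = "grey70", fontsize = 5,
                     main = "Column z-scores (grey = not detected)")
  dev.off()
  cat("wrote results/heatmap_zscore.png\n")
}
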