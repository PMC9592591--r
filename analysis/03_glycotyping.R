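#!/usr/bin/env Rscript
# Glycotyping: classify every retained glycoform by glycan type, most
# matured terminal sugar, antenna count, sialic-acid count and fucose
# count, and summarize each sample's total glycan amount as percentages
# over the five panels.

library(glycoatlas)

profile <- read_profile_csv("results/profile_matrix.csv")

assignments <- glycotype_assignments(parse_composition(colnames(profile$abundance)))
write.csv(assignments, "results/glycotype_assignments.csv", row.names = FALSE)
cat("glycoform library by type:\n")
print(table(assignments$glycan_type))
cat("by terminal sugar:\n")
print(table(assignments$terminal))

summ <- glycotype_summary(profile)
write.csv(summ$per_sample, "results/glycotype_per_sample.csv", row.names = FALSE)
write.csv(summ$per_class, "results/glycotype_per_class.csv", row.names = FALSE)

type_pc <- subset(summ$per_class, panel == "glycan_type")
wide <- reshape(type_pc[, c("class_label", "category", "percent")],
                idvar = "class_label", timevar = "category",
                direction = "wide")
names(wide) <- sub("^percent\\.", "", names(wide))
cat("\nper-class glycan-type percentages (replicate averages):\n")
print(wide, row.names = FALSE, digits = 3)
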