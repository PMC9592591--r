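#!/usr/bin/env Rscript
# Discrimination analyses: repeated stratified one-replicate-per-class
# holdout with the four classifier families over the organ/tissue
# profile matrix, then strain discrimination on one organ's perturbed
# variants with features restricted to the reference strain's detected
# glycoforms. 200 repetitions here keep the driver interactive; the
# full-scale 1000-repetition run lives in scripts/acceptance.R.

library(glycoatlas)

profile <- read_profile_csv("results/profile_matrix.csv")

organ_eval <- evaluate_classifiers(profile, n_reps = 200, seed = 20260105L)
print(organ_eval)
write.csv(organ_eval$per_class, "results/organ_f1_per_class.csv",
          row.names = FALSE)
write.csv(organ_eval$overall, "results/organ_f1_overall.csv",
          row.names = FALSE)

# strain variants of the first class's mean profile
atlas <- generate_atlas(synthetic_atlas_spec(seed = 20260101L))
strains <- generate_strain_variants(atlas$truth$class_mean_log[1, ],
                                    effect_size = 4, n_affected = 10,
                                    n_strains = 3, replicates = 5,
                                    seed = 20260110L)
ref_rows <- strains$profile$samples$class_label == "strain1"
ref_forms <- colnames(strains$profile$abundance)[
  colSums(strains$profile$mask[ref_rows, , drop = FALSE]) > 0]
strain_eval <- evaluate_classifiers(strains$profile, n_reps = 200,
                                    seed = 20260111L,
                                    feature_set = ref_forms)
print(strain_eval)
write.csv(strain_eval$overall, "results/strain_f1_overall.csv",
          row.names = FALSE)
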