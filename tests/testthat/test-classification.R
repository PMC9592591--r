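test_that("stratified split holds out exactly one replicate per class", {
  atlas <- small_atlas(n_classes = 6, replicates = 5, library_size = 10)
  samples <- atlas$profile$samples
  sp <- stratified_split(samples, seed = 99)
  expect_length(sp$test, 6)
  expect_length(sp$train, 24)
  expect_setequal(c(sp$test, sp$train), samples$sample_id)
  test_classes <- samples$class_label[match(sp$test, samples$sample_id)]
  expect_setequal(test_classes, unique(samples$class_label))
  # reproducible given the seed, different across seeds
  expect_identical(stratified_split(samples, seed = 99), sp)
  expect_false(identical(stratified_split(samples, seed = 100)$test, sp$test))
  # single-replicate classes are an error
  bad <- data.frame(sample_id = c("a", "b", "c"),
                    class_label = c("x", "x", "y"))
  expect_error(stratified_split(bad, 1), "2 replicates")
})

test_that("each replicate is held out with frequency ~ 1/5 across seeds", {
  samples <- data.frame(
    sample_id = sprintf("c%d_r%d", rep(1:3, each = 5), rep(1:5, 3)),
    class_label = sprintf("c%d", rep(1:3, each = 5)),
    replicate = rep(1:5, 3), stringsAsFactors = FALSE
  )
  picks <- table(unlist(lapply(1:10000, function(s) {
    stratified_split(samples, seed = s)$test
  })))
  freq <- picks[samples$sample_id] / 10000
  expect_true(all(abs(freq - 1 / 5) < 0.02))
})

test_that("per-class F1 matches hand-computed confusion arithmetic", {
  expect_equal(unname(f1_per_class(c("A", "B", "C"), c("A", "B", "C"))),
               c(1, 1, 1))
  # A: TP=1 FP=1 FN=0 -> P=1/2, R=1, F1=2/3; B never predicted -> 0; C perfect
  f1 <- f1_per_class(c("A", "B", "C"), c("A", "A", "C"))
  expect_equal(unname(f1), c(2 / 3, 0, 1))
  # class absent from correct predictions and truth hits: convention 0
  f1 <- f1_per_class(c("A", "A"), c("B", "B"))
  expect_equal(unname(f1), c(0, 0))
  expect_true(all(f1_per_class(sample(letters[1:4], 40, TRUE),
                               sample(letters[1:4], 40, TRUE)) >= 0))
})

test_that("evaluation report aggregates per-class F1 with SE over repetitions", {
  atlas <- small_atlas(n_classes = 4, replicates = 4, library_size = 20,
                       fold_change = 1000)
  rep_ <- evaluate_classifiers(atlas$profile,
                               algorithms = c("decision_tree", "random_forest"),
                               n_reps = 5, seed = 3, tune = "none")
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(nrow(rep_$per_class), 8)
  expect_true(all(rep_$per_class$mean_f1 >= 0 & rep_$per_class$mean_f1 <= 1))
  # across-class average equals the unweighted mean of per-class means
  for (alg in unique(rep_$overall$algorithm)) {
    expect_equal(rep_$overall$mean_f1[rep_$overall$algorithm == alg],
                 mean(rep_$per_class$mean_f1[rep_$per_class$algorithm == alg]))
  }
  # identical seed and config reproduce the report exactly
  rep2 <- evaluate_classifiers(atlas$profile,
                               algorithms = c("decision_tree", "random_forest"),
                               n_reps = 5, seed = 3, tune = "none")
  expect_identical(rep_$per_class, rep2$per_class)
  # n_reps = 1: SE not available
  rep1 <- evaluate_classifiers(atlas$profile, algorithms = "decision_tree",
                               n_reps = 1, seed = 3, tune = "none")
  expect_true(all(is.na(rep1$per_class$se_f1)))
  expect_true(all(is.na(rep1$overall$se_f1)))
})

test_that("near-infinite class separation drives F1 to 1", {
  atlas <- small_atlas(n_classes = 5, replicates = 5, library_size = 40,
                       fold_change = 1e4, marker_count = 10, seed = 8)
  rep_ <- evaluate_classifiers(atlas$profile, n_reps = 10, seed = 2,
                               tune = "none")
  # flexible learners attain the separability limit
  flexible <- rep_$overall$algorithm %in%
    c("random_forest", "neural_network", "svm")
  expect_true(all(rep_$overall$mean_f1[flexible] > 0.99))
  # the greedy univariate tree approaches but need not reach it: noisy
  # split thresholds between two classes sharing an elevated marker
  # misroute occasional test samples (it is the weakest family on real
  # atlas data too)
  expect_gt(rep_$overall$mean_f1[rep_$overall$algorithm == "decision_tree"], 0.8)
})

test_that("feature restriction to a reference library subsets the matrix", {
  atlas <- small_atlas(n_classes = 3, replicates = 3, library_size = 20,
                       fold_change = 100)
  keep <- colnames(atlas$profile$abundance)[1:8]
  rep_ <- evaluate_classifiers(atlas$profile, algorithms = "decision_tree",
                               n_reps = 2, seed = 1, tune = "none",
                               feature_set = keep)
  expect_s3_class(rep_, "evaluation_report")
  expect_error(evaluate_classifiers(atlas$profile, algorithms = "decision_tree",
                                    n_reps = 2, seed = 1,
                                    feature_set = "H99N99"),
               "feature_set")
})

test_that("inner grid search picks a grid point deterministically", {
  atlas <- small_atlas(n_classes = 4, replicates = 5, library_size = 15,
                       fold_change = 50)
  rep_ <- evaluate_classifiers(atlas$profile, algorithms = "decision_tree",
                               n_reps = 2, seed = 5, tune = "once")
  expect_true(rep_$tuning$chosen$decision_tree$cp %in%
                default_grids()$decision_tree$cp)
  rep2 <- evaluate_classifiers(atlas$profile, algorithms = "decision_tree",
                               n_reps = 2, seed = 5, tune = "once")
  expect_identical(rep_$tuning$chosen, rep2$tuning$chosen)
})
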