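test_that("internal-standard quantitation is a simple calibrated ratio", {
  p <- tiny_annotated_peaks(areas = 500, compositions = "H3N2", is_area = 1000)
  q <- quantify(p, is_amount = 10)
  expect_equal(q$amount, 5.0)
  # area equal to the standard's gives exactly the spiked amount
  p <- tiny_annotated_peaks(areas = 1000, compositions = "H5N2", is_area = 1000)
  expect_equal(quantify(p, is_amount = 10)$amount, 10)
  # amounts preserve area ratios regardless of is_amount, and rescaling
  # every area (standard included) changes nothing
  set.seed(2)
  areas <- runif(3, 10, 1000)
  p <- tiny_annotated_peaks(areas, c("H3N2", "H5N2", "H9N2"), is_area = 777)
  for (isa in c(1, 10, 100)) {
    q <- quantify(p, is_amount = isa)
    expect_equal(q$amount / q$amount[1],
                 areas[match(q$composition, c("H3N2", "H5N2", "H9N2"))] / areas[1],
                 tolerance = 1e-12)
  }
  p2 <- p; p2$area <- p2$area * 7.3
  expect_equal(quantify(p2, is_amount = 10)$amount, quantify(p, is_amount = 10)$amount)
})

test_that("missing or zero-area internal standard fails the whole sample", {
  p <- tiny_annotated_peaks(500, "H3N2")
  expect_error(quantify(p[p$source != "internal_standard", ]), "internal standard")
  p$area[p$source == "internal_standard"] <- 0
  expect_error(quantify(p), "internal standard")
  expect_error(quantify(tiny_annotated_peaks(500, "H3N2"), is_amount = 0), "positive")
})

test_that("detection filter implements both counting scopes", {
  # three replicates of one organ detect it: retained at min 3
  rec <- quant_records(
    sample_id = c("a1", "a2", "a3"), class_label = "organA",
    replicate = 1:3, composition = "H3N2", amount = c(1, 2, 3)
  )
  expect_identical(detection_filter(rec, 3)$retained, "H3N2")
  # 2 detections in each of two organs: dropped per-group, kept globally
  rec2 <- quant_records(
    sample_id = c("a1", "a2", "b1", "b2"),
    class_label = c("organA", "organA", "organB", "organB"),
    replicate = c(1, 2, 1, 2), composition = "H5N2", amount = 1
  )
  expect_length(detection_filter(rec2, 3, scope = "within-any-group")$retained, 0)
  expect_identical(detection_filter(rec2, 3, scope = "global")$retained, "H5N2")
  # zero amounts are non-detections
  rec3 <- rec; rec3$amount <- 0
  expect_length(detection_filter(rec3, 1)$retained, 0)
})

test_that("detection filter equals a brute-force recount and is monotone", {
  atlas <- small_atlas(n_classes = 5, replicates = 4, library_size = 30,
                       detection_limit = 1)
  prof <- atlas$profile
  rec <- do.call(rbind, lapply(seq_len(nrow(prof$abundance)), function(i) {
    det <- prof$mask[i, ]
    quant_records(prof$samples$sample_id[i], prof$samples$class_label[i],
                  prof$samples$replicate[i], colnames(prof$abundance)[det],
                  prof$abundance[i, det])
  }))
  for (mind in c(1, 2, 3, 4)) {
    got <- detection_filter(rec, mind)$retained
    # brute force: per composition, per class, count detected replicates
    want <- character(0)
    for (comp in colnames(prof$abundance)) {
      per_class <- tapply(prof$mask[, comp], prof$samples$class_label, sum)
      if (max(per_class) >= mind) want <- c(want, comp)
    }
    expect_setequal(got, want)
  }
  sizes <- vapply(1:4, function(m) length(detection_filter(rec, m)$retained),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("profile matrix assembly conserves signal and flags duplicates", {
  rec <- quant_records(
    sample_id = rep(c("a1", "a2", "b1"), each = 2),
    class_label = rep(c("organA", "organA", "organB"), each = 2),
    replicate = rep(c(1, 2, 1), each = 2),
    composition = rep(c("H3N2", "H5N2"), 3),
    amount = c(1, 2, 3, 4, 5, 0)
  )
  prof <- build_matrix(rec)
  expect_equal(dim(prof$abundance), c(3, 2))
  # column sums equal per-composition record sums
  expect_equal(unname(colSums(prof$abundance)),
               as.numeric(tapply(rec$amount, rec$composition, sum)))
  # zero-amount record is present but masked as not detected
  expect_false(prof$mask["b1", "H5N2"])
  # absent pair is zero + unmasked
  prof2 <- build_matrix(rec[-6, ])
  expect_equal(prof2$abundance["b1", "H5N2"], 0)
  expect_false(prof2$mask["b1", "H5N2"])
  # restriction to a retained set drops other columns
  expect_identical(colnames(build_matrix(rec, "H3N2")$abundance), "H3N2")
  # 1x1 matrix
  expect_equal(dim(build_matrix(rec[1, ])$abundance), c(1, 1))
  # duplicates are an error listing the pair
  expect_error(build_matrix(rbind(rec, rec[1, ])), "duplicate")
})

test_that("per-class summaries are medians across replicates", {
  rec <- quant_records(
    sample_id = sprintf("m%d", 1:5), class_label = "muscle",
    replicate = 1:5, composition = "H3N2",
    amount = c(80, 82.8, 85, 90, 79)
  )
  summ <- profile_summary(build_matrix(rec))
  expect_equal(summ$per_class$median_total, 82.8)
  expect_equal(summ$per_class$median_n_glycoforms, 1)
  # single replicate: median is that replicate
  summ1 <- profile_summary(build_matrix(rec[1, ]))
  expect_equal(summ1$per_class$median_total, 80)
  # synthetic atlas: summaries equal a direct recount
  atlas <- small_atlas()
  summ <- profile_summary(atlas$profile)
  for (cl in unique(atlas$profile$samples$class_label)) {
    rows <- atlas$profile$samples$class_label == cl
    expect_equal(
      summ$per_class$median_total[summ$per_class$class_label == cl],
      median(rowSums(atlas$profile$abundance[rows, , drop = FALSE])))
    expect_equal(
      summ$per_class$median_n_glycoforms[summ$per_class$class_label == cl],
      median(rowSums(atlas$profile$mask[rows, , drop = FALSE])))
  }
})

test_that("quant tables and profile matrices round-trip through text files", {
  atlas <- small_atlas(n_classes = 3, replicates = 2, library_size = 15)
  prof <- atlas$profile
  rec <- do.call(rbind, lapply(seq_len(nrow(prof$abundance)), function(i) {
    det <- prof$mask[i, ]
    quant_records(prof$samples$sample_id[i], prof$samples$class_label[i],
                  prof$samples$replicate[i], colnames(prof$abundance)[det],
                  prof$abundance[i, det])
  }))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(rec, tf)
  back <- read_quant_table(tf)
  expect_equal(back$amount, rec$amount, tolerance = 1e-12)
  expect_identical(back$composition, rec$composition)

  cf <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, cf)
  prof2 <- read_profile_csv(cf)
  expect_equal(prof2$abundance, prof$abundance, tolerance = 1e-12)
  expect_identical(prof2$mask, prof$mask)
  expect_equal(prof2$samples$class_label, prof$samples$class_label)
})
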