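test_that("composition solver equals the exhaustive grid oracle", {
  model <- derivatization_model()
  targets <- c("H3N2", "H5N4D1A2", "H9N2", "H4N5D2")
  for (tg in targets) {
    mz <- derivatized_mz(tg, model)
    got <- solve_compositions(mz, model, tol = 0.5)
    want <- oracle_solve(mz, model, tol_da = 0.5, bounds = composition_bounds())
    expect_equal(nrow(got), length(want))
    got_str <- sort(got$composition)
    want_str <- sort(vapply(want, function(w) {
      format_composition(glycan_composition(w["h"], w["n"], w["d"], w["a"], w["g"]))
    }, character(1)))
    expect_identical(got_str, want_str)
  }
  # random m/z values too, including ones with no solution
  set.seed(5)
  for (mz in runif(5, 800, 3200)) {
    got <- solve_compositions(mz, model, tol = 0.25)
    want <- oracle_solve(mz, model, tol_da = 0.25, bounds = composition_bounds())
    expect_equal(nrow(got), length(want))
  }
})

test_that("solver ranking, uniqueness and edge cases behave as specified", {
  model <- derivatization_model()
  # unique hit at generous Da tolerance
  res <- solve_compositions(derivatized_mz("H3N2", model), model, tol = 0.5)
  expect_identical(res$composition, "H3N2")
  # asialo compositions are unique at 10 ppm under default bounds
  res <- solve_compositions(derivatized_mz("H9N2", model), model,
                            tol = 10, tol_unit = "ppm")
  expect_identical(res$composition, "H9N2")
  # sialylated compositions hit the exact Hex+Neu5Ac = dHex+Neu5Gc
  # degeneracy (162.05282 + 291.09542 = 146.05791 + 307.09033), so even
  # at 10 ppm the generator is one of three exact isobars; the
  # deterministic tie-break (|error|, residue total, canonical string)
  # fixes their order
  res <- solve_compositions(derivatized_mz("H5N4D1A2", model), model,
                            tol = 10, tol_unit = "ppm")
  expect_setequal(res$composition, c("H5N4D1A2", "H3N4D3G2", "H4N4D2A1G1"))
  expect_identical(res$composition[1], "H3N4D3G2")
  # below any valid mass
  expect_equal(nrow(solve_compositions(0.0, model)), 0)
  # candidates sorted by |error|
  wide <- solve_compositions(derivatized_mz("H5N4A1", model), model, tol = 5)
  expect_true(!is.unsorted(abs(wide$error_da)))
  expect_error(solve_compositions(1000, model, tol = -1), "positive")
})

test_that("enlarging the tolerance never removes a candidate", {
  model <- derivatization_model()
  set.seed(9)
  for (mz in runif(6, 900, 3000)) {
    prev <- character(0)
    for (tol in c(0.05, 0.2, 1, 3)) {
      cur <- solve_compositions(mz, model, tol = tol)$composition
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("peak lists annotate against a library with de novo fallback", {
  model <- derivatization_model()
  lib <- c("H5N2", "H5N4A2", "H3N2")
  peaks <- data.frame(
    mz = c(derivatized_mz("H5N2", model),          # library hit
           derivatized_mz("H9N2", model),          # de novo hit
           derivatized_mz("H5N2", model) + 5),     # matches nothing at tol 0.2
    area = c(100, 50, 10),
    is_internal_standard = c(0, 0, 0)
  )
  ann <- annotate_peaklist(peaks, model, library = lib, tol = 0.2)
  expect_identical(ann$composition[1], "H5N2")
  expect_identical(ann$source[1], "library")
  expect_identical(ann$composition[2], "H9N2")
  expect_identical(ann$source[2], "de_novo")
  expect_true(is.na(ann$composition[3]))
  expect_identical(ann$source[3], "none")

  # the internal standard is never annotated as an analyte
  peaks$is_internal_standard <- c(1, 0, 0)
  ann <- annotate_peaklist(peaks, model, library = lib, tol = 0.2)
  expect_identical(ann$source[1], "internal_standard")
  expect_true(is.na(ann$composition[1]))

  # duplicate library entries warn and deduplicate
  expect_warning(annotate_peaklist(peaks, model, library = c("H5N2", "H5N2")),
                 "duplicate")
})

test_that("a synthetic atlas peak list round-trips its generating library", {
  atlas <- small_atlas(n_classes = 3, replicates = 2, library_size = 60)
  model <- derivatization_model(tag_delta = 389.2)
  peaks <- synthetic_peaklists(atlas$profile, model)
  lib <- colnames(atlas$profile$abundance)
  one <- peaks[peaks$sample_id == peaks$sample_id[1], ]
  ann <- annotate_peaklist(one, model, library = lib, tol = 0.01)
  analyte <- ann[ann$source != "internal_standard", ]
  expect_true(all(!is.na(analyte$composition)))
  expect_true(all(analyte$source == "library"))
  # recovered compositions are exactly the detected ones for that sample
  expect_setequal(analyte$composition,
                  lib[atlas$profile$mask[one$sample_id[1], ]])
})

test_that("tag-delta calibration inverts the derivatization algebra", {
  model <- derivatization_model()
  tagged <- derivatization_model(tag_delta = 389.2)
  mz_obs <- derivatized_mz("H5N4A2", tagged)
  expect_equal(calibrate_tag_delta("H5N4A2", mz_obs, model), 389.2,
               tolerance = 1e-9)
  expect_equal(calibrate_tag_delta("H3N2", derivatized_mz("H3N2", model), model),
               0, tolerance = 1e-9)
  # two pairs with +-0.01 Da noise agree within 0.05 Da
  expect_equal(
    calibrate_tag_delta("H5N4A2", mz_obs + 0.01, model,
                        check = list(comp = "H3N2",
                                     observed_mz = derivatized_mz("H3N2", tagged) - 0.01)),
    389.2, tolerance = 0.05
  )
  # inconsistent pairs fail with the residual reported
  expect_error(
    calibrate_tag_delta("H5N4A2", mz_obs, model,
                        check = list(comp = "H3N2",
                                     observed_mz = derivatized_mz("H3N2", tagged) + 1)),
    "inconsistent"
  )
})

test_that("sialyl linkage isomer counts match brute-force enumeration", {
  expect_identical(count_sialyl_linkage_isomers("H5N4A2"), 4L)
  expect_identical(count_sialyl_linkage_isomers("H5N4"), 1L)
  expect_identical(count_sialyl_linkage_isomers("H5N4A1"), 4L)
  # formula vs enumeration across the complex space
  for (h in 3:8) for (s in 0:4) {
    comp <- glycan_composition(h = h, n = max(4, s + 2), a = s)
    if (classify_type(comp) != "complex") next
    expect_identical(count_sialyl_linkage_isomers(comp),
                     oracle_isomers(h - 3, s))
  }
  # Neu5Gc counts like Neu5Ac in the isomer model
  expect_identical(count_sialyl_linkage_isomers("H5N4G2"), 4L)
  # undefined off the complex type
  expect_error(count_sialyl_linkage_isomers("H9N2"), "complex")
})
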