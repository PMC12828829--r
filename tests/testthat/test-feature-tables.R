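# Feature-table I/O and ppm/RT annotation.

make_meta <- function(ids, roles = NULL) {
  tibble::tibble(sample_id = ids,
                 role = roles %||% rep("study", length(ids)),
                 tissue_mg = ifelse((roles %||% rep("study", length(ids))) == "study",
                                    3, NA_real_))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature tables round-trip through the tab-separated dialect", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mz\trt\ts1\ts2",
               "758.5700\t5.4\t1000\t2000",
               "760.5850\t5.4\t\t500",
               "520.3398\t7.4\t300\t400"), tf)
  tab <- read_feature_table(tf, make_meta(c("s1", "s2")), "positive")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$area[tab$mz == 760.5850 & tab$sample_id == "s1"], NA_real_)
  expect_equal(tab$area[tab$mz == 758.5700 & tab$sample_id == "s2"], 2000)

  out <- withr::local_tempfile(fileext = ".txt")
  write_feature_table(tab, out)
  tab2 <- read_feature_table(out, make_meta(c("s1", "s2")), "positive")
  expect_equal(dplyr::arrange(tab2, mz, sample_id),
               dplyr::arrange(tab, mz, sample_id))
})

test_that("unmapped sample columns and malformed cells are rejected", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mz\trt\ts1\ts_unknown", "758.57\t5.4\t100\t200"), tf)
  expect_error(read_feature_table(tf, make_meta("s1"), "positive"),
               "s_unknown")
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mz\trt\ts1", "758.57\t5.4\tnot_a_number"), tf2)
  expect_error(read_feature_table(tf2, make_meta("s1"), "positive"),
               "malformed numeric cell.*row 1")
})

pc_window <- tibble::tibble(class_label = "PC", rt_min = 5.2, rt_max = 5.6)

test_that("ppm matching follows the tolerance and RT window contract", {
  cand <- adduct_candidates("PC 34:2", polarities = "positive")
  feats <- tibble::tibble(mz = c(758.5700, 758.5780),
                          rt = 5.4, polarity = "positive",
                          sample_id = "s1", area = c(100, 100))
  ann <- match_features(feats, cand, tol_ppm = 10, rt_windows = pc_window)
  expect_equal(nrow(ann), 1)           # 0.8 ppm matches, 11.3 ppm does not
  expect_equal(ann$species, "PC 34:2")
  expect_equal(ann$ppm_error, 0.8, tolerance = 0.1)

  # inside mass tolerance but outside the class RT window
  feats_rt <- tibble::tibble(mz = 758.5700, rt = 6.5, polarity = "positive",
                             sample_id = "s1", area = 100)
  expect_equal(nrow(match_features(feats_rt, cand, 10, pc_window)), 0)

  # polarity must agree
  feats_neg <- tibble::tibble(mz = 758.5700, rt = 5.4, polarity = "negative",
                              sample_id = "s1", area = 100)
  expect_equal(nrow(match_features(feats_neg, cand, 10, pc_window)), 0)
})

test_that("annotation is deterministic and monotone in the tolerance", {
  cand <- adduct_candidates(c("PC 34:2", "PC 34:1", "PC 36:2"),
                            polarities = "positive")
  feats <- tibble::tibble(
    mz = c(758.5700, 760.5860, 786.6000),
    rt = 5.4, polarity = "positive",
    sample_id = "s1", area = c(1, 2, 3)
  )
  a1 <- match_features(feats, cand, 10, pc_window)
  a2 <- match_features(feats, cand[sample(nrow(cand)), ], 10, pc_window)
  expect_equal(dplyr::arrange(a1, mz), dplyr::arrange(a2, mz))
  # matched set at 5 ppm is a subset of the matched set at 10 ppm
  tight <- match_features(feats, cand, 5, pc_window)
  expect_true(all(paste(tight$mz, tight$species) %in% paste(a1$mz, a1$species)))
})

test_that("decoy features far off-mass are never annotated", {
  cand <- adduct_candidates(c("PC 34:2", "PC 34:1"), polarities = "positive")
  decoys <- tibble::tibble(
    mz = cand$mz_theoretical * (1 + 25e-6),
    rt = 5.4, polarity = "positive",
    sample_id = "s1", area = 10
  )
  expect_equal(nrow(match_features(decoys, cand, 10, pc_window)), 0)
})

test_that("a missing class window is a configuration error", {
  cand <- adduct_candidates(c("PC 34:2", "PE 34:1"), polarities = "positive")
  feats <- tibble::tibble(mz = 758.5700, rt = 5.4, polarity = "positive",
                          sample_id = "s1", area = 1)
  expect_error(match_features(feats, cand, 10, pc_window), "PE")
})

test_that("each species keeps only its best feature; others are shadowed", {
  cand <- adduct_candidates("PC 34:2", polarities = "positive")
  mz0 <- cand$mz_theoretical
  feats <- tibble::tibble(mz = c(mz0 * (1 + 1e-6), mz0 * (1 + 6e-6)),
                          rt = 5.4, polarity = "positive",
                          sample_id = "s1", area = c(1, 2))
  ann <- match_features(feats, cand, 10, pc_window)
  expect_setequal(ann$status, c("matched", "shadowed"))
  expect_equal(ann$status[which.min(abs(ann$ppm_error))], "matched")
})

test_that("RT windows are inferred from the spiked IS features", {
  sc <- render_small_cohort(seed = 3, n_samples = 2)
  win <- infer_rt_windows(sc$rendered$features)
  expect_true(all(c("PC", "PE", "Cer") %in% win$class_label))
  rtmap <- synthetic_rt_map()
  for (cl in c("PC", "PE", "Cer")) {
    w <- win[win$class_label == cl, ]
    expect_true(w$rt_min < rtmap[[cl]] && rtmap[[cl]] < w$rt_max)
  }
})
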