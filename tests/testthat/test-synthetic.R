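# The synthetic lipidome generator and feature-table renderer.

test_that("ground truth hits the class profile exactly and is seed-stable", {
  truth <- simulate_ground_truth(seed = 5)
  totals <- truth$species |>
    dplyr::group_by(class_label) |>
    dplyr::summarise(total = sum(conc_nmol_mg))
  prof <- dplyr::inner_join(totals, default_class_profile(), by = "class_label")
  expect_equal(prof$total, prof$fraction * 54.18, tolerance = 1e-9)
  expect_equal(sum(truth$species$conc_nmol_mg), 54.18, tolerance = 1e-9)
  # determinism
  expect_identical(simulate_ground_truth(seed = 5)$species, truth$species)
  expect_false(identical(simulate_ground_truth(seed = 6)$species, truth$species))
  # degenerate single-species classes still render and quantify
  t1 <- simulate_ground_truth(n_species_per_class = 1, seed = 5)
  expect_equal(nrow(t1$species), nrow(default_class_profile()))
  bad <- default_class_profile()
  bad$fraction <- bad$fraction * 2
  expect_error(simulate_ground_truth(bad), "sum to 1")
})

test_that("hydrolysis kinetics conserve mass and obey the first-order limits", {
  truth <- simulate_ground_truth(seed = 5)
  k <- c("LPC/PC" = rate_for_conversion(0.3, 120))
  tc <- simulate_hydrolysis_timecourse(truth, k = k, n_replicates = 2)
  # k = 0 (all other pairs): time points identical to baseline
  tc0 <- simulate_hydrolysis_timecourse(truth, k = c("LPE/PE" = 0),
                                        n_replicates = 1)
  base <- tc0[tc0$time_min == 0, c("species", "conc_nmol_mg")]
  for (t in c(30, 60, 120)) {
    cur <- tc0[tc0$time_min == t, c("species", "conc_nmol_mg")]
    expect_equal(cur$conc_nmol_mg, base$conc_nmol_mg)
  }
  # mass balance per replicate: LPC + PC total conserved
  pool <- tc |>
    dplyr::filter(class_label %in% c("LPC", "PC")) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(conc_nmol_mg))
  expect_equal(pool$total, rep(pool$total[1], nrow(pool)), tolerance = 1e-12)
  # t -> infinity: precursor fully converted
  tc_inf <- simulate_hydrolysis_timecourse(truth, k = c("LPC/PC" = 1),
                                           times = c(0, 1e6), n_replicates = 1)
  pc_end <- tc_inf |>
    dplyr::filter(time_min == 1e6, class_label == "PC") |>
    dplyr::pull(conc_nmol_mg)
  expect_equal(sum(pc_end), 0, tolerance = 1e-12)
  expect_error(simulate_hydrolysis_timecourse(truth, k = c("A/B" = 1)),
               "unknown hydrolysis pair")
})

test_that("the doubling-rate closed form yields ~200% normalized ratio", {
  truth <- simulate_ground_truth(seed = 5)
  r0 <- sum(truth$species$conc_nmol_mg[truth$species$class_label == "LPC"]) /
    sum(truth$species$conc_nmol_mg[truth$species$class_label == "PC"])
  k <- rate_for_conversion(r0, 120)   # transfers exactly one lyso pool by 120'
  tc <- simulate_hydrolysis_timecourse(truth, k = c("LPC/PC" = k),
                                       n_replicates = 1, tissue_cv = 0)
  meas <- simulate_measured_areas(tc, truth, cv = 0)
  tot <- class_totals(meas, value = "area")
  hr <- hydrolysis_ratios(tot)
  hr <- dplyr::left_join(hr[hr$pair == "LPC/PC", ],
                         dplyr::distinct(meas, sample_id, time_min),
                         by = "sample_id")
  nr <- normalize_baseline(hr)
  # closed form: ratio(120)/ratio(0) = 2 / (1 - r0), i.e. just above 200%
  expect_equal(nr$normalized_pct[nr$time_min == 120], 200 / (1 - r0),
               tolerance = 1e-9)
  expect_equal(nr$normalized_pct[nr$time_min == 120], 200, tolerance = 0.02)
})

test_that("partition simulation is monotone for Cer and seed-stable", {
  truth <- simulate_ground_truth(total_class_profile(), seed = 9)
  obs <- simulate_partition(truth, seed = 17)
  expect_identical(simulate_partition(truth, seed = 17), obs)
  cer <- partition_fractions(obs) |>
    dplyr::filter(class_label == "Cer") |>
    dplyr::group_by(water_pct) |>
    dplyr::summarise(f = mean(fraction_meoh))
  expect_true(all(diff(cer$f) < 0))
  # negative-mode-only classes appear in the MeOH phase only
  expect_true(all(obs$phase[obs$class_label %in% c("PG", "PI", "PS")] == "MeOH"))
})

test_that("noise-free rendering inverts end to end through the pipeline", {
  sc <- render_small_cohort(seed = 7, n_samples = 2)
  res <- lipid_pipeline(sc$rendered$features, sc$rendered$metadata,
                        candidate_species = sc$truth$species$species,
                        include_nonquant = TRUE)
  q <- dplyr::inner_join(res$quant[grepl("^S", res$quant$sample_id), ],
                         sc$truth$species, by = "species",
                         suffix = c("", "_truth"))
  expect_equal(length(unique(q$species)), nrow(sc$truth$species))
  expect_lte(max(abs(q$conc_nmol_mg - q$conc_nmol_mg_truth) /
                   q$conc_nmol_mg_truth), 1e-9)
})

test_that("renderer censoring and carryover drive the designed filter outcomes", {
  truth <- simulate_ground_truth(seed = 13)
  target <- truth$species$species[truth$species$class_label == "PC"][1]
  cohort <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(sample_id = sprintf("S%d", i), group = "g1",
                   species = truth$species$species,
                   conc_nmol_mg = truth$species$conc_nmol_mg)
  })
  co <- stats::setNames(rep(0, nrow(truth$species)), truth$species$species)
  co[target] <- 0.3
  ren <- render_feature_table(cohort, truth, noise_cv = 0, lod = 0,
                              intensity_threshold = 0, carryover = co, seed = 13)
  res <- lipid_pipeline(ren$features, ren$metadata,
                        candidate_species = truth$species$species)
  matched <- res$annotated[res$annotated$status == "matched", ]
  ints <- matched[matched$label_d == 0, c("species", "sample_id", "area")]
  fres <- qc_filter(ints, res$quant, ren$metadata)
  expect_equal(fres$report$step_failed[fres$report$species == target], "blank")
  expect_false(target %in% fres$retained)

  # LOD above a species' area in 2 of 6 samples drops it at the prevalence step
  sc2 <- render_small_cohort(seed = 19, n_samples = 6)
  feats <- sc2$rendered$features
  # pick a positive-mode-only species so censoring one polarity silences it
  pos_only <- sc2$truth$species[sc2$truth$species$class_label %in%
                                  c("CE", "TG", "DG", "MG", "Chol"), ]
  lowest <- pos_only$species[which.min(pos_only$conc_nmol_mg)]
  mz_low <- lipid_mz(lowest, "positive")
  hit <- abs(feats$mz - mz_low) < 1e-6 & feats$polarity == "positive" &
    feats$sample_id %in% c("S1", "S2")
  feats$area[hit] <- NA_real_
  res2 <- lipid_pipeline(feats, sc2$rendered$metadata,
                         candidate_species = sc2$truth$species$species,
                         include_nonquant = TRUE)
  matched2 <- res2$annotated[res2$annotated$status == "matched", ]
  ints2 <- matched2[matched2$label_d == 0, c("species", "sample_id", "area")]
  fres2 <- qc_filter(ints2, res2$quant, sc2$rendered$metadata)
  expect_equal(fres2$report$step_failed[fres2$report$species == lowest],
               "prevalence")
  expect_equal(fres2$report$prevalence[fres2$report$species == lowest], 4 / 6)
})

test_that("rendered tables survive the disk round trip with metadata", {
  sc <- render_small_cohort(seed = 23, n_samples = 2)
  pos <- sc$rendered$features[sc$rendered$features$polarity == "positive", ]
  tf <- withr::local_tempfile(fileext = ".txt")
  mf <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(pos, tf)
  readr::write_csv(sc$rendered$metadata, mf)
  back <- read_feature_table(tf, read_sample_metadata(mf), "positive")
  expect_equal(sort(unique(back$sample_id)),
               sort(unique(pos$sample_id)))
  expect_equal(nrow(back), nrow(pos))
})
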