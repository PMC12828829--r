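# Hydrolysis-ratio statistics and the group-comparison machinery.

test_that("hydrolysis ratios divide degradation by precursor class totals", {
  tot <- tibble::tibble(
    sample_id = "s1",
    class_label = c("LPC", "PC", "LPE", "PE"),
    total = c(5, 500, 0, 300)
  )
  hr <- hydrolysis_ratios(tot)
  expect_equal(hr$ratio[hr$pair == "LPC/PC"], 0.01)
  expect_equal(hr$ratio[hr$pair == "LPE/PE"], 0)
  # zero precursor: undefined with a reason
  tot0 <- tibble::tibble(sample_id = "s1", class_label = c("LPC", "PC"),
                         total = c(5, 0))
  hr0 <- hydrolysis_ratios(tot0)
  expect_true(is.na(hr0$ratio))
  expect_match(hr0$reason, "zero")
})

test_that("class totals are additive over species", {
  areas <- parse_lipids(c("PC 34:1", "PC 34:2", "PC 36:2"))
  areas$sample_id <- "s1"
  areas$corrected_area <- c(100, 200, 300)
  tot <- class_totals(areas)
  expect_equal(tot$total, 600)
  # deuterated IS areas never count toward class totals
  withis <- dplyr::bind_rows(areas, dplyr::mutate(parse_lipids("PC 33:1 d7"),
                                                  sample_id = "s1",
                                                  corrected_area = 1e6))
  expect_equal(class_totals(withis)$total, 600)
})

test_that("baseline normalization maps the t0 mean to exactly 100%", {
  ser <- tibble::tibble(pair = "LPC/PC",
                        time_min = c(0, 120),
                        ratio = c(0.01, 0.0202))
  out <- normalize_baseline(ser)
  expect_equal(out$normalized_pct, c(100, 202))
  # replicated baseline: the baseline mean itself normalizes to 100
  ser2 <- tibble::tibble(pair = "p", time_min = c(0, 0, 60),
                         ratio = c(0.009, 0.011, 0.02))
  out2 <- normalize_baseline(ser2)
  expect_equal(mean(out2$normalized_pct[out2$time_min == 0]), 100)
  # constant series is 100% everywhere
  ser3 <- tibble::tibble(pair = "p", time_min = c(0, 30, 60), ratio = rep(0.4, 3))
  expect_equal(normalize_baseline(ser3)$normalized_pct, rep(100, 3))
  # zero baseline is reported, not propagated
  ser4 <- tibble::tibble(pair = "p", time_min = c(0, 30), ratio = c(0, 1))
  out4 <- normalize_baseline(ser4)
  expect_true(all(is.na(out4$normalized_pct)))
  expect_match(out4$norm_reason[1], "zero")
})

test_that("relative class totals scale each class to its baseline mean", {
  tot <- tidyr::expand_grid(time_min = c(0, 120), replicate = 1:2) |>
    dplyr::mutate(sample_id = paste0("s", dplyr::row_number()),
                  class_label = "Cer",
                  total = c(10, 10, 20, 20))
  out <- relative_class_totals(tot)
  expect_equal(out$relative_pct[out$time_min == 0], c(100, 100))
  expect_equal(out$relative_pct[out$time_min == 120], c(200, 200))
})

test_that("Dunnett comparisons behave under null and strong-shift alternatives", {
  set.seed(42)
  null_data <- tibble::tibble(value = rnorm(40),
                              group = rep(c("0", "30", "60", "120"), each = 10))
  fit0 <- anova_dunnett(null_data, control = "0")
  # identical generating distributions: expect no significance (seeded draw)
  expect_true(all(tidy(fit0)$adj_p > 0.05))
  shift <- tibble::tibble(value = c(rnorm(10), rnorm(10, mean = 5)),
                          group = rep(c("ctrl", "hi"), each = 10))
  fits <- anova_dunnett(shift, control = "ctrl")
  expect_true(tidy(fits)$adj_p < 0.05)
  # multiplicity: adjusted p is never smaller than the unadjusted p from the
  # same pooled-variance model
  td0 <- tidy(fit0)
  df_res <- stats::df.residual(fit0$fit)
  for (i in seq_len(nrow(td0))) {
    praw <- 2 * stats::pt(-abs(td0$statistic[i]), df_res)
    expect_gte(td0$adj_p[i], praw - 1e-9)
  }
  expect_error(anova_dunnett(tibble::tibble(value = c(1, 2, 3),
                                            group = c("a", "a", "b")),
                             control = "a"), "replicates")
})

test_that("Dunnett adjusted p agrees with a Monte-Carlo max-|t| reference", {
  set.seed(7)
  d <- tibble::tibble(value = rnorm(12, mean = rep(c(0, 0.8, 1.6, 0.4), each = 3)),
                      group = rep(c("0", "30", "60", "120"), each = 3))
  fit <- anova_dunnett(d, control = "0")
  td <- tidy(fit)
  # observed Dunnett t statistics recomputed from first principles
  means <- tapply(d$value, d$group, mean)
  s2 <- sum(tapply(d$value, d$group, function(v) sum((v - mean(v))^2))) / 8
  tobs <- (means[c("30", "60", "120")] - means[["0"]]) / sqrt(s2 * (2 / 3))
  # null distribution of max |t| by direct simulation
  set.seed(123)
  B <- 1e5
  draws <- matrix(rnorm(12 * B), nrow = 12)
  gm <- rowsum(draws, rep(1:4, each = 3)) / 3
  ss <- rowsum(draws^2, rep(1:4, each = 3)) - 3 * gm^2
  s2b <- colSums(ss) / 8
  tb <- abs(sweep(gm[2:4, , drop = FALSE], 2, gm[1, ], "-")) /
    sqrt(s2b[col(gm[2:4, , drop = FALSE])] * 2 / 3)
  maxt <- apply(tb, 2, max)
  p_mc <- vapply(abs(tobs), function(t0) mean(maxt >= t0), numeric(1))
  ord <- match(c("30 - 0", "60 - 0", "120 - 0"), td$comparison)
  expect_equal(unname(td$adj_p[ord]), unname(p_mc), tolerance = 0.01)
})

test_that("Welch t handles the degenerate and equal-variance cases", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  flat <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p, 1)
  expect_match(flat$note, "convention")
  # with equal n and s2, Welch equals the pooled-variance t
  a <- c(1.2, 2.4, 3.6, 4.8)
  b <- a + 1          # identical variance, shifted
  w <- welch_t(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-6)
  expect_equal(w$p, pooled$p.value, tolerance = 1e-6)
})

test_that("volcano flags true fold changes and is symmetric under group swap", {
  set.seed(11)
  n <- 6
  quant <- purrr::map_dfr(1:20, function(i) {
    shifted <- i <= 5   # species 1-5 carry a true 4-fold shift
    base <- exp(rnorm(1, 0, 0.5))
    tibble::tibble(
      species = sprintf("sp%02d", i),
      sample_id = c(paste0("a", 1:n), paste0("b", 1:n)),
      conc_nmol_mg = c(base * (if (shifted) 4 else 1) * rlnorm(n, 0, 0.1),
                       base * rlnorm(n, 0, 0.1))
    )
  })
  v <- volcano(quant, paste0("a", 1:n), paste0("b", 1:n))
  td <- tidy(v)
  expect_true(all(td$flagged[1:5]))
  expect_true(mean(td$flagged[6:20]) <= 0.2)
  v_swap <- volcano(quant, paste0("b", 1:n), paste0("a", 1:n))
  expect_equal(tidy(v_swap)$flagged, td$flagged)
  expect_equal(tidy(v_swap)$log2_fc, -td$log2_fc, tolerance = 1e-12)
  # identical groups: FC 1, unflagged
  same <- tibble::tibble(species = "x",
                         sample_id = c("a1", "a2", "b1", "b2"),
                         conc_nmol_mg = c(1, 2, 1, 2))
  expect_false(tidy(volcano(same, c("a1", "a2"), c("b1", "b2")))$flagged)
})

test_that("PCA scores are centered with non-increasing explained variance", {
  set.seed(5)
  quant <- purrr::map_dfr(1:10, function(i) {
    shift <- rnorm(1, 0, 2)
    tibble::tibble(
      species = sprintf("sp%02d", i),
      sample_id = sprintf("s%d", 1:8),
      conc_nmol_mg = rnorm(8) + shift + c(rep(0, 4), rep(3, 4))
    )
  })
  pc <- pca_scores(quant, n_components = 3)
  expect_equal(colMeans(as.matrix(tidy(pc)[, -1])), c(PC1 = 0, PC2 = 0, PC3 = 0),
               tolerance = 1e-10)
  ev <- glance(pc)$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1)
  # the group shift dominates: PC1 separates the two blocks
  s <- tidy(pc)
  g1 <- s$PC1[s$sample_id %in% sprintf("s%d", 1:4)]
  g2 <- s$PC1[s$sample_id %in% sprintf("s%d", 5:8)]
  expect_true(max(g1) < min(g2) || min(g1) > max(g2))
  # requesting more components than the rank truncates with a note
  pc_big <- pca_scores(quant, n_components = 50)
  expect_false(is.na(pc_big$note))
})
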