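# Independent oracles and constructed fixtures shared across tests.

# Brute-force isotopologue envelope: per element, enumerate every heavy-atom
# assignment and score it with dmultinom; combine elements by expanding the
# product of per-element shift distributions. Shares only the abundance
# table (configuration) with the package's convolution implementation.
brute_force_envelope <- function(comp, K = 6L) {
  ab <- lipidpipe::isotope_abundances()
  comp <- comp[comp > 0]
  pmf_total <- c(1, numeric(K))
  for (el in names(comp)) {
    rows <- ab[ab$element == el, ]
    rows <- rows[order(rows$shift), ]
    n <- comp[[el]]
    heavy <- rows[rows$shift > 0, ]
    pmf_el <- numeric(K + 1L)
    if (nrow(heavy) == 0L) {
      pmf_el[1] <- 1
    } else {
      counts_grid <- expand.grid(lapply(seq_len(nrow(heavy)), function(i) {
        0:min(n, K %/% heavy$shift[i])
      }))
      for (g in seq_len(nrow(counts_grid))) {
        ks <- as.integer(counts_grid[g, ])
        shift <- sum(ks * heavy$shift)
        if (shift > K || sum(ks) > n) next
        prob <- stats::dmultinom(c(n - sum(ks), ks),
                                 prob = c(rows$abundance[rows$shift == 0], heavy$abundance))
        pmf_el[shift + 1L] <- pmf_el[shift + 1L] + prob
      }
    }
    new_total <- numeric(K + 1L)
    for (i in 0:K) {
      for (j in 0:(K - i)) {
        new_total[i + j + 1L] <- new_total[i + j + 1L] +
          pmf_total[i + 1L] * pmf_el[j + 1L]
      }
    }
    pmf_total <- new_total
  }
  stats::setNames(pmf_total, paste0("p", 0:K))
}

# QC-filter fixture with one designed violation per rule.
# Roles: 2 blanks, 3 QCs, 6 study samples (one group).
# - sp_ok       passes everything
# - sp_blank    blank mean 30 vs QC mean 100 (ratio 0.30 > 0.20)
# - sp_cv       QC concentrations {1, 1, 2} (CV ~ 0.43 > 0.20)
# - sp_qcmiss   missing in one QC sample
# - sp_prev     detected in only 4 of 6 study samples (66.7% < 80%)
make_filter_fixture <- function() {
  blanks <- paste0("B", 1:2); qcs <- paste0("Q", 1:3); study <- paste0("S", 1:6)
  meta <- tibble::tibble(
    sample_id = c(blanks, qcs, study),
    role = c(rep("blank", 2), rep("QC", 3), rep("study", 6)),
    group = c(rep("blank", 2), rep("QC", 3), rep("g1", 6))
  )
  all_samples <- meta$sample_id
  base_int <- function(blank, qc, study_v) {
    c(rep(blank, 2), rep(qc, 3), study_v)
  }
  int <- tibble::tibble(
    species = rep(c("sp_ok", "sp_blank", "sp_cv", "sp_qcmiss", "sp_prev"),
                  each = length(all_samples)),
    sample_id = rep(all_samples, 5),
    area = c(
      base_int(0, 100, rep(100, 6)),       # sp_ok
      base_int(30, 100, rep(100, 6)),      # sp_blank
      base_int(0, 100, rep(100, 6)),       # sp_cv
      base_int(0, 100, rep(100, 6)),       # sp_qcmiss
      base_int(0, 100, rep(100, 6))        # sp_prev
    )
  )
  conc_row <- function(qc_v, study_v) c(rep(NA_real_, 2), qc_v, study_v)
  quant <- tibble::tibble(
    species = rep(c("sp_ok", "sp_blank", "sp_cv", "sp_qcmiss", "sp_prev"),
                  each = length(all_samples)),
    sample_id = rep(all_samples, 5),
    conc_nmol_mg = c(
      conc_row(c(1, 1, 1), rep(1, 6)),                      # sp_ok
      conc_row(c(1, 1, 1), rep(1, 6)),                      # sp_blank
      conc_row(c(1, 1, 2), rep(1, 6)),                      # sp_cv
      conc_row(c(1, NA, 1), rep(1, 6)),                     # sp_qcmiss
      conc_row(c(1, 1, 1), c(1, 1, 1, 1, NA, NA))           # sp_prev
    )
  )
  list(metadata = meta, intensities = int, quant = quant)
}

# One phase-I stability simulation: LPC/PC time course at rate k, measured
# with CV 10% at n replicates; returns the Dunnett adjusted p for the
# 120-min comparison against the 0-min control.
phase1_dunnett_p <- function(truth, k, seed, cv = 0.10, n_replicates = 3) {
  tc <- lipidpipe::simulate_hydrolysis_timecourse(
    truth, k = c("LPC/PC" = k), n_replicates = n_replicates, seed = seed)
  meas <- lipidpipe::simulate_measured_areas(tc, truth, cv = cv,
                                             seed = seed + 500000L)
  tot <- lipidpipe::class_totals(meas, value = "area")
  times <- dplyr::distinct(meas, sample_id, time_min)
  hr <- lipidpipe::hydrolysis_ratios(tot)
  hr <- dplyr::left_join(hr[hr$pair == "LPC/PC", ], times, by = "sample_id")
  nr <- lipidpipe::normalize_baseline(hr)
  fit <- lipidpipe::anova_dunnett(nr, value = "normalized_pct",
                                  group = "time_min", control = 0)
  cmp <- tidy(fit)
  cmp$adj_p[grepl("^120", cmp$comparison)]
}

# A small rendered cohort used by several end-to-end tests.
render_small_cohort <- function(seed = 7, n_samples = 4, noise_cv = 0, lod = 0,
                                intensity_threshold = 0, carryover = 0, ...) {
  truth <- lipidpipe::simulate_ground_truth(lipidpipe::total_class_profile(),
                                            n_species_per_class = 3, seed = seed)
  cohort <- purrr::map_dfr(seq_len(n_samples), function(i) {
    tibble::tibble(sample_id = sprintf("S%d", i),
                   group = ifelse(i <= n_samples / 2, "female", "male"),
                   species = truth$species$species,
                   conc_nmol_mg = truth$species$conc_nmol_mg)
  })
  ren <- lipidpipe::render_feature_table(
    cohort, truth, noise_cv = noise_cv, lod = lod,
    intensity_threshold = intensity_threshold, carryover = carryover,
    seed = seed, ...)
  list(truth = truth, cohort = cohort, rendered = ren)
}
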