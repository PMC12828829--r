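# Seeded synthetic lipidomes: ground-truth concentrations with the class
# structure of pancreatic tissue, first-order hydrolysis time courses,
# two-phase partition experiments, and a feature-table renderer that
# emulates the measurement chain (isotopologue envelopes with +2 overlap,
# IS spiking, multiplicative noise, detection-limit censoring, intensity
# threshold, QC and blank samples).

#' Default polar-lipid class profile
#'
#' Class mole fractions of the polar pancreatic lipidome: PC-type lipids
#' 57.4% and PE-type 30.4% (ether forms included in each), then PI, PS and
#' SM at 5.61/2.68/1.47%, with the remainder spread over the minor classes
#' (LPC, Cer, PG, LPE, HexCer and the ether lyso forms).
#'
#' @return Tibble `class_label`, `fraction` summing to 1.
#' @export
default_class_profile <- function() {
  tibble::tribble(
    ~class_label, ~fraction,
    "PC",     0.524,
    "PC O-",  0.050,
    "PE",     0.234,
    "PE O-",  0.070,
    "PI",     0.0561,
    "PS",     0.0268,
    "SM",     0.0147,
    "LPC",    0.005,
    "Cer",    0.005,
    "PG",     0.005,
    "LPE",    0.003,
    "HexCer", 0.0024,
    "LPC O-", 0.002,
    "LPE O-", 0.002
  )
}

#' Total-extract class profile
#'
#' Extends the polar profile with the neutral classes (CE, TG, DG, Chol,
#' MG) so that fractionation experiments cover hexane-dominant lipids.
#'
#' @return Tibble `class_label`, `fraction` summing to 1.
#' @export
total_class_profile <- function() {
  polar <- default_class_profile()
  polar$fraction <- polar$fraction * 0.518
  dplyr::bind_rows(
    polar,
    tibble::tribble(
      ~class_label, ~fraction,
      "TG",   0.300,
      "Chol", 0.080,
      "CE",   0.060,
      "DG",   0.040,
      "MG",   0.002
    )
  )
}

# Candidate carbon:double-bond grids per class family; consecutive
# double-bond counts at a shared carbon number make the +2 isotopologue
# overlap (and hence the type II correction) real.
species_grid <- function(class_label) {
  base <- sub(" O-$", "", class_label)
  ether <- grepl(" O-$", class_label)
  grid <- switch(base,
    "PC" = , "PE" = , "PG" = , "PI" = , "PS" =
      expand.grid(carbons = c(34L, 36L, 38L, 32L), db = 1:3),
    "LPC" = , "LPE" = expand.grid(carbons = c(18L, 16L, 20L), db = 0:2),
    "SM" = , "Cer" = , "HexCer" =
      expand.grid(carbons = c(34L, 36L, 38L, 40L, 42L), db = 1:2),
    "CE" = expand.grid(carbons = c(16L, 18L, 20L), db = 0:2),
    "TG" = expand.grid(carbons = c(48L, 50L, 52L, 54L), db = 1:3),
    "DG" = expand.grid(carbons = c(32L, 34L, 36L), db = 1:2),
    "MG" = expand.grid(carbons = c(16L, 18L), db = 0:1),
    "Chol" = data.frame(carbons = 0L, db = 0L),
    stop("no species grid for class label '", class_label, "'", call. = FALSE)
  )
  grid <- grid[order(grid$carbons, grid$db), , drop = FALSE]
  oxy <- if (base %in% c("SM", "Cer", "HexCer")) ";O2" else ""
  link <- if (ether) "O-" else ""
  if (base == "Chol") return("Chol")
  paste0(base, " ", link, grid$carbons, ":", grid$db, oxy)
}

#' Simulate a ground-truth lipidome
#'
#' Draws species-level concentrations (lognormal within class) and rescales
#' them so class totals hit the requested profile exactly. The result also
#' carries the default hydrolysis rate constants (zero), the per-class
#' partition functions over water content, the noise parameters and the
#' seed, so every downstream fixture derives from one object.
#'
#' @param profile Class profile (`class_label`, `fraction` summing to ~1);
#'   default [default_class_profile()].
#' @param n_species_per_class Species drawn per class (default 3; Chol is
#'   always a single species).
#' @param total_nmol_mg Total lipid concentration (default 54.18 nmol/mg
#'   wet tissue).
#' @param seed RNG seed; the same seed reproduces the truth exactly.
#' @param species_sdlog Lognormal spread of species within a class.
#' @param noise_cv Default measurement coefficient of variation carried by
#'   the truth (default 0.10).
#' @param lod Default detection limit in area units (default 0).
#' @param rf_sd Standard deviation of per-species response factors around 1
#'   (default 0: all response factors exactly 1, documented as synthetic).
#' @return Object of class `lipid_truth`: list with `species` (tibble
#'   `species`, `class_label`, `conc_nmol_mg`, `response_factor`),
#'   `partition` (per class and water content), `hydrolysis_k`, `noise_cv`,
#'   `lod`, `seed`.
#' @export
simulate_ground_truth <- function(profile = default_class_profile(),
                                  n_species_per_class = 3,
                                  total_nmol_mg = 54.18,
                                  seed = 1,
                                  species_sdlog = 0.8,
                                  noise_cv = 0.10,
                                  lod = 0,
                                  rf_sd = 0) {
  if (abs(sum(profile$fraction) - 1) > 1e-6) {
    stop("profile fractions must sum to 1 (got ", sum(profile$fraction), ")",
         call. = FALSE)
  }
  set.seed(seed)
  species <- purrr::map_dfr(seq_len(nrow(profile)), function(i) {
    cl <- profile$class_label[i]
    names <- species_grid(cl)
    names <- names[seq_len(min(n_species_per_class, length(names)))]
    raw <- stats::rlnorm(length(names), meanlog = 0, sdlog = species_sdlog)
    conc <- raw / sum(raw) * profile$fraction[i] * total_nmol_mg
    rf <- if (rf_sd > 0) stats::rlnorm(length(names), 0, rf_sd) else rep(1, length(names))
    tibble::tibble(species = names, class_label = cl, conc_nmol_mg = conc,
                   response_factor = rf)
  })
  out <- list(
    species = species,
    partition = default_partition_truth(),
    hydrolysis_k = stats::setNames(
      rep(0, nrow(default_hydrolysis_pairs())),
      paste0(default_hydrolysis_pairs()$degradation, "/",
             default_hydrolysis_pairs()$precursor)),
    noise_cv = noise_cv, lod = lod, seed = seed,
    total_nmol_mg = total_nmol_mg
  )
  class(out) <- "lipid_truth"
  out
}

#' @export
print.lipid_truth <- function(x, ...) {
  cat("Synthetic lipidome truth:", nrow(x$species), "species in",
      length(unique(x$species$class_label)), "classes; total",
      sprintf("%.2f nmol/mg", sum(x$species$conc_nmol_mg)),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Default ground-truth partition functions
#'
#' MeOH-rich phase fraction per class label at 0, 2 and 5% (v/v) water in
#' methanol. The defaults mirror the observed qualitative behavior: CE and
#' TG hexane-dominant, lysophospholipids almost entirely MeOH-bound, Cer
#' and Chol losing MeOH affinity as water increases. Negative-mode-only
#' classes (PG, PI, PS) are marked MeOH-only (`NA` fraction): only their
#' MeOH-rich phase is observed.
#'
#' @return Tibble `class_label`, `water_pct`, `fraction_meoh`, `meoh_only`.
#' @export
default_partition_truth <- function() {
  spec <- tibble::tribble(
    ~class_label, ~f0, ~f2, ~f5, ~meoh_only,
    "CE",     0.03, 0.02, 0.01,  FALSE,
    "TG",     0.05, 0.03, 0.02,  FALSE,
    "DG",     0.60, 0.50, 0.35,  FALSE,
    "MG",     1.00, 1.00, 1.00,  FALSE,
    "Chol",   0.70, 0.55, 0.40,  FALSE,
    "Cer",    0.70, 0.52, 0.30,  FALSE,
    "HexCer", 0.85, 0.85, 0.85,  FALSE,
    "SM",     0.90, 0.92, 0.93,  FALSE,
    "PE",     0.88, 0.88, 0.88,  FALSE,
    "PE O-",  0.85, 0.85, 0.85,  FALSE,
    "PC",     0.90, 0.92, 0.95,  FALSE,
    "PC O-",  0.88, 0.91, 0.94,  FALSE,
    "LPC",    0.97, 0.99, 0.995, FALSE,
    "LPC O-", 0.97, 0.98, 0.99,  FALSE,
    "LPE",    0.98, 0.98, 0.98,  FALSE,
    "LPE O-", 0.98, 0.98, 0.98,  FALSE,
    "PG",     NA,   NA,   NA,    TRUE,
    "PI",     NA,   NA,   NA,    TRUE,
    "PS",     NA,   NA,   NA,    TRUE
  )
  tidyr::pivot_longer(spec, c("f0", "f2", "f5"), names_to = "water_pct",
                      values_to = "fraction_meoh") |>
    dplyr::mutate(water_pct = as.numeric(sub("^f", "", .data$water_pct))) |>
    dplyr::select("class_label", "water_pct", "fraction_meoh", "meoh_only")
}

#' Rate constant that converts a target precursor fraction by a given time
#'
#' Convenience inverse of the first-order kinetics: the `k` (1/min) for
#' which `1 - exp(-k t)` equals `frac` at time `t`.
#'
#' @param frac Converted precursor fraction at time `t`.
#' @param t Time in minutes.
#' @return Rate constant in 1/min.
#' @export
rate_for_conversion <- function(frac, t) {
  stopifnot(frac >= 0, frac < 1, t > 0)
  -log(1 - frac) / t
}

#' Simulate a first-order hydrolysis time course
#'
#' For each degradation/precursor pair with rate constant `k`, every
#' precursor species loses `c0 (1 - exp(-k t))` by time `t`; the transferred
#' moles are mass-balanced into the paired degradation class, pro rata over
#' its baseline species. Replicate tissue heterogeneity is applied as a
#' per-species lognormal multiplier.
#'
#' @param truth A `lipid_truth` object.
#' @param k Named numeric vector of rate constants (1/min) keyed by
#'   `"degradation/precursor"` pair label (defaults to the truth's, all 0).
#' @param times Storage time points in minutes (default 0, 30, 60, 120).
#' @param n_replicates Replicates per time point (default 3).
#' @param tissue_cv Between-replicate heterogeneity CV (default 0).
#' @param seed RNG seed for the heterogeneity draws.
#' @return Tibble `sample_id`, `time_min`, `replicate`, `species`,
#'   `class_label`, `conc_nmol_mg` (per-sample ground truth, before
#'   measurement noise).
#' @export
simulate_hydrolysis_timecourse <- function(truth, k = truth$hydrolysis_k,
                                           times = c(0, 30, 60, 120),
                                           n_replicates = 3,
                                           tissue_cv = 0, seed = truth$seed) {
  stopifnot(inherits(truth, "lipid_truth"), all(k >= 0))
  pairs <- default_hydrolysis_pairs()
  pairs$pair <- paste0(pairs$degradation, "/", pairs$precursor)
  unknown <- setdiff(names(k), pairs$pair)
  if (length(unknown)) {
    stop("unknown hydrolysis pair(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- truth$species
  set.seed(seed)
  sdlog <- sqrt(log(1 + tissue_cv^2))
  purrr::map_dfr(times, function(t) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      conc <- stats::setNames(base$conc_nmol_mg, base$species)
      for (p in names(k)) {
        if (k[[p]] == 0) next
        i <- match(p, pairs$pair)
        pre_idx <- base$class_label == pairs$precursor[i]
        deg_idx <- base$class_label == pairs$degradation[i]
        if (!any(pre_idx) || !any(deg_idx)) next
        frac <- 1 - exp(-k[[p]] * t)
        transferred <- conc[base$species[pre_idx]] * frac
        conc[base$species[pre_idx]] <- conc[base$species[pre_idx]] - transferred
        deg_base <- truth$species$conc_nmol_mg[deg_idx]
        conc[base$species[deg_idx]] <- conc[base$species[deg_idx]] +
          sum(transferred) * deg_base / sum(deg_base)
      }
      mult <- if (tissue_cv > 0) {
        stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
      } else rep(1, length(conc))
      tibble::tibble(
        sample_id = sprintf("t%03d_r%d", t, r),
        time_min = t, replicate = r,
        species = base$species, class_label = base$class_label,
        conc_nmol_mg = unname(conc * mult)
      )
    })
  })
}

#' Apply multiplicative measurement noise to per-sample truths
#'
#' Areas are proportional to concentration times the species response
#' factor, with a mean-one lognormal multiplier of coefficient of variation
#' `cv`.
#'
#' @param sample_truths Tibble with `species` and `conc_nmol_mg` (e.g. from
#'   [simulate_hydrolysis_timecourse()]).
#' @param truth `lipid_truth` supplying response factors.
#' @param cv Measurement CV (default the truth's `noise_cv`).
#' @param area_scale Area units per nmol/mg (cancels in ratio statistics).
#' @param seed RNG seed.
#' @return Input with an `area` column and `label_d = 0`.
#' @export
simulate_measured_areas <- function(sample_truths, truth, cv = truth$noise_cv,
                                    area_scale = 1e5, seed = truth$seed + 1) {
  rf <- stats::setNames(truth$species$response_factor, truth$species$species)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- if (cv > 0) {
    stats::rlnorm(nrow(sample_truths), -sdlog^2 / 2, sdlog)
  } else rep(1, nrow(sample_truths))
  sample_truths$area <- sample_truths$conc_nmol_mg *
    unname(rf[sample_truths$species]) * area_scale * noise
  sample_truths$label_d <- 0L
  sample_truths
}

#' Simulate a two-phase partition experiment
#'
#' Per class, condition and replicate, the class total area is split between
#' the MeOH-rich and hexane-rich phases according to the truth's partition
#' function, with independent multiplicative lognormal noise per phase.
#' MeOH-only classes yield only MeOH-phase rows.
#'
#' @param truth `lipid_truth` object (its `partition` table supplies the
#'   generating fractions; classes absent from the truth's species are
#'   skipped).
#' @param water_contents Water contents evaluated (default 0, 2, 5 % v/v).
#' @param n_replicates Replicates per condition (default 3).
#' @param cv Measurement CV per phase area (default 0.05).
#' @param area_scale Area units per nmol/mg.
#' @param seed RNG seed.
#' @return Tidy observations: `class_label`, `water_pct`, `phase`,
#'   `replicate`, `area`.
#' @export
simulate_partition <- function(truth, water_contents = c(0, 2, 5),
                               n_replicates = 3, cv = 0.05,
                               area_scale = 1e5, seed = truth$seed + 2) {
  stopifnot(inherits(truth, "lipid_truth"))
  totals <- truth$species |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(total = sum(.data$conc_nmol_mg) * area_scale, .groups = "drop")
  part <- dplyr::inner_join(truth$partition, totals, by = "class_label")
  part <- part[part$water_pct %in% water_contents, ]
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mu, n) {
    if (cv > 0) mu * stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(mu, n)
  }
  purrr::map_dfr(seq_len(nrow(part)), function(i) {
    row <- part[i, ]
    reps <- seq_len(n_replicates)
    if (row$meoh_only) {
      return(tibble::tibble(class_label = row$class_label,
                            water_pct = row$water_pct, phase = "MeOH",
                            replicate = reps, area = draw(row$total, n_replicates)))
    }
    dplyr::bind_rows(
      tibble::tibble(class_label = row$class_label, water_pct = row$water_pct,
                     phase = "MeOH", replicate = reps,
                     area = draw(row$total * row$fraction_meoh, n_replicates)),
      tibble::tibble(class_label = row$class_label, water_pct = row$water_pct,
                     phase = "hexane", replicate = reps,
                     area = draw(row$total * (1 - row$fraction_meoh), n_replicates))
    )
  })
}

# Synthetic class retention-time map (minutes within an 8-min run); classes
# are chromatographically separated, species within a class co-elute.
SYNTHETIC_RT <- c(
  "CE" = 0.6, "TG" = 1.0, "DG" = 1.4, "MG" = 1.8, "Chol" = 2.2, "Cer" = 2.6,
  "HexCer" = 3.0, "PG" = 3.4, "PE" = 3.8, "PE O-" = 4.2, "PI" = 4.6,
  "PS" = 5.0, "PC" = 5.4, "PC O-" = 5.8, "SM" = 6.2, "LPE" = 6.6,
  "LPE O-" = 6.8, "LPC" = 7.4, "LPC O-" = 7.6
)

#' Synthetic class retention times
#' @return Named numeric vector of retention times (min) per class label.
#' @export
synthetic_rt_map <- function() SYNTHETIC_RT

#' Render feature tables from per-sample ground truths
#'
#' Emulates the measurement chain downstream of extraction: per species and
#' polarity, the total ion abundance is `concentration x tissue mass x
#' response factor x area_scale`, distributed over isotopologues; the
#' monoisotopic extraction window receives the species' own `p0` share plus
#' the `p2` share of the co-eluting same-carbon species with one more
#' double bond, so the type II correction is exercised. Internal standards
#' are spiked per the mix at their nominal per-mg amounts. QC samples are
#' rendered as the pooled mean of the study truths; blanks carry a
#' configurable fraction of the mean study signal (plus the IS spike).
#' Multiplicative lognormal noise, detection-limit censoring and the
#' intensity threshold are applied last; censored areas are missing, not
#' zero.
#'
#' @param sample_truths Tibble `sample_id`, `species`, `conc_nmol_mg`
#'   (optionally `group`, `time_min`, `replicate` carried into the
#'   metadata).
#' @param truth `lipid_truth` supplying response factors.
#' @param mix IS mix definition.
#' @param registry Lipid class registry.
#' @param n_qc,n_blank Number of QC and blank samples (defaults 3 and 2).
#' @param tissue_mg Tissue mass per study sample (default 3 mg, the
#'   homogenate aliquot).
#' @param noise_cv Measurement CV (default the truth's).
#' @param lod Detection limit in area units (default the truth's).
#' @param intensity_threshold Export intensity threshold (default 3000).
#' @param carryover Blank carryover fraction of the mean study signal
#'   (default 0.02); may be a named vector per species.
#' @param area_scale Area units per (nmol/mg x mg).
#' @param mz_jitter_ppm Gaussian m/z error applied per feature (ppm,
#'   default 0).
#' @param seed RNG seed.
#' @return List with `features` (long tibble over both polarities),
#'   `metadata` (sample sheet) and `candidates` (the species + IS names
#'   rendered, for annotation).
#' @export
render_feature_table <- function(sample_truths, truth, mix = is_mix(),
                                 registry = lipid_registry(),
                                 n_qc = 3, n_blank = 2, tissue_mg = 3,
                                 noise_cv = truth$noise_cv, lod = truth$lod,
                                 intensity_threshold = 3000, carryover = 0.02,
                                 area_scale = 1e5, mz_jitter_ppm = 0,
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "lipid_truth"))
  set.seed(seed)
  study_ids <- unique(sample_truths$sample_id)
  rf <- stats::setNames(truth$species$response_factor, truth$species$species)

  # per-sample species amounts (nmol), study samples
  amounts <- sample_truths |>
    dplyr::mutate(amount_nmol = .data$conc_nmol_mg * tissue_mg,
                  role = "study")
  # QC = pooled mean of study truths
  qc <- amounts |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(amount_nmol = mean(.data$amount_nmol), .groups = "drop")
  qc <- purrr::map_dfr(seq_len(n_qc), function(i) {
    dplyr::mutate(qc, sample_id = sprintf("QC_%d", i), role = "QC")
  })
  blank <- amounts |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(amount_nmol = mean(.data$amount_nmol), .groups = "drop")
  co <- if (length(carryover) == 1L) {
    rep(carryover, nrow(blank))
  } else {
    ifelse(is.na(carryover[blank$species]), 0, carryover[blank$species])
  }
  blank$amount_nmol <- blank$amount_nmol * co
  blank <- purrr::map_dfr(seq_len(n_blank), function(i) {
    dplyr::mutate(blank, sample_id = sprintf("blank_%d", i), role = "blank")
  })
  endo <- dplyr::bind_rows(
    amounts[, c("sample_id", "role", "species", "amount_nmol")],
    qc[, c("sample_id", "role", "species", "amount_nmol")],
    blank[, c("sample_id", "role", "species", "amount_nmol")]
  )
  endo$response_factor <- unname(rf[endo$species])

  # IS spike: nominal per-mg amounts, every sample including blanks
  all_ids <- unique(endo$sample_id)
  roles <- stats::setNames(endo$role[!duplicated(endo$sample_id)],
                           endo$sample_id[!duplicated(endo$sample_id)])
  is_tbl <- dplyr::bind_rows(
    tibble::tibble(species = mix$primary_is, amount_per_mg = mix$primary_nmol_mg),
    tibble::tibble(species = mix$secondary_is, amount_per_mg = mix$secondary_nmol_mg)
  )
  is_tbl <- is_tbl[!is.na(is_tbl$species), ]
  spikes <- purrr::map_dfr(all_ids, function(id) {
    tibble::tibble(sample_id = id, role = unname(roles[id]),
                   species = is_tbl$species,
                   amount_nmol = is_tbl$amount_per_mg * tissue_mg,
                   response_factor = 1)
  })
  panel <- dplyr::bind_rows(endo, spikes)

  parsed <- parse_lipids(unique(panel$species), registry)
  # map input names to canonical shorthand (alias-tolerant join)
  canon <- stats::setNames(parsed$species, unique(panel$species))
  panel$species <- unname(canon[panel$species])
  panel <- dplyr::left_join(panel, parsed, by = "species")

  features <- purrr::map_dfr(c("positive", "negative"), function(pol) {
    add <- class_adduct(parsed$class, pol, registry)
    sub <- parsed[!is.na(add), ]
    if (nrow(sub) == 0L) return(tibble::tibble())
    sub$adduct <- add[!is.na(add)]
    sub$mz_theoretical <- vapply(seq_len(nrow(sub)), function(i) {
      lipid_mz(sub[i, ], pol, registry = registry)
    }, numeric(1))
    env <- dplyr::bind_rows(lapply(sub$species, function(sp) {
      e <- isotope_envelope(lipid_composition(sp, registry), K = 2L)
      tibble::tibble(species = sp, p0 = e[["p0"]], p2 = e[["p2"]])
    }))
    sub <- dplyr::left_join(sub, env, by = "species")
    pp <- dplyr::inner_join(panel[, c("sample_id", "role", "species",
                                      "amount_nmol", "response_factor")],
                            sub, by = "species")
    pp$total_ions <- pp$amount_nmol * pp$response_factor * area_scale
    # monoisotopic window: own p0 plus the +2 of the DB+1 same-carbon species
    neighbor <- pp
    neighbor$db <- neighbor$db - 1L   # lands on the species it interferes with
    neighbor <- neighbor[, c("sample_id", "class_label", "label_d", "carbons",
                             "db", "total_ions", "p2")]
    names(neighbor)[names(neighbor) == "total_ions"] <- "nb_ions"
    names(neighbor)[names(neighbor) == "p2"] <- "nb_p2"
    pp <- dplyr::left_join(
      pp, neighbor,
      by = c("sample_id", "class_label", "label_d", "carbons", "db")
    )
    pp$nb_ions[is.na(pp$nb_ions)] <- 0
    pp$nb_p2[is.na(pp$nb_p2)] <- 0
    pp$area <- pp$total_ions * pp$p0 + pp$nb_ions * pp$nb_p2
    pp$polarity <- pol
    pp
  })

  sdlog <- sqrt(log(1 + noise_cv^2))
  if (noise_cv > 0) {
    features$area <- features$area *
      stats::rlnorm(nrow(features), -sdlog^2 / 2, sdlog)
  }
  features$area[features$area < lod] <- NA_real_
  if (intensity_threshold > 0) {
    features$area[!is.na(features$area) &
                    features$area < intensity_threshold] <- NA_real_
  }

  features$rt <- unname(SYNTHETIC_RT[features$class_label])
  features$mz <- features$mz_theoretical
  if (mz_jitter_ppm > 0) {
    keys <- dplyr::distinct(features, .data$species, .data$polarity)
    keys$jitter <- stats::rnorm(nrow(keys), 0, mz_jitter_ppm)
    features <- dplyr::left_join(features, keys, by = c("species", "polarity"))
    features$mz <- features$mz * (1 + features$jitter * 1e-6)
    features$jitter <- NULL
  }
  out_features <- tibble::as_tibble(
    features[, c("mz", "rt", "polarity", "sample_id", "area")]
  )

  meta_extra <- sample_truths[!duplicated(sample_truths$sample_id),
                              intersect(c("sample_id", "group", "time_min",
                                          "replicate"), names(sample_truths)),
                              drop = FALSE]
  metadata <- tibble::tibble(sample_id = all_ids, role = unname(roles[all_ids]))
  metadata$tissue_mg <- ifelse(metadata$role == "study", tissue_mg, NA_real_)
  metadata <- dplyr::left_join(metadata, meta_extra, by = "sample_id")
  if (!"group" %in% names(metadata)) metadata$group <- NA_character_
  metadata$group[metadata$role != "study"] <- metadata$role[metadata$role != "study"]

  list(features = out_features, metadata = metadata,
       candidates = unique(panel$species))
}
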