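# Three-step quantitative data curation: blank correction, QC robustness,
# prevalence, followed by group-wise imputation. The blank step runs on
# pre-quantification intensities; the robustness and prevalence steps on
# concentrations. Steps apply in that fixed order and a species excluded at
# one step is not evaluated at later ones. "Detected" means non-missing: a
# measured zero counts as detected, censoring below the detection limit
# does not.

#' Blank filter
#'
#' Excludes species whose mean blank intensity exceeds `threshold` times the
#' mean QC intensity (strict `>`: a ratio exactly at the threshold is
#' retained).
#'
#' @param intensities Tibble `species`, `sample_id`, `area` of
#'   pre-quantification intensities (annotated, uncorrected or corrected
#'   areas both work; the ratio is scale-free).
#' @param blank_samples,qc_samples Character vectors of sample ids.
#' @param threshold Blank-to-QC ratio above which a species is excluded
#'   (default 0.20).
#' @return List with `retained` (character vector of species) and `report`
#'   (tibble `species`, `blank_mean`, `qc_mean`, `blank_ratio`, `pass`). If
#'   no blank samples are supplied the step is skipped: all species are
#'   retained and the report says so explicitly.
#' @export
blank_filter <- function(intensities, blank_samples, qc_samples, threshold = 0.20) {
  species <- sort(unique(intensities$species))
  if (length(blank_samples) == 0L) {
    return(list(
      retained = species,
      report = tibble::tibble(species = species, blank_mean = NA_real_,
                              qc_mean = NA_real_, blank_ratio = NA_real_,
                              pass = TRUE, note = "no blanks: step skipped")
    ))
  }
  if (length(qc_samples) == 0L) stop("blank filter needs QC samples", call. = FALSE)
  stats_tbl <- purrr::map_dfr(species, function(sp) {
    rows <- intensities[intensities$species == sp, ]
    blank_mean <- mean(rows$area[rows$sample_id %in% blank_samples], na.rm = TRUE)
    qc_mean <- mean(rows$area[rows$sample_id %in% qc_samples], na.rm = TRUE)
    if (is.nan(blank_mean)) blank_mean <- 0   # never detected in blanks
    ratio <- if (is.nan(qc_mean) || qc_mean == 0) Inf else blank_mean / qc_mean
    if (blank_mean == 0) ratio <- 0
    tibble::tibble(species = sp, blank_mean = blank_mean, qc_mean = qc_mean,
                   blank_ratio = ratio, pass = !(ratio > threshold),
                   note = NA_character_)
  })
  list(retained = stats_tbl$species[stats_tbl$pass], report = stats_tbl)
}

#' QC robustness filter
#'
#' Retains species detected (non-missing) in every QC sample whose QC
#' concentration coefficient of variation is below `cv_max` (strict `<`).
#'
#' @param quant Quant table (`species`, `sample_id`, `conc_nmol_mg`).
#' @param qc_samples Character vector of QC sample ids (>= 2).
#' @param cv_max Maximum coefficient of variation (default 0.20).
#' @return List with `retained` and `report` (`species`, `n_detected`,
#'   `qc_cv`, `pass`).
#' @export
robustness_filter <- function(quant, qc_samples, cv_max = 0.20) {
  if (length(qc_samples) < 2L) {
    stop("robustness filter needs at least 2 QC samples (CV undefined)",
         call. = FALSE)
  }
  species <- sort(unique(quant$species))
  report <- purrr::map_dfr(species, function(sp) {
    vals <- purrr::map_dbl(qc_samples, function(s) {
      v <- quant$conc_nmol_mg[quant$species == sp & quant$sample_id == s]
      if (length(v) == 0L) NA_real_ else v[1]
    })
    n_det <- sum(!is.na(vals))
    cv <- if (n_det == length(qc_samples)) stats::sd(vals) / mean(vals) else NA_real_
    tibble::tibble(species = sp, n_detected = n_det,
                   qc_cv = cv,
                   pass = n_det == length(qc_samples) && !is.na(cv) && cv < cv_max)
  })
  list(retained = report$species[report$pass], report = report)
}

#' Prevalence filter
#'
#' Retains species detected in at least `min_frac` of the study samples
#' (inclusive boundary).
#'
#' @param quant Quant table.
#' @param study_samples Character vector of study sample ids.
#' @param min_frac Minimum detection fraction (default 0.80).
#' @param by_group Optional named group assignment (`sample_id` -> group);
#'   when given, the fraction must be met within every group.
#' @return List with `retained` and `report` (`species`, `prevalence`,
#'   `pass`).
#' @export
prevalence_filter <- function(quant, study_samples, min_frac = 0.80,
                              by_group = NULL) {
  if (length(study_samples) == 0L) stop("no study samples", call. = FALSE)
  species <- sort(unique(quant$species))
  prev_of <- function(sp, samples) {
    vals <- purrr::map_dbl(samples, function(s) {
      v <- quant$conc_nmol_mg[quant$species == sp & quant$sample_id == s]
      if (length(v) == 0L) NA_real_ else v[1]
    })
    mean(!is.na(vals))
  }
  report <- purrr::map_dfr(species, function(sp) {
    if (is.null(by_group)) {
      prev <- prev_of(sp, study_samples)
    } else {
      prev <- min(purrr::map_dbl(split(study_samples, by_group[study_samples]),
                                 function(ss) prev_of(sp, ss)))
    }
    tibble::tibble(species = sp, prevalence = prev, pass = prev >= min_frac)
  })
  list(retained = report$species[report$pass], report = report)
}

#' Three-step QC curation cascade
#'
#' Applies blank, robustness and prevalence filters in that fixed order; a
#' species failing a step is not evaluated at the following steps, and the
#' report attributes each exclusion to the first rule it violated.
#'
#' @param intensities Pre-quantification annotated intensities (for the
#'   blank step).
#' @param quant Quant table (for robustness and prevalence).
#' @param metadata Sample metadata tibble (`sample_id`, `role`).
#' @param blank_threshold,cv_max,min_frac Step thresholds (defaults 0.20,
#'   0.20, 0.80).
#' @return An object of class `qc_filter_report`: a list with `retained`
#'   (species surviving all steps), `report` (per species: `step_failed`,
#'   the computed statistics, `pass`), and `counts` (species surviving each
#'   step). `tidy()` returns the per-species report, `glance()` the counts.
#' @export
qc_filter <- function(intensities, quant, metadata, blank_threshold = 0.20,
                      cv_max = 0.20, min_frac = 0.80) {
  blanks <- metadata$sample_id[metadata$role == "blank"]
  qcs <- metadata$sample_id[metadata$role == "QC"]
  study <- metadata$sample_id[metadata$role == "study"]

  all_species <- sort(unique(quant$species))
  b <- blank_filter(intensities[intensities$species %in% all_species, ],
                    blanks, qcs, blank_threshold)
  after_blank <- intersect(all_species, b$retained)
  r <- robustness_filter(quant[quant$species %in% after_blank, ], qcs, cv_max)
  after_robust <- r$retained
  p <- prevalence_filter(quant[quant$species %in% after_robust, ], study, min_frac)
  survivors <- p$retained

  report <- tibble::tibble(species = all_species) |>
    dplyr::left_join(b$report[, c("species", "blank_ratio")], by = "species") |>
    dplyr::left_join(r$report[, c("species", "n_detected", "qc_cv")], by = "species") |>
    dplyr::left_join(p$report[, c("species", "prevalence")], by = "species") |>
    dplyr::mutate(
      step_failed = dplyr::case_when(
        !.data$species %in% after_blank ~ "blank",
        !.data$species %in% after_robust ~ "robustness",
        !.data$species %in% survivors ~ "prevalence",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$step_failed)
    )
  out <- list(
    retained = survivors,
    report = report,
    counts = tibble::tibble(
      step = c("input", "blank", "robustness", "prevalence"),
      n_retained = c(length(all_species), length(after_blank),
                     length(after_robust), length(survivors))
    ),
    thresholds = c(blank = blank_threshold, cv = cv_max, prevalence = min_frac)
  )
  class(out) <- "qc_filter_report"
  out
}

#' @export
print.qc_filter_report <- function(x, ...) {
  cat("QC filter cascade (blank > robustness > prevalence)\n")
  cat(sprintf("  thresholds: blank ratio %.2f, QC CV %.2f, prevalence %.2f\n",
              x$thresholds["blank"], x$thresholds["cv"], x$thresholds["prevalence"]))
  print(x$counts)
  invisible(x)
}

#' Group-wise imputation of missing concentrations
#'
#' Missing values become 80% (by default) of the minimum observed
#' concentration of that species within the sample's group. Species with no
#' observed value anywhere in a group stay missing and are listed in the
#' `unimputable` attribute.
#'
#' @param quant Quant table (`species`, `sample_id`, `conc_nmol_mg`).
#' @param groups Named character vector mapping every `sample_id` to exactly
#'   one group (QCs typically form their own group).
#' @param frac Fraction of the group minimum used (default 0.8).
#' @return The quant table with missing values imputed and a logical
#'   `imputed` column; attribute `unimputable` lists species x group cells
#'   left missing.
#' @export
impute_missing <- function(quant, groups, frac = 0.8) {
  if (!all(quant$sample_id %in% names(groups))) {
    stop("every sample must be assigned to exactly one group", call. = FALSE)
  }
  quant$group <- unname(groups[quant$sample_id])
  out <- quant |>
    dplyr::group_by(.data$species, .data$group) |>
    dplyr::mutate(
      group_min = if (all(is.na(.data$conc_nmol_mg))) NA_real_
                  else min(.data$conc_nmol_mg, na.rm = TRUE),
      imputed = is.na(.data$conc_nmol_mg) & !is.na(.data$group_min),
      conc_nmol_mg = dplyr::if_else(.data$imputed, frac * .data$group_min,
                                    .data$conc_nmol_mg)
    ) |>
    dplyr::ungroup()
  unimputable <- out |>
    dplyr::filter(is.na(.data$conc_nmol_mg)) |>
    dplyr::distinct(.data$species, .data$group)
  out <- dplyr::select(out, -"group_min")
  attr(out, "unimputable") <- unimputable
  out
}
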