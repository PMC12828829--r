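# One-point internal-standard calibration to nmol per mg wet tissue.
#
# Each lipid class carries a primary deuterated internal standard spiked at a
# known per-tissue amount; the concentration of a species is the ratio of its
# isotope-corrected area to the corrected IS area, multiplied by that amount.
# A secondary (typically nondeuterated) IS back-calculated against the
# primary estimates the per-class quantification error.

#' Internal-standard mix definition
#'
#' Per lipid class label: the primary deuterated IS with its mix
#' concentration (nmol/mL) and per-tissue amount (nmol/mg), an optional
#' secondary IS with the same two values, and whether the class is reported
#' quantitatively (the neutral classes CE, Chol, DG, MG and TG are spiked
#' for monitoring only). The per-mg column is the value the calibration
#' consumes; the nmol/mL column is carried for reference (the two are not
#' mutually consistent for MG and Chol in the source mix sheet and are left
#' verbatim).
#'
#' @param path Optional path to an alternative mix sheet (tab-separated,
#'   same columns as `inst/extdata/is_mix.tsv`).
#' @return A tibble with one row per class label.
#' @export
is_mix <- function(path = NULL) {
  if (is.null(path) && !is.null(the$is_mix)) return(the$is_mix)
  file <- path %||% system.file("extdata", "is_mix.tsv", package = "lipidpipe")
  mix <- readr::read_tsv(file, col_types = "ccddcddl", progress = FALSE)
  # the sheet carries the mix's verbatim names; canonicalize via the
  # alias-aware parser so joins against annotated species always match
  mix$primary_is <- vapply(mix$primary_is,
                           function(x) parse_lipid(x)$species, character(1))
  mix$secondary_is <- vapply(mix$secondary_is, function(x) {
    if (is.na(x)) NA_character_ else parse_lipid(x)$species
  }, character(1))
  if (is.null(path)) the$is_mix <- mix
  mix
}

#' Names of all internal-standard species in a mix
#'
#' @param mix IS mix definition.
#' @return Character vector of primary and secondary IS shorthand names.
#' @export
is_species_names <- function(mix = is_mix()) {
  unique(stats::na.omit(c(mix$primary_is, mix$secondary_is)))
}

is_lookup_label <- function(class_label, mix) {
  hit <- match(class_label, mix$class_label)
  # ether classes without a dedicated IS fall back to the ester class IS
  fallback <- match(sub(" O-$", "", class_label), mix$class_label)
  ifelse(is.na(hit), fallback, hit)
}

#' Single-species one-point calibration
#'
#' `c = (area / area_IS) * is_amount_per_mg`, with both areas already
#' type I/II corrected.
#'
#' @param corrected_area Corrected peak area of the analyte.
#' @param corrected_is_area Corrected peak area of the primary IS (> 0).
#' @param is_amount_per_mg IS amount per mg wet tissue (nmol/mg).
#' @return Concentration in nmol/mg wet tissue.
#' @export
quantify_species <- function(corrected_area, corrected_is_area, is_amount_per_mg) {
  if (any(is.na(corrected_is_area)) || any(corrected_is_area <= 0)) {
    stop("internal-standard area must be positive; flag the species ",
         "unquantifiable instead of passing a zero/missing IS area",
         call. = FALSE)
  }
  (corrected_area / corrected_is_area) * is_amount_per_mg
}

#' Quantify corrected areas against the class internal standards
#'
#' For each sample x class label, the primary IS's corrected area in that
#' sample and polarity anchors a one-point calibration of every species of
#' the class. Species annotated in both polarities are reported from the
#' positive-mode value by default; the other polarity is retained in the
#' provenance columns. Species whose class IS is missing in a sample are
#' returned with `NA` concentration and `quantifiable = FALSE`, never a
#' silent zero.
#'
#' @param corrected Tibble from [correct_isotopes()] over annotated areas
#'   (columns `species`, `sample_id`, `polarity`, `class_label`, `label_d`,
#'   `corrected_area`).
#' @param mix IS mix definition, see [is_mix()].
#' @param prefer_polarity Polarity reported when a species is measured in
#'   both (default `"positive"`).
#' @param include_nonquant Also report classes marked non-quantitative in
#'   the mix (default `FALSE`).
#' @param keep_is Keep internal-standard species rows in the output
#'   (default `FALSE`).
#' @return A quant table: `species`, `class_label`, `sample_id`,
#'   `conc_nmol_mg`, `quantifiable`, plus provenance (`polarity`, `adduct`
#'   if present, `is_species`, `corrected_area`, `is_area`,
#'   `conc_other_polarity`).
#' @export
quantify <- function(corrected, mix = is_mix(),
                     prefer_polarity = c("positive", "negative"),
                     include_nonquant = FALSE, keep_is = FALSE) {
  prefer_polarity <- match.arg(prefer_polarity)
  stopifnot(all(c("species", "sample_id", "polarity", "class_label",
                  "corrected_area") %in% names(corrected)))
  is_names <- is_species_names(mix)
  idx <- is_lookup_label(corrected$class_label, mix)
  if (anyNA(idx)) {
    bad <- unique(corrected$class_label[is.na(idx)])
    stop("no internal standard defined for class label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  corrected$is_species <- mix$primary_is[idx]
  corrected$is_amount <- mix$primary_nmol_mg[idx]
  corrected$quant_class <- mix$quantitative[idx]

  is_areas <- corrected |>
    dplyr::filter(.data$species == .data$is_species) |>
    dplyr::select("sample_id", "polarity", is_species = "species",
                  is_area = "corrected_area")
  out <- corrected |>
    dplyr::left_join(is_areas, by = c("sample_id", "polarity", "is_species")) |>
    dplyr::mutate(
      quantifiable = !is.na(.data$is_area) & .data$is_area > 0,
      conc_nmol_mg = dplyr::if_else(
        .data$quantifiable,
        (.data$corrected_area / .data$is_area) * .data$is_amount,
        NA_real_
      )
    )
  if (!keep_is) out <- dplyr::filter(out, !.data$species %in% is_names)
  if (!include_nonquant) out <- dplyr::filter(out, .data$quant_class)

  # collapse to one reported value per species x sample
  out <- out |>
    dplyr::group_by(.data$species, .data$sample_id) |>
    dplyr::arrange(.data$polarity != prefer_polarity, .by_group = TRUE) |>
    dplyr::mutate(conc_other_polarity = dplyr::if_else(
      dplyr::n() > 1L, dplyr::last(.data$conc_nmol_mg), NA_real_)) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("species", "class", "class_label", "sample_id",
                                  "conc_nmol_mg", "quantifiable", "polarity",
                                  "adduct", "is_species", "corrected_area",
                                  "is_area", "conc_other_polarity")))
  dplyr::arrange(out, .data$class_label, .data$species, .data$sample_id)
}

#' Secondary-IS back-calculation error
#'
#' The secondary IS of each class is quantified against the primary IS; the
#' relative deviation of the back-calculated concentration from its nominal
#' spiked per-mg amount estimates the class quantification error:
#' `error% = |c_backcalc - c_nominal| / c_nominal * 100`.
#'
#' @param corrected Corrected areas as for [quantify()] (must include the
#'   IS species rows).
#' @param mix IS mix definition.
#' @return Tibble `class_label`, `sample_id`, `polarity`, `c_backcalc`,
#'   `c_nominal`, `error_pct`, `reason` (`NA` when computed; classes without
#'   a secondary IS or with an undetected one carry the reason instead).
#' @export
secondary_is_error <- function(corrected, mix = is_mix()) {
  quant_all <- quantify(corrected, mix, include_nonquant = TRUE, keep_is = TRUE)
  purrr::map_dfr(seq_len(nrow(mix)), function(i) {
    cls <- mix$class_label[i]
    samples <- unique(corrected$sample_id)
    if (is.na(mix$secondary_is[i])) {
      return(tibble::tibble(class_label = cls, sample_id = samples,
                            polarity = NA_character_, c_backcalc = NA_real_,
                            c_nominal = NA_real_, error_pct = NA_real_,
                            reason = "no secondary IS"))
    }
    rows <- quant_all[quant_all$species == mix$secondary_is[i], ]
    purrr::map_dfr(samples, function(s) {
      r <- rows[rows$sample_id == s, ]
      if (nrow(r) == 0L || !isTRUE(r$quantifiable[1])) {
        return(tibble::tibble(class_label = cls, sample_id = s,
                              polarity = NA_character_, c_backcalc = NA_real_,
                              c_nominal = mix$secondary_nmol_mg[i],
                              error_pct = NA_real_,
                              reason = "secondary IS not detected"))
      }
      tibble::tibble(class_label = cls, sample_id = s, polarity = r$polarity[1],
                     c_backcalc = r$conc_nmol_mg[1],
                     c_nominal = mix$secondary_nmol_mg[i],
                     error_pct = abs(r$conc_nmol_mg[1] - mix$secondary_nmol_mg[i]) /
                       mix$secondary_nmol_mg[i] * 100,
                     reason = NA_character_)
    })
  })
}

#' Advisory check of analyte-to-IS area ratios
#'
#' The mix is designed so that the most abundant species of each class sits
#' at roughly 2-3 times its primary IS area; ratios far outside that band
#' suggest the one-point calibration is extrapolating.
#'
#' @param corrected Corrected areas as for [quantify()].
#' @param mix IS mix definition.
#' @param band Acceptable range of the class maximum analyte/IS ratio.
#' @return Tibble `class_label`, `sample_id`, `max_ratio`, `within_band`.
#' @export
is_design_check <- function(corrected, mix = is_mix(), band = c(2, 3)) {
  is_names <- is_species_names(mix)
  idx <- is_lookup_label(corrected$class_label, mix)
  corrected$is_species <- mix$primary_is[idx]
  is_areas <- corrected |>
    dplyr::filter(.data$species == .data$is_species) |>
    dplyr::select("sample_id", "polarity", is_species = "species",
                  is_area = "corrected_area")
  corrected |>
    dplyr::filter(!.data$species %in% is_names) |>
    dplyr::left_join(is_areas, by = c("sample_id", "polarity", "is_species")) |>
    dplyr::filter(!is.na(.data$is_area), .data$is_area > 0) |>
    dplyr::group_by(.data$class_label, .data$sample_id) |>
    dplyr::summarise(max_ratio = max(.data$corrected_area / .data$is_area),
                     .groups = "drop") |>
    dplyr::mutate(within_band = .data$max_ratio >= band[1] & .data$max_ratio <= band[2])
}
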