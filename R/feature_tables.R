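# MarkerLynx-style exported feature tables and species annotation.
#
# On disk a feature table is tab-separated text with header
# "mz\trt\t<sample ids...>" (decimal point, UTF-8), one file per ionization
# polarity; empty cells are missing (distinct from a measured zero). In
# memory the long form is used: one row per feature x sample.

#' Read a sample metadata sheet
#'
#' @param path CSV with columns `sample_id`, `role` (`study`/`QC`/`blank`),
#'   and optionally `group`, `time_min`, `phase`, `tissue_mg`.
#' @return A tibble, validated: roles are one of study/QC/blank and study
#'   samples carry a positive tissue mass when the column is present.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  stopifnot(all(c("sample_id", "role") %in% names(meta)))
  bad <- setdiff(unique(meta$role), c("study", "QC", "blank"))
  if (length(bad)) {
    stop("unknown sample role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if ("tissue_mg" %in% names(meta)) {
    study <- meta[meta$role == "study", ]
    if (any(!is.na(study$tissue_mg) & study$tissue_mg <= 0)) {
      stop("study samples must have positive tissue mass", call. = FALSE)
    }
  }
  meta
}

#' Read a tab-separated feature table
#'
#' @param path Tab-separated file, header `mz`, `rt`, then one column per
#'   sample; peak areas are non-negative, empty cells are missing.
#' @param metadata Sample metadata tibble (or path to its CSV); every sample
#'   column must be present in the metadata.
#' @param polarity Ionization polarity of this export, `"positive"` or
#'   `"negative"`.
#' @return Long tibble: `mz`, `rt`, `polarity`, `sample_id`, `area`.
#' @export
read_feature_table <- function(path, metadata, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  validate_metadata(metadata)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  if (!all(c("mz", "rt") %in% names(raw))) {
    stop("feature table must start with 'mz' and 'rt' columns", call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), c("mz", "rt"))
  unmapped <- setdiff(sample_cols, metadata$sample_id)
  if (length(unmapped)) {
    stop("sample column(s) not in metadata: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("mz", "rt", sample_cols)) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      stop("malformed numeric cell in column '", col, "', row ", bad[1],
           ": '", vals[bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (any(raw$mz <= 0)) stop("m/z values must be positive", call. = FALSE)
  if (anyDuplicated(raw[, c("mz", "rt")])) {
    stop("duplicate (mz, rt, polarity) feature keys", call. = FALSE)
  }
  long <- tidyr::pivot_longer(raw, dplyr::all_of(sample_cols),
                              names_to = "sample_id", values_to = "area")
  long$polarity <- polarity
  tibble::as_tibble(long[, c("mz", "rt", "polarity", "sample_id", "area")])
}

#' Write a long feature table back to the tab-separated dialect
#'
#' Inverse of [read_feature_table()] for a single polarity; missing areas
#' become empty cells.
#'
#' @param features Long feature tibble (one polarity).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(length(unique(features$polarity)) == 1L)
  wide <- tidyr::pivot_wider(features[, c("mz", "rt", "sample_id", "area")],
                             names_from = "sample_id", values_from = "area")
  wide <- dplyr::arrange(wide, .data$mz, .data$rt)
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Build an annotation candidate list
#'
#' Theoretical m/z values of species under their class adduct in each
#' polarity where the class ionizes.
#'
#' @param species Character vector of shorthand names.
#' @param registry Lipid class registry.
#' @param polarities Polarities to enumerate.
#' @return Tibble: parsed species columns plus `polarity`, `adduct`,
#'   `mz_theoretical`.
#' @export
adduct_candidates <- function(species, registry = lipid_registry(),
                              polarities = c("positive", "negative")) {
  parsed <- parse_lipids(unique(species), registry)
  purrr::map_dfr(polarities, function(pol) {
    add <- class_adduct(parsed$class, pol, registry)
    keep <- !is.na(add)
    if (!any(keep)) return(tibble::tibble())
    out <- parsed[keep, ]
    out$polarity <- pol
    out$adduct <- add[keep]
    out$mz_theoretical <- vapply(seq_len(nrow(out)), function(i) {
      lipid_mz(out[i, ], pol, registry = registry)
    }, numeric(1))
    out
  })
}

#' Default retention-time windows from internal-standard features
#'
#' The class windows are anchored by the spiked internal standards: for each
#' class the feature matching the primary IS m/z (within `tol_ppm`, by
#' m/z alone) defines the window center, extended by `halfwidth` minutes.
#'
#' @param features Long feature tibble.
#' @param mix IS mix definition, see [is_mix()].
#' @param registry Lipid class registry.
#' @param tol_ppm Mass tolerance for locating IS features.
#' @param halfwidth Window half width in minutes.
#' @return Tibble `class_label`, `rt_min`, `rt_max` (classes whose IS is not
#'   found are omitted).
#' @export
infer_rt_windows <- function(features, mix = is_mix(), registry = lipid_registry(),
                             tol_ppm = 10, halfwidth = 0.5) {
  purrr::map_dfr(seq_len(nrow(mix)), function(i) {
    sp <- parse_lipid(mix$primary_is[i], registry)
    hits <- purrr::map_dfr(c("positive", "negative"), function(pol) {
      add <- class_adduct(sp$class, pol, registry)
      if (is.na(add)) return(tibble::tibble())
      mz0 <- lipid_mz(sp, pol, registry = registry)
      f <- features[features$polarity == pol &
                      abs(features$mz - mz0) / mz0 * 1e6 <= tol_ppm, ]
      f
    })
    if (nrow(hits) == 0L) return(tibble::tibble())
    tibble::tibble(class_label = mix$class_label[i],
                   rt_min = min(hits$rt) - halfwidth,
                   rt_max = max(hits$rt) + halfwidth)
  })
}

#' Annotate features with lipid species
#'
#' A feature matches a candidate iff the relative mass error is within
#' `tol_ppm`, the retention time lies inside the candidate class's window,
#' and the polarity agrees. Ties are broken by smallest absolute ppm error,
#' then by the class whose window center is nearest. Each species keeps only
#' its best-matching feature per polarity; displaced features are reported
#' with status `"shadowed"`.
#'
#' @param features Long feature tibble from [read_feature_table()].
#' @param candidates Candidate tibble from [adduct_candidates()].
#' @param tol_ppm Mass tolerance (ppm), default 10.
#' @param rt_windows Tibble `class_label`, `rt_min`, `rt_max`; must cover
#'   every candidate class label.
#' @return Long annotated tibble: feature key columns, `species`, `adduct`,
#'   `ppm_error`, `sample_id`, `area`, parsed species columns, and `status`
#'   (`"matched"` or `"shadowed"`).
#' @export
match_features <- function(features, candidates, tol_ppm = 10, rt_windows) {
  stopifnot(tol_ppm > 0)
  missing_cls <- setdiff(unique(candidates$class_label), rt_windows$class_label)
  if (length(missing_cls)) {
    stop("no retention-time window for class label(s): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  cand <- dplyr::left_join(candidates, rt_windows, by = "class_label")
  cand$rt_center <- (cand$rt_min + cand$rt_max) / 2

  keys <- dplyr::distinct(features, .data$mz, .data$rt, .data$polarity)
  keys$feature_id <- seq_len(nrow(keys))

  pairs <- dplyr::inner_join(keys, cand, by = "polarity",
                             relationship = "many-to-many")
  pairs$ppm_error <- (pairs$mz - pairs$mz_theoretical) / pairs$mz_theoretical * 1e6
  pairs <- pairs[abs(pairs$ppm_error) <= tol_ppm &
                   pairs$rt >= pairs$rt_min & pairs$rt <= pairs$rt_max, ]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble())
  }
  # one species per feature: smallest |ppm|, then nearest window center
  pairs <- pairs |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::arrange(abs(.data$ppm_error), abs(.data$rt - .data$rt_center),
                   .data$species, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  # one feature per species per polarity: best |ppm| wins, rest shadowed
  pairs <- pairs |>
    dplyr::group_by(.data$species, .data$polarity) |>
    dplyr::arrange(abs(.data$ppm_error), .data$feature_id, .by_group = TRUE) |>
    dplyr::mutate(status = ifelse(dplyr::row_number() == 1L, "matched", "shadowed")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$feature_id)

  out <- dplyr::inner_join(features,
                           pairs[, c("mz", "rt", "polarity", "species", "adduct",
                                     "ppm_error", "status", "class", "class_label",
                                     "carbons", "db", "oxygens", "linkage",
                                     "label_d")],
                           by = c("mz", "rt", "polarity"))
  tibble::as_tibble(out)
}

#' Annotation report for audit
#'
#' One row per annotated feature (sample dimension collapsed), suitable for
#' writing as CSV.
#'
#' @param annotated Output of [match_features()].
#' @return Tibble with feature key, species, adduct, ppm error and status.
#' @export
annotation_report <- function(annotated) {
  dplyr::distinct(annotated, .data$mz, .data$rt, .data$polarity, .data$species,
                  .data$adduct, .data$ppm_error, .data$status)
}
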