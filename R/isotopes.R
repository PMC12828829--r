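# Isotopologue envelopes and the type I / type II isotopic corrections.
#
# The envelope p0..pK aggregates isotopologues by nominal mass shift
# (nucleon count above the monoisotopic form), the resolution at which a
# 20 mDa extraction window operates. Deuterium label positions are fixed
# (abundance 1) and contribute no envelope spread; their mass is carried by
# the composition itself.

element_shift_pmf <- function(element, K, abundances = isotope_abundances()) {
  rows <- abundances[abundances$element == element, ]
  if (nrow(rows) == 0L) {
    stop("no isotope abundance data for element '", element, "'", call. = FALSE)
  }
  pmf <- numeric(K + 1L)
  keep <- rows$shift <= K
  pmf[rows$shift[keep] + 1L] <- rows$abundance[keep]
  pmf
}

conv_trunc <- function(a, b, K) {
  out <- numeric(K + 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), K + 2L - i)
    if (jmax < 1L) break
    idx <- i + seq_len(jmax) - 1L
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

pmf_power <- function(pmf, n, K) {
  result <- c(1, numeric(K))
  base <- pmf
  while (n > 0L) {
    if (n %% 2L == 1L) result <- conv_trunc(result, base, K)
    base <- conv_trunc(base, base, K)
    n <- n %/% 2L
  }
  result
}

#' Isotopologue envelope of an elemental composition
#'
#' Probabilities of the monoisotopic through +K nominal-mass isotopologues,
#' computed by convolving per-element natural-abundance distributions.
#' Deuterium label atoms (`D`) are treated as fixed.
#'
#' @param comp Elemental composition (named counts or formula string).
#' @param K Highest nominal shift retained (default 6 covers lipid-sized
#'   molecules to better than 1e-3 total mass).
#' @param abundances Abundance table, see [isotope_abundances()].
#' @return Numeric vector `p0..pK` (names `"p0"`, `"p1"`, ...). The sum is
#'   at most 1; the truncated tail is not renormalized.
#' @export
isotope_envelope <- function(comp, K = 6L, abundances = isotope_abundances()) {
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- comp_canon(comp)
  if (sum(comp) == 0L) stop("empty composition", call. = FALSE)
  env <- c(1, numeric(K))
  for (el in names(comp)[comp > 0]) {
    pmf <- element_shift_pmf(el, K, abundances)
    env <- conv_trunc(env, pmf_power(pmf, comp[[el]], K), K)
  }
  stats::setNames(env, paste0("p", 0:K))
}

#' Envelopes for a set of species
#'
#' @param species Character vector of shorthand names (or parsed tibble).
#' @param registry Lipid class registry.
#' @param K Highest nominal shift retained.
#' @return A tibble `species`, `shift`, `p` in long form.
#' @export
envelope_table <- function(species, registry = lipid_registry(), K = 6L) {
  if (is.character(species)) species <- parse_lipids(species, registry)
  purrr::map_dfr(seq_len(nrow(species)), function(i) {
    env <- isotope_envelope(lipid_composition(species[i, ], registry), K)
    tibble::tibble(species = species$species[i], shift = 0:K, p = unname(env))
  })
}

#' Type I and type II isotopic correction of peak areas
#'
#' Under lipid-class separation, all species of one class co-elute, and the
#' monoisotopic extraction window of a species also captures the +2
#' isotopologue of the species with the same carbon number and one more
#' double bond (mass spacing 2.01565 vs 2.00671 Da, inside a 20 mDa
#' window). Species are therefore processed from most to least unsaturated
#' within each carbon number: the interferer's contribution
#' `T(L) * p2(L)` is subtracted (type II) before dividing by the species'
#' own monoisotopic fraction `p0` (type I):
#' `T(S) = (area(S) - T(L) p2(L)) / p0(S)`.
#'
#' @param areas A tibble with one row per species x sample, columns
#'   `species`, `sample_id`, `area`, and (from [parse_lipids()] or
#'   annotation) `class`, `class_label`, `carbons`, `db`, `label_d`; an
#'   optional `adduct`/`polarity` column joins the grouping.
#' @param registry Lipid class registry.
#' @param K Envelope length used (>= 2).
#' @return The input tibble with columns `corrected_area` (the
#'   interference-free total-species area) and `clamped` (`TRUE` where a
#'   negative intermediate was clamped to zero; a warning summarizes these).
#' @export
correct_isotopes <- function(areas, registry = lipid_registry(), K = 4L) {
  stopifnot(all(c("species", "area") %in% names(areas)))
  if (anyNA(areas$area)) {
    stop("correct_isotopes() expects non-missing areas; drop missing rows first",
         call. = FALSE)
  }
  if (!"sample_id" %in% names(areas)) areas$sample_id <- "sample"
  need <- c("class", "class_label", "carbons", "db")
  if (!all(need %in% names(areas))) {
    areas <- dplyr::left_join(
      areas, parse_lipids(unique(areas$species), registry), by = "species"
    )
  }
  key_cols <- intersect(c("species", "sample_id", "polarity", "adduct"),
                        names(areas))
  if (nrow(dplyr::distinct(areas[, key_cols])) != nrow(areas)) {
    stop("duplicate species/sample keys in input areas", call. = FALSE)
  }

  envs <- dplyr::distinct(areas, .data$species)
  envs <- dplyr::bind_rows(lapply(envs$species, function(sp) {
    e <- isotope_envelope(lipid_composition(sp, registry), K = max(2L, K))
    tibble::tibble(species = sp, p0 = e[["p0"]], p2 = e[["p2"]])
  }))
  areas <- dplyr::left_join(areas, envs, by = "species")

  grouping <- intersect(c("sample_id", "class_label", "adduct", "polarity", "label_d"),
                        names(areas))
  out <- areas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::group_modify(~ deconvolve_group(.x)) |>
    dplyr::ungroup()
  n_clamped <- sum(out$clamped)
  if (n_clamped > 0L) {
    warning(n_clamped, " corrected area(s) clamped to zero (interference ",
            "exceeded the measured monoisotopic area)", call. = FALSE)
  }
  out
}

# Within one class/adduct/sample group: sequential +2 deconvolution.
deconvolve_group <- function(g) {
  g <- dplyr::arrange(g, .data$carbons, dplyr::desc(.data$db))
  g$corrected_area <- NA_real_
  g$clamped <- FALSE
  for (i in seq_len(nrow(g))) {
    interference <- 0
    if (i > 1L && g$carbons[i - 1L] == g$carbons[i] &&
        g$db[i - 1L] == g$db[i] + 1L) {
      interference <- g$corrected_area[i - 1L] * g$p2[i - 1L]
    }
    num <- g$area[i] - interference
    if (num < 0) {
      g$clamped[i] <- TRUE
      num <- 0
    }
    g$corrected_area[i] <- num / g$p0[i]
  }
  g
}
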