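# Liquid-liquid fractionation summaries: per-class partitioning between the
# methanol-rich and hexane-rich phases across water contents, percent-change
# summaries against the anhydrous reference, and one-way ANOVA with Tukey
# HSD plus a compact letter display.

#' MeOH-rich phase fractions
#'
#' For each class x condition x replicate with both phases measured,
#' `f = A_MeOH / (A_MeOH + A_hexane)`. Classes analysed only in the
#' MeOH-rich phase (the negative-mode-only classes PG, PI, PS) have no
#' complement and are returned with `NA` and a reason, as are observations
#' where both areas are zero.
#'
#' @param obs Tidy partition observations: `class_label`, `water_pct`,
#'   `phase` (`"MeOH"` or `"hexane"`), `replicate`, `area`.
#' @return Tibble `class_label`, `water_pct`, `replicate`, `area_meoh`,
#'   `area_hexane`, `fraction_meoh`, `reason`.
#' @export
partition_fractions <- function(obs) {
  stopifnot(all(c("class_label", "water_pct", "phase", "replicate", "area")
                %in% names(obs)))
  bad <- setdiff(unique(obs$phase), c("MeOH", "hexane"))
  if (length(bad)) stop("unknown phase label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  wide <- tidyr::pivot_wider(obs, names_from = "phase", values_from = "area")
  if (!"MeOH" %in% names(wide)) wide$MeOH <- NA_real_
  if (!"hexane" %in% names(wide)) wide$hexane <- NA_real_
  wide |>
    dplyr::mutate(
      area_meoh = .data$MeOH, area_hexane = .data$hexane,
      fraction_meoh = dplyr::case_when(
        is.na(.data$MeOH) | is.na(.data$hexane) ~ NA_real_,
        .data$MeOH + .data$hexane == 0 ~ NA_real_,
        TRUE ~ .data$MeOH / (.data$MeOH + .data$hexane)
      ),
      reason = dplyr::case_when(
        is.na(.data$MeOH) | is.na(.data$hexane) ~ "one phase not measured",
        .data$MeOH + .data$hexane == 0 ~ "both areas zero",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("class_label", "water_pct", "replicate", "area_meoh",
                  "area_hexane", "fraction_meoh", "reason")
}

#' Percent change relative to a reference condition
#'
#' Reductions are positive: `100 * (reference - condition) / reference`.
#'
#' @param condition Total at the condition of interest.
#' @param reference Total at the reference condition (> 0); the anhydrous
#'   (0% water) condition by convention.
#' @return Signed percent change (positive = reduction).
#' @export
percent_change <- function(condition, reference) {
  if (any(reference <= 0)) stop("reference total must be positive", call. = FALSE)
  100 * (reference - condition) / reference
}

#' Per-class percent change across water contents
#'
#' Summarises phase totals per water content and expresses each condition as
#' a percent reduction versus the reference water content.
#'
#' @param obs Partition observations (see [partition_fractions()]).
#' @param phase Phase to summarise (default `"MeOH"`).
#' @param reference_water Reference water content (default 0).
#' @return Tibble `class_label`, `water_pct`, `mean_total`,
#'   `reduction_pct`.
#' @export
partition_percent_change <- function(obs, phase = "MeOH", reference_water = 0) {
  totals <- obs[obs$phase == phase, ] |>
    dplyr::group_by(.data$class_label, .data$water_pct) |>
    dplyr::summarise(mean_total = mean(.data$area, na.rm = TRUE), .groups = "drop")
  totals |>
    dplyr::group_by(.data$class_label) |>
    dplyr::mutate(reduction_pct = percent_change(
      .data$mean_total,
      .data$mean_total[.data$water_pct == reference_water][1])) |>
    dplyr::ungroup()
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' All pairwise comparisons with Tukey family-wise adjustment; groups are
#' assigned letters by insert-and-absorb over the significance graph, so
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (defaults `"value"`, `"group"`).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `lipid_tukey`; `tidy()` gives the pairwise table
#'   (`comparison`, `estimate`, `adj_p`, `significant`), `glance()` the
#'   ANOVA summary; `$letters` maps each group to its letters.
#' @export
anova_tukey <- function(data, value = "value", group = "group", alpha = 0.05) {
  d <- tibble::tibble(value = data[[value]], group = as.character(data[[group]]))
  d <- d[!is.na(d$value), ]
  counts <- table(d$group)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("every group needs at least 2 replicates (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")", call. = FALSE)
  }
  d$group <- factor(d$group)
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit)$group
  an <- summary(fit)[[1]]
  pairwise <- tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    adj_p = tk[, "p adj"],
    significant = tk[, "p adj"] <= alpha
  )
  letters_map <- compact_letters(pairwise, levels(d$group))
  out <- list(
    pairwise = pairwise,
    letters = letters_map,
    anova = tibble::tibble(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                           df1 = an$Df[1], df2 = an$Df[2]),
    alpha = alpha, fit = fit
  )
  class(out) <- "lipid_tukey"
  out
}

#' @export
print.lipid_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA, F(%d, %d) = %.3f, p = %.4g; Tukey HSD at alpha %g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p, x$alpha))
  print(x$letters)
  invisible(x)
}

# Insert-and-absorb compact letter display. Each significant pair must be
# separated in every letter set; each group must appear in at least one set.
compact_letters <- function(pairwise, groups) {
  n <- length(groups)
  sig <- matrix(FALSE, n, n, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    gs <- strsplit(pairwise$comparison[i], "-", fixed = TRUE)[[1]]
    if (length(gs) != 2L || !all(gs %in% groups)) next
    if (pairwise$significant[i]) {
      sig[gs[1], gs[2]] <- TRUE
      sig[gs[2], gs[1]] <- TRUE
    }
  }
  sets <- list(groups)  # start with one set holding everything
  for (g1 in groups) {
    for (g2 in groups) {
      if (g1 >= g2 || !sig[g1, g2]) next
      for (k in seq_along(sets)) {
        s <- sets[[k]]
        if (all(c(g1, g2) %in% s)) {
          # split the offending set into two, dropping one member each
          sets[[k]] <- setdiff(s, g1)
          sets[[length(sets) + 1L]] <- setdiff(s, g2)
        }
      }
      # absorb: drop sets contained in another set
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(sets[[a]] %in% sets[[b]]) && length(sets[[a]]) < length(sets[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(sets[keep])
    }
  }
  labels <- letters[seq_along(sets)]
  tibble::tibble(
    group = groups,
    letters = vapply(groups, function(g) {
      paste(labels[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
    }, character(1))
  )
}
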