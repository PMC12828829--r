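# Lipidome-stability statistics: hydrolysis ratios over storage time,
# baseline normalization, relative class totals, and the group-comparison
# machinery (one-way ANOVA with Dunnett many-to-one contrasts, Welch t,
# volcano, PCA).

#' Default degradation/precursor class pairs
#'
#' The four glycerophospholipid pairs plus the neutral-lipid pairs tracked
#' alongside them.
#'
#' @return Tibble `degradation`, `precursor` of class labels.
#' @export
default_hydrolysis_pairs <- function() {
  tibble::tribble(
    ~degradation, ~precursor,
    "LPC",    "PC",
    "LPC O-", "PC O-",
    "LPE",    "PE",
    "LPE O-", "PE O-",
    "DG",     "TG",
    "MG",     "DG",
    "Chol",   "CE"
  )
}

#' Per-sample class totals of corrected areas
#'
#' @param areas Tibble with `sample_id`, `class_label`, an area column, and
#'   `label_d` (deuterated internal standards are excluded).
#' @param value Name of the area column (default `"corrected_area"`).
#' @return Tibble `sample_id`, `class_label`, `total`.
#' @export
class_totals <- function(areas, value = "corrected_area") {
  stopifnot(value %in% names(areas))
  if ("label_d" %in% names(areas)) areas <- areas[areas$label_d == 0L, ]
  areas |>
    dplyr::group_by(.data$sample_id, .data$class_label) |>
    dplyr::summarise(total = sum(.data[[value]], na.rm = TRUE), .groups = "drop")
}

#' Hydrolysis ratios per sample
#'
#' The total area of each degradation class relative to the total area of
#' its precursor class. A zero degradation total gives ratio 0; a zero or
#' absent precursor total gives `NA` with the reason recorded.
#'
#' @param totals Class totals from [class_totals()].
#' @param pairs Degradation/precursor pairs (default
#'   [default_hydrolysis_pairs()]); pairs whose classes are absent from the
#'   data are dropped.
#' @return Tibble `sample_id`, `degradation`, `precursor`, `pair`, `ratio`,
#'   `reason`.
#' @export
hydrolysis_ratios <- function(totals, pairs = default_hydrolysis_pairs()) {
  present <- unique(totals$class_label)
  pairs <- pairs[pairs$degradation %in% present & pairs$precursor %in% present, ]
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    deg <- totals[totals$class_label == pairs$degradation[i], ]
    pre <- totals[totals$class_label == pairs$precursor[i], ]
    joined <- dplyr::inner_join(
      dplyr::select(deg, "sample_id", deg_total = "total"),
      dplyr::select(pre, "sample_id", pre_total = "total"),
      by = "sample_id"
    )
    joined |>
      dplyr::mutate(
        degradation = pairs$degradation[i], precursor = pairs$precursor[i],
        pair = paste0(pairs$degradation[i], "/", pairs$precursor[i]),
        ratio = dplyr::if_else(.data$pre_total > 0,
                               .data$deg_total / .data$pre_total, NA_real_),
        reason = dplyr::if_else(.data$pre_total > 0, NA_character_,
                                "precursor total is zero")
      ) |>
      dplyr::select("sample_id", "degradation", "precursor", "pair", "ratio",
                    "reason")
  })
}

#' Normalize a replicate series to its baseline mean
#'
#' Each value is scaled by `100 / mean(baseline values)` within the series,
#' so the baseline time point averages exactly 100%.
#'
#' @param series Tibble with a time column, a value column and optionally
#'   series identifiers.
#' @param time Name of the time column (minutes; default `"time_min"`).
#' @param value Name of the value column (default `"ratio"`).
#' @param t0 Baseline time point (default 0).
#' @param by Character vector of columns identifying independent series
#'   (default `"pair"` if present).
#' @return The input with a `normalized_pct` column; series with a zero or
#'   missing baseline mean get `NA` and a `norm_reason`.
#' @export
normalize_baseline <- function(series, time = "time_min", value = "ratio",
                               t0 = 0, by = intersect("pair", names(series))) {
  stopifnot(time %in% names(series), value %in% names(series))
  norm_one <- function(g) {
    base <- g[[value]][g[[time]] == t0]
    base <- base[!is.na(base)]
    if (length(base) == 0L) {
      g$normalized_pct <- NA_real_
      g$norm_reason <- "no baseline replicates"
    } else if (mean(base) == 0) {
      g$normalized_pct <- NA_real_
      g$norm_reason <- "baseline mean is zero"
    } else {
      g$normalized_pct <- g[[value]] * 100 / mean(base)
      g$norm_reason <- NA_character_
    }
    g
  }
  if (length(by) == 0L) return(norm_one(series))
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ norm_one(.x)) |>
    dplyr::ungroup()
}

#' Relative class (or species) totals scaled to the baseline group
#'
#' The heatmap-style matrix: per class label (or species), totals are scaled
#' so the baseline group's mean is 100%.
#'
#' @param totals Tibble `sample_id`, `class_label` (or `species`), `total`,
#'   plus a grouping column such as `time_min`.
#' @param group Name of the grouping column (default `"time_min"`).
#' @param baseline Baseline group value (default 0).
#' @param by Row identifier column (default `"class_label"`).
#' @return Input with `relative_pct` (and `norm_reason`).
#' @export
relative_class_totals <- function(totals, group = "time_min", baseline = 0,
                                  by = "class_label") {
  normalize_baseline(totals, time = group, value = "total", t0 = baseline,
                     by = by) |>
    dplyr::rename(relative_pct = "normalized_pct")
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way ANOVA and compares every non-control group against the
#' control with family-wise adjusted p-values (single-step multivariate-t
#' adjustment).
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (defaults `"value"`, `"group"`).
#' @param control Control group level.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return Object of class `lipid_dunnett`; `tidy()` gives one row per
#'   comparison (`comparison`, `estimate`, `statistic`, `adj_p`,
#'   `significant`), `glance()` the ANOVA F and p.
#' @export
anova_dunnett <- function(data, value = "value", group = "group", control,
                          alpha = 0.05) {
  d <- tibble::tibble(value = data[[value]], group = as.character(data[[group]]))
  if (anyNA(d$value)) d <- d[!is.na(d$value), ]
  counts <- table(d$group)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("every group needs at least 2 replicates (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")", call. = FALSE)
  }
  if (!control %in% d$group) stop("control group not present", call. = FALSE)
  d$group <- stats::relevel(factor(d$group), ref = as.character(control))
  fit <- stats::aov(value ~ group, data = d)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(glt)
  an <- summary(fit)[[1]]
  out <- list(
    comparisons = tibble::tibble(
      comparison = names(sm$test$coefficients),
      estimate = unname(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      adj_p = unname(sm$test$pvalues),
      significant = unname(sm$test$pvalues) <= alpha
    ),
    anova = tibble::tibble(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                           df1 = an$Df[1], df2 = an$Df[2]),
    control = control, alpha = alpha, fit = fit
  )
  class(out) <- "lipid_dunnett"
  out
}

#' @export
print.lipid_dunnett <- function(x, ...) {
  cat("One-way ANOVA with Dunnett comparisons vs '", x$control, "'\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$anova$df1, x$anova$df2,
              x$anova$F, x$anova$p))
  print(x$comparisons)
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unpaired t with the Satterthwaite degrees-of-freedom correction. Two
#' degenerate identical zero-variance groups give `p = 1` by convention
#' (reported in `note`) rather than an error.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return Tibble `t`, `df`, `p`, `mean_a`, `mean_b`, `note`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(
      t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
      df = NA_real_, p = if (same) 1 else 0,
      mean_a = mean(a), mean_b = mean(b),
      note = "zero variance in both groups; p by convention"
    ))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 note = NA_character_)
}

#' Volcano analysis of two groups
#'
#' Per species: fold change `mean_a / mean_b` and a Welch t p-value (on
#' log-transformed concentrations by default), flagged when
#' `|log2 FC| >= log2(fc_threshold)` and `p <= alpha`.
#'
#' @param quant Quant table (`species`, `sample_id`, `conc_nmol_mg`).
#' @param samples_a,samples_b Sample ids of the two groups.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param log_scale Run the t-test on log-transformed values (default
#'   `TRUE`); the fold change is always computed on the raw scale.
#' @return Object of class `lipid_volcano`; `tidy()` gives `species`,
#'   `fc`, `log2_fc`, `p`, `flagged`, `reason`.
#' @export
volcano <- function(quant, samples_a, samples_b, fc_threshold = 2, alpha = 0.05,
                    log_scale = TRUE) {
  species <- sort(unique(quant$species))
  res <- purrr::map_dfr(species, function(sp) {
    rows <- quant[quant$species == sp, ]
    a <- rows$conc_nmol_mg[rows$sample_id %in% samples_a]
    b <- rows$conc_nmol_mg[rows$sample_id %in% samples_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(tibble::tibble(species = sp, fc = NA_real_, log2_fc = NA_real_,
                            p = NA_real_, flagged = FALSE,
                            reason = "fewer than 2 values in a group"))
    }
    if (mean(b) == 0) {
      return(tibble::tibble(species = sp, fc = NA_real_, log2_fc = NA_real_,
                            p = NA_real_, flagged = FALSE,
                            reason = "reference group mean is zero"))
    }
    fc <- mean(a) / mean(b)
    tt <- if (log_scale && all(a > 0) && all(b > 0)) {
      welch_t(log2(a), log2(b))
    } else {
      welch_t(a, b)
    }
    tibble::tibble(species = sp, fc = fc, log2_fc = log2(fc), p = tt$p,
                   flagged = abs(log2(fc)) >= log2(fc_threshold) & tt$p <= alpha,
                   reason = NA_character_)
  })
  out <- list(results = res, fc_threshold = fc_threshold, alpha = alpha)
  class(out) <- "lipid_volcano"
  out
}

#' @export
print.lipid_volcano <- function(x, ...) {
  cat(sprintf("Volcano analysis: %d species, %d flagged (FC >= %g, p <= %g)\n",
              nrow(x$results), sum(x$results$flagged, na.rm = TRUE),
              x$fc_threshold, x$alpha))
  invisible(x)
}

#' Principal component analysis of a quant matrix
#'
#' Centered (optionally unit-variance scaled) PCA of samples x species.
#' Missing values must be imputed beforehand.
#'
#' @param quant Quant table (`species`, `sample_id`, `conc_nmol_mg`),
#'   complete cases only.
#' @param n_components Number of components kept; silently truncated to the
#'   matrix rank with a note.
#' @param scale Unit-variance scaling (default `TRUE`); zero-variance
#'   species are dropped before scaling.
#' @return Object of class `lipid_pca` with `scores`, `loadings`,
#'   `explained_variance` (ratios), `note`. `tidy()` returns the scores.
#' @export
pca_scores <- function(quant, n_components = 2, scale = TRUE) {
  wide <- tidyr::pivot_wider(quant[, c("species", "sample_id", "conc_nmol_mg")],
                             names_from = "species", values_from = "conc_nmol_mg")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$sample_id
  if (anyNA(mat)) stop("missing values present: impute before PCA", call. = FALSE)
  if (nrow(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (scale) {
    keep <- apply(mat, 2, stats::sd) > 0
    mat <- mat[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)
  rank <- ncol(pc$x)
  note <- NA_character_
  if (n_components > rank) {
    note <- sprintf("requested %d components, rank allows %d", n_components, rank)
    n_components <- rank
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores$sample_id <- rownames(mat)
  loadings <- tibble::as_tibble(pc$rotation[, seq_len(n_components), drop = FALSE])
  loadings$species <- rownames(pc$rotation)
  out <- list(scores = scores[, c("sample_id", setdiff(names(scores), "sample_id"))],
              loadings = loadings[, c("species", setdiff(names(loadings), "species"))],
              explained_variance = ev[seq_len(n_components)],
              note = note)
  class(out) <- "lipid_pca"
  out
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "species\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
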