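# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname anova_dunnett
#' @param x A `lipid_dunnett` object.
#' @param ... Unused.
#' @exportS3Method
tidy.lipid_dunnett <- function(x, ...) x$comparisons

#' @rdname anova_dunnett
#' @exportS3Method
glance.lipid_dunnett <- function(x, ...) x$anova

#' @rdname anova_tukey
#' @param x A `lipid_tukey` object.
#' @param ... Unused.
#' @exportS3Method
tidy.lipid_tukey <- function(x, ...) {
  dplyr::left_join(
    x$pairwise,
    tidyr::separate(x$pairwise[, "comparison"], "comparison",
                    into = c("group_a", "group_b"), sep = "-", remove = FALSE),
    by = "comparison"
  )
}

#' @rdname anova_tukey
#' @exportS3Method
glance.lipid_tukey <- function(x, ...) x$anova

#' @rdname volcano
#' @param x A `lipid_volcano` object.
#' @param ... Unused.
#' @exportS3Method
tidy.lipid_volcano <- function(x, ...) x$results

#' @rdname volcano
#' @exportS3Method
glance.lipid_volcano <- function(x, ...) {
  tibble::tibble(n_species = nrow(x$results),
                 n_flagged = sum(x$results$flagged, na.rm = TRUE),
                 fc_threshold = x$fc_threshold, alpha = x$alpha)
}

#' @rdname pca_scores
#' @param x A `lipid_pca` object.
#' @param ... Unused.
#' @exportS3Method
tidy.lipid_pca <- function(x, ...) x$scores

#' @rdname pca_scores
#' @exportS3Method
glance.lipid_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance),
                 explained_variance = x$explained_variance)
}

#' @rdname qc_filter
#' @param x A `qc_filter_report` object.
#' @param ... Unused.
#' @exportS3Method
tidy.qc_filter_report <- function(x, ...) x$report

#' @rdname qc_filter
#' @exportS3Method
glance.qc_filter_report <- function(x, ...) x$counts
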