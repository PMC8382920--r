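#' Pick candidate normalizer exons from gene models
#'
#' For each putatively single-copy gene, keeps its longest exon provided it
#' reaches the minimum length; genes whose longest exon falls short
#' contribute no candidate. Length ties within a gene are broken by
#' coordinate order (scaffold, then start).
#'
#' @param gene_models Data frame with columns `gene`, `exon`, `scaffold`,
#'   `start`, `end` (1-based inclusive spans).
#' @param min_length Minimum exon length in bp (default 300).
#' @return Tibble of candidates: `gene`, `exon`, `scaffold`, `start`, `end`,
#'   `length`.
#' @export
#' @examples
#' gm <- tibble::tibble(gene = "g1", exon = c("e1", "e2"), scaffold = "s",
#'                      start = c(1L, 500L), end = c(250L, 899L))
#' pick_candidate_exons(gm)$exon # "e2" (400 bp beats 250 bp)
pick_candidate_exons <- function(gene_models, min_length = 300) {
  stopifnot(all(c("gene", "exon", "scaffold", "start", "end") %in% names(gene_models)))
  if (any(gene_models$end < gene_models$start)) {
    stop("malformed exon span(s): end < start", call. = FALSE)
  }
  gene_models %>%
    tibble::as_tibble() %>%
    dplyr::mutate(length = .data$end - .data$start + 1L) %>%
    dplyr::arrange(.data$gene, dplyr::desc(.data$length), .data$scaffold, .data$start) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::slice_head(n = 1) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$length >= min_length)
}

#' Mean/median/mode concordance test for single-copy behavior
#'
#' A feature behaves like clean single-copy sequence in a lineage when its
#' mean, median and mode depth agree: the test passes when the largest of
#' the three is at most `(1 + tolerance)` times the smallest. A zero minimum
#' passes only when all three are zero.
#'
#' @param mean_depth,median_depth,mode_depth Numeric vectors (recycled
#'   together) of the three per-feature depth statistics.
#' @param tolerance Relative tolerance (default 0.10).
#' @return Logical vector.
#' @export
#' @examples
#' concordance_pass(105, 100, 95) # FALSE: 105/95 > 1.10
#' concordance_pass(104, 100, 95) # TRUE: 104/95 <= 1.10
concordance_pass <- function(mean_depth, median_depth, mode_depth, tolerance = 0.10) {
  if (any(c(mean_depth, median_depth, mode_depth) < 0, na.rm = TRUE)) {
    stop("depth statistics must be non-negative", call. = FALSE)
  }
  mx <- pmax(mean_depth, median_depth, mode_depth)
  mn <- pmin(mean_depth, median_depth, mode_depth)
  ifelse(mn == 0, mx == 0, mx <= (1 + tolerance) * mn)
}

#' Cross-lineage retention threshold
#'
#' Default stringency retains a feature only when it passes the concordance
#' test in at least 20 of 27 lineages; for other cohort sizes the same ratio
#' is rescaled with a ceiling.
#'
#' @param n_lineages Cohort size.
#' @param ratio Required pass fraction (default 20/27).
#' @return Integer minimum number of passing lineages.
#' @export
retention_threshold <- function(n_lineages, ratio = 20 / 27) {
  as.integer(ceiling(ratio * n_lineages))
}

#' Retain exons passing concordance in enough lineages
#'
#' @param pass_tbl Tibble with columns `exon`, `lineage`, `pass` (logical).
#' @param min_lineages Minimum number of passing lineages; defaults to
#'   [retention_threshold()] of the number of distinct lineages.
#' @return Character vector of retained exon ids (sorted).
#' @export
retain_exons <- function(pass_tbl, min_lineages = NULL) {
  stopifnot(all(c("exon", "lineage", "pass") %in% names(pass_tbl)))
  n_lineages <- dplyr::n_distinct(pass_tbl$lineage)
  if (is.null(min_lineages)) min_lineages <- retention_threshold(n_lineages)
  if (min_lineages > n_lineages) {
    stop("min_lineages (", min_lineages, ") exceeds the cohort size (",
         n_lineages, ")", call. = FALSE)
  }
  pass_tbl %>%
    dplyr::group_by(.data$exon) %>%
    dplyr::summarise(n_pass = sum(.data$pass), .groups = "drop") %>%
    dplyr::filter(.data$n_pass >= min_lineages) %>%
    dplyr::pull("exon") %>%
    sort()
}

#' Exclude high-copy outlier exons from a retained set
#'
#' Computes each exon's across-lineage median of median depths and excludes
#' exons exceeding `factor` times the median of those medians -- the
#' signature of a sequence that passed concordance but sits at high copy
#' number. With fewer than three exons no exclusion is attempted and a
#' warning is signaled.
#'
#' @param exon_medians Tibble with columns `exon`, `lineage`,
#'   `median_depth` for the retained exons.
#' @param factor Exclusion multiple (default 2).
#' @return Tibble with one row per exon: `exon`, `median_depth` (the
#'   across-lineage median), `times_median` (ratio to the median of
#'   medians), `excluded`.
#' @export
#' @examples
#' em <- tidyr::crossing(lineage = c("a", "b", "c"),
#'                       tibble::tibble(exon = c("e1", "e2", "e3", "e4"),
#'                                      median_depth = c(25, 26, 24, 275)))
#' exclude_high_coverage(em) # e4 excluded at ~11x the typical median
exclude_high_coverage <- function(exon_medians, factor = 2) {
  stopifnot(all(c("exon", "lineage", "median_depth") %in% names(exon_medians)))
  per_exon <- exon_medians %>%
    dplyr::group_by(.data$exon) %>%
    dplyr::summarise(median_depth = stats::median(.data$median_depth),
                     .groups = "drop")
  if (nrow(per_exon) < 3) {
    warning("fewer than 3 retained exons; outlier exclusion not performed",
            call. = FALSE)
    return(dplyr::mutate(per_exon, times_median = NA_real_, excluded = FALSE))
  }
  mom <- stats::median(per_exon$median_depth)
  per_exon %>%
    dplyr::mutate(times_median = .data$median_depth / mom,
                  excluded = .data$median_depth > factor * mom)
}

#' Select the single-copy normalizer exon set
#'
#' Runs the complete selection chain on per-exon coverage summaries:
#' per-lineage mean/median/mode concordance, cross-lineage retention, and
#' high-copy outlier exclusion. The surviving exons form the depth
#' normalizer used by [estimate_copy_number()].
#'
#' @param summaries Coverage summaries (from [summarize_coverage()]) for the
#'   candidate exon features, with columns `lineage`, `feature`, `length`,
#'   `mean_depth`, `median_depth`, `mode_depth`.
#' @param tolerance Concordance tolerance (default 0.10).
#' @param min_lineages Retention threshold; default rescales 20/27.
#' @param outlier_factor Outlier exclusion multiple (default 2).
#' @return List of class `sc_selection`: `retained` (final exon ids),
#'   `excluded` (outlier table), `pass` (long exon x lineage pass tibble),
#'   `n_pass` (per-exon pass counts), `min_lineages`, `n_lineages`,
#'   `total_length` (bp of the final set).
#' @export
select_single_copy <- function(summaries, tolerance = 0.10, min_lineages = NULL,
                               outlier_factor = 2) {
  stopifnot(all(c("lineage", "feature", "length", "mean_depth", "median_depth",
                  "mode_depth") %in% names(summaries)))
  pass_tbl <- summaries %>%
    dplyr::transmute(
      exon = .data$feature, lineage = .data$lineage,
      pass = concordance_pass(.data$mean_depth, .data$median_depth,
                              .data$mode_depth, tolerance)
    )
  n_lineages <- dplyr::n_distinct(pass_tbl$lineage)
  if (is.null(min_lineages)) min_lineages <- retention_threshold(n_lineages)
  retained <- retain_exons(pass_tbl, min_lineages)
  if (length(retained) == 0) {
    stop("no exon passed the concordance filter in >= ", min_lineages,
         " lineages; no single-copy baseline can be formed", call. = FALSE)
  }
  outliers <- summaries %>%
    dplyr::filter(.data$feature %in% retained) %>%
    dplyr::transmute(exon = .data$feature, lineage = .data$lineage,
                     median_depth = .data$median_depth) %>%
    exclude_high_coverage(factor = outlier_factor)
  final <- setdiff(retained, outliers$exon[outliers$excluded])
  lengths <- summaries %>%
    dplyr::filter(.data$feature %in% final) %>%
    dplyr::distinct(.data$feature, .data$length)
  structure(list(
    retained = sort(final),
    excluded = dplyr::filter(outliers, .data$excluded),
    pass = pass_tbl,
    n_pass = pass_tbl %>%
      dplyr::group_by(.data$exon) %>%
      dplyr::summarise(n_pass = sum(.data$pass), .groups = "drop"),
    min_lineages = min_lineages,
    n_lineages = n_lineages,
    total_length = sum(lengths$length)
  ), class = "sc_selection")
}

#' @export
print.sc_selection <- function(x, ...) {
  cat("Single-copy normalizer selection\n")
  cat("  lineages:", x$n_lineages, " (retention >= ", x$min_lineages, ")\n", sep = "")
  cat("  retained exons:", length(x$retained), "(", x$total_length, "bp total )\n")
  cat("   ", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded high-copy outliers:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("    %s (~%.1fx the typical exon median)\n",
                  x$excluded$exon[i], x$excluded$times_median[i]))
    }
  }
  invisible(x)
}
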