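#' Pooled single-copy baseline depth for one lineage
#'
#' The normalizer is the median of the pooled per-base depths over all
#' retained single-copy exons -- one concatenated multiset, not a mean of
#' per-exon medians, so longer exons carry proportionally more weight.
#'
#' @param depth_tbl Per-base depth tibble for one lineage (`feature`,
#'   `depth`).
#' @param exons Character vector of retained exon feature ids.
#' @return The baseline median depth (numeric scalar).
#' @export
#' @examples
#' d <- tibble::tibble(feature = rep(c("e1", "e2"), each = 4),
#'                     position = rep(1:4, 2),
#'                     depth = rep(c(24L, 26L), each = 4))
#' single_copy_baseline(d, c("e1", "e2")) # 25
single_copy_baseline <- function(depth_tbl, exons) {
  pooled <- depth_tbl$depth[depth_tbl$feature %in% exons]
  if (length(pooled) == 0) {
    stop("no per-base depth available for the retained exons", call. = FALSE)
  }
  stats::median(pooled)
}

#' Per-haploid copy number of one gene
#'
#' Median depth of the gene track divided by the single-copy baseline.
#' Because both numerator and denominator scale with sequencing effort and
#' ploidy, the ratio estimates copies per haploid genome equivalent.
#'
#' @param gene_depths Per-base depths of the gene (numeric vector).
#' @param baseline Single-copy baseline from [single_copy_baseline()]; must
#'   be > 0.
#' @return Copy-number estimate (numeric scalar).
#' @export
#' @examples
#' per_haploid_cn(rep(500, 100), 25) # 20
per_haploid_cn <- function(gene_depths, baseline) {
  if (length(gene_depths) == 0) stop("empty gene track", call. = FALSE)
  if (is.na(baseline) || baseline <= 0) {
    stop("single-copy baseline must be > 0", call. = FALSE)
  }
  stats::median(gene_depths) / baseline
}

#' Genomic proportion of the repeat locus from mapped-read counts
#'
#' @param reads_locus Reads mapping to the (masked) repeat locus.
#' @param reads_genome Reads mapping to the whole assembly; must be > 0 and
#'   at least `reads_locus`.
#' @return Percent of mapped reads attributable to the locus (vectorized).
#' @export
#' @examples
#' genomic_proportion(21, 10000) # 0.21
genomic_proportion <- function(reads_locus, reads_genome) {
  if (any(reads_genome <= 0)) stop("reads_genome must be > 0", call. = FALSE)
  if (any(reads_locus < 0)) stop("reads_locus must be >= 0", call. = FALSE)
  if (any(reads_locus > reads_genome)) {
    stop("reads_locus cannot exceed reads_genome", call. = FALSE)
  }
  100 * reads_locus / reads_genome
}

#' Lineage x gene table of per-haploid copy-number estimates
#'
#' For every lineage, pools the retained exons into the single-copy
#' baseline and divides each target gene's median depth by it. A gene with
#' no depth data in a lineage yields an explicit `NA` estimate (missing is
#' never silently coded as zero -- zero is a meaningful copy number).
#'
#' @param depth_tbl Long per-base depth tibble (`lineage`, `feature`,
#'   `position`, `depth`), e.g. from [simulate_cohort_depths()].
#' @param retained_exons Character vector of normalizer exon ids, e.g.
#'   `select_single_copy(...)$retained`.
#' @param genes Target gene features (default [rdna_histone_genes()]).
#' @return Tibble with columns `lineage`, `gene`, `copy_number`, `baseline`.
#' @export
estimate_copy_number <- function(depth_tbl, retained_exons,
                                 genes = rdna_histone_genes()) {
  stopifnot(all(c("lineage", "feature", "depth") %in% names(depth_tbl)))
  if (length(retained_exons) == 0) stop("no retained exons supplied", call. = FALSE)
  depth_tbl %>%
    dplyr::group_by(.data$lineage) %>%
    dplyr::group_modify(function(df, key) {
      baseline <- single_copy_baseline(df, retained_exons)
      gene_med <- df %>%
        dplyr::filter(.data$feature %in% genes) %>%
        dplyr::group_by(.data$feature) %>%
        dplyr::summarise(median_depth = stats::median(.data$depth),
                         .groups = "drop")
      tibble::tibble(gene = genes) %>%
        dplyr::left_join(gene_med, by = c(gene = "feature")) %>%
        dplyr::transmute(gene = .data$gene,
                         copy_number = .data$median_depth / baseline,
                         baseline = baseline)
    }) %>%
    dplyr::ungroup()
}

#' Genomic-proportion table from read-count summaries
#'
#' @param read_counts Tibble with columns `lineage`, `reads_locus`,
#'   `reads_genome`.
#' @return The input with a `proportion_pct` column (percent, 4 significant
#'   digits).
#' @export
proportion_table <- function(read_counts) {
  stopifnot(all(c("lineage", "reads_locus", "reads_genome") %in% names(read_counts)))
  read_counts %>%
    dplyr::mutate(proportion_pct = signif(
      genomic_proportion(.data$reads_locus, .data$reads_genome), 4))
}
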