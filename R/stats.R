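#' Pairwise Pearson correlation matrix of per-gene copy numbers
#'
#' Spreads a long copy-number table to a lineage x gene matrix and computes
#' every pairwise Pearson correlation together with two-sided p-values from
#' the t transform.
#'
#' @param cn_tbl Long tibble with columns `lineage`, `gene`, `copy_number`
#'   (as from [estimate_copy_number()]).
#' @param genes Genes to compare; default all present.
#' @return List of class `cn_correlations`: `r` (correlation matrix), `p`
#'   (p-value matrix, `NA` diagonal), `n` (lineages used).
#' @export
pearson_matrix <- function(cn_tbl, genes = NULL) {
  stopifnot(all(c("lineage", "gene", "copy_number") %in% names(cn_tbl)))
  if (!is.null(genes)) cn_tbl <- dplyr::filter(cn_tbl, .data$gene %in% genes)
  wide <- cn_tbl %>%
    dplyr::select("lineage", "gene", "copy_number") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "copy_number")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$lineage
  if (nrow(m) < 3) stop("need >= 3 lineages for correlation", call. = FALSE)
  if (anyNA(m)) stop("missing copy-number cells for compared genes", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m, method = "pearson")
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  for (i in seq_len(ncol(m) - 1)) {
    for (j in seq(i + 1, ncol(m))) {
      p[i, j] <- p[j, i] <- stats::cor.test(m[, i], m[, j])$p.value
    }
  }
  structure(list(r = r, p = p, n = nrow(m)), class = "cn_correlations")
}

#' @export
print.cn_correlations <- function(x, digits = 3, ...) {
  cat("Pearson correlations over", x$n, "lineages\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Tidy a correlation-matrix object into one row per gene pair
#'
#' @param x A `cn_correlations` object.
#' @param ... Unused.
#' @return Tibble with columns `gene1`, `gene2`, `r`, `p_value`.
#' @exportS3Method generics::tidy
tidy.cn_correlations <- function(x, ...) {
  genes <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    gene1 = genes[idx[, 1]],
    gene2 = genes[idx[, 2]],
    r = x$r[idx],
    p_value = x$p[idx]
  )
}

#' Mann-Whitney U test between two groups
#'
#' Wraps the rank-sum machinery behind a consistent surface: the exact
#' distribution is used when the combined sample size is at most
#' `exact_max_n` and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y Numeric observations of the two groups (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param exact_max_n Combined-size cutoff for the exact path (default 12).
#' @return One-row tibble: `method`, `statistic` (U for the first group),
#'   `p_value`, `n1`, `n2`, `exact`, `alternative`.
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))$p_value # exact: 0.1
mwu_test <- function(x, y, alternative = "two.sided", exact_max_n = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(
    method = "Mann-Whitney U",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n1 = length(x),
    n2 = length(y),
    exact = exact,
    alternative = alternative
  )
}

#' Kruskal-Wallis test across groups
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return One-row tibble: `method`, `statistic` (tie-corrected H),
#'   `df`, `p_value`, `n_groups`, `degenerate` (TRUE when all observations
#'   are identical, in which case H is set to 0 and p to 1).
#' @export
kw_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(tibble::tibble(method = "Kruskal-Wallis", statistic = 0,
                          df = nlevels(droplevels(groups)) - 1L, p_value = 1,
                          n_groups = nlevels(droplevels(groups)),
                          degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(
    method = "Kruskal-Wallis",
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n_groups = nlevels(droplevels(groups)),
    degenerate = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone after sorting.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Copy-number comparisons by reproductive mode and ploidy
#'
#' Runs the comparison battery on representative genes: a Mann-Whitney U
#' test of sexual versus asexual lineages and a Kruskal-Wallis test across
#' ploidy levels for each gene, with Benjamini-Hochberg adjustment applied
#' within the Kruskal-Wallis family.
#'
#' @param cn_tbl Long copy-number table (`lineage`, `gene`, `copy_number`).
#' @param metadata Lineage metadata (`lineage`, `mode`, `ploidy`).
#' @param genes Genes to test (default the 45S representative 5.8S and the
#'   separately inherited 5S).
#' @return Tibble with one row per test: `gene`, `comparison`, `method`,
#'   `statistic`, `p_value`, `p_adjusted` (only within the KW family),
#'   `degenerate`.
#' @export
compare_copy_numbers <- function(cn_tbl, metadata, genes = c("5.8S", "5S")) {
  stopifnot(all(c("lineage", "mode", "ploidy") %in% names(metadata)))
  df <- cn_tbl %>%
    dplyr::filter(.data$gene %in% genes) %>%
    dplyr::inner_join(dplyr::select(metadata, "lineage", "mode", "ploidy"),
                      by = "lineage")
  res <- purrr::map_dfr(genes, function(g) {
    d <- dplyr::filter(df, .data$gene == g)
    out <- list()
    if (dplyr::n_distinct(d$mode) == 2) {
      mw <- mwu_test(d$copy_number[d$mode == "sexual"],
                     d$copy_number[d$mode == "asexual"])
      out$mwu <- tibble::tibble(gene = g, comparison = "sexual vs asexual",
                                method = mw$method, statistic = mw$statistic,
                                p_value = mw$p_value, degenerate = FALSE)
    } else {
      warning("only one reproductive mode present; skipping the two-group test for ",
              g, call. = FALSE)
    }
    if (dplyr::n_distinct(d$ploidy) >= 2) {
      kw <- kw_test(d$copy_number, d$ploidy)
      out$kw <- tibble::tibble(gene = g, comparison = "across ploidy",
                               method = kw$method, statistic = kw$statistic,
                               p_value = kw$p_value, degenerate = kw$degenerate)
    }
    dplyr::bind_rows(out)
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(gene = character(), comparison = character(),
                          method = character(), statistic = numeric(),
                          p_value = numeric(), degenerate = logical(),
                          p_adjusted = numeric()))
  }
  res %>%
    dplyr::group_by(is_kw = .data$method == "Kruskal-Wallis") %>%
    dplyr::mutate(p_adjusted = ifelse(.data$is_kw, bh_adjust(.data$p_value),
                                      NA_real_)) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"is_kw")
}
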