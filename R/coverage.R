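#' Read a per-base depth table
#'
#' Reads the three-column per-base depth dialect produced by genome-coverage
#' tools run with per-base output (feature, 1-based position, integer depth;
#' no header). Positions must be contiguous from 1 within each feature;
#' gaps, duplicates and non-integer depths are errors rather than silently
#' repaired.
#'
#' @param path Path to a TSV file with columns feature, position, depth.
#' @param lineage Optional lineage id to attach as a column (depth tables are
#'   typically one file per lineage).
#' @return A tibble with columns `feature`, `position`, `depth` (and
#'   `lineage` if given), sorted by feature and position.
#' @export
read_depth_table <- function(path, lineage = NULL) {
  raw <- readr::read_tsv(path, col_names = c("feature", "position", "depth"),
                         col_types = readr::cols(
                           feature = readr::col_character(),
                           position = readr::col_double(),
                           depth = readr::col_double()
                         ), progress = FALSE)
  validate_depth_table(raw, lineage = lineage)
}

#' Validate an in-memory per-base depth table
#'
#' @param depth_tbl Data frame with columns `feature`, `position`, `depth`.
#' @param lineage Optional lineage id to attach.
#' @return The validated tibble, sorted by feature and position.
#' @export
validate_depth_table <- function(depth_tbl, lineage = NULL) {
  stopifnot(all(c("feature", "position", "depth") %in% names(depth_tbl)))
  if (nrow(depth_tbl) == 0) stop("empty depth table", call. = FALSE)
  if (anyNA(depth_tbl$depth) || any(depth_tbl$depth < 0) ||
      any(depth_tbl$depth != floor(depth_tbl$depth))) {
    stop("depths must be non-negative integers", call. = FALSE)
  }
  if (any(depth_tbl$position != floor(depth_tbl$position))) {
    stop("positions must be integers", call. = FALSE)
  }
  out <- tibble::as_tibble(depth_tbl) %>%
    dplyr::arrange(.data$feature, .data$position)
  bad <- out %>%
    dplyr::group_by(.data$feature) %>%
    dplyr::summarise(
      dup = anyDuplicated(.data$position) > 0,
      gap = !identical(as.integer(.data$position), seq_len(dplyr::n())),
      .groups = "drop"
    )
  if (any(bad$dup)) {
    stop("duplicated position(s) in feature(s): ",
         paste(bad$feature[bad$dup], collapse = ", "), call. = FALSE)
  }
  if (any(bad$gap)) {
    stop("positions not contiguous from 1 in feature(s): ",
         paste(bad$feature[bad$gap], collapse = ", "), call. = FALSE)
  }
  out$position <- as.integer(out$position)
  out$depth <- as.integer(out$depth)
  if (!is.null(lineage)) out <- dplyr::mutate(out, lineage = lineage, .before = 1)
  out
}

#' Mode of an integer depth vector
#'
#' Most frequent value; ties are broken by the smallest value so the
#' statistic is deterministic on multimodal tracks.
#'
#' @param x Non-empty vector of non-negative integer depths.
#' @return The modal depth (integer).
#' @export
#' @examples
#' mode_of(c(2, 2, 3, 3, 4)) # 2 (smallest of the tied values)
mode_of <- function(x) {
  if (length(x) == 0) stop("cannot take the mode of an empty vector", call. = FALSE)
  if (anyNA(x)) stop("NA depths", call. = FALSE)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Per-feature coverage summaries
#'
#' Computes mean, median and mode depth plus feature length for every
#' feature (and lineage, when a `lineage` column is present). The median
#' uses the midpoint convention for even-length tracks; the mode breaks ties
#' toward the smallest value.
#'
#' @param depth_tbl Tibble with columns `feature`, `position`, `depth` and
#'   optionally `lineage`, as from [read_depth_table()] or
#'   [simulate_cohort_depths()].
#' @return Tibble with columns (`lineage`,) `feature`, `length`,
#'   `mean_depth`, `median_depth`, `mode_depth`.
#' @export
#' @examples
#' d <- tibble::tibble(feature = "x", position = 1:4, depth = c(1L, 2L, 3L, 4L))
#' summarize_coverage(d)$median_depth # 2.5
summarize_coverage <- function(depth_tbl) {
  stopifnot(all(c("feature", "depth") %in% names(depth_tbl)))
  if (nrow(depth_tbl) == 0) stop("empty depth table", call. = FALSE)
  keys <- intersect(c("lineage", "feature"), names(depth_tbl))
  depth_tbl %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      length = dplyr::n(),
      mean_depth = mean(.data$depth),
      median_depth = stats::median(.data$depth),
      mode_depth = mode_of(.data$depth),
      .groups = "drop"
    )
}
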