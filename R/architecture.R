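#' Read a tabular homology-hit file (outfmt-6 layout)
#'
#' @param path TSV with the 12 standard tabular columns (query, subject,
#'   percent identity, alignment length, mismatches, gap opens, qstart,
#'   qend, sstart, send, e-value, bit score); no header.
#' @return Tibble with those columns.
#' @export
read_blast_hits <- function(path) {
  readr::read_tsv(path,
                  col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                                "gapopen", "qstart", "qend", "sstart", "send",
                                "evalue", "bitscore"),
                  col_types = "ccdiiiiiiidd", progress = FALSE)
}

#' Filter homology hits by e-value and normalize strand encoding
#'
#' Keeps hits at or below the e-value cutoff and rewrites subject
#' coordinates to `start <= end` plus an explicit strand (`sstart > send`
#' encodes a minus-strand hit in the tabular dialect).
#'
#' @param hits Tibble from [read_blast_hits()] or [reference_hits()].
#' @param evalue_cutoff Maximum e-value (default `1e-50`).
#' @return Tibble with columns `gene`, `scaffold`, `start`, `end`, `strand`,
#'   `evalue`, `pident`.
#' @export
#' @examples
#' h <- tibble::tibble(qseqid = "5S", sseqid = "s", pident = 99, length = 400,
#'                     mismatch = 1, gapopen = 0, qstart = 1, qend = 400,
#'                     sstart = 500, send = 101, evalue = 1e-60, bitscore = 700)
#' filter_hits(h)[, c("start", "end", "strand")] # [101, 500], "-"
filter_hits <- function(hits, evalue_cutoff = 1e-50) {
  stopifnot(all(c("qseqid", "sseqid", "sstart", "send", "evalue") %in% names(hits)))
  if (any(hits$sstart < 1 | hits$send < 1)) {
    stop("negative or zero subject coordinates", call. = FALSE)
  }
  hits %>%
    dplyr::filter(.data$evalue <= evalue_cutoff) %>%
    dplyr::transmute(
      gene = .data$qseqid,
      scaffold = .data$sseqid,
      start = pmin(.data$sstart, .data$send),
      end = pmax(.data$sstart, .data$send),
      strand = ifelse(.data$sstart <= .data$send, "+", "-"),
      evalue = .data$evalue,
      pident = if ("pident" %in% names(hits)) .data$pident else NA_real_
    )
}

#' Infer the tandem repeat-unit model from filtered hits
#'
#' Formalizes the manual curation of a tandem multigene array: the gene with
#' the most occurrences anchors the array (ties broken toward the gene with
#' the longest hits); the unit period is the median spacing between
#' consecutive anchor starts; every other hit is assigned to the unit whose
#' anchor precedes it; and the consensus gene order, offsets, and
#' orientations (relative to the anchor's strand) are taken by majority vote
#' across complete units. Edge units truncated by the scaffold boundary --
#' hits before the first anchor, or a trailing unit whose missing genes are
#' exactly a cut-off suffix of the consensus -- are reported as partial and
#' excluded from the vote.
#'
#' @param hits Filtered hits from [filter_hits()].
#' @return List of class `repeat_unit_model`: `anchor`, `scaffold`,
#'   `period` (bp; `NA` with `single_unit = TRUE` when only one unit is
#'   present), `n_units`, `consensus` (tibble: gene, offset, strand,
#'   orientation relative to anchor, support, n_voting), `units` (per-hit
#'   unit assignment with `partial` flag), `per_unit_genes` (presence of
#'   each consensus gene in each unit).
#' @export
infer_unit_model <- function(hits) {
  stopifnot(all(c("gene", "scaffold", "start", "end", "strand") %in% names(hits)))
  if (nrow(hits) == 0) stop("no hits to build a unit model from", call. = FALSE)
  # work on the scaffold carrying the most hits
  scaffold <- hits %>%
    dplyr::count(.data$scaffold, sort = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::pull("scaffold")
  h <- hits %>%
    dplyr::filter(.data$scaffold == .env$scaffold) %>%
    dplyr::arrange(.data$start)

  tally <- h %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(n = dplyr::n(),
                     hit_len = stats::median(.data$end - .data$start + 1),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$hit_len))
  anchor <- tally$gene[1]

  a <- h %>% dplyr::filter(.data$gene == anchor)
  anchor_starts <- sort(a$start)
  anchor_strand <- names(sort(table(a$strand), decreasing = TRUE))[1]
  n_occ <- length(anchor_starts)
  single_unit <- n_occ < 2
  period <- if (single_unit) NA_real_ else stats::median(diff(anchor_starts))

  units <- h %>%
    dplyr::mutate(unit = findInterval(.data$start, anchor_starts),
                  offset = ifelse(.data$unit >= 1,
                                  .data$start - anchor_starts[pmax(.data$unit, 1)],
                                  NA_real_))
  if (single_unit) {
    cons <- units %>%
      dplyr::filter(.data$unit == 1) %>%
      dplyr::transmute(
        gene = .data$gene, offset = .data$offset, strand = .data$strand,
        orientation = ifelse(.data$strand == anchor_strand, "+", "-"),
        support = 1L, n_voting = 1L
      ) %>%
      dplyr::arrange(.data$offset)
    units$partial <- units$unit < 1
    model <- list(anchor = anchor, scaffold = scaffold, period = period,
                  n_units = max(n_occ, 1L), single_unit = TRUE,
                  consensus = cons, units = units,
                  per_unit_genes = dplyr::filter(units, .data$unit >= 1) %>%
                    dplyr::distinct(.data$unit, .data$gene))
    class(model) <- "repeat_unit_model"
    return(model)
  }

  # majority complement over units 1..n; unit 0 (leading fragment) is partial
  complement <- units %>%
    dplyr::filter(.data$unit >= 1) %>%
    dplyr::distinct(.data$unit, .data$gene)
  gene_support <- complement %>% dplyr::count(.data$gene, name = "support")
  majority_genes <- gene_support$gene[gene_support$support > n_occ / 2]

  # the last unit is partial only if its missing genes form a cut-off suffix
  med_offsets <- units %>%
    dplyr::filter(.data$unit >= 1) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(offset = stats::median(.data$offset), .groups = "drop")
  last_genes <- complement$gene[complement$unit == n_occ]
  missing_last <- setdiff(majority_genes, last_genes)
  last_partial <- length(missing_last) > 0 &&
    min(med_offsets$offset[med_offsets$gene %in% missing_last]) >
      max(units$offset[units$unit == n_occ], na.rm = TRUE)

  units <- units %>%
    dplyr::mutate(partial = .data$unit < 1 | (.data$unit == n_occ & last_partial))
  voting_units <- setdiff(unique(units$unit[!units$partial]), 0L)
  n_voting <- length(voting_units)

  votes <- units %>% dplyr::filter(.data$unit %in% voting_units)
  cons <- votes %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      offset = stats::median(.data$offset),
      strand = names(sort(table(.data$strand), decreasing = TRUE))[1],
      support = dplyr::n_distinct(.data$unit),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$support > n_voting / 2) %>%
    dplyr::mutate(orientation = ifelse(.data$strand == anchor_strand, "+", "-"),
                  n_voting = n_voting) %>%
    dplyr::arrange(.data$offset) %>%
    dplyr::select("gene", "offset", "strand", "orientation", "support", "n_voting")

  model <- list(anchor = anchor, scaffold = scaffold, period = period,
                n_units = n_occ, single_unit = FALSE,
                consensus = cons, units = units,
                per_unit_genes = complement)
  class(model) <- "repeat_unit_model"
  model
}

#' Render a repeat-unit model as a deterministic text schematic
#'
#' @param model A [infer_unit_model()] result.
#' @return Character vector of report lines (also usable with
#'   `writeLines()`).
#' @export
report_unit_model <- function(model) {
  stopifnot(inherits(model, "repeat_unit_model"))
  lines <- c(
    sprintf("repeat unit model on %s", model$scaffold),
    sprintf("anchor gene: %s", model$anchor),
    if (model$single_unit) {
      "WARNING: single unit detected; period undefined"
    } else {
      sprintf("period: %s bp over %d units", format(model$period), model$n_units)
    },
    sprintf("consensus (%d genes):", nrow(model$consensus))
  )
  arrows <- ifelse(model$consensus$orientation == "+", "-->", "<--")
  body <- sprintf("  %-5s offset %6s bp  %s  strand %s  support %d/%d",
                  model$consensus$gene, format(model$consensus$offset),
                  arrows, model$consensus$strand,
                  model$consensus$support, model$consensus$n_voting)
  c(lines, body)
}

#' @export
print.repeat_unit_model <- function(x, ...) {
  writeLines(report_unit_model(x))
  invisible(x)
}
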