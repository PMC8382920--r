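#' Pipeline configuration
#'
#' Bundles the simulator configuration with the parameters of every
#' downstream stage. All numeric outputs are written with 6 significant
#' digits so that re-runs under the same seed are byte-identical.
#'
#' @param sim A [simulation_config()]; its `seed` drives all randomness.
#' @param tolerance Concordance tolerance for exon selection.
#' @param min_lineages Retention threshold (`NULL` = rescaled 20/27).
#' @param outlier_factor High-copy outlier exclusion multiple.
#' @param evalue_cutoff Homology-hit e-value cutoff.
#' @param stats_genes Genes for the MWU/KW comparisons.
#' @param gee_response Gene whose copy number is the GEE response.
#' @param gee_max_iter,gee_tol GEE fitting controls.
#' @param skip_architecture Skip the architecture stage in [run_pipeline()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(seed = 1),
                            tolerance = 0.10,
                            min_lineages = NULL,
                            outlier_factor = 2,
                            evalue_cutoff = 1e-50,
                            stats_genes = c("5.8S", "5S"),
                            gee_response = "5.8S",
                            gee_max_iter = 50,
                            gee_tol = 1e-8,
                            skip_architecture = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  stopifnot(tolerance >= 0, outlier_factor > 0, evalue_cutoff > 0)
  structure(list(
    sim = sim, tolerance = tolerance, min_lineages = min_lineages,
    outlier_factor = outlier_factor, evalue_cutoff = evalue_cutoff,
    stats_genes = stats_genes, gee_response = gee_response,
    gee_max_iter = gee_max_iter, gee_tol = gee_tol,
    skip_architecture = isTRUE(skip_architecture)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `sim:` mirror [simulation_config()]. A seed is mandatory.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed)) stop("config must set sim: seed:", call. = FALSE)
  sim <- do.call(simulation_config, sim_args)
  rest <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_num <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
}

write_num_tsv <- function(df, path) {
  readr::write_tsv(round_num(df), path, progress = FALSE)
}

update_manifest <- function(dir, stage, files) {
  manifest_path <- file.path(dir, "manifest.tsv")
  entry <- tibble::tibble(
    stage = stage,
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  old <- if (file.exists(manifest_path)) {
    readr::read_tsv(manifest_path, col_types = "ccc", progress = FALSE) %>%
      dplyr::filter(.data$stage != .env$stage)
  } else NULL
  readr::write_tsv(dplyr::bind_rows(old, entry), manifest_path, progress = FALSE)
  invisible(entry)
}

write_fasta <- function(scaffolds, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::DNAStringSet(scaffolds$seq)
    names(seqs) <- scaffolds$scaffold
    Biostrings::writeXStringSet(seqs, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(scaffolds))) {
      writeLines(paste0(">", scaffolds$scaffold[i]), con)
      writeLines(gsub("(.{80})", "\\1\n", scaffolds$seq[i]), con)
    }
  }
  invisible(path)
}

stage_simulate <- function(config, dir) {
  sim <- config$sim
  template <- unit_template()
  reference <- build_reference(template, sim)
  cohort <- simulate_cohort(sim, template)
  depths <- simulate_cohort_depths(reference, cohort, sim)

  depth_dir <- file.path(dir, "depth")
  dir.create(depth_dir, showWarnings = FALSE, recursive = TRUE)
  depth_files <- purrr::map_chr(
    split(depths$depth, depths$depth$lineage),
    function(d) {
      f <- file.path(depth_dir, paste0(d$lineage[1], ".depth.tsv"))
      readr::write_tsv(d[, c("feature", "position", "depth")], f,
                       col_names = FALSE, progress = FALSE)
      f
    }
  )
  files <- c(
    fasta = write_fasta(reference$scaffolds, file.path(dir, "reference.fasta")),
    gene_models = {
      f <- file.path(dir, "gene_models.tsv")
      readr::write_tsv(reference$gene_models, f, progress = FALSE); f
    },
    unit_genes = {
      f <- file.path(dir, "unit_genes.tsv")
      readr::write_tsv(reference$unit_genes, f, progress = FALSE); f
    },
    masked_locus = {
      f <- file.path(dir, "masked_locus.tsv")
      readr::write_tsv(reference$masked_locus, f, progress = FALSE); f
    },
    hits = {
      f <- file.path(dir, "blast_hits.tsv")
      readr::write_tsv(round_num(reference_hits(reference)), f,
                       col_names = FALSE, progress = FALSE); f
    },
    read_counts = {
      f <- file.path(dir, "read_counts.tsv")
      readr::write_tsv(depths$read_counts, f, progress = FALSE); f
    },
    tree = {
      f <- file.path(dir, "tree.nwk")
      ape::write.tree(cohort$tree, f); f
    },
    lineages = {
      f <- file.path(dir, "lineages.tsv")
      write_num_tsv(cohort$lineages, f); f
    },
    truth = {
      f <- file.path(dir, "truth.tsv")
      write_num_tsv(cohort$truth, f); f
    }
  )
  update_manifest(dir, "simulate", c(files, depth_files))
  invisible(files)
}

read_all_depths <- function(dir) {
  files <- sort(list.files(file.path(dir, "depth"), pattern = "\\.depth\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no depth tables under ", dir, call. = FALSE)
  purrr::map_dfr(files, function(f) {
    read_depth_table(f, lineage = sub("\\.depth\\.tsv$", "", basename(f)))
  })
}

stage_summarize <- function(config, dir) {
  depth <- read_all_depths(dir)
  summaries <- summarize_coverage(depth)
  f <- file.path(dir, "coverage_summary.tsv")
  write_num_tsv(summaries, f)
  update_manifest(dir, "summarize", f)
  invisible(f)
}

stage_select <- function(config, dir) {
  summaries <- readr::read_tsv(file.path(dir, "coverage_summary.tsv"),
                               col_types = "cciddi", progress = FALSE)
  gene_models <- readr::read_tsv(file.path(dir, "gene_models.tsv"),
                                 col_types = "cccii", progress = FALSE)
  candidates <- pick_candidate_exons(gene_models, config$sim$min_exon_length)
  sel <- select_single_copy(
    dplyr::filter(summaries, .data$feature %in% candidates$exon),
    tolerance = config$tolerance,
    min_lineages = config$min_lineages,
    outlier_factor = config$outlier_factor
  )
  sel_tbl <- sel$n_pass %>%
    dplyr::mutate(retained = .data$exon %in% sel$retained,
                  excluded_outlier = .data$exon %in% sel$excluded$exon)
  f1 <- file.path(dir, "selection.tsv")
  write_num_tsv(sel_tbl, f1)
  f2 <- file.path(dir, "selection_report.txt")
  writeLines(utils::capture.output(print(sel)), f2)
  update_manifest(dir, "select", c(f1, f2))
  invisible(sel)
}

stage_copynumber <- function(config, dir) {
  depth <- read_all_depths(dir)
  sel <- readr::read_tsv(file.path(dir, "selection.tsv"),
                         col_types = "cill", progress = FALSE)
  retained <- sel$exon[sel$retained]
  cn <- estimate_copy_number(depth, retained)
  f1 <- file.path(dir, "copy_number.tsv")
  write_num_tsv(cn, f1)
  read_counts <- readr::read_tsv(file.path(dir, "read_counts.tsv"),
                                 col_types = "cdd", progress = FALSE)
  prop <- proportion_table(read_counts)
  f2 <- file.path(dir, "genomic_proportion.tsv")
  write_num_tsv(prop, f2)
  update_manifest(dir, "copynumber", c(f1, f2))
  invisible(cn)
}

stage_architecture <- function(config, dir) {
  hits <- read_blast_hits(file.path(dir, "blast_hits.tsv"))
  model <- infer_unit_model(filter_hits(hits, config$evalue_cutoff))
  f1 <- file.path(dir, "unit_model.tsv")
  write_num_tsv(model$consensus, f1)
  f2 <- file.path(dir, "unit_model_report.txt")
  writeLines(report_unit_model(model), f2)
  update_manifest(dir, "architecture", c(f1, f2))
  invisible(model)
}

stage_stats <- function(config, dir) {
  cn <- readr::read_tsv(file.path(dir, "copy_number.tsv"),
                        col_types = "ccdd", progress = FALSE)
  metadata <- readr::read_tsv(file.path(dir, "lineages.tsv"),
                              col_types = "ccicid", progress = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  if (!file.exists(tree_path)) {
    stop("tree file missing; the phylogenetic GEE requires tree.nwk", call. = FALSE)
  }
  tree <- ape::read.tree(tree_path)

  cors <- pearson_matrix(cn)
  f1 <- file.path(dir, "pearson.tsv")
  write_num_tsv(tidy(cors), f1)

  tests <- compare_copy_numbers(cn, metadata, genes = config$stats_genes)
  f2 <- file.path(dir, "stats_tests.tsv")
  write_num_tsv(tests, f2)

  gee_data <- cn %>%
    dplyr::filter(.data$gene == config$gee_response) %>%
    dplyr::inner_join(dplyr::select(metadata, "lineage", "mode"), by = "lineage") %>%
    dplyr::mutate(mode = factor(.data$mode, levels = c("sexual", "asexual")))
  fit <- NULL
  if (dplyr::n_distinct(gee_data$mode) == 2) {
    fit <- fit_poisson_gee(copy_number ~ mode, gee_data, tree = tree,
                           max_iter = config$gee_max_iter, tol = config$gee_tol)
    f3 <- file.path(dir, "gee_coefficients.tsv")
    write_num_tsv(tidy(fit), f3)
  } else {
    warning("only one reproductive mode present; GEE stage skipped", call. = FALSE)
    f3 <- NULL
  }
  update_manifest(dir, "stats", c(f1, f2, f3))
  invisible(list(correlations = cors, tests = tests, gee = fit))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `summarize`, `select`, `copynumber`, `architecture`,
#' `stats`. Each stage reads its upstream files from `dir`, writes its
#' outputs there, and records them (with checksums) in `manifest.tsv`.
#' Missing upstream files are errors.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param dir Results directory (created if needed).
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(stage, config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(
    simulate = stage_simulate, summarize = stage_summarize,
    select = stage_select, copynumber = stage_copynumber,
    architecture = stage_architecture, stats = stage_stats
  )
  fn <- stages[[match.arg(stage, names(stages))]]
  fn(config, dir)
}

#' Run the full pipeline
#'
#' Executes simulate, summarize, select, copynumber, architecture (unless
#' skipped) and stats in order, writing all outputs and a checksum manifest
#' to `dir`.
#'
#' @param config A [pipeline_config()].
#' @param dir Results directory.
#' @return Invisible list with the `stats` stage results plus the
#'   copy-number table and selection.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = simulation_config(seed = 42))
#' res <- run_pipeline(cfg, tempfile("run"))
#' res$tests
#' }
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  run_stage("simulate", config, dir)
  run_stage("summarize", config, dir)
  sel <- run_stage("select", config, dir)
  cn <- run_stage("copynumber", config, dir)
  model <- if (config$skip_architecture) NULL else run_stage("architecture", config, dir)
  stats <- run_stage("stats", config, dir)
  invisible(c(stats, list(selection = sel, copy_number = cn, unit_model = model)))
}
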