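#' Template of the tandem rDNA-histone repeat unit
#'
#' Describes one copy of the tandemly repeated unit: the ordered genes, their
#' lengths and transcriptional orientations, and the intergenic spacer that
#' follows each gene. The default reproduces an approximately 13 kb unit in
#' which the core histone genes and the 5S rRNA gene sit between successive
#' copies of the 45S (18S-5.8S-28S) cassette.
#'
#' @param genes Character vector of gene names; must be a subset of
#'   [rdna_histone_genes()] with no duplicates.
#' @param lengths Integer vector of gene lengths in bp.
#' @param strands Character vector of `"+"`/`"-"` orientations.
#' @param spacers Integer vector of spacer lengths (bp) following each gene;
#'   the last entry is the spacer linking one unit to the next.
#'
#' @return A tibble of class `unit_template` with columns `gene`, `length`,
#'   `strand`, `spacer_after`. The total unit length is
#'   `sum(length + spacer_after)`; see [unit_length()].
#' @export
#' @examples
#' tpl <- unit_template()
#' unit_length(tpl) # 13000
unit_template <- function(genes = c("18S", "5.8S", "28S", "5S", "H2A", "H2B", "H3", "H4"),
                          lengths = c(1800L, 160L, 3500L, 120L, 400L, 400L, 400L, 300L),
                          strands = c("+", "+", "+", "+", "-", "+", "-", "+"),
                          spacers = c(400L, 600L, 2000L, 500L, 400L, 400L, 400L, 1220L)) {
  if (length(genes) == 0) {
    stop("a unit template must contain at least one gene", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("each gene may appear only once in the unit template", call. = FALSE)
  }
  if (!all(genes %in% RDNA_HISTONE_GENES)) {
    stop("unknown gene name(s): ",
         paste(setdiff(genes, RDNA_HISTONE_GENES), collapse = ", "), call. = FALSE)
  }
  stopifnot(length(lengths) == length(genes), length(strands) == length(genes),
            length(spacers) == length(genes))
  if (any(lengths < 1) || any(spacers < 0)) {
    stop("gene lengths must be >= 1 bp and spacers >= 0 bp", call. = FALSE)
  }
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'", call. = FALSE)
  out <- tibble::tibble(
    gene = as.character(genes),
    length = as.integer(lengths),
    strand = as.character(strands),
    spacer_after = as.integer(spacers)
  )
  class(out) <- c("unit_template", class(out))
  out
}

#' Total length of one repeat unit
#'
#' @param template A [unit_template()].
#' @return Unit period in bp (genes plus spacers).
#' @export
unit_length <- function(template) {
  sum(template$length + template$spacer_after)
}

#' Simulation configuration for a synthetic cohort
#'
#' Collects every free parameter of the synthetic-data generator: cohort
#' composition, depth and overdispersion of sequencing, the per-mode ranges
#' the planted per-haploid copy numbers are drawn from, and the layout of the
#' single-copy normalizer exons.
#'
#' Per-base depth is modeled as Poisson sampling around a lineage-level
#' Gamma(k, k) sequencing-effort factor with k = `dispersion`, so the
#' marginal per-base depth at a single-copy base is negative binomial with
#' mean `base_depth` and size `dispersion` (Poisson in the `dispersion = Inf`
#' limit), while all features of one lineage share the same effort factor --
#' the structure the single-copy normalization is designed to cancel.
#'
#' @param n_sexual,n_asexual_triploid,n_asexual_tetraploid Lineage counts by
#'   reproductive mode and ploidy. Defaults give 10 sexual diploid and 16
#'   asexual (12 triploid + 4 tetraploid) lineages.
#' @param base_depth Expected sequencing depth (x) of a single-copy locus.
#' @param dispersion Negative-binomial size parameter of the marginal per-base
#'   depth; `Inf` gives Poisson depth.
#' @param sexual_cn_range,asexual_cn_range Integer ranges (length 2) from
#'   which planted per-haploid unit copy numbers are drawn uniformly.
#' @param background_length Length (bp) of the single-copy background genome,
#'   used for genomic-proportion truth and read-count totals. Not
#'   materialized as sequence.
#' @param n_exons Number of candidate single-copy exons to plant.
#' @param exon_length_range Range (bp) of planted exon lengths.
#' @param min_exon_length Exon-length threshold used downstream when picking
#'   candidates from gene models.
#' @param exon_copy_multipliers Per-exon true copy multipliers (length
#'   `n_exons`). The default plants all exons at single copy except the last
#'   two at 11x and 15x, so the selection stage has genuine high-copy
#'   outliers to exclude.
#' @param frac_5s_missing_range Range of the per-lineage fraction of repeat
#'   units lacking the 5S gene.
#' @param n_units Number of tandem unit copies placed on the repeat scaffold
#'   of the synthetic reference.
#' @param read_length Read length (bp) used to convert depth to read counts.
#' @param seed Integer random seed; mandatory for all `simulate_*` functions.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$base_depth
simulation_config <- function(n_sexual = 10L,
                              n_asexual_triploid = 12L,
                              n_asexual_tetraploid = 4L,
                              base_depth = 25,
                              dispersion = 10,
                              sexual_cn_range = c(10L, 30L),
                              asexual_cn_range = c(100L, 300L),
                              background_length = 6e7,
                              n_exons = 12L,
                              exon_length_range = c(400L, 1200L),
                              min_exon_length = 300L,
                              exon_copy_multipliers = NULL,
                              frac_5s_missing_range = c(0, 0.25),
                              n_units = 3L,
                              read_length = 150L,
                              seed = NULL) {
  if (n_sexual < 0 || n_asexual_triploid < 0 || n_asexual_tetraploid < 0) {
    stop("lineage counts must be >= 0", call. = FALSE)
  }
  if (base_depth <= 0) stop("base_depth must be > 0", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  check_range <- function(r, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      stop(what, " must be a non-empty integer interval with lower bound >= 1",
           call. = FALSE)
    }
  }
  check_range(sexual_cn_range, "sexual_cn_range")
  check_range(asexual_cn_range, "asexual_cn_range")
  if (n_exons < 1) stop("configuration error: at least one exon is required", call. = FALSE)
  if (is.null(exon_copy_multipliers)) {
    exon_copy_multipliers <- rep(1, n_exons)
    if (n_exons >= 3) {
      exon_copy_multipliers[n_exons - 1L] <- 11
      exon_copy_multipliers[n_exons] <- 15
    }
  }
  stopifnot(length(exon_copy_multipliers) == n_exons, all(exon_copy_multipliers > 0))
  if (any(frac_5s_missing_range < 0) || any(frac_5s_missing_range > 1)) {
    stop("frac_5s_missing_range must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_sexual = as.integer(n_sexual),
    n_asexual_triploid = as.integer(n_asexual_triploid),
    n_asexual_tetraploid = as.integer(n_asexual_tetraploid),
    base_depth = base_depth,
    dispersion = dispersion,
    sexual_cn_range = as.integer(sexual_cn_range),
    asexual_cn_range = as.integer(asexual_cn_range),
    background_length = background_length,
    n_exons = as.integer(n_exons),
    exon_length_range = as.integer(exon_length_range),
    min_exon_length = as.integer(min_exon_length),
    exon_copy_multipliers = as.numeric(exon_copy_multipliers),
    frac_5s_missing_range = as.numeric(frac_5s_missing_range),
    n_units = as.integer(n_units),
    read_length = as.integer(read_length),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

require_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("a seed is mandatory for simulation; set simulation_config(seed = ...)",
         call. = FALSE)
  }
  invisible(config$seed)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic reference for the repeat locus and single-copy exons
#'
#' Lays out one scaffold carrying `config$n_units` tandem copies of the
#' repeat unit and one background scaffold per candidate single-copy exon.
#' Each BUSCO-like background gene gets two exons (one above, one below the
#' downstream length threshold) so that candidate picking is exercised. All
#' coordinates are 1-based inclusive. The masked-locus span covers exactly
#' one unit.
#'
#' @param template A [unit_template()].
#' @param config A [simulation_config()] with a seed.
#' @return A list of class `repeat_reference` with elements `scaffolds`
#'   (tibble: scaffold, length, seq), `unit_genes` (per-copy gene
#'   annotations), `exons` (planted candidate exons with their true copy
#'   multipliers), `gene_models` (gene/exon spans for candidate picking),
#'   `masked_locus`, `template`, `config`.
#' @export
#' @examples
#' ref <- build_reference(unit_template(), simulation_config(seed = 1))
#' ref$masked_locus
build_reference <- function(template, config) {
  if (!inherits(template, "unit_template") || nrow(template) == 0) {
    stop("empty or invalid unit template", call. = FALSE)
  }
  stopifnot(inherits(config, "sim_config"))
  require_seed(config)
  set.seed(config$seed + 1L)

  period <- unit_length(template)
  flank <- 500L
  n_units <- config$n_units

  # per-unit gene annotations on the repeat scaffold
  offsets <- cumsum(c(0L, utils::head(template$length + template$spacer_after, -1L)))
  unit_genes <- purrr::map_dfr(seq_len(n_units), function(u) {
    start <- flank + (u - 1L) * period + offsets + 1L
    tibble::tibble(
      scaffold = "repeat_scaffold",
      gene = template$gene,
      unit = u,
      start = start,
      end = start + template$length - 1L,
      strand = template$strand
    )
  })
  repeat_len <- flank * 2L + n_units * period

  # background scaffolds: one per candidate exon, each BUSCO-like gene also
  # carries a short second exon so the longest-exon rule has work to do
  exon_len <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                     config$n_exons, replace = TRUE)
  short_len <- sample(150:290, config$n_exons, replace = TRUE)
  exons <- tibble::tibble(
    exon = sprintf("SCE%02d", seq_len(config$n_exons)),
    gene_model = sprintf("BUSCO%03d", seq_len(config$n_exons)),
    scaffold = sprintf("bg_scaffold_%02d", seq_len(config$n_exons)),
    start = 201L,
    end = 200L + exon_len,
    length = exon_len,
    copy_multiplier = config$exon_copy_multipliers
  )
  gene_models <- dplyr::bind_rows(
    tibble::tibble(
      gene = exons$gene_model, exon = exons$exon, scaffold = exons$scaffold,
      start = exons$start, end = exons$end
    ),
    tibble::tibble(
      gene = exons$gene_model,
      exon = sprintf("SCE%02d.2", seq_len(config$n_exons)),
      scaffold = exons$scaffold,
      start = exons$end + 101L,
      end = exons$end + 100L + short_len
    )
  ) %>% dplyr::arrange(.data$scaffold, .data$start)

  bg_len <- exons$end + 100L + short_len + 200L
  scaffolds <- tibble::tibble(
    scaffold = c("repeat_scaffold", exons$scaffold),
    length = c(repeat_len, bg_len)
  )
  scaffolds$seq <- purrr::map_chr(scaffolds$length, random_dna)

  masked_locus <- tibble::tibble(
    scaffold = "repeat_scaffold",
    start = flank + 1L,
    end = flank + period
  )

  structure(list(
    scaffolds = scaffolds,
    unit_genes = unit_genes,
    exons = exons,
    gene_models = gene_models,
    masked_locus = masked_locus,
    template = template,
    config = config
  ), class = "repeat_reference")
}

# disjoint clades (plus singleton fill) covering n_asex tips, >= 3 groups
assign_asexual_clades <- function(tree, n_asex) {
  n <- length(tree$tip.label)
  if (n_asex == 0) return(list(tips = character(0), groups = list()))
  cap <- max(2L, ceiling(n_asex / 3))
  parts <- ape::prop.part(tree)
  clades <- Filter(function(x) length(x) >= 2 && length(x) <= cap, as.list(parts))
  # prefer the largest disjoint clades (random among equals) so that
  # reproductive mode is strongly confounded with tree structure
  clades <- clades[sample.int(length(clades))]
  clades <- clades[order(-vapply(clades, length, integer(1)))]
  chosen <- integer(0)
  groups <- list()
  for (cl in clades) {
    if (length(chosen) + length(cl) <= n_asex && !any(cl %in% chosen)) {
      chosen <- c(chosen, cl)
      groups <- c(groups, list(cl))
    }
    if (length(chosen) == n_asex) break
  }
  if (length(chosen) < n_asex) {
    extra <- sample(setdiff(seq_len(n), chosen), n_asex - length(chosen))
    groups <- c(groups, as.list(extra))
    chosen <- c(chosen, extra)
  }
  list(tips = tree$tip.label[chosen],
       groups = lapply(groups, function(g) tree$tip.label[g]))
}

#' Simulate a lineage cohort, its phylogeny, and the planted truth
#'
#' Draws a random coalescent tree over the cohort, assigns asexual labels to
#' at least three separate clades (emulating repeated transitions to
#' asexuality), draws planted per-haploid unit copy numbers uniformly from
#' the mode-specific ranges, and records the expected genomic proportion of
#' the repeat implied by each draw.
#'
#' @param config A [simulation_config()] with a seed.
#' @param template A [unit_template()]; only its total length enters the
#'   expected-proportion arithmetic.
#' @return A list of class `sim_cohort` with `lineages` (tibble: lineage,
#'   mode, ploidy, population, copy_number, frac_5s_missing), `tree` (an
#'   `ape::phylo`), and `truth` (tibble adding `effective_5s` and
#'   `expected_proportion`, in percent).
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 1))
#' nrow(cohort$lineages) # 26
simulate_cohort <- function(config, template = unit_template()) {
  stopifnot(inherits(config, "sim_config"))
  require_seed(config)
  set.seed(config$seed + 2L)

  n_asex <- config$n_asexual_triploid + config$n_asexual_tetraploid
  n <- config$n_sexual + n_asex
  if (n < 2) stop("a cohort needs at least two lineages", call. = FALSE)
  ids <- sprintf("L%02d", seq_len(n))
  # coalescent-style bifurcating topology with iid exponential branch lengths
  tree <- ape::rcoal(n, tip.label = ids)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1)

  asx <- assign_asexual_clades(tree, n_asex)
  mode <- ifelse(ids %in% asx$tips, "asexual", "sexual")
  ploidy <- integer(n)
  ploidy[mode == "sexual"] <- 2L
  asex_ploidies <- rep(c(3L, 4L),
                       c(config$n_asexual_triploid, config$n_asexual_tetraploid))
  ploidy[mode == "asexual"] <- asex_ploidies[sample.int(length(asex_ploidies))]

  # populations: asexuals labeled by origin clade, sexuals by lake-style pool
  population <- character(n)
  population[mode == "sexual"] <- paste0("pop", sample(1:4, sum(mode == "sexual"),
                                                       replace = TRUE))
  for (g in seq_along(asx$groups)) {
    population[match(asx$groups[[g]], ids)] <- paste0("clade", g)
  }

  draw_cn <- function(rng, k) {
    if (k == 0) return(integer(0))
    rng[1] + sample.int(rng[2] - rng[1] + 1L, k, replace = TRUE) - 1L
  }
  copy_number <- integer(n)
  copy_number[mode == "sexual"] <- draw_cn(config$sexual_cn_range, sum(mode == "sexual"))
  copy_number[mode == "asexual"] <- draw_cn(config$asexual_cn_range, sum(mode == "asexual"))
  frac_5s <- runif(n, config$frac_5s_missing_range[1], config$frac_5s_missing_range[2])

  lineages <- tibble::tibble(
    lineage = ids, mode = mode, ploidy = ploidy, population = population,
    copy_number = copy_number, frac_5s_missing = frac_5s
  )
  l_unit <- unit_length(template)
  truth <- lineages %>%
    dplyr::mutate(
      effective_5s = .data$copy_number * (1 - .data$frac_5s_missing),
      expected_proportion = 100 * .data$copy_number * l_unit /
        (config$background_length + .data$copy_number * l_unit)
    )
  structure(list(lineages = lineages, tree = tree, truth = truth),
            class = "sim_cohort")
}

# conditional feature means for one lineage given its effort factor
lineage_feature_means <- function(reference, lineage, effort) {
  config <- reference$config
  tpl <- reference$template
  cn <- lineage$copy_number
  gene_mult <- ifelse(tpl$gene == "5S", cn * (1 - lineage$frac_5s_missing), cn)
  dplyr::bind_rows(
    tibble::tibble(feature = reference$exons$exon,
                   length = reference$exons$length,
                   mean = effort * config$base_depth * reference$exons$copy_multiplier),
    tibble::tibble(feature = tpl$gene,
                   length = tpl$length,
                   mean = effort * config$base_depth * gene_mult)
  )
}

#' Simulate per-base depth and mapped-read counts for one lineage
#'
#' Depth at each base is Poisson around the lineage's Gamma-distributed
#' sequencing-effort factor times the feature's expected single-effort mean:
#' `base_depth` for a single-copy exon base (times the exon's planted copy
#' multiplier), `base_depth * copy_number` for a repeat-unit gene base, and
#' `base_depth * copy_number * (1 - frac_5s_missing)` for 5S bases.
#' Marginally over lineages a single-copy base is therefore negative binomial
#' with mean `base_depth` and size `dispersion`. Mapped-read totals are drawn
#' so that the expected locus/genome read ratio equals the planted genomic
#' proportion.
#'
#' @param reference A [build_reference()] result.
#' @param lineage One row of a cohort's `lineages` tibble (or a list with
#'   `lineage`, `copy_number`, `frac_5s_missing`).
#' @param config The [simulation_config()] used for the cohort.
#' @param seed Integer seed for this lineage's draws.
#' @return List with `depth` (tibble: lineage, feature, position, depth),
#'   `read_counts` (tibble: lineage, reads_locus, reads_genome), and the
#'   realized `effort` factor.
#' @export
simulate_depths <- function(reference, lineage, config, seed) {
  stopifnot(inherits(reference, "repeat_reference"))
  set.seed(as.integer(seed))
  effort <- if (is.finite(config$dispersion)) {
    rgamma(1, shape = config$dispersion, rate = config$dispersion)
  } else 1
  means <- lineage_feature_means(reference, lineage, effort)
  depth <- means %>%
    dplyr::mutate(depth = purrr::map2(.data$length, .data$mean,
                                      function(n, mu) rpois(n, mu))) %>%
    dplyr::transmute(
      lineage = lineage$lineage,
      feature = .data$feature,
      position = purrr::map(.data$length, seq_len),
      depth = .data$depth
    ) %>%
    tidyr::unnest(c("position", "depth"))

  l_unit <- unit_length(reference$template)
  cn <- lineage$copy_number
  p_locus <- cn * l_unit / (config$background_length + cn * l_unit)
  lambda <- effort * config$base_depth *
    (config$background_length + cn * l_unit) / config$read_length
  reads_genome <- rpois(1, lambda)
  reads_locus <- rbinom(1, reads_genome, p_locus)
  list(
    depth = depth,
    read_counts = tibble::tibble(lineage = lineage$lineage,
                                 reads_locus = reads_locus,
                                 reads_genome = reads_genome),
    effort = effort
  )
}

#' Simulate depth tables and read counts for a whole cohort
#'
#' @param reference A [build_reference()] result.
#' @param cohort A [simulate_cohort()] result.
#' @param config The shared [simulation_config()].
#' @return List with `depth` (long tibble over all lineages), `read_counts`,
#'   and `efforts` (tibble: lineage, effort).
#' @export
#' @examples
#' cfg <- simulation_config(n_sexual = 2, n_asexual_triploid = 2,
#'                          n_asexual_tetraploid = 0, n_exons = 4, seed = 7)
#' ref <- build_reference(unit_template(), cfg)
#' cohort <- simulate_cohort(cfg)
#' sim <- simulate_cohort_depths(ref, cohort, cfg)
#' dplyr::count(sim$depth, lineage)
simulate_cohort_depths <- function(reference, cohort, config) {
  stopifnot(inherits(cohort, "sim_cohort"))
  require_seed(config)
  rows <- split(cohort$lineages, seq_len(nrow(cohort$lineages)))
  sims <- purrr::imap(rows, function(row, i) {
    simulate_depths(reference, row, config, seed = config$seed + 100L + as.integer(i))
  })
  list(
    depth = purrr::map_dfr(sims, "depth"),
    read_counts = purrr::map_dfr(sims, "read_counts"),
    efforts = tibble::tibble(
      lineage = cohort$lineages$lineage,
      effort = purrr::map_dbl(sims, "effort")
    )
  )
}

#' Emit exact homology-hit coordinates for the synthetic reference
#'
#' Converts the reference's per-copy unit-gene annotations into a tabular
#' homology-hit table (BLAST outfmt-6 column layout) with perfect identity,
#' as an idealized stand-in for a BLASTN search of the eight query genes
#' against the assembly. Minus-strand hits are encoded by `sstart > send`.
#'
#' @param reference A [build_reference()] result.
#' @return Tibble with outfmt-6-style columns (`qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`).
#' @export
reference_hits <- function(reference) {
  ug <- reference$unit_genes
  len <- ug$end - ug$start + 1L
  tibble::tibble(
    qseqid = ug$gene,
    sseqid = ug$scaffold,
    pident = 100,
    length = len,
    mismatch = 0L,
    gapopen = 0L,
    qstart = 1L,
    qend = len,
    sstart = ifelse(ug$strand == "+", ug$start, ug$end),
    send = ifelse(ug$strand == "+", ug$end, ug$start),
    evalue = 0,
    bitscore = 2 * len
  )
}
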