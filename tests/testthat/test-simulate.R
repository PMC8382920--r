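test_that("unit template validates and sums to the configured period", {
  tpl <- unit_template()
  expect_equal(unit_length(tpl), 13000)
  expect_setequal(tpl$gene, rdna_histone_genes())
  expect_error(unit_template(genes = character(0)), "at least one gene")
  expect_error(unit_template(genes = c("18S", "18S"),
                             lengths = c(100, 100), strands = c("+", "+"),
                             spacers = c(0, 0)), "only once")
  expect_error(unit_template(genes = "XYZ", lengths = 100, strands = "+",
                             spacers = 0), "unknown gene")
})

test_that("simulation_config rejects invalid parameters", {
  expect_error(simulation_config(n_exons = 0, seed = 1), "configuration error")
  expect_error(simulation_config(base_depth = 0, seed = 1), "base_depth")
  expect_error(simulation_config(dispersion = -1, seed = 1), "dispersion")
  expect_error(simulation_config(sexual_cn_range = c(30, 10), seed = 1),
               "non-empty integer interval")
  expect_error(build_reference(unit_template(), simulation_config()),
               "seed is mandatory")
})

test_that("build_reference lays out the masked locus and exon annotations", {
  cfg <- simulation_config(n_exons = 10L,
                           exon_copy_multipliers = rep(1, 10), seed = 3)
  ref <- build_reference(unit_template(), cfg)
  locus <- ref$masked_locus
  expect_equal(locus$end - locus$start + 1L, 13000L)
  expect_equal(nrow(ref$exons), 10L)
  expect_true(all(ref$exons$length >= 300))
  # one unit-gene annotation per gene per unit, 1-based inclusive
  expect_equal(nrow(ref$unit_genes), 8L * cfg$n_units)
  expect_true(all(ref$unit_genes$start >= 1))
  tpl <- unit_template()
  lens <- ref$unit_genes$end - ref$unit_genes$start + 1L
  expect_equal(sort(unique(lens)), sort(unique(tpl$length)))
})

test_that("simulate_cohort conserves counts, is deterministic, and spreads asexual clades", {
  cfg <- simulation_config(seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$lineages), 26L)
  expect_equal(sum(cohort$lineages$mode == "sexual"), 10L)
  expect_equal(sum(cohort$lineages$ploidy == 3), 12L)
  expect_equal(sum(cohort$lineages$ploidy == 4), 4L)
  expect_s3_class(cohort$tree, "phylo")
  expect_setequal(cohort$tree$tip.label, cohort$lineages$lineage)
  expect_true(all(cohort$tree$edge.length > 0))
  # newick round trip
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(cohort$tree, f)
  expect_s3_class(ape::read.tree(f), "phylo")
  # asexual labels fall in >= 3 separate population clusters
  asex_pops <- unique(cohort$lineages$population[cohort$lineages$mode == "asexual"])
  expect_gte(length(asex_pops), 3L)

  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$lineages, cohort2$lineages)
  expect_identical(ape::write.tree(cohort$tree), ape::write.tree(cohort2$tree))

  # disjoint mode ranges imply strict separation of planted copy numbers
  cn <- cohort$lineages$copy_number
  expect_true(min(cn[cohort$lineages$mode == "asexual"]) >
                max(cn[cohort$lineages$mode == "sexual"]))

  # truth table consistency
  l_unit <- unit_length(unit_template())
  expect_equal(cohort$truth$expected_proportion,
               100 * cn * l_unit / (cfg$background_length + cn * l_unit))
})

test_that("depth generator matches its distributional contract", {
  # Poisson limit: effort factor degenerates to 1 and the sample mean of a
  # long single-copy track is within 3 standard errors of the base depth
  cfg <- simulation_config(n_exons = 1L, exon_copy_multipliers = 1,
                           exon_length_range = c(10000L, 10000L),
                           dispersion = Inf, seed = 11)
  ref <- build_reference(unit_template(), cfg)
  sim <- one_lineage_depths(ref, cn = 1, seed = 77)
  expect_equal(sim$effort, 1)
  exon_track <- sim$depth$depth[sim$depth$feature == ref$exons$exon[1]]
  se <- sqrt(cfg$base_depth / length(exon_track))
  expect_lt(abs(mean(exon_track) - cfg$base_depth), 3 * se)

  # copy number 20 at depth 25: median unit-gene depth tracks the conditional
  # mean effort * 500 (Monte-Carlo at fixed seed, oracle = Poisson quantile)
  cfg2 <- simulation_config(seed = 12)
  ref2 <- build_reference(unit_template(), cfg2)
  sim2 <- one_lineage_depths(ref2, cn = 20, seed = 78)
  med_28s <- median(sim2$depth$depth[sim2$depth$feature == "28S"])
  expect_lt(abs(med_28s - qpois(0.5, sim2$effort * 500)) /
              qpois(0.5, sim2$effort * 500), 0.05)
  # the marginal negative-binomial median sits within 5% of mean 500
  expect_lt(abs(qnbinom(0.5, size = 10, mu = 500) - 500) / 500, 0.05)

  # zero 5S dropout: 5S depth mean matches the other unit genes
  sim3 <- one_lineage_depths(ref2, cn = 20, seed = 79, frac_5s = 0)
  d3 <- sim3$depth
  m5s <- mean(d3$depth[d3$feature == "5S"])
  m18 <- mean(d3$depth[d3$feature == "18S"])
  expect_lt(abs(m5s - m18) / m18, 0.10)
})

test_that("cohort depth simulation is seed-deterministic", {
  cfg <- small_config(seed = 21)
  ref <- build_reference(unit_template(), cfg)
  cohort <- simulate_cohort(cfg)
  s1 <- simulate_cohort_depths(ref, cohort, cfg)
  s2 <- simulate_cohort_depths(ref, cohort, cfg)
  expect_identical(s1$depth, s2$depth)
  expect_identical(s1$read_counts, s2$read_counts)
})

test_that("read-count draws respect the planted genomic proportion", {
  cfg <- simulation_config(seed = 31)
  ref <- build_reference(unit_template(), cfg)
  cohort <- simulate_cohort(cfg)
  sim <- simulate_cohort_depths(ref, cohort, cfg)
  prop <- proportion_table(sim$read_counts)
  joined <- dplyr::inner_join(prop, cohort$truth, by = "lineage")
  expect_true(all(joined$reads_locus <= joined$reads_genome))
  rel <- abs(joined$proportion_pct - joined$expected_proportion) /
    joined$expected_proportion
  expect_lt(max(rel), 0.10)
})
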