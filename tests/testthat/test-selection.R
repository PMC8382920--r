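test_that("candidate picking keeps the longest exon above threshold", {
  gm <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3", "g3"),
    exon = c("e1a", "e1b", "e2", "e3a", "e3b"),
    scaffold = c("s1", "s1", "s2", "s3", "s3"),
    start = c(1L, 500L, 1L, 900L, 100L),
    end = c(250L, 899L, 299L, 1299L, 499L)
  )
  cand <- pick_candidate_exons(gm)
  # g1: 400 bp beats 250 bp; g2: single 299 bp exon is below threshold;
  # g3: equal 400 bp exons, first by coordinate order wins
  expect_setequal(cand$gene, c("g1", "g3"))
  expect_equal(cand$exon[cand$gene == "g1"], "e1b")
  expect_equal(cand$exon[cand$gene == "g3"], "e3b")

  expect_error(pick_candidate_exons(dplyr::mutate(gm, end = start - 2L)),
               "malformed")
})

test_that("concordance rule is a max/min ratio with an all-zero escape", {
  expect_true(concordance_pass(100, 100, 100))
  expect_false(concordance_pass(105, 100, 95)) # 105/95 > 1.10
  expect_true(concordance_pass(104, 100, 95))  # 104/95 <= 1.10
  expect_true(concordance_pass(0, 0, 0))
  expect_false(concordance_pass(1, 0, 0))
  expect_error(concordance_pass(-1, 1, 1), "non-negative")
})

test_that("tightening tolerance never enlarges the pass set", {
  set.seed(7)
  m <- runif(200, 10, 40)
  md <- m * runif(200, 0.85, 1.15)
  mo <- m * runif(200, 0.85, 1.15)
  tols <- c(0.25, 0.15, 0.10, 0.05, 0)
  passes <- lapply(tols, function(t) which(concordance_pass(m, md, mo, t)))
  for (i in seq_len(length(tols) - 1)) {
    expect_true(all(passes[[i + 1]] %in% passes[[i]]))
  }
})

test_that("retention threshold rescales 20/27 and filters by pass count", {
  expect_identical(retention_threshold(27), 20L)
  expect_identical(retention_threshold(26), 20L)
  expect_identical(retention_threshold(10), 8L)

  pass <- tidyr::crossing(exon = c("e1", "e2", "e3"),
                          lineage = c("l1", "l2", "l3")) %>%
    dplyr::mutate(pass = c(TRUE, TRUE, TRUE,   # e1: 3 passes
                           TRUE, TRUE, FALSE,  # e2: 2
                           TRUE, FALSE, FALSE)) # e3: 1
  expect_setequal(retain_exons(pass, min_lineages = 2), c("e1", "e2"))
  expect_error(retain_exons(pass, min_lineages = 4), "exceeds the cohort")

  # a 19/27 exon is dropped at the default threshold of 20
  pass27 <- tidyr::crossing(exon = "e1", lineage = sprintf("l%02d", 1:27)) %>%
    dplyr::mutate(pass = c(rep(TRUE, 19), rep(FALSE, 8)))
  expect_length(retain_exons(pass27), 0)
  pass27$pass[20] <- TRUE
  expect_identical(retain_exons(pass27), "e1")

  # increasing min_lineages never enlarges the retained set
  set.seed(8)
  pass_rand <- tidyr::crossing(exon = sprintf("e%02d", 1:12),
                               lineage = sprintf("l%02d", 1:10)) %>%
    dplyr::mutate(pass = runif(dplyr::n()) < 0.7)
  prev <- retain_exons(pass_rand, min_lineages = 1)
  for (k in 2:10) {
    cur <- retain_exons(pass_rand, min_lineages = k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("high-coverage outlier exclusion matches direct arithmetic", {
  em <- function(v) {
    tidyr::crossing(lineage = c("a", "b", "c"),
                    tibble::tibble(exon = sprintf("e%d", seq_along(v)),
                                   median_depth = v))
  }
  r1 <- exclude_high_coverage(em(c(25, 26, 24, 275)))
  expect_identical(r1$exon[r1$excluded], "e4")
  expect_equal(r1$times_median[r1$exon == "e4"], 275 / 25.5, tolerance = 1e-10)

  r2 <- exclude_high_coverage(em(c(25, 25, 25)))
  expect_false(any(r2$excluded))

  r3 <- exclude_high_coverage(em(c(25, 26, 24, 45)))
  expect_false(any(r3$excluded)) # 45 / 25.5 < 2

  expect_warning(r4 <- exclude_high_coverage(em(c(25, 26))), "fewer than 3")
  expect_false(any(r4$excluded))
})

test_that("outlier exclusion is a fixed point on depth-like exon sets", {
  set.seed(9)
  for (i in 1:30) {
    n_sc <- sample(8:14, 1)
    meds <- c(rnorm(n_sc, 25, 1.5),
              25 * runif(sample(0:2, 1), 8, 16)) # 0-2 planted outliers
    em <- tidyr::crossing(lineage = c("a", "b", "c"),
                          tibble::tibble(exon = sprintf("e%02d", seq_along(meds)),
                                         median_depth = meds))
    r1 <- exclude_high_coverage(em, factor = 2)
    surviving <- r1$exon[!r1$excluded]
    r2 <- exclude_high_coverage(dplyr::filter(em, exon %in% surviving),
                                factor = 2)
    expect_false(any(r2$excluded))
  }
})

test_that("a planted 12x exon, and only it, is excluded on simulated cohorts", {
  hits <- vapply(1:12, function(s) {
    cfg <- small_config(seed = 400 + s)
    ref <- build_reference(unit_template(), cfg)
    cohort <- simulate_cohort(cfg)
    sim <- simulate_cohort_depths(ref, cohort, cfg)
    summaries <- summarize_coverage(sim$depth) %>%
      dplyr::filter(feature %in% ref$exons$exon)
    sel <- select_single_copy(summaries, min_lineages = 3)
    identical(sel$excluded$exon, "SCE06")
  }, logical(1))
  expect_true(all(hits))
})

test_that("selection on the default cohort retains ten exons and flags the planted outliers", {
  cfg <- simulation_config(seed = 1)
  ref <- build_reference(unit_template(), cfg)
  cohort <- simulate_cohort(cfg)
  sim <- simulate_cohort_depths(ref, cohort, cfg)
  cand <- pick_candidate_exons(ref$gene_models, cfg$min_exon_length)
  expect_equal(nrow(cand), 12L)
  sel <- select_single_copy(
    dplyr::filter(summarize_coverage(sim$depth), feature %in% cand$exon))
  expect_length(sel$retained, 10L)
  expect_setequal(sel$excluded$exon, c("SCE11", "SCE12"))
  expect_equal(sort(sel$excluded$times_median), c(11, 15), tolerance = 0.15)
  expect_equal(sel$min_lineages, 20L)
})
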