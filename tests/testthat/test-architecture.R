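# hand-built filtered-hit fixture: tandem units anchored at 28S, with the
# histones and 5S between successive 45S cassettes
unit_layout <- tibble::tibble(
  gene = c("28S", "5S", "H2A", "H2B", "H3", "H4", "18S", "5.8S"),
  offset = c(0, 5500, 6120, 6920, 7720, 8520, 10040, 12240),
  len = c(3500, 120, 400, 400, 400, 300, 1800, 160),
  strand = c("+", "+", "-", "+", "-", "+", "+", "+")
)

make_unit_hits <- function(n_units, period = 13000, origin = 1000,
                           drop = NULL, shift = 0) {
  purrr::map_dfr(seq_len(n_units), function(u) {
    lay <- unit_layout
    if (!is.null(drop) && u %in% names(drop)) {
      lay <- dplyr::filter(lay, !gene %in% drop[[as.character(u)]])
    }
    dplyr::transmute(lay,
      gene, scaffold = "scf1",
      start = origin + (u - 1) * period + offset + shift,
      end = start + len - 1,
      strand, evalue = 0, pident = 100)
  })
}

test_that("hit filtering applies the e-value cutoff and strand normalization", {
  hits <- tibble::tibble(
    qseqid = c("18S", "18S", "5S"), sseqid = "scf1",
    pident = c(99, 98, 97), length = c(1800, 1800, 400),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 400,
    sstart = c(100, 5000, 500), send = c(1899, 6799, 101),
    evalue = c(1e-60, 1e-40, 1e-120), bitscore = 100
  )
  out <- filter_hits(hits)
  expect_equal(nrow(out), 2L) # the 1e-40 hit is dropped
  minus <- out[out$gene == "5S", ]
  expect_equal(minus$start, 101)
  expect_equal(minus$end, 500)
  expect_equal(minus$strand, "-")
  expect_error(filter_hits(dplyr::mutate(hits, sstart = c(-5, 1, 1))),
               "coordinates")
})

test_that("tabular hit files round-trip through read_blast_hits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(q = "18S", s = "scf1", p = 100, l = 1800, mm = 0L, g = 0L,
                   qs = 1L, qe = 1800L, ss = 100L, se = 1899L,
                   ev = 0, bs = 3600),
    f, col_names = FALSE)
  h <- read_blast_hits(f)
  expect_named(h, c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore"))
  expect_equal(h$sstart, 100)
})

test_that("three exact tandem units give period 13000 and count 3", {
  model <- infer_unit_model(make_unit_hits(3))
  expect_equal(model$anchor, "28S")
  expect_equal(model$period, 13000)
  expect_equal(model$n_units, 3L)
  expect_false(model$single_unit)
  expect_setequal(model$consensus$gene, unit_layout$gene)
  expect_equal(model$consensus$gene[order(model$consensus$offset)],
               unit_layout$gene)
  # orientations are relative to the anchor's strand
  expect_equal(model$consensus$orientation[model$consensus$gene == "H2A"], "-")
  expect_equal(model$consensus$orientation[model$consensus$gene == "H4"], "+")
})

test_that("a single unit is flagged with undefined period", {
  model <- infer_unit_model(make_unit_hits(1))
  expect_true(model$single_unit)
  expect_equal(model$n_units, 1L)
  expect_true(is.na(model$period))
  lines <- report_unit_model(model)
  expect_true(any(grepl("single unit", lines)))
})

test_that("a unit missing 5S still votes; consensus keeps 5S by majority", {
  hits <- make_unit_hits(3, drop = list(`2` = "5S"))
  model <- infer_unit_model(hits)
  expect_true("5S" %in% model$consensus$gene)
  s <- model$consensus[model$consensus$gene == "5S", ]
  expect_equal(s$support, 2L)
  expect_equal(s$n_voting, 3L)
  # per-unit presence records the absence in unit 2
  present <- model$per_unit_genes
  expect_false(any(present$unit == 2 & present$gene == "5S"))
  expect_true(any(present$unit == 1 & present$gene == "5S"))
})

test_that("the model is invariant to coordinate translation", {
  m0 <- infer_unit_model(make_unit_hits(3))
  m1 <- infer_unit_model(make_unit_hits(3, shift = 54321))
  expect_equal(m1$period, m0$period)
  expect_equal(m1$n_units, m0$n_units)
  expect_equal(m1$consensus, m0$consensus)
})

test_that("reverse-complementing the scaffold mirrors the consensus", {
  hits <- make_unit_hits(3)
  L <- max(hits$end) + 1000
  flipped <- hits %>%
    dplyr::mutate(
      new_start = L - end + 1, new_end = L - start + 1,
      start = new_start, end = new_end,
      strand = ifelse(strand == "+", "-", "+")
    ) %>%
    dplyr::select(-new_start, -new_end)
  m0 <- infer_unit_model(hits)
  m1 <- infer_unit_model(flipped)
  expect_equal(m1$period, m0$period)
  expect_equal(m1$n_units, m0$n_units)
  # mirrored gene order, up to cyclic rotation: the anchor re-roots the unit
  # at offset 0, so the reversed order is compared after rotating it to
  # start at the anchor
  ord0 <- m0$consensus$gene[order(m0$consensus$offset)]
  ord1 <- m1$consensus$gene[order(m1$consensus$offset)]
  rev0 <- rev(ord0)
  k <- which(rev0 == m1$anchor)
  rotated <- rev0[c(k:length(rev0), seq_len(k - 1))]
  expect_equal(ord1, rotated)
  # absolute strands all invert; anchor-relative orientations are preserved
  s0 <- m0$consensus[order(m0$consensus$gene), ]
  s1 <- m1$consensus[order(m1$consensus$gene), ]
  expect_true(all(s1$strand != s0$strand))
  expect_equal(s1$orientation, s0$orientation)
})

test_that("synthetic references are recovered exactly for 2 to 4 units", {
  for (n in 2:4) {
    cfg <- simulation_config(n_units = n, n_exons = 3L,
                             exon_copy_multipliers = rep(1, 3), seed = 70 + n)
    ref <- build_reference(unit_template(), cfg)
    model <- infer_unit_model(filter_hits(reference_hits(ref)))
    expect_equal(model$period, 13000)
    expect_equal(model$n_units, n)
  }
})

test_that("the text report is deterministic and complete", {
  model <- infer_unit_model(make_unit_hits(3))
  r1 <- report_unit_model(model)
  r2 <- report_unit_model(model)
  expect_identical(r1, r2)
  expect_equal(sum(grepl("support", r1)), 8L) # one row per consensus gene
})
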