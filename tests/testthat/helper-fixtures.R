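# shared fixtures and independent oracles used across test files

# small, fast cohort: 2 sexual + 2 triploid asexual lineages, 6 exons
small_config <- function(seed, ...) {
  simulation_config(
    n_sexual = 2L, n_asexual_triploid = 2L, n_asexual_tetraploid = 0L,
    n_exons = 6L, exon_copy_multipliers = c(1, 1, 1, 1, 1, 12),
    seed = seed, ...
  )
}

# build a depth tibble from a named list of per-feature depth vectors
depth_tbl <- function(tracks, lineage = NULL) {
  out <- purrr::imap_dfr(tracks, function(d, f) {
    tibble::tibble(feature = f, position = seq_along(d), depth = as.integer(d))
  })
  if (!is.null(lineage)) out <- dplyr::mutate(out, lineage = lineage, .before = 1)
  out
}

# exhaustive mode: frequency count over unique values, smallest wins ties
oracle_mode <- function(x) {
  u <- sort(unique(x))
  counts <- vapply(u, function(v) sum(x == v), numeric(1))
  u[which.max(counts)]
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Benjamini-Hochberg step-up by the hand formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# simulated depths for one lineage with explicit copy number, via the package
one_lineage_depths <- function(reference, cn, seed, frac_5s = 0) {
  lineage <- tibble::tibble(lineage = "LX", mode = "asexual", ploidy = 3L,
                            population = "cladeA", copy_number = cn,
                            frac_5s_missing = frac_5s)
  simulate_depths(reference, lineage, reference$config, seed = seed)
}
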