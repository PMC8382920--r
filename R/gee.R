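#' Phylogenetic working correlation from a tree
#'
#' Shared ancestry induces correlation among lineages: the covariance
#' between two tips is the branch length shared from the root to their most
#' recent common ancestor, and the correlation scales that by the square
#' roots of the two tip depths. For an ultrametric tree the diagonal is
#' exactly 1; a star tree yields the identity.
#'
#' @param tree An `ape::phylo` with branch lengths; tip labels are the
#'   lineage ids.
#' @param lineages Optional character vector giving the row/column order;
#'   must match the tip labels as a set. Default: tree tip order.
#' @return Lineage x lineage correlation matrix (positive semi-definite).
#' @export
phylo_correlation <- function(tree, lineages = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  v <- ape::vcv(tree)
  depths <- diag(v)
  if (any(depths <= 0)) stop("zero root-to-tip depth", call. = FALSE)
  r <- stats::cov2cor(v)
  if (!is.null(lineages)) {
    if (!setequal(lineages, rownames(r)) || length(lineages) != nrow(r)) {
      stop("lineage ids do not match the tree's tip labels", call. = FALSE)
    }
    r <- r[lineages, lineages]
  }
  r
}

#' Phylogenetic degrees of freedom of a tree
#'
#' A tree with long shared branches carries far less independent information
#' than its number of tips. The phylogenetic degrees of freedom rescale the
#' tip count by the ratio of total branch length to the summed root-to-tip
#' depths: a star tree returns the full tip count, a tree of clones returns
#' values near 1.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Effective degrees of freedom (numeric scalar, between 1 and the
#'   number of tips).
#' @export
phylo_df <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  n <- length(tree$tip.label)
  sum(tree$edge.length) * n / sum(diag(ape::vcv(tree)))
}

#' Poisson regression with generalized estimating equations
#'
#' Fits a log-link Poisson-family marginal regression of a non-negative
#' response (copy-number estimates need not be integers; only the
#' mean-variance relation is used) with a fixed working correlation `R`,
#' typically [phylo_correlation()] of the cohort tree. Coefficients solve
#' the quasi-score equation by Fisher scoring with working covariance
#' `phi * A^{1/2} R A^{1/2}` (variance function `A = diag(mu)`); the
#' dispersion `phi` is estimated from Pearson residuals. With a
#' phylogenetic working correlation the cohort forms a single cluster, so
#' Wald inference uses the model-based (dispersion-scaled) covariance; the
#' one-cluster sandwich matrix, which is rank-deficient in this design, is
#' stored as `vcov_robust` for inspection.
#'
#' When a `tree` is supplied, the working correlation is taken from
#' [phylo_correlation()] (unless given explicitly) and Wald p-values use a
#' t reference with `phylo_df(tree) - p` degrees of freedom -- shared
#' ancestry leaves far fewer than `n` independent observations, and the
#' normal reference is anti-conservative in that regime. Without a tree (or
#' with `df = Inf`) the standard normal reference is used.
#'
#' @param formula Model formula, e.g. `copy_number ~ mode`.
#' @param data Data frame with the response and covariates, one row per
#'   lineage, in the same order as the rows of `correlation`.
#' @param correlation Working correlation matrix (identity if `NULL` and no
#'   tree is given). If it has dimnames and `data` has a `lineage` column,
#'   rows are aligned by id.
#' @param tree Optional `ape::phylo` over the lineages; sets both the
#'   working correlation (if not given) and the small-sample t reference.
#' @param df Degrees of freedom for the Wald t reference; `Inf` (the
#'   default without a tree) means standard normal.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @return Object of class `phylo_gee` with coefficients, standard errors,
#'   Wald statistics and p-values, dispersion, iteration count, convergence
#'   flag, fitted values, and both covariance estimates.
#' @export
#' @examples
#' d <- tibble::tibble(y = c(2, 3, 2, 9, 11, 10),
#'                     mode = rep(c("sexual", "asexual"), each = 3))
#' fit <- fit_poisson_gee(y ~ mode, d)
#' tidy(fit)
fit_poisson_gee <- function(formula, data, correlation = NULL, tree = NULL,
                            df = NULL, max_iter = 50, tol = 1e-8) {
  if (!is.null(tree)) {
    if (is.null(correlation)) {
      correlation <- phylo_correlation(
        tree, lineages = if ("lineage" %in% names(data)) data$lineage else NULL)
    }
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (any(y < 0)) stop("response must be non-negative", call. = FALSE)
  if (qr(X)$rank < p) stop("singular design matrix", call. = FALSE)
  if (is.null(correlation)) {
    R <- diag(n)
  } else {
    R <- correlation
    if (!is.null(rownames(R)) && "lineage" %in% names(data)) {
      if (!setequal(rownames(R), data$lineage)) {
        stop("correlation dimnames do not match data$lineage", call. = FALSE)
      }
      R <- R[data$lineage, data$lineage]
    }
    stopifnot(nrow(R) == n, ncol(R) == n)
  }

  # scale-invariant quasi-score criterion used to safeguard the updates
  score_crit <- function(beta) {
    mu <- exp(drop(X %*% beta))
    A_half <- sqrt(mu)
    V0 <- (A_half %o% A_half) * R
    D <- X * mu
    V0_inv_D <- solve(V0, D)
    B <- crossprod(D, V0_inv_D)
    score <- crossprod(V0_inv_D, y - mu)
    list(crit = drop(crossprod(score, solve(B, score))),
         delta = drop(solve(B, score)))
  }

  beta <- c(log(mean(y) + 1e-8), rep(0, p - 1))
  names(beta) <- colnames(X)
  converged <- FALSE
  iter <- 0
  cur <- score_crit(beta)
  for (iter in seq_len(max_iter)) {
    # Fisher-scoring step with step-halving: shrink the update until the
    # quasi-score criterion decreases (guards against 2-cycle oscillation)
    step <- cur$delta
    for (h in 0:20) {
      cand <- beta + step
      nxt <- score_crit(cand)
      if (nxt$crit <= cur$crit || max(abs(step)) < tol) break
      step <- step / 2
    }
    beta <- cand
    cur <- nxt
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("GEE did not converge in ", max_iter, " iterations", call. = FALSE)
  }

  eta <- drop(X %*% beta)
  mu <- exp(eta)
  pearson <- (y - mu) / sqrt(mu)
  phi <- sum(pearson^2) / (n - p)
  A_half <- sqrt(mu)
  V0 <- (A_half %o% A_half) * R
  D <- X * mu
  V0_inv_D <- solve(V0, D)
  B <- crossprod(D, V0_inv_D)
  B_inv <- solve(B)
  vcov_model <- phi * B_inv
  meat <- crossprod(V0_inv_D, (y - mu)) %*% t(crossprod(V0_inv_D, (y - mu)))
  vcov_robust <- B_inv %*% meat %*% B_inv

  if (is.null(df)) {
    df <- if (is.null(tree)) Inf else max(phylo_df(tree) - p, 1)
  }
  se <- sqrt(diag(vcov_model))
  z <- beta / se
  pval <- 2 * stats::pt(-abs(z), df = df)
  structure(list(
    coefficients = beta, se = se, z = z, p_value = pval, df = df,
    dispersion = phi, iter = iter, converged = converged,
    fitted = mu, residuals_pearson = pearson,
    vcov = vcov_model, vcov_robust = vcov_robust,
    correlation = R, n = n, formula = formula, call = match.call()
  ), class = "phylo_gee")
}

#' @export
print.phylo_gee <- function(x, ...) {
  cat("Poisson GEE (log link",
      if (isTRUE(all.equal(x$correlation, diag(x$n)))) ", independence working correlation)"
      else ", phylogenetic working correlation)", "\n", sep = "")
  print(tidy(x))
  cat(sprintf("dispersion %.3f; Wald reference: %s; %d iterations; converged: %s\n",
              x$dispersion,
              if (is.infinite(x$df)) "normal" else sprintf("t (df %.2f)", x$df),
              x$iter, x$converged))
  invisible(x)
}

#' Tidy the coefficient table of a Poisson GEE fit
#'
#' @param x A `phylo_gee` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.phylo_gee <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p_value)
  )
}

#' One-row model summary of a Poisson GEE fit
#'
#' @param x A `phylo_gee` object.
#' @param ... Unused.
#' @return Tibble with `nobs`, `dispersion`, `n.iter`, `converged`.
#' @exportS3Method generics::glance
glance.phylo_gee <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    dispersion = x$dispersion,
    df = x$df,
    n.iter = x$iter,
    converged = x$converged
  )
}
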