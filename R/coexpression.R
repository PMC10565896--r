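#' Median-normalize an expression matrix
#'
#' Divides every gene row by its median across timepoints, the usual
#' within-gene rescaling that puts genes measured at different absolute
#' levels on the same relative scale. Rows whose median is zero (or not
#' finite) cannot be rescaled and are dropped with a warning. Spearman
#' correlations between rows are unchanged by this positive rescaling.
#'
#' @param mat Numeric matrix, genes x timepoints, with gene ids as
#'   rownames.
#' @return The normalized matrix with attribute `normalized = TRUE`;
#'   dropped gene ids are recorded in attribute `dropped`.
#' @export
median_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  med <- apply(mat, 1, median, na.rm = TRUE)
  bad <- !is.finite(med) | med == 0
  if (any(bad)) {
    warnf("dropping %d gene(s) with zero or undefined median expression",
          sum(bad))
  }
  out <- mat[!bad, , drop = FALSE] / med[!bad]
  attr(out, "normalized") <- TRUE
  attr(out, "dropped") <- rownames(mat)[bad]
  out
}

## rank-transform rows, then center and scale each row so that
## tcrossprod() of the result gives the pairwise Spearman matrix
spearman_row_ranks <- function(mat) {
  rk <- t(apply(mat, 1, rank, ties.method = "average"))
  rk <- rk - rowMeans(rk)
  nrm <- sqrt(rowSums(rk^2))
  ok <- nrm > 0
  rk[ok, ] <- rk[ok, , drop = FALSE] / nrm[ok]
  rk[!ok, ] <- NA_real_
  rk
}

#' Mean pairwise Spearman correlation within a gene set
#'
#' Averages Spearman's rho over all unordered pairs of the set, with
#' average ranks for ties. With k genes there are k(k-1)/2 pairs.
#'
#' @param mat Expression matrix (genes x timepoints), rownames = gene ids.
#' @param gene_set Character vector of member gene ids (>= 2, all present).
#' @return List with `rho_mean` and `num_pairs`.
#' @export
mean_pairwise_spearman <- function(mat, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2) stopf("gene_set needs at least 2 members")
  missing <- setdiff(gene_set, rownames(mat))
  if (length(missing) > 0) {
    stopf("gene set members absent from matrix: %s",
          paste(missing, collapse = ", "))
  }
  rk <- spearman_row_ranks(mat[gene_set, , drop = FALSE])
  k <- length(gene_set)
  cc <- tcrossprod(rk)
  rho <- (sum(cc) - sum(diag(cc))) / (k * (k - 1))
  list(rho_mean = rho, num_pairs = as.integer(k * (k - 1L) / 2L))
}

#' Bootstrap null for gene-set co-expression
#'
#' Compares an observed set-mean pairwise Spearman correlation against the
#' distribution of the same statistic for `B` random gene sets of equal
#' size drawn uniformly without replacement from all measured genes
#' (candidate members included, as nothing excludes them from a random
#' draw). Genes whose expression is constant across timepoints have no
#' defined rank correlation and are removed from the universe first.
#'
#' @param mat Expression matrix (genes x timepoints).
#' @param set_size Size of each random set.
#' @param B Number of bootstrap sets (default 10000).
#' @param seed Integer seed for the draw sequence.
#' @param observed_set Character vector of gene ids whose co-expression is
#'   being tested; its mean pairwise rho becomes `rho_obs`. Alternatively
#'   supply `rho_obs` directly.
#' @param rho_obs Observed statistic, if precomputed.
#' @return List of class `bootstrap_null_result`: `rho_obs`, `B`,
#'   `null_means`, `percentile` (share of null means below `rho_obs`,
#'   in percent) and add-one empirical `p`
#'   = (1 + #\{null >= rho_obs\}) / (1 + B).
#' @export
bootstrap_null <- function(mat, set_size, B = 10000, seed = 1L,
                           observed_set = NULL, rho_obs = NULL) {
  if (B < 100) warnf("B = %d bootstrap sets gives an unstable tail", B)
  rk <- spearman_row_ranks(mat)
  constant <- !is.finite(rk[, 1])
  if (any(constant)) {
    message(sprintf("excluding %d constant gene(s) from the universe",
                    sum(constant)))
    rk <- rk[!constant, , drop = FALSE]
  }
  universe <- rownames(rk)
  if (length(universe) <= set_size) {
    stopf("gene universe (%d) must exceed set_size (%d)",
          length(universe), set_size)
  }
  if (is.null(rho_obs)) {
    if (is.null(observed_set)) stopf("supply observed_set or rho_obs")
    rho_obs <- mean_pairwise_spearman(mat, observed_set)$rho_mean
  }
  set.seed(seed)
  null_means <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(rk), set_size)
    cc <- tcrossprod(rk[idx, , drop = FALSE])
    (sum(cc) - sum(diag(cc))) / (set_size * (set_size - 1))
  }, numeric(1))
  structure(
    list(rho_obs = rho_obs, B = as.integer(B), null_means = null_means,
         percentile = 100 * sum(null_means < rho_obs) / B,
         p = (1 + sum(null_means >= rho_obs)) / (1 + B)),
    class = "bootstrap_null_result")
}

#' @export
print.bootstrap_null_result <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_null_result> rho_obs = %.4f, null mean = %.4f",
                     " (B = %d), percentile = %.1f%%, p = %.4g\n"),
              x$rho_obs, mean(x$null_means), x$B, x$percentile, x$p))
  invisible(x)
}
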