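#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares k group means without assuming equal variances (weights
#' n_i/s_i^2, Welch 1951), the appropriate omnibus test when class sizes
#' differ strongly. Thin wrapper over `stats::oneway.test(var.equal =
#' FALSE)`.
#'
#' @param groups List of k numeric vectors (each n_i >= 2, nonzero
#'   variance).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups, need_variance = TRUE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- oneway.test(x ~ g, var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value)
}

check_groups <- function(groups, need_variance = FALSE, min_n = 2) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  nm <- names(groups) %||% as.character(seq_along(groups))
  for (i in seq_along(groups)) {
    gi <- groups[[i]][!is.na(groups[[i]])]
    if (length(gi) < min_n) {
      stopf("group '%s' has fewer than %d observations", nm[i], min_n)
    }
    if (need_variance && var(gi) == 0) {
      stopf("group '%s' has zero variance", nm[i])
    }
  }
  invisible(TRUE)
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons after a Welch ANOVA: per pair a Welch t statistic
#' with Welch-Satterthwaite degrees of freedom, referred to the
#' studentized-range distribution with q = t * sqrt(2) and k groups
#' (Tukey-style familywise adjustment without assuming equal variances).
#'
#' @param groups Named list of k numeric vectors.
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `t`, `df`, `p_adj`.
#' @export
games_howell <- function(groups) {
  check_groups(groups, need_variance = TRUE)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  pairs <- combn(k, 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    t = NA_real_, df = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    out$t[j] <- t
    out$df[j] <- df
    out$p_adj[j] <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                           lower.tail = FALSE)
  }
  out
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Rank-based omnibus comparison of k groups (the test of medians used
#' for skewed variables), with the standard tie-correction divisor.
#' Thin wrapper over `stats::kruskal.test`; a fully tied input returns
#' H = 0 with a warning.
#'
#' @param groups List of k numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_n = 1)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < length(groups) + 1) stopf("need N >= k + 1 observations")
  if (length(unique(x[!is.na(x)])) == 1) {
    warnf("all values tied; H = 0")
    return(list(H = 0, df = length(groups) - 1, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with
#' the tie term in the variance; two-sided normal p values, unadjusted by
#' default (Holm or Bonferroni on request).
#'
#' @param groups Named list of k numeric vectors.
#' @param adjustment One of "none" (default), "holm", "bonferroni".
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(groups, adjustment = c("none", "holm", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  check_groups(groups, min_n = 1)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  ok <- !is.na(x)
  x <- x[ok]; g <- g[ok]
  N <- length(x)
  rk <- rank(x, ties.method = "average")
  rbar <- tapply(rk, g, mean)
  n_i <- tabulate(g, nbins = k)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- combn(k, 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(base_var * (1 / n_i[i1] + 1 / n_i[i2]))
    z <- (rbar[[i1]] - rbar[[i2]]) / se
    out$z[j] <- z
    out$p[j] <- 2 * pnorm(-abs(z))
  }
  out$p_adj <- if (adjustment == "none") out$p else
    stats::p.adjust(out$p, method = adjustment)
  out
}

#' Exact Wilcoxon signed-rank test
#'
#' V is the sum of ranks of positive differences (zero differences
#' dropped, with the count reported). For n <= 25 the two-sided p is
#' exact, computed from the full null distribution of V over all 2^n
#' sign assignments (evaluated by dynamic programming over the possible
#' rank sums, which enumerates the same distribution; average ranks keep
#' ties exact). Larger n uses the normal approximation with tie and
#' continuity corrections.
#'
#' @param differences Numeric vector of paired differences.
#' @return List with `V`, `p`, `method` ("exact" or "normal"), and
#'   `n_zero_dropped`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[!is.na(differences)]
  nz <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(V = NA_real_, p = NA_real_, method = "undefined",
                n_zero_dropped = nz))
  }
  rk <- rank(abs(d), ties.method = "average")
  V <- sum(rk[d > 0])
  if (n <= 25) {
    ## exact null distribution of V: each |difference| contributes its
    ## rank with probability 1/2; ranks doubled so half-ranks stay integer
    r2 <- as.integer(round(2 * rk))
    tot <- sum(r2)
    probs <- numeric(tot + 1)   # index = 2V + 1
    probs[1] <- 1
    for (r in r2) {
      shifted <- c(rep(0, r), probs[seq_len(tot + 1 - r)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * V))
    p_ge <- sum(probs[(v2 + 1):(tot + 1)])
    p_le <- sum(probs[seq_len(v2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(V = V, p = p, method = method, n_zero_dropped = nz)
}

#' Compare gene classes on one statistic
#'
#' Dispatches a per-gene statistic to the configured test family and
#' returns omnibus plus post hoc results; genes with a flagged-missing
#' value are dropped listwise. The family is an explicit choice per
#' variable (roughly: approximately normal per-site measures to Welch
#' ANOVA + Games-Howell, skewed measures to Kruskal-Wallis + Dunn), never
#' inferred from the data. The paired family aggregates the statistic to
#' per-trait-group medians within each class and runs the exact Wilcoxon
#' signed-rank test on cooperative-minus-private differences.
#'
#' @param gene_stats A `gene_stats` data frame with a `category` column.
#' @param variable Column name of the statistic to compare.
#' @param classes Character vector of class labels to include (default
#'   cooperative/private/background).
#' @param family One of `welch_anova`, `kruskal_wallis`,
#'   `wilcoxon_signed_rank`.
#' @return List of class `comparison_result`: `variable`, `family`,
#'   `omnibus` (statistic, df, p), `posthoc` (pairwise table or the
#'   paired test), `group_summary`.
#' @export
compare_classes <- function(gene_stats, variable,
                            classes = c("cooperative", "private",
                                        "background"),
                            family = c("welch_anova", "kruskal_wallis",
                                       "wilcoxon_signed_rank")) {
  family <- match.arg(family)
  if (!variable %in% names(gene_stats)) {
    stopf("variable '%s' not present in gene_stats", variable)
  }
  df <- gene_stats[gene_stats$category %in% classes &
                     !is.na(gene_stats[[variable]]), , drop = FALSE]

  if (family == "wilcoxon_signed_rank") {
    if (!all(c("trait_group") %in% names(df)) || all(is.na(df$trait_group))) {
      stopf("paired family requires trait_group annotations")
    }
    need <- c("cooperative", "private")
    med <- tapply(df[[variable]], list(df$trait_group, df$category), median)
    if (!all(need %in% colnames(med))) {
      stopf("paired family requires both cooperative and private genes")
    }
    diffs <- med[, "cooperative"] - med[, "private"]
    diffs <- diffs[!is.na(diffs)]
    wt <- wilcoxon_signed_rank(diffs)
    res <- list(variable = variable, family = family,
                omnibus = list(statistic = wt$V, df = NA_real_, p = wt$p),
                posthoc = wt,
                group_summary = data.frame(
                  trait_group = names(diffs), difference = unname(diffs),
                  stringsAsFactors = FALSE))
    class(res) <- "comparison_result"
    return(res)
  }

  present <- intersect(classes, unique(df$category))
  if (length(present) < 2) stopf("need >= 2 non-empty classes")
  groups <- lapply(present, function(cl) df[[variable]][df$category == cl])
  names(groups) <- present
  summ <- data.frame(
    class = present,
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    median = vapply(groups, median, numeric(1)),
    variance = vapply(groups, var, numeric(1)),
    stringsAsFactors = FALSE)
  if (family == "welch_anova") {
    om <- welch_anova(groups)
    ph <- games_howell(groups)
    omnibus <- list(statistic = om$F, df = c(om$df1, om$df2), p = om$p)
  } else {
    om <- kruskal_wallis(groups)
    ph <- dunn_test(groups)
    omnibus <- list(statistic = om$H, df = om$df, p = om$p)
  }
  res <- list(variable = variable, family = family, omnibus = omnibus,
              posthoc = ph, group_summary = summ)
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  dfs <- paste(format(x$omnibus$df, digits = 4), collapse = ", ")
  cat(sprintf("<comparison_result> %s by %s: statistic = %.4g (df %s), p = %.4g\n",
              x$variable, x$family, x$omnibus$statistic, dfs, x$omnibus$p))
  invisible(x)
}
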