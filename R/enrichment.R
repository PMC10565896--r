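#' Exact binomial enrichment test
#'
#' Tests whether a focal gene set is over-represented among
#' deleterious-mutation hits: with `k` hits in the focal set out of `n`
#' total hits, and the focal set making up fraction `f` of categorized
#' genes, the one-sided upper-tail exact binomial probability is
#' P(X >= k | n, f). The directional (over-representation) test matches
#' the prediction that relaxed selection concentrates deleterious
#' mutations in cooperative genes.
#'
#' @param k Focal-set hits.
#' @param n Total hits (>= 1).
#' @param f Focal-set fraction of the genome, in (0, 1).
#' @return List of class `enrichment_result`: `k`, `n`, `f`,
#'   `observed_percent` (100 k/n), `expected_percent` (100 f), `p`.
#' @export
binomial_enrichment <- function(k, n, f) {
  if (n < 1) stopf("n must be at least 1")
  if (!(f > 0 && f < 1)) stopf("f must lie in (0, 1), got %g", f)
  if (k < 0 || k > n) stopf("k must lie in [0, n]")
  p <- pbinom(k - 1, size = n, prob = f, lower.tail = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), f = f,
                 observed_percent = 100 * k / n,
                 expected_percent = 100 * f, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_result> %d/%d hits (%.1f%%) vs expected ",
                     "%.1f%%: binomial p = %.3g\n"),
              x$k, x$n, x$observed_percent, x$expected_percent, x$p))
  invisible(x)
}

#' Count deleterious-mutation hits for an enrichment test
#'
#' In `gene_presence` mode, n is the number of genes carrying at least
#' one deleterious mutation and k those among them in the focal category;
#' in `mutation_count` mode, n is the total number of deleterious
#' mutations and k those falling in focal-category genes. The genome
#' fraction f counts focal genes over genes of known (categorized)
#' sociality only.
#'
#' @param annotations Output of [annotate_deleterious()] (must carry a
#'   `category` column).
#' @param focal_category Focal class (default "cooperative").
#' @param mode `gene_presence` or `mutation_count`.
#' @return List with `k`, `n`, `f`.
#' @export
count_hits <- function(annotations, focal_category = "cooperative",
                       mode = c("gene_presence", "mutation_count")) {
  mode <- match.arg(mode)
  known <- annotations[annotations$category != "uncategorized", , drop = FALSE]
  focal <- known$category == focal_category
  if (!any(focal)) stopf("no genes in focal category '%s'", focal_category)
  f <- mean(focal)
  if (mode == "gene_presence") {
    hits <- known$has_deleterious
    n <- sum(hits)
    k <- sum(hits & focal)
  } else {
    n <- sum(known$deleterious_count)
    k <- sum(known$deleterious_count[focal])
  }
  list(k = k, n = n, f = f)
}

#' Cooperative-versus-private 2x2 chi-square contrast
#'
#' Companion test contrasting deleterious-mutation hits between the
#' cooperative and private classes directly: a 2x2 chi-square (with
#' continuity correction) on (hit, no hit) x (cooperative, private) in
#' `gene_presence` mode, or on total mutation counts versus gene counts
#' in `mutation_count` mode.
#'
#' @param annotations Output of [annotate_deleterious()].
#' @param mode `gene_presence` or `mutation_count`.
#' @return List with `statistic`, `df`, `p`, `table`.
#' @export
deleterious_chisq <- function(annotations,
                              mode = c("gene_presence", "mutation_count")) {
  mode <- match.arg(mode)
  coop <- annotations$category == "cooperative"
  priv <- annotations$category == "private"
  if (mode == "gene_presence") {
    tab <- rbind(cooperative = c(sum(annotations$has_deleterious[coop]),
                                 sum(!annotations$has_deleterious[coop])),
                 private = c(sum(annotations$has_deleterious[priv]),
                             sum(!annotations$has_deleterious[priv])))
    colnames(tab) <- c("hit", "no_hit")
  } else {
    tab <- rbind(cooperative = c(sum(annotations$deleterious_count[coop]),
                                 sum(coop)),
                 private = c(sum(annotations$deleterious_count[priv]),
                             sum(priv)))
    colnames(tab) <- c("mutations", "genes")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
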