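#' Assemble and validate a pipeline run configuration
#'
#' Collects input paths, filter thresholds, test-family choices and seeds
#' for [run_pipeline()]. The configuration round-trips losslessly through
#' YAML (see [read_run_config()]).
#'
#' @param vcf,gff,fasta Paths to the strain VCF, gene models and
#'   reference FASTA (required).
#' @param outgroup_vcf,outgroup_fasta Outgroup SNPs against the reference
#'   or a ready pseudogenome (at most one; optional — divergence-based
#'   statistics are skipped without an outgroup).
#' @param expression Optional gene x timepoint TSV (first column gene
#'   ids).
#' @param min_call_rate,min_mapped_fraction Filter thresholds (defaults
#'   0.8 and 0.5).
#' @param drop_indels Must remain TRUE (indels are excluded from popgen
#'   statistics by contract; they are still used for deleterious
#'   annotation).
#' @param family_map Named list mapping statistic columns to test
#'   families; defaults mirror the usual choice of Welch ANOVA for the
#'   approximately normal per-site measures and Kruskal-Wallis for the
#'   skewed ones.
#' @param bootstrap_B Bootstrap sets for the co-expression null.
#' @param coexpression_set Optional character vector of gene ids whose
#'   co-expression is tested (defaults to all cooperative + private
#'   genes).
#' @param seed Integer seed for all randomness.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf, gff, fasta,
                       outgroup_vcf = NULL, outgroup_fasta = NULL,
                       expression = NULL,
                       min_call_rate = 0.8, min_mapped_fraction = 0.5,
                       drop_indels = TRUE,
                       family_map = NULL,
                       bootstrap_B = 10000,
                       coexpression_set = NULL,
                       seed = 1L, out_dir = "kinsig_out") {
  if (!isTRUE(drop_indels)) {
    stopf("drop_indels = FALSE violates the popgen contract: indels cannot enter the population-genetic statistics")
  }
  for (p in c(vcf, gff, fasta, outgroup_vcf, outgroup_fasta, expression)) {
    if (!is.null(p) && !file.exists(p)) stopf("input path does not exist: %s", p)
  }
  if (!is.null(outgroup_vcf) && !is.null(outgroup_fasta)) {
    stopf("give either outgroup_vcf or outgroup_fasta, not both")
  }
  for (th in c(min_call_rate, min_mapped_fraction)) {
    if (!(th >= 0 && th <= 1)) stopf("thresholds must lie in [0, 1]")
  }
  if (is.null(family_map)) {
    family_map <- list(pi = "welch_anova", pi_S = "welch_anova",
                       Ks = "welch_anova",
                       pi_N = "kruskal_wallis", Ka = "kruskal_wallis",
                       pi_N_over_pi_S = "kruskal_wallis",
                       Ka_over_Ks = "kruskal_wallis")
  }
  structure(
    list(vcf = vcf, gff = gff, fasta = fasta,
         outgroup_vcf = outgroup_vcf, outgroup_fasta = outgroup_fasta,
         expression = expression,
         min_call_rate = min_call_rate,
         min_mapped_fraction = min_mapped_fraction,
         drop_indels = TRUE, family_map = family_map,
         bootstrap_B = as.integer(bootstrap_B),
         coexpression_set = coexpression_set,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

#' Read or write a run configuration as YAML
#' @param path YAML file path.
#' @return A `run_config` (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> filter -> per-gene statistics -> class comparisons
#' -> co-expression bootstrap -> deleterious enrichment -> relatedness,
#' writing machine-readable outputs (per-gene stats TSV, comparison JSON,
#' bootstrap distribution TSV, enrichment JSON, relatedness JSON) and a
#' log that accounts for every filter (sites and genes in/out). A stage
#' failure aborts with the stage name; outputs of completed stages are
#' preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the result objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  paths <- list(log = log_path)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  log_line(con, "kinsig %s | seed %d",
           as.character(utils::packageVersion("kinsig")), config$seed)

  ## ingest + filter
  ingest <- stage("ingest", {
    reference <- read_fasta(config$fasta)
    genes <- read_gff(config$gff, contigs = names(reference))
    records <- read_vcf(config$vcf)
    list(reference = reference, genes = genes, records = records)
  })
  log_line(con, "ingest: %d variant records, %d genes, %d contig(s)",
           nrow(ingest$records), nrow(ingest$genes),
           length(ingest$reference))

  filt <- stage("filter", {
    fv <- filter_variants(ingest$records,
                          min_call_rate = config$min_call_rate)
    fg <- filter_genes(ingest$genes,
                       min_mapped_fraction = config$min_mapped_fraction,
                       variants = fv$snps)
    list(snps = fv$snps, indels = fv$indels, genes = fg)
  })
  log_line(con, "filter: %d -> %d SNPs (call rate >= %.2f), %d indels side-channel",
           sum(ingest$records$variant_class == "SNP"), nrow(filt$snps),
           config$min_call_rate, nrow(filt$indels))
  log_line(con, "filter: %d -> %d genes (mapped fraction >= %.2f, with polymorphism data)",
           nrow(ingest$genes), nrow(filt$genes), config$min_mapped_fraction)

  ## outgroup pseudogenome
  pseudo <- NULL
  if (!is.null(config$outgroup_fasta)) {
    pseudo <- stage("outgroup", read_fasta(config$outgroup_fasta))
    log_line(con, "outgroup: pseudogenome read from %s", config$outgroup_fasta)
  } else if (!is.null(config$outgroup_vcf)) {
    pseudo <- stage("outgroup", {
      ov <- read_vcf(config$outgroup_vcf)
      build_outgroup_pseudogenome(ingest$reference, ov)
    })
    log_line(con, "outgroup: pseudogenome built from %s", config$outgroup_vcf)
  } else {
    log_line(con, "outgroup: none; divergence statistics skipped")
  }

  ## per-gene statistics
  stats_tab <- stage("stats", {
    alns <- lapply(seq_len(nrow(filt$genes)), function(g) {
      gene <- filt$genes[g, ]
      aln <- build_alignment(gene, filt$snps, ingest$reference)
      if (!is.null(pseudo)) aln <- add_outgroup(aln, outgroup_slice(gene, pseudo))
      aln
    })
    names(alns) <- filt$genes$gene_id
    compute_gene_stats_table(alns, genes = filt$genes)
  })
  paths$stats <- file.path(config$out_dir, "gene_stats.tsv")
  write.table(stats_tab, paths$stats, sep = "\t", quote = FALSE,
              row.names = FALSE)
  results$gene_stats <- stats_tab
  log_line(con, "stats: %d genes x %d statistics -> %s",
           nrow(stats_tab), ncol(stats_tab), paths$stats)

  ## class comparisons
  comparisons <- stage("compare", {
    out <- list()
    for (v in names(config$family_map)) {
      fam <- config$family_map[[v]]
      res <- tryCatch(compare_classes(stats_tab, v, family = fam),
                      error = function(e) list(error = conditionMessage(e)))
      out[[v]] <- res
    }
    out
  })
  paths$comparisons <- file.path(config$out_dir, "comparisons.json")
  jsonlite::write_json(
    lapply(comparisons, function(x) {
      if (!is.null(x$error)) return(list(error = x$error))
      list(variable = x$variable, family = x$family,
           omnibus = x$omnibus, posthoc = x$posthoc,
           group_summary = x$group_summary)
    }),
    paths$comparisons, auto_unbox = TRUE, digits = NA, force = TRUE)
  results$comparisons <- comparisons
  log_line(con, "compare: %d variables -> %s", length(comparisons),
           paths$comparisons)

  ## co-expression bootstrap
  if (!is.null(config$expression)) {
    coexpr <- stage("coexpr", {
      tab <- read.table(config$expression, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE)
      mat <- as.matrix(tab[, -1, drop = FALSE])
      rownames(mat) <- tab[[1]]
      mat <- median_normalize(mat)
      set <- config$coexpression_set
      if (is.null(set)) {
        set <- filt$genes$gene_id[filt$genes$category %in%
                                    c("cooperative", "private")]
      }
      set <- intersect(set, rownames(mat))
      bootstrap_null(mat, set_size = length(set), B = config$bootstrap_B,
                     seed = config$seed, observed_set = set)
    })
    paths$bootstrap <- file.path(config$out_dir, "bootstrap_null.tsv")
    write.table(data.frame(null_mean = coexpr$null_means), paths$bootstrap,
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$coexpression <- coexpr
    log_line(con, "coexpr: rho_obs = %.4f, percentile = %.1f%%, p = %.4g (B = %d)",
             coexpr$rho_obs, coexpr$percentile, coexpr$p, coexpr$B)
  }

  ## deleterious enrichment
  enrich <- stage("enrich", {
    ann <- annotate_deleterious(list(snps = filt$snps, indels = filt$indels),
                                filt$genes, ingest$reference)
    out <- list()
    for (mode in c("gene_presence", "mutation_count")) {
      ct <- tryCatch(count_hits(ann, mode = mode),
                     error = function(e) NULL)
      out[[mode]] <- if (is.null(ct) || ct$n < 1) {
        list(error = "no deleterious hits")
      } else {
        unclass(binomial_enrichment(ct$k, ct$n, ct$f))
      }
    }
    list(annotations = ann, tests = out)
  })
  paths$enrichment <- file.path(config$out_dir, "enrichment.json")
  jsonlite::write_json(enrich$tests, paths$enrichment, auto_unbox = TRUE,
                       digits = NA)
  results$enrichment <- enrich
  log_line(con, "enrich: %d genes with deleterious mutations -> %s",
           sum(enrich$annotations$has_deleterious), paths$enrichment)

  ## relatedness
  related <- stage("relatedness", {
    out <- list()
    for (sc in c("nonsynonymous", "all_sites")) {
      out[[sc]] <- tryCatch(
        unclass(estimate_relatedness(stats_tab, site_class = sc,
                                     seed = config$seed)),
        error = function(e) list(error = conditionMessage(e)))
    }
    out
  })
  paths$relatedness <- file.path(config$out_dir, "relatedness.json")
  jsonlite::write_json(related, paths$relatedness, auto_unbox = TRUE,
                       digits = NA)
  results$relatedness <- related
  for (sc in names(related)) {
    if (is.null(related[[sc]]$error)) {
      log_line(con, "relatedness (%s): r_hat = %.3f [%.3f, %.3f]",
               sc, related[[sc]]$r_hat, related[[sc]]$ci[1],
               related[[sc]]$ci[2])
    }
  }

  invisible(list(results = results, paths = paths))
}
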