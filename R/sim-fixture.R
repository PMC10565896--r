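## ---- genome layout ---------------------------------------------------------

## Place the simulated genes on a single contig, alternating strands, with
## random intergenic spacers. Deterministic given the simulation seed.
genome_layout <- function(sim, spacer_bp = 60L) {
  config <- sim$config
  ids <- names(sim$alignments)
  L <- config$gene_length_bp
  n <- length(ids)
  strands <- rep(c("+", "-"), length.out = n)
  starts <- spacer_bp + (seq_len(n) - 1L) * (L + spacer_bp) + 1L
  ends <- starts + L - 1L
  genome_len <- ends[n] + spacer_bp

  set.seed(config$seed + 1L)
  genome <- sample(BASES, genome_len, replace = TRUE)
  for (g in seq_len(n)) {
    cds <- sim$reference[[ids[g]]]
    if (strands[g] == "-") cds <- revcomp(cds)
    genome[starts[g]:ends[g]] <- seq_chars(cds)
  }
  list(contig = "sim_chr",
       genome = chars_seq(genome),
       genes = data.frame(gene_id = ids, contig = "sim_chr",
                          start = starts, end = ends, strand = strands,
                          category = sim$truth$class,
                          stringsAsFactors = FALSE))
}

## map a CDS-oriented position/allele pair to genome coordinates
cds_to_genomic <- function(gene_row, site, base) {
  if (gene_row$strand == "+") {
    list(pos = gene_row$start + site - 1L, base = base)
  } else {
    list(pos = gene_row$end - site + 1L, base = unname(comp_base(base)))
  }
}

## ---- writers ---------------------------------------------------------------

write_fasta_file <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
}

vcf_header <- function(contig, contig_len, strains) {
  c("##fileformat=VCFv4.2",
    "##source=kinsig",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
}

vcf_row <- function(contig, pos, ref, alt, gts) {
  paste(c(contig, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the post-variant-calling products a real analysis would start
#' from: a multi-strain haploid SNP VCF (with configured MCAR missingness
#' and, optionally, spiked stop-gain SNPs and frameshift indels), a GFF3
#' of CDS gene models carrying a `sociality` attribute, reference and
#' outgroup pseudogenome FASTAs, an outgroup SNP VCF against the
#' reference, a gene x timepoint expression TSV and the simulation truth
#' table. Reading these files back through the genome-io layer reproduces
#' the in-memory alignments exactly at fully called sites.
#'
#' @param output_dir Output directory (created if needed).
#' @param sim A [simulate_population()] result.
#' @param outgroup Optional [simulate_outgroup()] result.
#' @param expression Optional expression matrix from
#'   [generate_expression()].
#' @param mapped_fraction Named numeric vector of per-gene mapped-length
#'   fractions written to the GFF3 (default 1 for every gene).
#' @param spike_stop_gains Optional data frame (`gene_id`, `codon`): for
#'   each row a single-base SNP converting that codon to a stop is added,
#'   carried by strain 1.
#' @param spike_frameshifts Optional data frame (`gene_id`, `codon`,
#'   `len`): an indel of `len` inserted (positive) or deleted (negative)
#'   bases anchored at that codon, carried by strain 1.
#' @param force Overwrite existing fixture files (default FALSE).
#' @return Invisibly, a list with the file paths, the genome layout and
#'   any spiked variant descriptions.
#' @export
write_fixture <- function(output_dir, sim, outgroup = NULL,
                          expression = NULL, mapped_fraction = NULL,
                          spike_stop_gains = NULL, spike_frameshifts = NULL,
                          force = FALSE) {
  stopifnot(inherits(sim, "kinsig_simulation"))
  config <- sim$config
  paths <- list(
    vcf = file.path(output_dir, "variants.vcf"),
    gff = file.path(output_dir, "genes.gff3"),
    fasta = file.path(output_dir, "reference.fasta"),
    outgroup_fasta = file.path(output_dir, "outgroup.fasta"),
    outgroup_vcf = file.path(output_dir, "outgroup.vcf"),
    expression = file.path(output_dir, "expression.tsv"),
    truth = file.path(output_dir, "truth.tsv"))
  existing <- Filter(file.exists, paths)
  if (length(existing) > 0 && !force) {
    stopf("fixture files already exist in %s; use force = TRUE to overwrite",
          output_dir)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  lay <- genome_layout(sim)
  genes <- lay$genes
  strains <- sprintf("strain_%02d", seq_len(config$sample_size))
  if (is.null(mapped_fraction)) {
    mapped_fraction <- setNames(rep(1, nrow(genes)), genes$gene_id)
  }

  ## GFF3
  gff_lines <- c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", lay$contig,
                         nchar(lay$genome)))
  for (g in seq_len(nrow(genes))) {
    attrs <- sprintf(
      "ID=%s;gene_biotype=protein_coding;sociality=%s;mapped_fraction=%s",
      genes$gene_id[g], genes$category[g],
      format(mapped_fraction[[genes$gene_id[g]]], digits = 6))
    gff_lines <- c(gff_lines, paste(
      c(genes$contig[g], "kinsig_sim", "CDS", genes$start[g], genes$end[g],
        ".", genes$strand[g], "0", attrs), collapse = "\t"))
  }
  writeLines(gff_lines, paths$gff)

  ## reference FASTA
  write_fasta_file(setNames(lay$genome, lay$contig), paths$fasta)

  ## strain VCF: one row per site at which any sampled strain differs from
  ## the reference (sample-segregating sites plus fixed differences)
  set.seed(config$seed + 2L)
  rows <- list()
  if (!is.null(sim$mutations) && nrow(sim$mutations) > 0) {
    for (i in seq_len(nrow(sim$mutations))) {
      m <- sim$mutations[i, ]
      gene <- genes[genes$gene_id == m$gene_id, ]
      aln <- sim$alignments[[m$gene_id]]
      carriers <- aln$mat[, m$site] == m$alt
      gt <- ifelse(carriers, "1", "0")
      if (config$missingness_rate > 0) {
        miss <- runif(length(gt)) < config$missingness_rate
        gt[miss] <- "."
      }
      gpos <- cds_to_genomic(gene, m$site, m$ref)
      galt <- cds_to_genomic(gene, m$site, m$alt)
      rows[[length(rows) + 1L]] <-
        list(pos = gpos$pos, ref = gpos$base, alt = galt$base, gt = gt)
    }
  }

  spiked <- list()
  genome_chars <- seq_chars(lay$genome)
  if (!is.null(spike_stop_gains)) {
    for (i in seq_len(nrow(spike_stop_gains))) {
      gid <- spike_stop_gains$gene_id[i]
      ci <- spike_stop_gains$codon[i]
      gene <- genes[genes$gene_id == gid, ]
      cds <- sim$reference[[gid]]
      codon <- substr(cds, 3 * ci - 2, 3 * ci)
      if (is_stop_codon(codon)) stopf("codon %d of %s is already a stop", ci, gid)
      hit <- NULL
      for (p in 1:3) {
        for (alt in setdiff(BASES, substr(codon, p, p))) {
          cand <- codon
          substr(cand, p, p) <- alt
          if (is_stop_codon(cand)) { hit <- list(p = p, alt = alt); break }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) stopf("codon %s of %s cannot gain a stop by one change",
                              codon, gid)
      site <- 3L * (ci - 1L) + hit$p
      gpos <- cds_to_genomic(gene, site, substr(codon, hit$p, hit$p))
      galt <- cds_to_genomic(gene, site, hit$alt)
      gt <- c("1", rep("0", length(strains) - 1L))
      rows[[length(rows) + 1L]] <-
        list(pos = gpos$pos, ref = gpos$base, alt = galt$base, gt = gt)
      spiked[[length(spiked) + 1L]] <-
        data.frame(gene_id = gid, type = "stop_gain", pos = gpos$pos,
                   stringsAsFactors = FALSE)
    }
  }
  if (!is.null(spike_frameshifts)) {
    for (i in seq_len(nrow(spike_frameshifts))) {
      gid <- spike_frameshifts$gene_id[i]
      ci <- spike_frameshifts$codon[i]
      len <- spike_frameshifts$len[i]
      gene <- genes[genes$gene_id == gid, ]
      anchor <- gene$start + 3L * (ci - 1L)   # inside the CDS on any strand
      refb <- genome_chars[anchor]
      if (len > 0) {
        ins <- chars_seq(sample(BASES, len, replace = TRUE))
        ref <- refb; alt <- paste0(refb, ins)
      } else {
        d <- -len
        ref <- chars_seq(genome_chars[anchor:(anchor + d)])
        alt <- refb
      }
      gt <- c("1", rep("0", length(strains) - 1L))
      rows[[length(rows) + 1L]] <-
        list(pos = anchor, ref = ref, alt = alt, gt = gt)
      spiked[[length(spiked) + 1L]] <-
        data.frame(gene_id = gid, type = "frameshift", pos = anchor,
                   stringsAsFactors = FALSE)
    }
  }

  ord <- order(vapply(rows, `[[`, numeric(1), "pos"))
  vcf_lines <- vcf_header(lay$contig, nchar(lay$genome), strains)
  for (i in ord) {
    r <- rows[[i]]
    vcf_lines <- c(vcf_lines, vcf_row(lay$contig, r$pos, r$ref, r$alt, r$gt))
  }
  writeLines(vcf_lines, paths$vcf)

  ## outgroup pseudogenome + outgroup SNP VCF
  if (!is.null(outgroup)) {
    og_chars <- genome_chars
    og_rows <- list()
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      cds_ref <- seq_chars(sim$reference[[gid]])
      cds_out <- seq_chars(outgroup$sequences[[gid]])
      diff <- which(cds_ref != cds_out)
      for (site in diff) {
        gpos <- cds_to_genomic(genes[g, ], site, cds_ref[site])
        galt <- cds_to_genomic(genes[g, ], site, cds_out[site])
        og_chars[gpos$pos] <- galt$base
        og_rows[[length(og_rows) + 1L]] <-
          list(pos = gpos$pos, ref = gpos$base, alt = galt$base, gt = "1")
      }
    }
    write_fasta_file(setNames(chars_seq(og_chars), lay$contig),
                     paths$outgroup_fasta)
    ord <- order(vapply(og_rows, `[[`, numeric(1), "pos"))
    og_lines <- vcf_header(lay$contig, nchar(lay$genome), "outgroup")
    for (i in ord) {
      r <- og_rows[[i]]
      og_lines <- c(og_lines, vcf_row(lay$contig, r$pos, r$ref, r$alt, r$gt))
    }
    writeLines(og_lines, paths$outgroup_vcf)
  }

  ## expression TSV
  if (!is.null(expression)) {
    df <- data.frame(gene_id = rownames(expression), expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, paths$expression, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ## truth table
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(paths = paths, layout = lay,
                 spiked = if (length(spiked)) do.call(rbind, spiked) else NULL))
}
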