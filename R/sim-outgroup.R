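#' Simulate an outgroup sequence for each gene
#'
#' Places substitutions on the outgroup branch by a per-codon jump process
#' over a branch of unit length: every possible single-base change has
#' hazard `expected_Ks / 3` if it is synonymous in the current codon and
#' `expected_Ks * omega_class / 3` if nonsynonymous, where `omega_class`
#' is `outgroup_omega` for private/background genes and
#' `outgroup_omega / r` for cooperative genes when the configured omega
#' asymmetry is on (relaxed selection elevates divergence, not only
#' polymorphism). Because hazards are re-evaluated after every event, a
#' site may substitute more than once (Jukes-Cantor-style multiple hits).
#'
#' @param config A [simulation_config()].
#' @param reference_sequences Named character vector of reference CDS
#'   strings (as produced by [simulate_population()]).
#' @param classes Character vector of gene classes aligned with
#'   `reference_sequences` (values `cooperative`, `private`,
#'   `background`). Defaults to all private.
#' @return A list with `sequences` (named character vector of outgroup CDS)
#'   and `truth` (data frame of realized synonymous/nonsynonymous
#'   substitution event counts per gene).
#' @export
simulate_outgroup <- function(config, reference_sequences,
                              classes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(reference_sequences) == 0) stopf("no reference sequences given")
  set.seed(config$seed + 3L)   # own deterministic stream
  if (is.null(classes)) classes <- rep("private", length(reference_sequences))
  stopifnot(length(classes) == length(reference_sequences))

  Ks <- config$outgroup_expected_Ks
  out <- character(length(reference_sequences))
  n_syn <- integer(length(reference_sequences))
  n_non <- integer(length(reference_sequences))
  cons <- codon_consequence_table()
  alt_tab <- alt_base_table()

  for (g in seq_along(reference_sequences)) {
    omega <- config$outgroup_omega
    if (config$outgroup_omega_asymmetry && classes[g] == "cooperative") {
      omega <- omega / config$true_relatedness
    }
    lam_s <- Ks / 3
    lam_n <- Ks * omega / 3
    chars <- seq_chars(reference_sequences[g])
    L <- length(chars)
    if (Ks > 0) {
      for (ci in seq_len(L / 3)) {
        pos <- codon_positions(ci)
        codon <- chars_seq(chars[pos])
        t <- 0
        repeat {
          m <- cons[[codon]]            # 3x3 nonsynonymous flags
          haz <- ifelse(m, lam_n, lam_s)
          H <- sum(haz)
          if (H <= 0) break
          t <- t + stats::rexp(1, H)
          if (t > 1) break
          pick <- sample.int(9L, 1L, prob = as.vector(haz))
          p <- (pick - 1L) %% 3L + 1L   # position within codon
          j <- (pick - 1L) %/% 3L + 1L  # alternative index
          b <- seq_chars(codon)
          newb <- alt_tab[b[p], j]
          if (m[p, j]) n_non[g] <- n_non[g] + 1L else n_syn[g] <- n_syn[g] + 1L
          substr(codon, p, p) <- newb
        }
        chars[pos] <- seq_chars(codon)
      }
    }
    out[g] <- chars_seq(chars)
  }
  names(out) <- names(reference_sequences)
  list(sequences = out,
       truth = data.frame(gene_id = names(reference_sequences) %||%
                            seq_along(out),
                          class = classes,
                          syn_substitutions = n_syn,
                          nonsyn_substitutions = n_non,
                          stringsAsFactors = FALSE))
}
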