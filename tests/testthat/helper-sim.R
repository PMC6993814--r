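# Shared fixtures: small simulator configurations and truth-derived
# expectations used across test files.

tiny_config <- function(...) {
  defaults <- list(n_clades = 3, genes_per_chromosome = c(10, 10),
                   gene_length = 50, n_strains_per_clade = 2,
                   n_recombinants = 1, n_crossovers = 3,
                   intra_mut_rate = 2, gap_rate = 1, mean_depth = 30,
                   seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Dummy ancestors for recombination-only tests: clade label -> per-og
# one-codon sequences, distinct across clades.
dummy_ancestors <- function(clades, ogs) {
  base <- c("AAA", "CCC", "GGG", "TTT", "ACG", "TGC")
  out <- lapply(seq_along(clades), function(i) {
    stats::setNames(rep(base[i], length(ogs)), ogs)
  })
  names(out) <- clades
  out
}

# Expected distinct-variant mutation counts for a set of strains, derived
# from the simulator truth table: substitution variants are keyed by
# (og, codon, alt); gap events are merged into maximal runs per strain
# and keyed by (og, run start, run length).
expected_counts_from_truth <- function(mutations, strains) {
  mut <- mutations[mutations$strain %in% strains, , drop = FALSE]
  subs <- mut[mut$kind != "gap", , drop = FALSE]
  key <- paste(subs$og_id, subs$codon_index, subs$alt_codon)
  subs <- subs[!duplicated(key), , drop = FALSE]
  gap_keys <- character(0)
  gaps <- mut[mut$kind == "gap", , drop = FALSE]
  for (s in unique(gaps$strain)) {
    g <- gaps[gaps$strain == s, , drop = FALSE]
    g <- g[order(g$og_id, g$codon_index), , drop = FALSE]
    if (nrow(g) == 0) next
    new_run <- c(TRUE, diff(g$codon_index) != 1 | g$og_id[-1] != g$og_id[-nrow(g)])
    run_id <- cumsum(new_run)
    for (rid in unique(run_id)) {
      idx <- which(run_id == rid)
      gap_keys <- c(gap_keys, paste(g$og_id[idx[1]], g$codon_index[idx[1]],
                                    length(idx)))
    }
  }
  list(syn = sum(subs$kind == "syn"),
       nonsyn = sum(subs$kind == "nonsyn"),
       gap = length(unique(gap_keys)))
}

# Fraction of true breakpoints matched by a closest-clade label change
# within +/- tol genes on the same chromosome.
breakpoint_recall <- function(track, breakpoints, tol = 10) {
  if (nrow(breakpoints) == 0) return(NA_real_)
  hits <- vapply(seq_len(nrow(breakpoints)), function(i) {
    chr <- breakpoints$chromosome[i]
    oi <- breakpoints$order_index[i]
    sub <- track[track$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$order_index), , drop = FALSE]
    change_at <- sub$order_index[-1][sub$closest[-1] != sub$closest[-nrow(sub)]]
    any(abs(change_at - oi) <= tol)
  }, logical(1))
  mean(hits)
}
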