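# Forward simulator of clonally domesticated mosaic genomes.
#
# The generative model: n_clades ancestral genomes diverge from a common
# root on a star phylogeny (pairwise divergence ~ `divergence`); each
# clade's strains descend directly from their clade ancestor and
# accumulate sparse private "domestication" mutations with a tunable
# non-synonymous/synonymous odds; additional recombinant query strains
# are mosaics of the ancestors with crossovers at gene junctions. Depth
# tracks carry Poisson noise around mean_depth x copy_number, and each
# strain carries one of two MAT idiomorph markers. Full ground truth is
# retained for recovery testing.

# Fixed synthetic 30 bp MAT idiomorph markers (not the published primer
# sequences, which are external inputs in real analyses).
MAT1_1_MARKER <- "ATGCGTACCTTGGACAAGTCCGAGTTACAC"
MAT1_2_MARKER <- "ATGTCATACCGGAAGCTTGTCAACGGTCAG"

#' Synthetic MAT markers used by the simulator
#'
#' @return list with elements `mat1_1` and `mat1_2`, two distinct 30 bp
#'   synthetic marker sequences.
#' @export
sim_mat_markers <- function() list(mat1_1 = MAT1_1_MARKER, mat1_2 = MAT1_2_MARKER)

#' Simulation configuration
#'
#' Bundles and validates every knob of the forward simulator. The default
#' values define the standard validation conditions used throughout the
#' package: 5 clades of 3 strains, 200 genes of 200 codons on two
#' chromosomes, 1% ancestor divergence, 1 mutated codon and 1 gap
#' event per strain at a non-synonymous/synonymous odds multiplier of
#' 2.9, and mean read depth 100. The per-strain mutation load keeps the
#' expected intra-clade p-distance (about 3e-5) within the 1e-4
#' dissimilarity bound that defines a clade, orders of magnitude under
#' the ancestor divergence.
#'
#' @param n_clades number of ancestral clades (>= 2).
#' @param genes_per_chromosome integer vector, genes on each chromosome.
#' @param gene_length gene length in codons (>= 10; bp = 3 x codons).
#' @param divergence expected per-site substitution fraction between any
#'   two clade ancestors, in (0, 0.2].
#' @param n_strains_per_clade strains descending from each clade ancestor.
#' @param n_recombinants extra mosaic query strains built by
#'   [simulate_recombinant_strain()].
#' @param n_crossovers crossovers per recombinant strain.
#' @param intra_mut_rate expected substituted codons per strain (Poisson).
#' @param target_ns_odds multiplier on the neutral non-synonymous/synonymous
#'   event odds (1 = neutral codon replacement).
#' @param gap_rate expected single-codon deletion events per strain.
#' @param cnv_spec optional data frame (`og_id`, `clade`, `copy_number`)
#'   assigning integer copy numbers to genes within clades.
#' @param mean_depth mean per-base read depth for a single-copy gene.
#' @param seed integer RNG seed; the emitted dataset is a pure function of
#'   the full configuration.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_clades = 5,
                       genes_per_chromosome = c(100, 100),
                       gene_length = 200,
                       divergence = 0.01,
                       n_strains_per_clade = 3,
                       n_recombinants = 2,
                       n_crossovers = 5,
                       intra_mut_rate = 1,
                       target_ns_odds = 2.9,
                       gap_rate = 1,
                       cnv_spec = NULL,
                       mean_depth = 100,
                       seed = 1) {
  stopifnot(n_clades >= 2, all(genes_per_chromosome >= 1),
            gene_length >= 10, divergence > 0, divergence <= 0.2,
            n_strains_per_clade >= 1, n_recombinants >= 0,
            n_crossovers >= 0, intra_mut_rate >= 0, target_ns_odds > 0,
            gap_rate >= 0, mean_depth >= 0)
  if (!is.null(cnv_spec)) {
    stopifnot(is.data.frame(cnv_spec),
              all(c("og_id", "clade", "copy_number") %in% names(cnv_spec)))
  }
  structure(list(
    n_clades = as.integer(n_clades),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_length = as.integer(gene_length),
    divergence = divergence,
    n_strains_per_clade = as.integer(n_strains_per_clade),
    n_recombinants = as.integer(n_recombinants),
    n_crossovers = as.integer(n_crossovers),
    intra_mut_rate = intra_mut_rate,
    target_ns_odds = target_ns_odds,
    gap_rate = gap_rate,
    cnv_spec = cnv_spec,
    mean_depth = mean_depth,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Gene-order map implied by a simulation configuration
#'
#' Orthogroups `OG0001`, `OG0002`, ... laid out consecutively along
#' chromosomes `I`, `II`, ...
#'
#' @param config a [sim_config()].
#' @return a `gene_order_map` data frame.
#' @export
sim_gene_map <- function(config) {
  n_chr <- length(config$genes_per_chromosome)
  chrom <- rep(as.character(utils::as.roman(seq_len(n_chr))),
               config$genes_per_chromosome)
  total <- sum(config$genes_per_chromosome)
  gene_order_map(data.frame(
    og_id = sprintf("OG%04d", seq_len(total)),
    chromosome = chrom,
    order_index = unlist(lapply(config$genes_per_chromosome, seq_len)),
    stringsAsFactors = FALSE
  ))
}

# Neutral fraction of non-synonymous events when a codon is replaced
# uniformly by one of the other 60 sense codons.
neutral_nonsyn_fraction <- local({
  q0 <- NULL
  function() {
    if (is.null(q0)) {
      sc <- sense_codons()
      aa <- translate_codon(sc)
      n_nonsyn <- vapply(seq_along(sc), function(i) sum(aa != aa[i]), numeric(1))
      n_alt <- length(sc) - 1
      q0 <<- sum(n_nonsyn) / (n_alt * length(sc))
    }
    q0
  }
})

#' Per-event non-synonymous probability for an odds multiplier
#'
#' Maps the `target_ns_odds` multiplier m to the probability that a single
#' substitution event is non-synonymous:
#' `p = m q0 / (m q0 + 1 - q0)` where q0 is the neutral non-synonymous
#' fraction under uniform replacement over sense codons, so that
#' `E[nonsyn]/E[syn] = m * q0/(1-q0)`.
#'
#' @param target_ns_odds odds multiplier (> 0).
#' @return probability in (0, 1).
#' @export
nonsyn_event_prob <- function(target_ns_odds) {
  q0 <- neutral_nonsyn_fraction()
  target_ns_odds * q0 / (target_ns_odds * q0 + 1 - q0)
}

# Substitute one base with transition:transversion = 2:1, avoiding any
# replacement that turns the host codon into a stop.
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

mutate_gene <- function(chars, positions) {
  for (pos in positions) {
    base <- chars[pos]
    if (!base %in% c("A", "C", "G", "T")) next
    ts <- .TRANSITION[[base]]
    tv <- setdiff(c("A", "C", "G", "T"), c(base, ts))
    # order candidate bases by decreasing draw probability (2:1:1)
    cand <- if (stats::runif(1) < 2 / 3) c(ts, sample(tv)) else c(sample(tv), ts)
    cstart <- pos - (pos - 1L) %% 3L
    for (nb in cand) {
      codon <- chars[cstart:(cstart + 2L)]
      codon[pos - cstart + 1L] <- nb
      if (!paste(codon, collapse = "") %in% STOP_CODONS) {
        chars[pos] <- nb
        break
      }
    }
  }
  chars
}

#' Simulate diverged clade-ancestor genomes
#'
#' Draws one random root coding sequence per orthogroup (ATG start, no
#' internal stop, terminal stop) and derives each clade ancestor on a star
#' phylogeny: every branch substitutes sites at rate `divergence/2`,
#' uniformly over internal-codon sites, with transition:transversion 2:1,
#' never creating an internal stop, so any two ancestors differ at about
#' `divergence` of sites.
#'
#' Seeds the RNG from `config$seed`; the result is bit-identical across
#' calls with the same configuration.
#'
#' @param config a [sim_config()].
#' @return named list, clade label (`A`, `B`, ...) -> named character
#'   vector of per-orthogroup CDS strings; the root genome is attached as
#'   attribute `root`.
#' @export
simulate_ancestors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- sim_gene_map(config)
  ogs <- map$og_id
  L <- config$gene_length
  sc <- sense_codons()
  root <- vapply(ogs, function(og) {
    paste(c("ATG", sample(sc, L - 2L, replace = TRUE), sample(STOP_CODONS, 1L)),
          collapse = "")
  }, character(1))
  clades <- LETTERS[seq_len(config$n_clades)]
  mutable <- seq.int(4L, 3L * L - 3L)  # internal codons only
  ancestors <- lapply(clades, function(cl) {
    vapply(ogs, function(og) {
      chars <- seq_chars(root[[og]])
      n <- stats::rbinom(1L, length(mutable), config$divergence / 2)
      if (n > 0L) chars <- mutate_gene(chars, sample(mutable, n))
      paste(chars, collapse = "")
    }, character(1))
  })
  names(ancestors) <- clades
  attr(ancestors, "root") <- root
  ancestors
}

#' Simulate one recombinant mosaic strain
#'
#' Partitions the gene order into `n_crossovers + 1` contiguous segments
#' (crossover positions drawn uniformly without replacement over
#' intra-chromosome gene junctions); each segment copies one donor clade's
#' ancestral genes verbatim, with adjacent segments from different donors.
#'
#' Consumes the session RNG stream (seed once at the dataset level, or via
#' `set.seed()` before standalone calls).
#'
#' @param ancestors output of [simulate_ancestors()].
#' @param config a [sim_config()].
#' @param strain_id name for the new strain.
#' @param donor_pool optional subset of clade labels to draw donors from
#'   (>= 2 unless `n_crossovers` is 0).
#' @return list with `strain`, `genome` (named og -> CDS), `donors`
#'   (data frame og_id, donor) and `breakpoints` (data frame chromosome,
#'   order_index of the first gene after each crossover).
#' @export
simulate_recombinant_strain <- function(ancestors, config, strain_id,
                                        donor_pool = NULL) {
  stopifnot(length(ancestors) >= 2)
  pool <- donor_pool %||% names(ancestors)
  if (config$n_crossovers > 0 && length(pool) < 2) {
    stop("need at least 2 donor clades")
  }
  map <- sim_gene_map(config)
  junctions <- which(map$order_index >= 2L)  # gene starting a potential new segment
  if (config$n_crossovers >= length(junctions)) {
    stop("n_crossovers (", config$n_crossovers, ") must be below the number of ",
         "gene junctions (", length(junctions), ")")
  }
  cross <- sort(sample(junctions, config$n_crossovers))
  seg <- findInterval(seq_len(nrow(map)), cross) + 1L
  donors <- character(max(seg))
  for (s in seq_len(max(seg))) {
    avail <- if (s == 1L) pool else setdiff(pool, donors[s - 1L])
    donors[s] <- if (length(avail) == 1L) avail else sample(avail, 1L)
  }
  donor_per_gene <- donors[seg]
  genome <- vapply(seq_len(nrow(map)), function(i) {
    ancestors[[donor_per_gene[i]]][[map$og_id[i]]]
  }, character(1))
  names(genome) <- map$og_id
  list(strain = strain_id,
       genome = genome,
       donors = data.frame(og_id = map$og_id, donor = donor_per_gene,
                           stringsAsFactors = FALSE),
       breakpoints = data.frame(chromosome = map$chromosome[cross],
                                order_index = map$order_index[cross],
                                stringsAsFactors = FALSE))
}

#' Inject domestication mutations into one strain genome
#'
#' Substitution events (count ~ Poisson(`intra_mut_rate`)) pick distinct
#' internal codons uniformly over the genome; each event is
#' non-synonymous with probability [nonsyn_event_prob()] and the
#' replacement codon is drawn uniformly from the same-amino-acid (syn) or
#' different-amino-acid non-stop (nonsyn) codons. Codons without a
#' required alternative (e.g. ATG for syn) trigger a position resample.
#' Gap events (count ~ Poisson(`gap_rate`)) delete one whole codon,
#' written as `---` so alignment columns are preserved.
#'
#' @param genome named character vector og -> CDS string.
#' @param config a [sim_config()].
#' @return list with `genome` (mutated) and `mutations` (data frame
#'   og_id, codon_index, kind, ref_codon, alt_codon).
#' @export
inject_domestication_mutations <- function(genome, config) {
  L <- config$gene_length
  ogs <- names(genome)
  n_sub <- stats::rpois(1L, config$intra_mut_rate)
  n_gap <- stats::rpois(1L, config$gap_rate)
  n_events <- n_sub + n_gap
  empty <- data.frame(og_id = character(0), codon_index = integer(0),
                      kind = character(0), ref_codon = character(0),
                      alt_codon = character(0), stringsAsFactors = FALSE)
  if (n_events == 0L) return(list(genome = genome, mutations = empty))

  # universe of internal codon slots, visited in random order
  n_int <- L - 2L
  slots <- sample.int(length(ogs) * n_int)
  p_ns <- nonsyn_event_prob(config$target_ns_odds)
  kinds <- c(ifelse(stats::runif(n_sub) < p_ns, "nonsyn", "syn"),
             rep("gap", n_gap))
  sc <- sense_codons()
  aa_all <- translate_codon(sc)

  rows <- vector("list", n_events)
  ptr <- 0L
  for (e in seq_len(n_events)) {
    repeat {
      ptr <- ptr + 1L
      if (ptr > length(slots)) stop("genome too short to host requested events")
      slot <- slots[ptr]
      og <- ogs[(slot - 1L) %/% n_int + 1L]
      ci <- (slot - 1L) %% n_int + 2L  # codon index, 1-based, internal
      ref <- substr(genome[[og]], 3L * ci - 2L, 3L * ci)
      kind <- kinds[e]
      if (kind == "gap") {
        alt <- "---"
      } else {
        aa <- translate_codon(ref)
        alts <- if (kind == "syn") sc[aa_all == aa & sc != ref] else sc[aa_all != aa]
        if (length(alts) == 0L) next  # resample position
        alt <- if (length(alts) == 1L) alts else sample(alts, 1L)
      }
      substr(genome[[og]], 3L * ci - 2L, 3L * ci) <- alt
      rows[[e]] <- data.frame(og_id = og, codon_index = ci, kind = kind,
                              ref_codon = ref, alt_codon = alt,
                              stringsAsFactors = FALSE)
      break
    }
  }
  list(genome = genome, mutations = do.call(rbind, rows))
}

#' Replay a mutation list onto a genome
#'
#' Applies the `alt_codon` of each recorded mutation at its codon index;
#' used to verify that ancestors + truth reproduce emitted sequences.
#'
#' @param genome named character vector og -> CDS string.
#' @param mutations data frame as produced by
#'   [inject_domestication_mutations()].
#' @return the mutated genome.
#' @export
apply_mutations <- function(genome, mutations) {
  for (i in seq_len(nrow(mutations))) {
    og <- mutations$og_id[i]
    ci <- mutations$codon_index[i]
    substr(genome[[og]], 3L * ci - 2L, 3L * ci) <- mutations$alt_codon[i]
  }
  genome
}

#' Simulate a read-depth track for one strain
#'
#' Genes are laid out by concatenating reference-length genes
#' (3 x `gene_length` bp) in map order per chromosome with no gaps;
#' per-base depth is Poisson(`mean_depth` x copy number).
#'
#' @param config a [sim_config()].
#' @param strain strain ID.
#' @param copy_number optional named numeric vector og -> integer copy
#'   number (default 1 everywhere).
#' @return a [depth_track()].
#' @export
simulate_depth <- function(config, strain, copy_number = NULL) {
  map <- sim_gene_map(config)
  bp <- 3L * config$gene_length
  cn <- stats::setNames(rep(1, nrow(map)), map$og_id)
  if (!is.null(copy_number)) cn[names(copy_number)] <- copy_number
  recs <- lapply(unique(map$chromosome), function(chr) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    lambda <- rep(config$mean_depth * cn[sub$og_id], each = bp)
    data.frame(chromosome = chr,
               position = seq_along(lambda),
               depth = stats::rpois(length(lambda), lambda),
               stringsAsFactors = FALSE)
  })
  depth_track(strain, do.call(rbind, recs))
}

#' Simulate a complete dataset with ground truth
#'
#' Seeds the RNG once from `config$seed` and generates, in fixed order:
#' clade ancestors, per-clade strains with private domestication
#' mutations, recombinant mosaic query strains, per-strain MAT regions
#' (one of two fixed synthetic markers, random strand, between random
#' flanks), copy-number assignments from `cnv_spec`, and Poisson depth
#' tracks. MAT idiomorphs alternate by clade (odd clades MAT1-1, even
#' MAT1-2), reproducing the MAT-by-clade linkage seen in clonal lineages.
#'
#' @param config a [sim_config()].
#' @param with_depth generate per-strain depth tracks (default `TRUE`).
#'   Depth is drawn after all other components, so disabling it leaves
#'   every other output bit-identical for a given configuration.
#' @return a `koji_sim` list: `config`, `ancestors`, `gene_map`,
#'   `alignments` (an [alignment_set()] over all strains), `depth` (named
#'   list of [depth_track()]), `mat_regions` (named strain -> sequence),
#'   `markers`, and `truth` (clade, mat, donors, breakpoints, mutations,
#'   copy_number tables).
#' @export
simulate_dataset <- function(config, with_depth = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ancestors <- simulate_ancestors(config)   # reseeds to the same seed
  map <- sim_gene_map(config)
  clades <- names(ancestors)
  pure <- unlist(lapply(clades, function(cl) {
    paste0(cl, seq_len(config$n_strains_per_clade))
  }))
  recomb <- if (config$n_recombinants > 0) {
    paste0("R", seq_len(config$n_recombinants))
  } else character(0)
  strains <- c(pure, recomb)

  clade_of <- stats::setNames(
    c(rep(clades, each = config$n_strains_per_clade),
      rep("recombinant", length(recomb))), strains)
  mat_of_clade <- stats::setNames(
    ifelse(seq_along(clades) %% 2L == 1L, "MAT1-1", "MAT1-2"), clades)

  genomes <- list()
  donors <- list()
  breakpoints <- list()
  mutations <- list()
  true_mat <- character(0)

  for (s in strains) {
    if (clade_of[[s]] != "recombinant") {
      base <- ancestors[[clade_of[[s]]]]
      donors[[s]] <- data.frame(strain = s, og_id = map$og_id,
                                donor = clade_of[[s]], stringsAsFactors = FALSE)
      breakpoints[[s]] <- data.frame(strain = character(0), chromosome = character(0),
                                     order_index = integer(0), stringsAsFactors = FALSE)
      true_mat[s] <- mat_of_clade[[clade_of[[s]]]]
    } else {
      rec <- simulate_recombinant_strain(ancestors, config, s)
      base <- rec$genome
      donors[[s]] <- cbind(strain = s, rec$donors, stringsAsFactors = FALSE)
      breakpoints[[s]] <- if (nrow(rec$breakpoints) > 0) {
        cbind(strain = s, rec$breakpoints, stringsAsFactors = FALSE)
      } else {
        data.frame(strain = character(0), chromosome = character(0),
                   order_index = integer(0), stringsAsFactors = FALSE)
      }
      true_mat[s] <- sample(c("MAT1-1", "MAT1-2"), 1L)
    }
    mut <- inject_domestication_mutations(base, config)
    genomes[[s]] <- mut$genome
    mutations[[s]] <- if (nrow(mut$mutations) > 0) {
      cbind(strain = s, mut$mutations, stringsAsFactors = FALSE)
    } else NULL
  }

  # copy numbers: default 1, cnv_spec applied to pure strains by clade
  cn <- expand.grid(strain = strains, og_id = map$og_id,
                    stringsAsFactors = FALSE)
  cn$copy_number <- 1L
  if (!is.null(config$cnv_spec)) {
    for (i in seq_len(nrow(config$cnv_spec))) {
      row <- config$cnv_spec[i, ]
      hit <- cn$og_id == row$og_id & clade_of[cn$strain] == row$clade
      cn$copy_number[hit] <- as.integer(row$copy_number)
    }
  }

  # MAT regions: flank + marker (random strand) + flank
  markers <- sim_mat_markers()
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  mat_regions <- vapply(strains, function(s) {
    m <- if (true_mat[[s]] == "MAT1-1") markers$mat1_1 else markers$mat1_2
    if (stats::runif(1) < 0.5) m <- revcomp(m)
    paste0(rand_dna(40L), m, rand_dna(40L))
  }, character(1))

  depth <- if (with_depth) {
    stats::setNames(lapply(strains, function(s) {
      cns <- cn[cn$strain == s, ]
      simulate_depth(config, s, stats::setNames(cns$copy_number, cns$og_id))
    }), strains)
  } else {
    NULL
  }

  alns <- lapply(map$og_id, function(og) {
    gene_alignment(og, vapply(strains, function(s) genomes[[s]][[og]], character(1)))
  })

  structure(list(
    config = config,
    ancestors = ancestors,
    gene_map = map,
    alignments = alignment_set(alns),
    depth = depth,
    mat_regions = mat_regions,
    markers = markers,
    truth = list(
      clade = clade_of,
      mat = true_mat,
      donors = do.call(rbind, unname(donors)),
      breakpoints = do.call(rbind, unname(breakpoints)),
      mutations = do.call(rbind, unname(mutations)) %||%
        data.frame(strain = character(0), og_id = character(0),
                   codon_index = integer(0), kind = character(0),
                   ref_codon = character(0), alt_codon = character(0)),
      copy_number = cn
    )
  ), class = "koji_sim")
}

#' @export
print.koji_sim <- function(x, ...) {
  cat("koji_sim:", length(x$truth$clade), "strains,",
      nrow(x$gene_map), "genes,", x$config$n_clades, "clades (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits per-orthogroup aligned FASTA (codon deletions re-padded with
#' `-`), the gene map TSV, samtools-depth-style TSV per strain, the MAT
#' marker FASTA and per-strain MAT region FASTA, truth tables, and a
#' manifest with MD5 checksums. A failed write aborts and removes the
#' output directory.
#'
#' @param config a [sim_config()].
#' @param output_dir directory to create/populate.
#' @return the manifest data frame (file, md5), invisibly; the `koji_sim`
#'   object is attached as attribute `sim`.
#' @export
emit_dataset <- function(config, output_dir) {
  sim <- simulate_dataset(config)
  created <- !dir.exists(output_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(output_dir, recursive = TRUE), add = TRUE)

  dir.create(file.path(output_dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "depth"), showWarnings = FALSE)
  files <- character(0)
  put <- function(rel) {
    files <<- c(files, rel)
    file.path(output_dir, rel)
  }
  wtsv <- function(df, rel, col.names = TRUE) {
    utils::write.table(df, put(rel), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  for (og in names(sim$alignments$alignments)) {
    write_fasta(sim$alignments$alignments[[og]]$sequences,
                put(file.path("alignments", paste0(og, ".fasta"))))
  }
  wtsv(as.data.frame(sim$gene_map), "gene_map.tsv")
  for (s in names(sim$depth)) {
    wtsv(sim$depth[[s]]$records, file.path("depth", paste0(s, ".tsv")),
         col.names = FALSE)
  }
  write_fasta(c("MAT1-1" = sim$markers$mat1_1, "MAT1-2" = sim$markers$mat1_2),
              put("mat_markers.fasta"))
  write_fasta(sim$mat_regions, put("mat_regions.fasta"))
  wtsv(data.frame(strain = names(sim$truth$clade),
                  clade = unname(sim$truth$clade),
                  mat = unname(sim$truth$mat[names(sim$truth$clade)])),
       "truth_strains.tsv")
  wtsv(sim$truth$donors, "truth_donors.tsv")
  wtsv(sim$truth$breakpoints, "truth_breakpoints.tsv")
  wtsv(sim$truth$mutations, "truth_mutations.tsv")
  wtsv(sim$truth$copy_number, "truth_copy_number.tsv")

  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(output_dir, files))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  attr(manifest, "sim") <- sim
  invisible(manifest)
}
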