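test_that("ancestor simulation is deterministic and respects CDS structure", {
  cfg <- tiny_config()
  a1 <- simulate_ancestors(cfg)
  a2 <- simulate_ancestors(cfg)
  expect_identical(a1, a2)

  for (cl in names(a1)) {
    for (seq in a1[[cl]]) {
      codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
      expect_identical(codons[1], "ATG")
      expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
      expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("realized ancestor divergence matches the configured rate", {
  # 50 genes x 200 codons = 30,000 sites; binomial CI around 0.01
  cfg <- sim_config(n_clades = 4, genes_per_chromosome = 50,
                    gene_length = 200, divergence = 0.01, seed = 3)
  anc <- simulate_ancestors(cfg)
  prs <- utils::combn(names(anc), 2)
  d <- apply(prs, 2, function(p) {
    a <- paste(anc[[p[1]]], collapse = "")
    b <- paste(anc[[p[2]]], collapse = "")
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  })
  expect_gt(mean(d), 0.0085)
  expect_lt(mean(d), 0.0115)
})

test_that("recombinant strains have the configured segment structure", {
  clades <- c("A", "B", "C")
  ogs <- sprintf("OG%04d", 1:20)
  anc <- dummy_ancestors(clades, ogs)

  cfg0 <- tiny_config(n_crossovers = 0)
  set.seed(5)
  rec0 <- simulate_recombinant_strain(anc, cfg0, "r0")
  expect_identical(nrow(rec0$breakpoints), 0L)
  expect_length(unique(rec0$donors$donor), 1L)

  cfg3 <- tiny_config(n_crossovers = 3)
  set.seed(6)
  rec3 <- simulate_recombinant_strain(anc, cfg3, "r3")
  expect_identical(nrow(rec3$breakpoints), 3L)
  runs <- rle(rec3$donors$donor)
  expect_identical(length(runs$lengths), 4L)
  # adjacent segments always change donor
  expect_true(all(runs$values[-1] != runs$values[-length(runs$values)]))
  # genes are copied verbatim from the recorded donor
  expect_true(all(vapply(seq_len(nrow(rec3$donors)), function(i) {
    og <- rec3$donors$og_id[i]
    identical(rec3$genome[[og]], anc[[rec3$donors$donor[i]]][[og]])
  }, logical(1))))

  # too many crossovers for the junction count
  expect_error(simulate_recombinant_strain(anc, tiny_config(n_crossovers = 18),
                                           "rx"), "junction")
})

test_that("donor clades are drawn with near-uniform share", {
  clades <- c("A", "B", "C")
  ogs <- sprintf("OG%04d", 1:20)
  anc <- dummy_ancestors(clades, ogs)
  cfg <- tiny_config(n_crossovers = 3)
  set.seed(77)
  share <- rowMeans(vapply(1:200, function(i) {
    rec <- simulate_recombinant_strain(anc, cfg, "r")
    tab <- table(factor(rec$donors$donor, levels = clades))
    as.numeric(tab) / length(ogs)
  }, numeric(3)))
  expect_true(all(abs(share - 1 / 3) < 0.05))
})

test_that("injected mutation spectrum hits the requested nonsyn/syn ratio", {
  # choose the odds multiplier m so that E[nonsyn]/E[syn] = 2
  q0 <- kojimosaic:::neutral_nonsyn_fraction()
  m <- 2 * (1 - q0) / q0
  expect_equal(nonsyn_event_prob(m), 2 / 3, tolerance = 1e-12)

  cfg <- sim_config(n_clades = 2, genes_per_chromosome = 100,
                    gene_length = 100, intra_mut_rate = 1000, gap_rate = 0,
                    target_ns_odds = m, seed = 9)
  anc <- simulate_ancestors(cfg)
  mut <- inject_domestication_mutations(anc$A, cfg)$mutations
  n <- sum(mut$kind %in% c("syn", "nonsyn"))
  frac <- sum(mut$kind == "nonsyn") / n
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(frac - 2 / 3), 3 * se)
})

test_that("zero mutation rate leaves the genome unchanged", {
  cfg <- tiny_config(intra_mut_rate = 0, gap_rate = 0)
  anc <- simulate_ancestors(cfg)
  set.seed(2)
  out <- inject_domestication_mutations(anc$B, cfg)
  expect_identical(out$genome, anc$B)
  expect_identical(nrow(out$mutations), 0L)
})

test_that("recorded syn events never change the protein", {
  cfg <- tiny_config(intra_mut_rate = 200, gap_rate = 0, seed = 4)
  anc <- simulate_ancestors(cfg)
  set.seed(4)
  mut <- inject_domestication_mutations(anc$A, cfg)$mutations
  syn <- mut[mut$kind == "syn", ]
  expect_gt(nrow(syn), 0)
  gc <- Biostrings::GENETIC_CODE
  expect_true(all(gc[syn$ref_codon] == gc[syn$alt_codon]))
  nonsyn <- mut[mut$kind == "nonsyn", ]
  expect_true(all(gc[nonsyn$ref_codon] != gc[nonsyn$alt_codon]))
  # no nonsyn replacement creates a stop
  expect_false(any(nonsyn$alt_codon %in% c("TAA", "TAG", "TGA")))
})

test_that("simulated depth tracks have Poisson copy-number structure", {
  cfg <- sim_config(n_clades = 2, genes_per_chromosome = 10, gene_length = 200,
                    mean_depth = 100, seed = 8)
  set.seed(8)
  cn <- c(OG0003 = 2)
  trk <- simulate_depth(cfg, "s1", cn)
  spans <- make_gene_spans(sim_gene_map(cfg), 600)
  gm <- gene_mean_depth(trk, spans)
  expect_gt(gm$mean_depth[gm$og_id == "OG0003"], 180)
  expect_lt(gm$mean_depth[gm$og_id == "OG0003"], 220)

  cfg0 <- sim_config(n_clades = 2, genes_per_chromosome = 5, gene_length = 20,
                     mean_depth = 0, seed = 8)
  expect_true(all(simulate_depth(cfg0, "s1")$records$depth == 0))

  set.seed(8)
  trk2 <- simulate_depth(cfg, "s1", cn)
  expect_identical(trk, trk2)
})

test_that("gap columns and frame are conserved in emitted alignments", {
  cfg <- tiny_config(intra_mut_rate = 5, gap_rate = 3, seed = 21)
  sim <- simulate_dataset(cfg, with_depth = FALSE)
  truth <- sim$truth$mutations
  for (s in names(sim$truth$clade)) {
    genome <- vapply(sim$alignments$alignments,
                     function(a) a$sequences[[s]], character(1))
    n_dash <- sum(vapply(genome, function(x) {
      lengths(regmatches(x, gregexpr("-", x, fixed = TRUE)))
    }, integer(1)))
    n_gap_events <- sum(truth$strain == s & truth$kind == "gap")
    expect_identical(n_dash, 3L * n_gap_events)
    for (g in genome) {
      ungapped <- gsub("-", "", g, fixed = TRUE)
      expect_identical(nchar(ungapped) %% 3L, 0L)
      codons <- substring(ungapped, seq(1, nchar(ungapped) - 3, 3),
                          seq(3, nchar(ungapped) - 3, 3))
      expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("emitted datasets read back through core_io and replay truth", {
  cfg <- tiny_config(seed = 13)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "ds")
  manifest <- emit_dataset(cfg, out)
  sim <- attr(manifest, "sim")

  aset <- read_alignment_set(file.path(out, "alignments"))
  expect_identical(sort(aset$strains), sort(names(sim$truth$clade)))
  map <- read_gene_map(file.path(out, "gene_map.tsv"))
  expect_identical(map$og_id, sim$gene_map$og_id)
  trk <- read_depth_table(file.path(out, "depth", "A1.tsv"), "A1")
  expect_identical(nrow(trk$records), nrow(sim$depth[["A1"]]$records))
  markers <- read_fasta(file.path(out, "mat_markers.fasta"))
  expect_identical(unname(markers["MAT1-1"]), sim_mat_markers()$mat1_1)

  # replaying the truth mutation list onto the donor ancestors reproduces
  # every emitted sequence
  truth <- sim$truth
  for (s in names(truth$clade)) {
    donors <- truth$donors[truth$donors$strain == s, ]
    base <- vapply(seq_len(nrow(donors)), function(i) {
      sim$ancestors[[donors$donor[i]]][[donors$og_id[i]]]
    }, character(1))
    names(base) <- donors$og_id
    replayed <- apply_mutations(base, truth$mutations[truth$mutations$strain == s, ])
    emitted <- vapply(sim$alignments$alignments, function(a) a$sequences[[s]],
                      character(1))
    expect_identical(replayed[names(emitted)], emitted)
  }

  # checksums are a pure function of the configuration
  out2 <- file.path(dir, "ds2")
  manifest2 <- emit_dataset(cfg, out2)
  expect_identical(manifest$md5, manifest2$md5)
})
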