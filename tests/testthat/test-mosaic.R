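# helpers to build tiny alignment sets with known structure
aset_from <- function(mat) {
  # mat: named list og -> named char vector of aligned sequences
  alignment_set(lapply(names(mat), function(og) gene_alignment(og, mat[[og]])))
}

test_that("clade references take the per-column majority with fixed tie order", {
  aset <- aset_from(list(
    og1 = c(m1 = "AAA", m2 = "AAA", m3 = "AAG", q = "AAA")
  ))
  labels <- c(m1 = "X", m2 = "X", m3 = "X", q = "Q")
  expect_identical(unname(clade_reference(aset, labels, "X")[["og1"]]), "AAA")

  aset2 <- aset_from(list(og1 = c(m1 = "AAA", m2 = "AAG", q = "CCC")))
  labels2 <- c(m1 = "X", m2 = "X", q = "Q")
  # tie at position 3 between A and G: A wins (A < G)
  expect_identical(unname(clade_reference(aset2, labels2, "X")[["og1"]]), "AAA")
  # single-member clade: reference is that member
  expect_identical(unname(clade_reference(aset2, labels2, "Q")[["og1"]]), "CCC")
  expect_error(clade_reference(aset2, labels2, "Z"), "no members")
})

test_that("gap-majority columns are retained as '-' in references", {
  aset <- aset_from(list(og1 = c(m1 = "A---", m2 = "A--A", m3 = "A--A")))
  labels <- c(m1 = "X", m2 = "X", m3 = "X")
  expect_identical(unname(clade_reference(aset, labels, "X")[["og1"]]), "A--A")
})

test_that("identity profiles require exact equality up to shared gaps", {
  aset <- aset_from(list(
    og1 = c(m1 = "AAATTT", q = "AAATTT"),
    og2 = c(m1 = "AAATTT", q = "AAATTA"),
    og3 = c(m1 = "AAA---", q = "AAA---")
  ))
  refs <- clade_references(aset, c(m1 = "X", q = "Q"), "X")
  prof <- identity_profile("q", aset, refs)
  expect_identical(unname(prof$indicator["X", ]), c(1L, 0L, 1L))
  expect_error(identity_profile("nope", aset, refs), "missing")
})

test_that("a shared gap column is ignored, a private one is not", {
  aset <- aset_from(list(og1 = c(ref = "AAA---CCC", q = "AAA---CCC"),
                         og2 = c(ref = "AAA---CCC", q = "AAACCCCCC")))
  refs <- clade_references(aset, c(ref = "X", q = "Q"), "X")
  prof <- identity_profile("q", aset, refs)
  expect_identical(unname(prof$indicator["X", ]), c(1L, 0L))
})

test_that("window-1 mosaic tracks equal the raw indicators", {
  cfg <- tiny_config(seed = 15)
  sim <- simulate_dataset(cfg, with_depth = FALSE)
  pure <- sim$truth$clade[sim$truth$clade != "recombinant"]
  refs <- clade_references(sim$alignments, pure)
  prof <- identity_profile("R1", sim$alignments, refs)
  trk <- mosaic_track(prof, sim$gene_map, window = 1)
  for (cl in names(refs)) {
    expect_identical(trk[[paste0("score_", cl)]],
                     100 * as.numeric(prof$indicator[cl, trk$og_id]))
  }
})

test_that("uniform indicators give a constant track and argmax closest", {
  ogs <- sprintf("OG%04d", 1:12)
  ind <- matrix(0L, 2, 12, dimnames = list(c("A", "B"), ogs))
  ind["B", ] <- 1L
  prof <- structure(list(strain = "q", indicator = ind),
                    class = "identity_profile")
  map <- gene_order_map(data.frame(og_id = ogs, chromosome = "I",
                                   order_index = 1:12))
  trk <- mosaic_track(prof, map, window = 5)
  expect_true(all(trk$score_B == 100))
  expect_true(all(trk$score_A == 0))
  expect_true(all(trk$closest == "B"))
})

test_that("score ties are reported as unassigned", {
  ogs <- sprintf("OG%04d", 1:6)
  ind <- matrix(1L, 2, 6, dimnames = list(c("A", "B"), ogs))
  prof <- structure(list(strain = "q", indicator = ind),
                    class = "identity_profile")
  map <- gene_order_map(data.frame(og_id = ogs, chromosome = "I",
                                   order_index = 1:6))
  trk <- mosaic_track(prof, map, window = 3)
  expect_true(all(trk$closest == "unassigned"))
})

test_that("oversized windows are clipped with a warning", {
  ogs <- sprintf("OG%04d", 1:4)
  ind <- matrix(rep(c(1L, 0L), each = 4), 2, 4, byrow = TRUE,
                dimnames = list(c("A", "B"), ogs))
  prof <- structure(list(strain = "q", indicator = ind),
                    class = "identity_profile")
  map <- gene_order_map(data.frame(og_id = ogs, chromosome = "I",
                                   order_index = 1:4))
  expect_warning(trk <- mosaic_track(prof, map, window = 21), "clipped")
  expect_true(all(trk$closest == "A"))
  expect_error(mosaic_track(prof, map, window = 4), "odd")
})

test_that("genome shares are indicator means, not a partition", {
  ogs <- sprintf("OG%04d", 1:100)
  ind <- matrix(0L, 2, 100, dimnames = list(c("A", "B"), ogs))
  ind["B", 1:46] <- 1L
  ind["A", 40:50] <- 1L
  prof <- structure(list(strain = "q", indicator = ind),
                    class = "identity_profile")
  share <- genome_share(prof)
  expect_identical(unname(share["B"]), 0.46)
  expect_identical(unname(share["A"]), 0.11)

  ind0 <- matrix(0L, 2, 100, dimnames = list(c("A", "B"), ogs))
  prof0 <- structure(list(strain = "q", indicator = ind0),
                     class = "identity_profile")
  expect_true(all(genome_share(prof0) == 0))
})

test_that("a strain dominated by one clade keeps a high share of it", {
  # analogous to the TK-27 pattern: >= 85% of the genome homologous to one
  # clade, the remainder scattered over others
  ogs <- sprintf("OG%04d", 1:200)
  ind <- matrix(0L, 3, 200, dimnames = list(c("G", "A", "B"), ogs))
  ind["G", 1:174] <- 1L
  ind["A", 175:187] <- 1L
  ind["B", 188:200] <- 1L
  prof <- structure(list(strain = "tk27", indicator = ind),
                    class = "identity_profile")
  expect_gte(genome_share(prof)[["G"]], 0.85)
  expect_false(mixture_test(prof)$is_mixture)
})

test_that("mixture verdicts separate two-donor from one- and three-donor strains", {
  cfg <- tiny_config(intra_mut_rate = 0, gap_rate = 0, n_crossovers = 5,
                     genes_per_chromosome = c(30, 30), gene_length = 200,
                     seed = 16)
  anc <- simulate_ancestors(cfg)
  refs <- lapply(anc, identity)  # ancestors are the clade references here

  profile_of <- function(rec) {
    aln <- alignment_set(lapply(names(rec$genome), function(og) {
      gene_alignment(og, c(stats::setNames(rec$genome[og], "q"),
                           vapply(refs, function(r) r[[og]], character(1))))
    }))
    refs2 <- lapply(names(refs), function(cl) {
      vapply(aln$alignments, function(a) a$sequences[[cl]], character(1))
    })
    names(refs2) <- names(refs)
    identity_profile("q", aln, refs2)
  }

  set.seed(16)
  two <- simulate_recombinant_strain(anc, cfg, "two", donor_pool = c("A", "B"))
  v2 <- mixture_test(profile_of(two))
  expect_true(v2$is_mixture)
  expect_setequal(v2$best_pair, c("A", "B"))

  cfg1 <- tiny_config(intra_mut_rate = 0, gap_rate = 0, n_crossovers = 0,
                      genes_per_chromosome = c(30, 30), gene_length = 200,
                      seed = 16)
  one <- simulate_recombinant_strain(anc, cfg1, "one", donor_pool = "A")
  v1 <- mixture_test(profile_of(one))
  expect_false(v1$is_mixture)
  expect_equal(v1$pair_coverage, 1)  # pair covers all, but one donor fails min_each

  cfg3 <- tiny_config(intra_mut_rate = 0, gap_rate = 0, n_crossovers = 8,
                      genes_per_chromosome = c(30, 30), gene_length = 200,
                      seed = 16)
  three <- simulate_recombinant_strain(anc, cfg3, "three",
                                       donor_pool = c("A", "B", "C"))
  v3 <- mixture_test(profile_of(three))
  expect_false(v3$is_mixture)
  expect_lt(v3$pair_coverage, 0.95)
})

test_that("donor-clade share never grows with the mutation load", {
  shares <- vapply(c(0, 5, 25), function(rate) {
    mean(vapply(1:4, function(s) {
      cfg <- tiny_config(n_clades = 2, n_strains_per_clade = 2,
                         n_recombinants = 0, intra_mut_rate = rate,
                         gap_rate = 0, seed = 100 + s)
      sim <- simulate_dataset(cfg, with_depth = FALSE)
      refs <- list(A = sim$ancestors$A)
      prof <- identity_profile("A1", sim$alignments, refs)
      genome_share(prof)[["A"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(shares) <= 1e-9))
})
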