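# Chromosomal mosaicism analysis: per-gene identity of a query strain to
# each clade's consensus reference, sliding-window similarity scores and
# closest-clade tracks along chromosomes, genome-share summaries, and the
# two-clade mixture test.

#' Per-clade consensus reference sequences
#'
#' For each alignment column, the majority character among clade members;
#' ties are broken by the fixed order `A < C < G < T < N < -`.
#' Gap-majority columns are retained as `-` in the reference.
#'
#' @param aset an [alignment_set()].
#' @param assignment a [clade_assignment()] (or named strain -> clade
#'   vector).
#' @param clade clade label with >= 1 member.
#' @return named character vector og_id -> reference CDS string (aligned
#'   coordinates).
#' @export
clade_reference <- function(aset, assignment, clade) {
  labels <- if (inherits(assignment, "clade_assignment")) assignment$labels else assignment
  members <- names(labels)[labels == clade]
  if (length(members) == 0L) stop("clade ", clade, " has no members")
  vapply(aset$alignments, function(a) {
    consensus_string(a$sequences[members])
  }, character(1))
}

# Majority-vote consensus of equal-length aligned strings with the fixed
# tie order A < C < G < T < N < -.
consensus_string <- function(seqs) {
  if (length(seqs) == 1L) return(unname(seqs[[1]]))
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  counts <- vapply(CONSENSUS_ORDER, function(s) colSums(m == s),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, CONSENSUS_ORDER))
  paste(CONSENSUS_ORDER[max.col(counts, ties.method = "first")], collapse = "")
}

#' References for every clade at once
#'
#' @param aset an [alignment_set()].
#' @param assignment a [clade_assignment()] or named label vector.
#' @param clades clade labels to build (default: all observed labels).
#' @return named list clade -> [clade_reference()] vector.
#' @export
clade_references <- function(aset, assignment, clades = NULL) {
  labels <- if (inherits(assignment, "clade_assignment")) assignment$labels else assignment
  clades <- clades %||% unique(labels)
  refs <- lapply(clades, function(cl) clade_reference(aset, labels, cl))
  names(refs) <- clades
  refs
}

#' Per-gene identity profile of a query strain against clade references
#'
#' The indicator is 1 iff the query's aligned gene sequence equals the
#' clade reference exactly, after dropping columns gapped in both query
#' and reference.
#'
#' @param strain query strain ID (must be present in every alignment).
#' @param aset an [alignment_set()].
#' @param references named list clade -> reference vector from
#'   [clade_references()].
#' @return an `identity_profile` list: `strain` and `indicator`, a 0/1
#'   matrix (clades x orthogroups).
#' @export
identity_profile <- function(strain, aset, references) {
  ogs <- names(aset$alignments)
  ind <- matrix(0L, nrow = length(references), ncol = length(ogs),
                dimnames = list(names(references), ogs))
  for (og in ogs) {
    q <- aset$alignments[[og]]$sequences[strain]
    if (is.na(q)) stop("strain ", strain, " missing from orthogroup ", og)
    q <- unname(q)
    for (cl in names(references)) {
      r <- references[[cl]][[og]]
      if (q == r) {
        ind[cl, og] <- 1L
      } else if (grepl("-", q, fixed = TRUE) && grepl("-", r, fixed = TRUE)) {
        qc <- seq_chars(q); rc <- seq_chars(r)
        keep <- !(qc == "-" & rc == "-")
        ind[cl, og] <- as.integer(all(qc[keep] == rc[keep]))
      }
    }
  }
  structure(list(strain = strain, indicator = ind), class = "identity_profile")
}

#' Closest-clade track along chromosomes
#'
#' For each gene position i, the similarity score of a clade is 100 times
#' the mean identity indicator over a `window`-gene window centred at i
#' (clipped at chromosome ends); the closest clade is the argmax, with
#' ties reported as `"unassigned"`.
#'
#' @param profile an [identity_profile()].
#' @param gene_map a `gene_order_map` covering the profiled orthogroups.
#' @param window odd positive window size in genes (default 21). A window
#'   larger than a chromosome is clipped with a warning.
#' @return a `mosaic_track` data frame: chromosome, order_index, og_id,
#'   one `score_<clade>` column per clade (percent), and `closest`.
#' @export
mosaic_track <- function(profile, gene_map, window = 21) {
  stopifnot(inherits(profile, "identity_profile"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd positive integer")
  clades <- rownames(profile$indicator)
  out <- lapply(unique(gene_map$chromosome), function(chr) {
    sub <- gene_map[gene_map$chromosome == chr, , drop = FALSE]
    ng <- nrow(sub)
    w <- window
    if (w > ng) {
      w <- if (ng %% 2L == 1L) ng else ng - 1L
      warning("window ", window, " exceeds chromosome ", chr,
              " (", ng, " genes); clipped to ", w)
    }
    half <- (w - 1L) %/% 2L
    ind <- profile$indicator[, sub$og_id, drop = FALSE]
    lo <- pmax(seq_len(ng) - half, 1L)
    hi <- pmin(seq_len(ng) + half, ng)
    scores <- do.call(rbind, lapply(seq_len(nrow(ind)), function(r) {
      cs <- c(0, cumsum(ind[r, ]))
      100 * (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }))
    best <- apply(scores, 2L, function(col) {
      top <- max(col)
      w2 <- which(col >= top - 1e-9)
      if (length(w2) == 1L) clades[w2] else "unassigned"
    })
    df <- data.frame(chromosome = chr, order_index = sub$order_index,
                     og_id = sub$og_id, stringsAsFactors = FALSE)
    for (k in seq_along(clades)) df[[paste0("score_", clades[k])]] <- scores[k, ]
    df$closest <- best
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "strain") <- profile$strain
  attr(res, "window") <- window
  class(res) <- c("mosaic_track", "data.frame")
  res
}

#' Fraction of genes identical to each clade reference
#'
#' The genome share of a clade is the mean identity indicator over all
#' orthogroups. Shares need not sum to 1: a gene can be identical to
#' several clade references.
#'
#' @param profile an [identity_profile()].
#' @return named numeric vector clade -> share in `[0, 1]`.
#' @export
genome_share <- function(profile) {
  stopifnot(inherits(profile, "identity_profile"))
  rowMeans(profile$indicator)
}

#' Two-clade mixture test
#'
#' Asks whether a strain's genome is explained as a mixture of two other
#' clades: for every unordered clade pair the pair coverage is the
#' fraction of genes identical to at least one of the two references.
#' The verdict is "mixture" iff the best pair coverage reaches
#' `coverage_threshold` and each member of the pair individually covers
#' at least `min_each` (both donors must contribute; a single-donor
#' strain is not a mixture).
#'
#' @param profile an [identity_profile()] over >= 2 candidate clades.
#' @param coverage_threshold minimum joint coverage (default 0.95).
#' @param min_each minimum individual coverage per pair member
#'   (default 0.10).
#' @return list with `is_mixture`, `best_pair`, `pair_coverage`,
#'   `member_coverage` (shares of the best pair) and `pairs` (all pairs,
#'   decreasing coverage).
#' @export
mixture_test <- function(profile, coverage_threshold = 0.95, min_each = 0.10) {
  ind <- profile$indicator
  clades <- rownames(ind)
  if (length(clades) < 2L) stop("need at least 2 candidate clades")
  shares <- rowMeans(ind)
  prs <- utils::combn(clades, 2L)
  cov <- apply(prs, 2L, function(p) mean(ind[p[1], ] | ind[p[2], ]))
  ord <- order(cov, decreasing = TRUE)
  pairs <- data.frame(clade_x = prs[1, ord], clade_y = prs[2, ord],
                      pair_coverage = cov[ord], stringsAsFactors = FALSE)
  best <- pairs[1, ]
  mc <- shares[c(best$clade_x, best$clade_y)]
  list(is_mixture = best$pair_coverage >= coverage_threshold && all(mc >= min_each),
       best_pair = c(best$clade_x, best$clade_y),
       pair_coverage = best$pair_coverage,
       member_coverage = mc,
       pairs = pairs)
}
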