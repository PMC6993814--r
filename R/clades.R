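# Clade analysis on concatenated degapped gene sequences: p-distances,
# single-linkage clade clustering at a dissimilarity threshold,
# neighbor-joining trees, MAT typing and MAT-by-clade linkage.

#' Concatenate degapped gene sequences
#'
#' For each alignment, every column containing `-` in any strain is
#' removed; the remaining columns are concatenated in lexicographic og_id
#' order. An orthogroup losing all columns is skipped with a warning.
#'
#' @param aset an [alignment_set()].
#' @return a `concat_matrix` list: `strains`, `columns` (total retained),
#'   `matrix` (named per-strain concatenated string) and `per_og`
#'   (data frame og_id, total, retained, skipped).
#' @export
concat_degapped <- function(aset) {
  stopifnot(inherits(aset, "alignment_set"))
  strains <- aset$strains
  ogs <- sort(names(aset$alignments))
  pieces <- vector("list", length(ogs))
  report <- data.frame(og_id = ogs, total = 0L, retained = 0L, skipped = FALSE)
  for (k in seq_along(ogs)) {
    a <- aset$alignments[[ogs[k]]]
    m <- do.call(rbind, strsplit(a$sequences[strains], "", fixed = TRUE))
    keep <- colSums(m == "-") == 0L
    report$total[k] <- a$length
    report$retained[k] <- sum(keep)
    if (!any(keep)) {
      warning("orthogroup ", ogs[k], " has no gap-free columns; skipped")
      report$skipped[k] <- TRUE
      next
    }
    mm <- m[, keep, drop = FALSE]
    pieces[[k]] <- apply(mm, 1L, paste, collapse = "")
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) stop("no gap-free columns in any orthogroup")
  mat <- do.call(paste0, pieces)
  names(mat) <- strains
  structure(list(strains = strains, columns = nchar(mat[[1]]),
                 matrix = mat, per_og = report),
            class = "concat_matrix")
}

#' @export
print.concat_matrix <- function(x, ...) {
  cat("concat_matrix:", length(x$strains), "strains x", nchar(x$matrix[[1]]),
      "retained columns (", sum(!x$per_og$skipped), "of", nrow(x$per_og),
      "orthogroups )\n")
  invisible(x)
}

#' Pairwise p-distance on a concatenated matrix
#'
#' `d[i,j]` is the fraction of columns at which strains i and j differ;
#' `N` is a wildcard matching anything (low-coverage ambiguity does not
#' inflate distances). The denominator is the full column count.
#'
#' @param concat a [concat_degapped()] result, or a named character vector
#'   of equal-length gap-free strings.
#' @return symmetric numeric matrix with zero diagonal, strains as
#'   dimnames.
#' @export
pdistance <- function(concat) {
  seqs <- if (inherits(concat, "concat_matrix")) concat$matrix else concat
  n <- length(seqs)
  L <- nchar(seqs[[1]])
  stopifnot(L >= 1L, all(nchar(seqs) == L))
  raws <- lapply(seqs, charToRaw)
  rawN <- charToRaw("N")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- raws[[i]]; b <- raws[[j]]
      diff <- sum(a != b & a != rawN & b != rawN)
      d[i, j] <- d[j, i] <- diff / L
    }
  }
  d
}

#' Cluster strains into clades by single linkage
#'
#' Strains whose chained dissimilarity stays within `threshold` (default
#' 0.01%, i.e. 1e-4) form one clade. Clusters are labelled `C1`, `C2`, ...
#' in order of their first-appearing strain; singletons get their own
#' label.
#'
#' @param distmat symmetric distance matrix from [pdistance()].
#' @param threshold maximum within-clade link distance.
#' @return named character vector strain -> clade label.
#' @export
cluster_clades <- function(distmat, threshold = 1e-4) {
  strains <- rownames(distmat)
  n <- length(strains)
  if (n == 1L) return(stats::setNames("C1", strains))
  hc <- stats::hclust(stats::as.dist(distmat), method = "single")
  cl <- stats::cutree(hc, h = threshold)
  first <- !duplicated(cl)
  relabel <- stats::setNames(paste0("C", seq_len(sum(first))), cl[first])
  stats::setNames(unname(relabel[as.character(cl)]), strains)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining. Q-matrix ties are broken by the
#' smallest (i, j) index pair; negative branch lengths are clamped to
#' zero with the deficit moved to the sister branch. The result is the
#' usual unrooted tree with a basal trifurcation.
#'
#' @param distmat symmetric distance matrix (>= 3 strains).
#' @return an `ape` `phylo` tree.
#' @seealso [write_newick()]
#' @export
nj_tree <- function(distmat) {
  D <- as.matrix(distmat)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 strains")
  fmt <- function(x) sprintf("%.10g", x)
  node <- vapply(labels, newick_quote, character(1))
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # tie-break: smallest (i, j), i < j, row-major
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (Q[i, j] < qmin - 1e-12) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- paste0("(", node[i], ":", fmt(li), ",", node[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- paste0("(", node[1], ":", fmt(la), ",", node[2], ":", fmt(lb),
                ",", node[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

#' Type the MAT locus of an assembly
#'
#' Exact substring search for each idiomorph marker and its reverse
#' complement across the supplied sequences.
#'
#' @param genome_sequences character vector of DNA strings (e.g. scaffold
#'   or MAT-region sequences of one strain).
#' @param markers list with elements `mat1_1` and `mat1_2` (marker DNA).
#' @return one of `"MAT1-1"`, `"MAT1-2"` (exactly one marker found),
#'   `"unknown"` (neither), `"ambiguous"` (both).
#' @export
mat_type <- function(genome_sequences, markers) {
  stopifnot(all(c("mat1_1", "mat1_2") %in% names(markers)),
            nzchar(markers$mat1_1), nzchar(markers$mat1_2),
            markers$mat1_1 != markers$mat1_2)
  hit <- function(m) {
    any(vapply(genome_sequences, function(s) {
      grepl(m, s, fixed = TRUE) || grepl(revcomp(m), s, fixed = TRUE)
    }, logical(1)))
  }
  h1 <- hit(markers$mat1_1)
  h2 <- hit(markers$mat1_2)
  if (h1 && h2) "ambiguous" else if (h1) "MAT1-1" else if (h2) "MAT1-2" else "unknown"
}

#' MAT-by-clade linkage check
#'
#' In clonal clade structure every strain of a clade carries the same MAT
#' idiomorph. Reports, per clade, the set of observed MAT types (strains
#' typed `unknown` are ignored) and flags clades showing more than one.
#'
#' @param assignment a [clade_assignment()] with `mat` populated.
#' @return list with `per_clade` (data frame clade, n_strains, mat_types,
#'   consistent) and `all_consistent` (logical).
#' @export
mat_clade_ld <- function(assignment) {
  stopifnot(inherits(assignment, "clade_assignment"))
  clades <- unique(assignment$labels)
  rows <- lapply(clades, function(cl) {
    strains <- names(assignment$labels)[assignment$labels == cl]
    types <- setdiff(unique(assignment$mat[strains]), "unknown")
    data.frame(clade = cl, n_strains = length(strains),
               mat_types = paste(sort(types), collapse = ","),
               consistent = length(types) <= 1L,
               stringsAsFactors = FALSE)
  })
  per_clade <- do.call(rbind, rows)
  list(per_clade = per_clade, all_consistent = all(per_clade$consistent))
}
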