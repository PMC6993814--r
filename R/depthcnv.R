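# Depth-based copy-number estimation: per-gene mean depth, strain-level
# median normalization (normalized depth ~ gene copy number), integer
# calls, and intra-cladal CNV reporting.

#' Gene spans implied by a gene map and fixed gene length
#'
#' Lays genes out back-to-back along each chromosome, matching the
#' simulator's depth layout. Spans are 1-based, half-open `[start, end)`.
#'
#' @param gene_map a `gene_order_map`.
#' @param gene_length_bp gene length in bp.
#' @return data frame og_id, chromosome, start, end.
#' @export
make_gene_spans <- function(gene_map, gene_length_bp) {
  gene_length_bp <- as.integer(gene_length_bp)
  out <- lapply(unique(gene_map$chromosome), function(chr) {
    sub <- gene_map[gene_map$chromosome == chr, , drop = FALSE]
    start <- (sub$order_index - 1L) * gene_length_bp + 1L
    data.frame(og_id = sub$og_id, chromosome = chr,
               start = start, end = start + gene_length_bp,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean read depth per gene span
#'
#' Positions absent from the track count as depth 0 (the span length is
#' the denominator). Spans are half-open `[start, end)`, 1-based.
#'
#' @param depth_track a [depth_track()].
#' @param gene_spans data frame with og_id, chromosome, start, end.
#' @return data frame strain, og_id, mean_depth.
#' @export
gene_mean_depth <- function(depth_track, gene_spans) {
  stopifnot(inherits(depth_track, "depth_track"),
            all(c("og_id", "chromosome", "start", "end") %in% names(gene_spans)))
  recs <- split(depth_track$records, depth_track$records$chromosome)
  means <- numeric(nrow(gene_spans))
  for (chr in unique(gene_spans$chromosome)) {
    if (!chr %in% names(recs)) {
      stop("chromosome ", chr, " not present in depth track of ",
           depth_track$strain)
    }
    pos <- recs[[chr]]$position
    cs <- c(0, cumsum(recs[[chr]]$depth))
    idx <- which(gene_spans$chromosome == chr)
    lo <- findInterval(gene_spans$start[idx] - 1L, pos)
    hi <- findInterval(gene_spans$end[idx] - 1L, pos)
    means[idx] <- (cs[hi + 1L] - cs[lo + 1L]) /
      (gene_spans$end[idx] - gene_spans$start[idx])
  }
  data.frame(strain = depth_track$strain, og_id = gene_spans$og_id,
             mean_depth = means, stringsAsFactors = FALSE)
}

#' Normalize per-gene depths into copy-number calls
#'
#' The strain normalization constant is the median per-gene mean depth
#' (robust to the CNV genes themselves); the normalized depth is the
#' estimated copy number, rounded half-up to an integer call. A
#' zero-depth gene is called copy number 0 (deletion).
#'
#' @param gene_means data frame from [gene_mean_depth()] (one strain).
#' @param stat normalization statistic, `"median"` (default) or
#'   `"mode"` (most common rounded depth).
#' @return `gene_depth` data frame: strain, og_id, mean_depth,
#'   normalized, copy_number.
#' @export
normalize_depths <- function(gene_means, stat = c("median", "mode")) {
  stat <- match.arg(stat)
  stopifnot(all(c("strain", "og_id", "mean_depth") %in% names(gene_means)))
  if (length(unique(gene_means$strain)) != 1L) {
    stop("normalize_depths works on one strain at a time")
  }
  if (nrow(gene_means) < 10L) stop("need >= 10 genes to normalize")
  const <- switch(stat,
    median = stats::median(gene_means$mean_depth),
    mode = {
      r <- round(gene_means$mean_depth)
      as.numeric(names(sort(table(r), decreasing = TRUE))[1])
    })
  if (const == 0) stop("normalization constant is 0: no usable coverage for ",
                       gene_means$strain[1])
  out <- gene_means
  out$normalized <- out$mean_depth / const
  out$copy_number <- as.integer(round_half_up(out$normalized))
  class(out) <- c("gene_depth", "data.frame")
  out
}

#' Intra-cladal copy-number variation report
#'
#' Per (orthogroup, clade), lists the distinct integer copy numbers
#' observed among clade members and flags intra-cladal variability
#' (>= 2 distinct values). The summary counts orthogroups variable in at
#' least one clade and in two or more clades.
#'
#' @param gene_depths row-bound [normalize_depths()] output across
#'   strains.
#' @param assignment a [clade_assignment()] or named strain -> clade
#'   vector.
#' @return list with `rows` (og_id, clade, copy_numbers, n_distinct,
#'   intra_cladal_variable) and `summary` (n_og_variable_ge1,
#'   n_og_variable_ge2).
#' @export
cnv_by_clade <- function(gene_depths, assignment) {
  labels <- if (inherits(assignment, "clade_assignment")) assignment$labels else assignment
  gd <- gene_depths[gene_depths$strain %in% names(labels), , drop = FALSE]
  gd$clade <- unname(labels[gd$strain])
  agg <- stats::aggregate(copy_number ~ og_id + clade, data = gd,
                          FUN = function(x) sort(unique(x)), simplify = FALSE)
  rows <- data.frame(
    og_id = agg$og_id,
    clade = agg$clade,
    copy_numbers = vapply(agg$copy_number, paste, character(1), collapse = ","),
    n_distinct = vapply(agg$copy_number, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rows$intra_cladal_variable <- rows$n_distinct >= 2L
  per_og <- tapply(rows$intra_cladal_variable, rows$og_id, sum)
  list(rows = rows[order(rows$og_id, rows$clade), ],
       summary = list(n_og_variable_ge1 = sum(per_og >= 1L),
                      n_og_variable_ge2 = sum(per_og >= 2L)))
}
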