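# Codon-level mutation spectra: synonymous / non-synonymous / gap
# classification against clade consensus references, intra- and
# inter-cladal counting with distinct-variant semantics, odds ratios
# against a baseline species and Fisher exact tests.

#' Classify a codon change
#'
#' A `-` in either codon makes the change a gap; otherwise an `N` makes
#' it ambiguous; otherwise the standard genetic code decides: same amino
#' acid (stop counted equal to stop) is synonymous, different is
#' non-synonymous. Changes between a sense codon and a stop are
#' non-synonymous. Multi-position differences are classified by the
#' amino-acid comparison alone.
#'
#' @param ref_codon,alt_codon 3-character strings over `{A,C,G,T,N,-}`.
#' @return one of `"syn"`, `"nonsyn"`, `"gap"`, `"ambiguous"`.
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  if (nchar(ref_codon) != 3L || nchar(alt_codon) != 3L) {
    stop("codons must have length 3 (got '", ref_codon, "', '", alt_codon, "')")
  }
  both <- paste0(ref_codon, alt_codon)
  if (grepl("-", both, fixed = TRUE)) return("gap")
  if (grepl("N", both, fixed = TRUE)) return("ambiguous")
  gc <- .genetic_code()
  a1 <- gc[[ref_codon]]
  a2 <- gc[[alt_codon]]
  if (is.null(a1) || is.null(a2)) stop("invalid codon: ", ref_codon, " / ", alt_codon)
  if (a1 == a2) "syn" else "nonsyn"
}

# Compare one sequence to a reference, both as codon vectors. Returns the
# change rows: substitutions one per codon, gap changes merged into
# maximal runs of consecutive differing gap codons (one event per run).
codon_changes <- function(ref_codons, alt_codons, og_id) {
  diff_idx <- which(ref_codons != alt_codons)
  if (length(diff_idx) == 0L) return(NULL)
  kind <- vapply(diff_idx, function(i) {
    classify_codon_change(ref_codons[i], alt_codons[i])
  }, character(1))
  rows <- list()
  gapped <- diff_idx[kind == "gap"]
  if (length(gapped) > 0L) {
    run_id <- cumsum(c(1L, diff(gapped) != 1L))
    for (rid in unique(run_id)) {
      idx <- gapped[run_id == rid]
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og_id, codon_index = idx[1], run_length = length(idx),
        ref_codon = paste(ref_codons[idx], collapse = ""),
        alt_codon = paste(alt_codons[idx], collapse = ""),
        kind = "gap", stringsAsFactors = FALSE)
    }
  }
  sub_idx <- diff_idx[kind != "gap"]
  if (length(sub_idx) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      og_id = og_id, codon_index = sub_idx, run_length = 1L,
      ref_codon = ref_codons[sub_idx], alt_codon = alt_codons[sub_idx],
      kind = kind[kind != "gap"], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Count changes of a set of member sequences against a reference.
count_against_reference <- function(aset, members, refs, scope,
                                    distinct = TRUE) {
  changes <- list()
  for (og in names(aset$alignments)) {
    a <- aset$alignments[[og]]
    if (a$length %% 3L != 0L) {
      stop("orthogroup ", og, " alignment length (", a$length,
           ") is not divisible by 3")
    }
    ref_codons <- split_codons(refs[[og]])
    for (s in members) {
      ch <- codon_changes(ref_codons, split_codons(a$sequences[[s]]), og)
      if (!is.null(ch)) {
        ch$strain <- s
        changes[[length(changes) + 1L]] <- ch
      }
    }
  }
  changes <- do.call(rbind, changes)
  build_mutation_table(changes, scope, distinct)
}

build_mutation_table <- function(changes, scope, distinct = TRUE) {
  if (is.null(changes) || nrow(changes) == 0L) {
    return(mutation_table(scope, 0L, 0L, 0L,
                          genes_with_syn = 0L, genes_with_nonsyn = 0L,
                          genes_with_gap = 0L, ambiguous = 0L,
                          changes = changes))
  }
  counted <- if (distinct) {
    key <- paste(changes$og_id, changes$codon_index, changes$alt_codon, changes$kind)
    changes[!duplicated(key), , drop = FALSE]
  } else {
    changes
  }
  n_of <- function(k) sum(counted$kind == k)
  genes_of <- function(k) length(unique(counted$og_id[counted$kind == k]))
  mutation_table(scope,
                 syn = n_of("syn"), nonsyn = n_of("nonsyn"), gap = n_of("gap"),
                 genes_with_syn = genes_of("syn"),
                 genes_with_nonsyn = genes_of("nonsyn"),
                 genes_with_gap = genes_of("gap"),
                 ambiguous = n_of("ambiguous"),
                 changes = counted)
}

#' Construct a mutation count table
#'
#' @param scope one of `intra_clade`, `inter_clade`, `baseline_species`.
#' @param syn,nonsyn,gap event counts.
#' @param genes_with_syn,genes_with_nonsyn,genes_with_gap number of genes
#'   with >= 1 event of each kind.
#' @param ambiguous count of N-containing changes (excluded from the
#'   three main classes).
#' @param changes optional data frame of the underlying codon changes.
#' @return a `mutation_table` object.
#' @export
mutation_table <- function(scope, syn, nonsyn, gap,
                           genes_with_syn = NA_integer_,
                           genes_with_nonsyn = NA_integer_,
                           genes_with_gap = NA_integer_,
                           ambiguous = 0L, changes = NULL) {
  stopifnot(syn >= 0, nonsyn >= 0, gap >= 0)
  structure(list(scope = scope, syn = as.integer(syn),
                 nonsyn = as.integer(nonsyn), gap = as.integer(gap),
                 genes_with_syn = as.integer(genes_with_syn),
                 genes_with_nonsyn = as.integer(genes_with_nonsyn),
                 genes_with_gap = as.integer(genes_with_gap),
                 ambiguous = as.integer(ambiguous),
                 changes = changes),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("mutation_table [%s]: syn %d (in %d genes), nonsyn %d (in %d), gap %d (in %d)\n",
              x$scope, x$syn, x$genes_with_syn, x$nonsyn, x$genes_with_nonsyn,
              x$gap, x$genes_with_gap))
  invisible(x)
}

#' Count intra-cladal mutations
#'
#' Each clade member is compared codon-by-codon to the clade consensus
#' reference ([clade_reference()]). By default, identical alternate
#' codons seen in several members at the same site count once
#' (distinct-variant counting, invariant to clade size); a maximal run of
#' consecutive gap codons in one member counts as one gap mutation.
#'
#' @param aset an [alignment_set()].
#' @param assignment a [clade_assignment()] or named label vector.
#' @param clade clade label with >= 2 members.
#' @param distinct count distinct variants (default) or every
#'   per-strain occurrence (`FALSE`).
#' @return a `mutation_table` with scope `intra_clade`; the underlying
#'   changes are in `$changes`.
#' @export
count_intra <- function(aset, assignment, clade, distinct = TRUE) {
  labels <- if (inherits(assignment, "clade_assignment")) assignment$labels else assignment
  members <- names(labels)[labels == clade]
  if (length(members) < 2L) stop("clade ", clade, " needs >= 2 members")
  refs <- clade_reference(aset, labels, clade)
  count_against_reference(aset, members, refs, "intra_clade", distinct)
}

#' Count inter-cladal mutations
#'
#' For every unordered pair of clades, the two consensus references are
#' compared codon-by-codon and classified; counts are summed over pairs.
#' Gap runs count once per pair per run.
#'
#' @param aset an [alignment_set()].
#' @param assignment a [clade_assignment()] or named label vector.
#' @param clades clade labels to include (default: all with >= 1 member).
#' @return a `mutation_table` with scope `inter_clade`.
#' @export
count_inter <- function(aset, assignment, clades = NULL) {
  labels <- if (inherits(assignment, "clade_assignment")) assignment$labels else assignment
  clades <- clades %||% unique(labels)
  if (length(clades) < 2L) stop("need >= 2 clades")
  refs <- clade_references(aset, labels, clades)
  changes <- list()
  prs <- utils::combn(clades, 2L)
  for (og in names(aset$alignments)) {
    if (aset$alignments[[og]]$length %% 3L != 0L) {
      stop("orthogroup ", og, " alignment length is not divisible by 3")
    }
    codons <- lapply(clades, function(cl) split_codons(refs[[cl]][[og]]))
    names(codons) <- clades
    for (p in seq_len(ncol(prs))) {
      ch <- codon_changes(codons[[prs[1, p]]], codons[[prs[2, p]]], og)
      if (!is.null(ch)) {
        ch$strain <- paste(prs[1, p], prs[2, p], sep = "|")
        changes[[length(changes) + 1L]] <- ch
      }
    }
  }
  build_mutation_table(do.call(rbind, changes), "inter_clade", distinct = FALSE)
}

#' Count baseline-species mutations
#'
#' Identical procedure to [count_intra()] with the whole baseline species
#' treated as one group (species consensus as the reference).
#'
#' @param aset an [alignment_set()].
#' @param species_strains character vector of >= 2 strain IDs.
#' @param distinct distinct-variant counting (default `TRUE`).
#' @return a `mutation_table` with scope `baseline_species`.
#' @export
count_baseline <- function(aset, species_strains, distinct = TRUE) {
  if (length(species_strains) < 2L) stop("need >= 2 baseline strains")
  labels <- stats::setNames(rep("baseline", length(species_strains)), species_strains)
  refs <- clade_reference(aset, labels, "baseline")
  count_against_reference(aset, species_strains, refs, "baseline_species", distinct)
}

#' Mutation-class odds against a baseline
#'
#' `odds_nonsyn = (group nonsyn/syn) / (baseline nonsyn/syn)`, and
#' analogously for gap mutations; two-sided p-values come from
#' [fisher_exact()] on the corresponding 2x2 tables. An elevated
#' non-synonymous or gap odds relative to the baseline species is the
#' signature of relaxed/directional selection under domestication.
#'
#' @param group,baseline `mutation_table` objects (or lists with `syn`,
#'   `nonsyn`, `gap`).
#' @param continuity add 0.5 to all cells of the odds ratios (not the
#'   p-values) when a zero count would otherwise make them undefined.
#' @return an `odds_result` list: `odds_nonsyn`, `odds_gap`, `p_nonsyn`,
#'   `p_gap`, and the two scopes.
#' @export
odds_vs_baseline <- function(group, baseline, continuity = FALSE) {
  g <- group; b <- baseline
  if (!continuity && (g$syn == 0 || b$syn == 0)) {
    stop("zero synonymous count; re-run with continuity = TRUE ",
         "to apply a +0.5 continuity correction")
  }
  cc <- if (continuity) 0.5 else 0
  odds <- function(x, y) {
    ((g[[x]] + cc) / (g[[y]] + cc)) / ((b[[x]] + cc) / (b[[y]] + cc))
  }
  structure(list(
    numerator_scope = g$scope %||% "group",
    baseline_scope = b$scope %||% "baseline",
    odds_nonsyn = odds("nonsyn", "syn"),
    odds_gap = odds("gap", "syn"),
    p_nonsyn = fisher_exact(g$nonsyn, g$syn, b$nonsyn, b$syn),
    p_gap = fisher_exact(g$gap, g$syn, b$gap, b$syn)
  ), class = "odds_result")
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("odds_result (%s vs %s): nonsyn/syn odds %.3g (p = %.3g), gap/syn odds %.3g (p = %.3g)\n",
              x$numerator_scope, x$baseline_scope,
              x$odds_nonsyn, x$p_nonsyn, x$odds_gap, x$p_gap))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric computation over all tables with the observed
#' margins, summed in log space; the two-sided p-value is the total
#' probability of tables no more probable than the observed one (with the
#' customary `1 + 1e-7` relative fudge on the comparison). Tables whose
#' margin support exceeds 2e7 states fall back to a normal approximation,
#' flagged in the `method` attribute.
#'
#' @param a,b,c,d non-negative integer cell counts, by row:
#'   `[[a, b], [c, d]]`.
#' @return the two-sided p-value, with attribute `method` (`"exact"` or
#'   `"normal"`).
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  total <- sum(cells)
  if (total == 0) stop("empty table")
  m <- a + b  # row 1 margin (white balls)
  n <- c + d  # row 2 margin (black balls)
  k <- a + c  # column 1 margin (draws)
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (hi - lo + 1 > 2e7) {
    # normal approximation to the hypergeometric tail
    mu <- k * m / total
    sig <- sqrt(k * (m / total) * (n / total) * ((total - k) / (total - 1)))
    z <- abs(a - mu) / sig
    p <- min(1, 2 * stats::pnorm(-z))
    attr(p, "method") <- "normal"
    return(p)
  }
  x <- lo:hi
  logp <- stats::dhyper(x, m, n, k, log = TRUE)
  lobs <- stats::dhyper(a, m, n, k, log = TRUE)
  p <- min(1, sum(exp(logp[logp <= lobs + log(1 + 1e-7)])))
  attr(p, "method") <- "exact"
  p
}
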