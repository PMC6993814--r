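# Readers and writers for the external formats the pipeline touches:
# FASTA sequence files, the gene-order map, samtools-depth tables and
# Newick trees, plus the light containers shared by all analysis stages.

#' Read a FASTA file into a named character vector
#'
#' IDs are the first whitespace-delimited token of each header line.
#' Sequences are uppercased and `U` is mapped to `T`; any character outside
#' `{A,C,G,T,N,-}` is an error, as are duplicate IDs and empty files.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one DNA string per record.
#' @seealso [write_fasta()], [read_alignment_set()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA ID(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    check_alphabet(seqs[[i]], where = paste0(path, " record '", ids[[i]], "'"))
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector of DNA strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a single-orthogroup alignment
#'
#' @param og_id orthogroup identifier.
#' @param sequences named character vector of equal-length aligned DNA
#'   strings (gaps as `-`), one per strain.
#' @return a `gene_alignment` object.
#' @export
gene_alignment <- function(og_id, sequences) {
  stopifnot(is.character(og_id), length(og_id) == 1L, nzchar(og_id))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- names(sequences)[lens != stats::median(lens)]
    stop("alignment ", og_id, ": unequal sequence lengths (", paste(bad, collapse = ", "), ")")
  }
  if (lens[[1]] < 1L) stop("alignment ", og_id, ": zero-length alignment")
  structure(list(og_id = og_id, sequences = sequences, length = unname(lens[[1]])),
            class = "gene_alignment")
}

#' Construct an alignment set (one alignment per single-copy orthogroup)
#'
#' Every alignment must contain exactly the same strain set — the
#' single-copy constraint.
#'
#' @param alignments list of [gene_alignment()] objects.
#' @return an `alignment_set` object with elements `alignments` (named by
#'   og_id) and `strains` (sorted common strain set).
#' @export
alignment_set <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  ids <- vapply(alignments, function(a) a$og_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate og_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  names(alignments) <- ids
  sets <- lapply(alignments, function(a) sort(names(a$sequences)))
  ref <- sort(unique(unlist(sets)))
  bad <- ids[!vapply(sets, identical, logical(1), y = ref)]
  if (length(bad) > 0L) {
    stop("not single-copy: strain sets differ from the common set in: ",
         paste(bad, collapse = ", "))
  }
  structure(list(alignments = alignments, strains = ref), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", length(x$alignments), "orthogroups x",
      length(x$strains), "strains\n")
  invisible(x)
}

#' Read a directory of per-orthogroup aligned FASTA files
#'
#' One file per orthogroup; the filename (without extension) is the og_id.
#' Strains present in every file form the common set; a file whose strain
#' set differs is rejected with a listing.
#'
#' @param directory path containing `.fasta`/`.fa` files.
#' @return an [alignment_set()].
#' @export
read_alignment_set <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files in ", directory)
  alns <- lapply(files, function(f) {
    seqs <- read_fasta(f)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      off <- names(seqs)[lens != max(lens)]
      stop("unequal sequence lengths in ", f, " (IDs: ", paste(off, collapse = ", "), ")")
    }
    gene_alignment(sub("\\.(fa|fasta|fna)$", "", basename(f)), seqs)
  })
  tryCatch(alignment_set(alns), error = function(e) {
    stop("in ", directory, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Read a gene-order map
#'
#' TSV with header columns `og_id`, `chromosome`, `order_index`, anchoring
#' orthogroups to a reference chromosome layout. Order indices must be
#' 1-based and consecutive within each chromosome.
#'
#' @param path path to the TSV.
#' @return a `gene_order_map` data frame sorted by chromosome then index.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("og_id", "chromosome", "order_index")
  if (!all(need %in% names(df))) {
    stop(path, ": gene map must have header columns ", paste(need, collapse = ", "))
  }
  gene_order_map(df[need])
}

#' Validate a gene-order map data frame
#'
#' @param df data frame with columns `og_id`, `chromosome`, `order_index`.
#' @return the validated map with class `gene_order_map`.
#' @export
gene_order_map <- function(df) {
  df$order_index <- as.integer(df$order_index)
  df$chromosome <- as.character(df$chromosome)
  key <- paste(df$chromosome, df$order_index)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, order_index): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (anyDuplicated(df$og_id)) {
    stop("duplicate og_id in gene map: ", paste(df$og_id[duplicated(df$og_id)], collapse = ", "))
  }
  df <- df[order(df$chromosome, df$order_index), , drop = FALSE]
  for (chr in unique(df$chromosome)) {
    idx <- df$order_index[df$chromosome == chr]
    expect <- seq_along(idx)
    if (!identical(as.integer(idx), as.integer(expect))) {
      gap <- setdiff(expect, idx)[1] %||% idx[which(idx != expect)[1]]
      stop("chromosome ", chr, ": order indices not consecutive from 1 (gap at ", gap, ")")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("gene_order_map", "data.frame")
  df
}

#' Read a samtools-depth style table
#'
#' Three tab-separated columns without a header: chromosome, 1-based
#' position, depth. Positions must be strictly increasing within a
#' chromosome and depths non-negative.
#'
#' @param path path to the depth TSV.
#' @param strain strain ID the track belongs to.
#' @return a `depth_track` object with elements `strain` and `records`.
#' @export
read_depth_table <- function(path, strain) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chromosome", "position", "depth"))
  depth_track(strain, df)
}

#' Construct a depth track
#'
#' @param strain strain ID.
#' @param records data frame with columns `chromosome`, `position`, `depth`.
#' @return a `depth_track` object.
#' @export
depth_track <- function(strain, records) {
  stopifnot(all(c("chromosome", "position", "depth") %in% names(records)))
  records$position <- as.integer(records$position)
  records$depth <- as.numeric(records$depth)
  if (any(records$depth < 0)) {
    i <- which(records$depth < 0)[1]
    stop("negative depth at ", records$chromosome[i], ":", records$position[i])
  }
  for (chr in unique(records$chromosome)) {
    pos <- records$position[records$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      i <- which(diff(pos) <= 0)[1]
      stop("positions not strictly increasing on ", chr, " near position ", pos[i + 1])
    }
  }
  structure(list(strain = strain, records = records), class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("depth_track for", x$strain, "-", nrow(x$records), "positions on",
      length(unique(x$records$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Construct a clade assignment
#'
#' @param labels named character vector, strain -> clade label.
#' @param mat optional named character vector, strain -> one of
#'   `MAT1-1`, `MAT1-2`, `unknown`, `ambiguous`; defaults to `unknown`.
#' @return a `clade_assignment` object.
#' @export
clade_assignment <- function(labels, mat = NULL) {
  stopifnot(is.character(labels), !is.null(names(labels)))
  if (is.null(mat)) {
    mat <- stats::setNames(rep("unknown", length(labels)), names(labels))
  }
  if (!all(names(labels) %in% names(mat))) {
    stop("MAT value missing for: ",
         paste(setdiff(names(labels), names(mat)), collapse = ", "))
  }
  ok <- c("MAT1-1", "MAT1-2", "unknown", "ambiguous")
  if (!all(mat %in% ok)) {
    stop("invalid MAT value(s): ", paste(unique(mat[!mat %in% ok]), collapse = ", "))
  }
  structure(list(labels = labels, mat = mat[names(labels)]), class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat("clade_assignment:", length(x$labels), "strains in", length(tab), "clades\n")
  print(tab)
  invisible(x)
}

# -- Newick ------------------------------------------------------------------

newick_quote <- function(label) {
  if (grepl("[][(),:;'\"= \t{}]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' Serialize a phylogenetic tree to Newick text
#'
#' Writes an [ape::read.tree()]-compatible Newick string with branch
#' lengths at >= 6 significant digits. Labels containing Newick
#' metacharacters (spaces, parentheses, quotes, ...) are single-quoted per
#' the standard, which `ape::write.tree()` does not do.
#'
#' @param tree an `ape` `phylo` object.
#' @param path optional file to write to.
#' @param digits significant digits for branch lengths (default 10).
#' @return the Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    if (node <= ntip) return(newick_quote(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      s <- rec(child)
      if (!is.null(tree$edge.length)) s <- paste0(s, ":", fmt(tree$edge.length[r]))
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  out <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
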