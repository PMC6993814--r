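# Internal helpers shared across modules.

DNA_SYMBOLS <- c("A", "C", "G", "T", "N", "-")

# Majority-vote tie-break order for consensus building.
CONSENSUS_ORDER <- c("A", "C", "G", "T", "N", "-")

STOP_CODONS <- c("TAA", "TAG", "TGA")

.genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  gc <- .genetic_code()
  aa <- unname(gc[codon])
  if (anyNA(aa)) stop("not a valid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T (N and gap map to themselves) and reverses. Used by
#' [mat_type()] to search both strands for a marker.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N,-}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

round_half_up <- function(x) floor(x + 0.5)

# Split a DNA string into its codons. Length must be divisible by 3.
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_alphabet <- function(seq, where = "sequence") {
  bad <- setdiff(unique(seq_chars(seq)), DNA_SYMBOLS)
  if (length(bad) > 0L) {
    stop(where, " contains characters outside {A,C,G,T,N,-}: ",
         paste(bad, collapse = " "))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
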