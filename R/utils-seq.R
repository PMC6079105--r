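# Low-level nucleotide-string helpers shared across modules. Sequences are
# plain uppercase ACGT character vectors; Biostrings does the heavy lifting.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' @noRd
assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf(
      "%s contains characters outside A/C/G/T (degenerate bases are rejected): %s",
      what, paste(utils::head(x[bad], 3), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_frame <- function(x, what = "sequence") {
  bad <- nchar(x) %% 3L != 0L
  if (any(bad)) {
    stop(sprintf("%s length is not a multiple of 3 (record: %s)",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Split an in-frame CDS into codons
#' @noRd
codons <- function(cds) {
  if (nchar(cds) == 0L) return(character(0))
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

#' TRUE if the frame-0 translation hits a stop before the final codon
#' @noRd
has_internal_stop <- function(cds) {
  cod <- codons(cds)
  if (length(cod) <= 1L) return(FALSE)
  any(cod[-length(cod)] %in% STOP_CODONS)
}

#' Translate an in-frame CDS to amino acids (stops as *)
#' @noRd
translate_cds <- function(cds) {
  if (nchar(cds) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

#' Find occurrences of a motif on either strand of a sequence
#'
#' @return Tibble with columns `start`, `end` (1-based, top-strand
#'   coordinates of the occupied bases) and `strand` ("+" or "-").
#' @noRd
motif_hits <- function(seq, motif) {
  hit_one <- function(pat, strand) {
    if (nchar(seq) < nchar(pat)) return(NULL)
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    tibble::tibble(start = as.integer(m),
                   end = as.integer(m) + nchar(pat) - 1L,
                   strand = strand)
  }
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0))
  fwd <- hit_one(motif, "+")
  rc <- revcomp(motif)
  rev <- if (identical(rc, motif)) NULL else hit_one(rc, "-")
  out <- dplyr::bind_rows(empty, fwd, rev)
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Count motif occurrences (both strands) across a set of motifs
#' @noRd
n_motif_hits <- function(seq, motifs) {
  sum(vapply(motifs, function(m) nrow(motif_hits(seq, m)), integer(1)))
}

#' Random codon-valid DNA of a given nucleotide length
#'
#' Draws codon-by-codon from the 61 sense codons, rejection-sampling until the
#' sequence is free of every motif in `avoid` (either strand). Uses the
#' session RNG; callers seed.
#' @noRd
random_cds <- function(len_nt, avoid = character(0)) {
  stopifnot(len_nt %% 3L == 0L)
  if (len_nt == 0L) return("")
  sense <- setdiff(all_codons(), STOP_CODONS)
  for (i in 1:200) {
    s <- paste(sample(sense, len_nt %/% 3L, replace = TRUE), collapse = "")
    if (length(avoid) == 0L || n_motif_hits(s, avoid) == 0L) return(s)
  }
  stop("could not generate a motif-free codon-valid sequence; constraints too tight",
       call. = FALSE)
}

#' @noRd
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

#' Random unconstrained DNA (promoter/operator space, not codon-valid)
#' @noRd
random_dna <- function(len, avoid = character(0)) {
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (length(avoid) == 0L || n_motif_hits(s, avoid) == 0L) return(s)
  }
  stop("could not generate a motif-free sequence", call. = FALSE)
}

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Replace a substring by position (1-based, inclusive)
#' @noRd
str_sub_replace <- function(x, start, end, value) {
  paste0(substr(x, 1L, start - 1L), value, substr(x, end + 1L, nchar(x)))
}
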