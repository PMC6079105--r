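#' Type IIS enzyme definitions used by the assembly workflow
#'
#' Recognition motifs and cut offsets for the enzymes that trim the
#' amplification adapters off staple oligonucleotides. Offsets follow the
#' usual N(a/b) notation: the strand carrying the motif is cut `cut_top`
#' nucleotides 3' of the motif, its complement `cut_bottom` nucleotides.
#'
#' @return Tibble with columns `enzyme`, `motif`, `cut_top`, `cut_bottom`.
#' @examples
#' type_iis_enzymes()
#' @export
type_iis_enzymes <- function() {
  tibble::tibble(
    enzyme     = c("BsmFI", "BspQI"),
    motif      = c("GGGAC", "GCTCTTC"),
    cut_top    = c(10L, 1L),
    cut_bottom = c(14L, 4L)
  )
}

#' @noRd
synonym_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

#' Remove restriction sites from a CDS by silent mutation
#'
#' Scans the coding sequence (both strands) for each recognition motif and
#' removes every occurrence by synonymous codon substitution, so the protein
#' is untouched while the DNA becomes compatible with downstream Type IIS
#' processing. For each site, the smallest number of codon substitutions that
#' removes it without creating a new site is used; ties are broken by the
#' lexicographically smallest resulting sequence, so the operation is
#' deterministic.
#'
#' @param cds In-frame coding sequence (uppercase ACGT, length divisible
#'   by 3).
#' @param enzymes Character vector of recognition motifs to eliminate
#'   (scanned on both strands). Defaults to the motifs in
#'   [type_iis_enzymes()].
#' @return The scrubbed CDS. Translates identically to the input and contains
#'   no occurrence of any motif on either strand.
#' @section Errors:
#' If a site cannot be silently removed (e.g. it sits on codons with no
#' synonymous alternative), an error reports its 1-based position.
#' @examples
#' scrub_restriction_sites("CTGGGACTG")   # BsmFI site across two Leu codons
#' @export
scrub_restriction_sites <- function(cds, enzymes = type_iis_enzymes()$motif) {
  assert_acgt(cds, "cds")
  assert_frame(cds, "cds")
  syn <- synonym_table()
  aa_of <- Biostrings::GENETIC_CODE

  all_hits <- function(s) {
    dplyr::bind_rows(lapply(enzymes, function(m) motif_hits(s, m)))
  }

  guard <- 0L
  repeat {
    hits <- all_hits(cds)
    if (nrow(hits) == 0L) return(cds)
    guard <- guard + 1L
    if (guard > 500L) stop("scrub did not converge", call. = FALSE)
    hits <- dplyr::arrange(hits, .data$start, .data$end)
    h <- hits[1, ]
    n_before <- nrow(hits)

    cod <- codons(cds)
    first_codon <- (h$start - 1L) %/% 3L + 1L
    last_codon <- (h$end - 1L) %/% 3L + 1L
    idx <- first_codon:last_codon
    syn_choices <- lapply(idx, function(i) syn[[aa_of[[cod[i]]]]])

    best <- NULL
    for (k in seq_along(idx)) {
      subsets <- utils::combn(seq_along(idx), k, simplify = FALSE)
      for (sub in subsets) {
        grids <- expand.grid(syn_choices[sub], stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grids))) {
          new_cod <- cod
          new_cod[idx[sub]] <- as.character(grids[r, ])
          if (all(new_cod[idx[sub]] == cod[idx[sub]])) next
          if (sum(new_cod[idx] != cod[idx]) != k) next
          cand <- paste(new_cod, collapse = "")
          cand_hits <- all_hits(cand)
          removed <- !any(cand_hits$start == h$start & cand_hits$end == h$end &
                            cand_hits$strand == h$strand)
          if (removed && nrow(cand_hits) < n_before) {
            if (is.null(best) || cand < best) best <- cand
          }
        }
      }
      if (!is.null(best)) break
    }
    if (is.null(best)) {
      stop(sprintf(
        "restriction site at position %d cannot be removed by synonymous substitution",
        h$start), call. = FALSE)
    }
    cds <- best
  }
}
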