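#' Simulate cycle-wise LCR assembly of fragments and staples
#'
#' Models the ligase-chain-reaction thermal program as discrete cycles. Each
#' cycle melts every duplex into single strands, lets strands anneal to any
#' exact reverse-complement partner over at least `min_anneal` bases, and
#' seals abutting 5'-phosphate/3'-OH nicks held together by a splint. A
#' strand ligated in one cycle persists and can serve as the splint (or the
#' growing product) of later cycles — which is how a strand assembled in one
#' cycle templates the assembly of its complement in the next.
#'
#' The simulation is species-level and deterministic: every oligo species is
#' treated as present in excess, so the product set is monotone
#' non-decreasing in the cycle count.
#'
#' @param fragments Character vector of the dsDNA fragments' coding-strand
#'   sequences, left to right (both strands of each enter the pool).
#' @param staples Tibble with columns `sequence` and `phosphorylated_5p`
#'   (e.g. the `staples` element of a [design_staples()] result), or a
#'   `junction_design`.
#' @param cycles Number of melt/anneal/ligate cycles (>= 1).
#' @param min_anneal Minimum stable exact-complement overlap (nt); shorter
#'   strands anneal over their full length when nick-flanked.
#' @param max_species Safety cap on the strand-species pool.
#' @return Tibble of full-length products, one row per distinct duplex:
#'   `product` (coding-strand sequence), `length_nt`, `n_pieces`. A product
#'   is full-length when its ligated strand runs from the first fragment's
#'   terminus to the last fragment's terminus (either orientation;
#'   canonicalized to the coding strand). Zero rows mean the design cannot
#'   reconstruct a complete molecule.
#' @examples
#' jd <- design_staples("ATGGCTGCTGGTGCTGCTGGTCATCACGGT",
#'                      "GCTCCGGCTGGTTCTACCGCTCCGGCTTAA", "GGTTCTGGC")
#' simulate_assembly(c(jd$left_fragment, jd$right_fragment), jd, cycles = 4)
#' @export
simulate_assembly <- function(fragments, staples, cycles = 6L,
                              min_anneal = 10L, max_species = 5000L) {
  stopifnot(length(fragments) >= 1L, cycles >= 1L)
  if (inherits(staples, "junction_design")) staples <- staples$staples
  assert_acgt(fragments, "fragment")

  nf <- length(fragments)
  seqs <- character(0); phos <- logical(0); first <- character(0)
  last <- character(0)
  add <- function(s, p, id) {
    seqs <<- c(seqs, s); phos <<- c(phos, p)
    first <<- c(first, id); last <<- c(last, id)
  }
  for (i in seq_len(nf)) {
    add(fragments[i], TRUE, sprintf("F%d_top", i))
    add(revcomp(fragments[i]), TRUE, sprintf("F%d_bottom", i))
  }
  if (nrow(staples) > 0) {
    for (i in seq_len(nrow(staples))) {
      add(staples$sequence[i], isTRUE(staples$phosphorylated_5p[i]),
          sprintf("S%d", i))
    }
  }
  # species table: sequence, 5'-phos of the leading piece, first/last piece id
  pool <- tibble::tibble(seq = seqs, phos = phos, first = first, last = last)
  pool <- dplyr::distinct(pool)

  suffix_key <- function(s) substr(s, pmax(1L, nchar(s) - min_anneal + 1L), nchar(s))
  prefix_key <- function(s) substr(s, 1L, pmin(nchar(s), min_anneal))

  for (cycle in seq_len(cycles)) {
    rc_all <- paste(revcomp(pool$seq), collapse = "|")
    a_keys <- suffix_key(pool$seq)
    b_ok <- pool$phos
    b_keys <- prefix_key(pool$seq)
    combos <- tidyr::expand_grid(ak = unique(a_keys),
                                 bk = unique(b_keys[b_ok]))
    combos$joinable <- vapply(seq_len(nrow(combos)), function(i) {
      grepl(paste0(combos$ak[i], combos$bk[i]), rc_all, fixed = TRUE)
    }, logical(1))
    combos <- combos[combos$joinable, , drop = FALSE]
    if (nrow(combos) == 0L) break

    new <- list()
    for (i in seq_len(nrow(combos))) {
      ai <- which(a_keys == combos$ak[i])
      bi <- which(b_keys == combos$bk[i] & b_ok)
      for (a in ai) for (b in bi) {
        new[[length(new) + 1L]] <- tibble::tibble(
          seq = paste0(pool$seq[a], pool$seq[b]),
          phos = pool$phos[a], first = pool$first[a], last = pool$last[b]
        )
      }
    }
    pool2 <- dplyr::distinct(dplyr::bind_rows(pool, dplyr::bind_rows(new)))
    if (nrow(pool2) > max_species)
      stop("assembly simulation exceeded the species cap; inputs too promiscuous",
           call. = FALSE)
    if (nrow(pool2) == nrow(pool)) { pool <- pool2; break }
    pool <- pool2
  }

  top <- pool$first == "F1_top" & pool$last == sprintf("F%d_top", nf)
  bottom <- pool$first == sprintf("F%d_bottom", nf) & pool$last == "F1_bottom"
  products <- unique(c(pool$seq[top], revcomp(pool$seq[bottom])))
  tibble::tibble(product = products,
                 length_nt = nchar(products)) |>
    dplyr::arrange(.data$product)
}

#' Verify a junction design by in silico assembly
#'
#' Runs [simulate_assembly()] on a design's fragments and staples and checks
#' that exactly one full-length product forms and that its coding strand is
#' the intended left + insert + right concatenation.
#'
#' @param design A `junction_design`.
#' @param cycles Assembly cycles.
#' @return Logical scalar; attribute `"products"` holds the product table.
#' @export
verify_junction_design <- function(design, cycles = 6L) {
  stopifnot(inherits(design, "junction_design"))
  prod <- simulate_assembly(c(design$left_fragment, design$right_fragment),
                            design$staples, cycles = cycles,
                            min_anneal = design$params$min_anneal)
  intended <- paste0(design$left_fragment, design$insert_sequence,
                     design$right_fragment)
  ok <- nrow(prod) == 1L && prod$product[1] == intended
  attr(ok, "products") <- prod
  ok
}
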