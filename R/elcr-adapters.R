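# Amplification adapters and the Type IIS / streptavidin / USER processing
# chain that converts a dsDNA amplicon back into the ssDNA staple payload.

#' Default amplification adapter set for a staple pool
#'
#' Supra and Infra pools carry orthogonal adapter pairs. The 5' adapter is
#' synthesized with a 5'-biotin and a uracil in place of its 3'-terminal
#' thymidine (marks carried as metadata, not sequence characters); the 3'
#' adapter carries the pool's Type IIS recognition site (BsmFI for Supra,
#' BspQI for Infra) on the template strand, spaced so the enzyme's
#' coding-strand cut falls exactly on the payload/adapter boundary.
#'
#' @param role `"supra"` or `"infra"`.
#' @return List with `role`, `enzyme`, `a5` (5' adapter, uracil at its last
#'   position), `a3` (3' adapter).
#' @export
default_adapter_set <- function(role = c("supra", "infra")) {
  role <- match.arg(role)
  enz <- type_iis_enzymes()
  if (role == "supra") {
    e <- enz[enz$enzyme == "BsmFI", ]
    # spacer of cut_bottom nt puts the coding-strand cut at the boundary
    a3 <- paste0(strrep("AT", 7), revcomp(e$motif), "ATGACGTCAGGT")
    a5 <- "CAGCCTACGACCAGTTAGTT"
  } else {
    e <- enz[enz$enzyme == "BspQI", ]
    a3 <- paste0("ATCA", revcomp(e$motif), "TGACCTGCAGGA")
    a5 <- "GATTACCGAGTGCAACGTT"
  }
  list(role = role, enzyme = e$enzyme, a5 = a5, a3 = a3)
}

#' Build the dsDNA amplicon of one staple oligo
#'
#' Mimics PCR amplification of a microarray-synthesized oligo with its
#' adapter pair: the amplicon's coding strand is 5'adapter + payload +
#' 3'adapter, with biotin on the coding strand's 5' end and the uracil mark
#' at the 5' adapter's final position.
#'
#' @param payload The staple sequence ordered on the array (must be free of
#'   the pool's Type IIS motif).
#' @param role `"supra"` or `"infra"` (selects the adapter set).
#' @param adapters Adapter set; defaults to [default_adapter_set()].
#' @return A `staple_amplicon`: list with `top` (coding strand), `biotin`
#'   (`"top5"`), `uracil_pos` (coding-strand index), `enzyme`, `payload`.
#' @export
build_staple_amplicon <- function(payload, role = c("supra", "infra"),
                                  adapters = default_adapter_set(role)) {
  role <- match.arg(role)
  assert_acgt(payload, "payload")
  structure(
    list(top = paste0(adapters$a5, payload, adapters$a3),
         biotin = "top5", uracil_pos = nchar(adapters$a5),
         enzyme = adapters$enzyme, payload = payload),
    class = "staple_amplicon"
  )
}

#' Type IIS cleavage positions on a duplex
#'
#' @param top Coding-strand sequence of the duplex.
#' @param enzyme Enzyme name in [type_iis_enzymes()].
#' @return Tibble with one row per recognition site: `motif_strand`,
#'   `cut_top_after`, `cut_bottom_after` (coding-strand coordinates; the
#'   strand is cut between that position and the next).
#' @export
type_iis_cut_sites <- function(top, enzyme) {
  e <- type_iis_enzymes()
  e <- e[e$enzyme == enzyme, ]
  if (nrow(e) != 1L) stop(sprintf("unknown enzyme '%s'", enzyme), call. = FALSE)
  hits <- motif_hits(top, e$motif)
  if (nrow(hits) == 0L) return(tibble::tibble(motif_strand = character(0),
                                              cut_top_after = integer(0),
                                              cut_bottom_after = integer(0)))
  n <- nchar(top)
  purrr::pmap(hits, function(start, end, strand) {
    if (strand == "+") {
      tibble::tibble(motif_strand = "+",
                     cut_top_after = end + e$cut_top,
                     cut_bottom_after = end + e$cut_bottom)
    } else {
      # motif on the template strand: mirror the offsets
      e_r <- n - start + 1L
      tibble::tibble(motif_strand = "-",
                     cut_top_after = n - (e_r + e$cut_bottom),
                     cut_bottom_after = n - (e_r + e$cut_top))
    }
  }) |> dplyr::bind_rows()
}

#' Recover a staple payload from its amplicon in silico
#'
#' Applies the adapter-removal chain in order: (1) Type IIS digestion cuts
#' off the non-biotinylated 3' adapter; (2) streptavidin capture retains the
#' biotinylated fragment and the wash discards the rest; (3) alkaline
#' denaturation discards the non-biotinylated strand; (4) USER digestion
#' cleaves the retained strand at its uracil and the biotinylated 5' piece
#' is discarded. What remains is the ssDNA staple payload.
#'
#' @param amplicon A `staple_amplicon`.
#' @return The recovered ssDNA payload (character scalar).
#' @section Errors:
#' Zero or multiple recognition sites on the amplicon, cuts falling outside
#' the molecule, and a missing uracil mark each raise a distinct error.
#' @examples
#' amp <- build_staple_amplicon("ATGGCTTCTGATAAAGGTCTG", "supra")
#' simulate_adapter_processing(amp)
#' @export
simulate_adapter_processing <- function(amplicon) {
  stopifnot(inherits(amplicon, "staple_amplicon"))
  top <- amplicon$top
  sites <- type_iis_cut_sites(top, amplicon$enzyme)
  if (nrow(sites) == 0L)
    stop(sprintf("no %s recognition site on the amplicon", amplicon$enzyme),
         call. = FALSE)
  if (nrow(sites) > 1L)
    stop(sprintf("multiple %s recognition sites on the amplicon (payload must be scrubbed)",
                 amplicon$enzyme), call. = FALSE)
  cut <- sites$cut_top_after[1]
  if (cut <= 0L || cut >= nchar(top))
    stop("Type IIS cut falls outside the amplicon", call. = FALSE)

  # biotin sits on the coding strand's 5' end: keep the left fragment, then
  # keep only its biotinylated (coding) strand
  retained <- substr(top, 1L, cut)

  u <- amplicon$uracil_pos
  if (is.null(u) || is.na(u) || u < 1L || u > nchar(retained))
    stop("no uracil mark on the retained strand; USER digestion impossible",
         call. = FALSE)
  substr(retained, u + 1L, nchar(retained))
}
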