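#' Design Supra/Infra staple oligonucleotides for one junction
#'
#' Given the two flanking dsDNA fragments (DBD-CORE side and LBD side, as
#' coding-strand sequences) and the insert to introduce between them
#' (END + LNK), designs the staple set for the junction's assembly class:
#'
#' * Class I — one Infra bridging the direct fragment-fragment nick.
#' * Classes II/III — one Supra carrying the whole insert on the coding
#'   strand, one Infra spanning arm + insert + arm on the template strand
#'   ("long" for Class II inserts, "short" for Class III).
#' * Class IV — three Supra segments tiling the insert coding strand
#'   (abutting, no gaps or overlaps) and two Infra staples bridging the
#'   left and right junctions, each extended far enough over the insert to
#'   splint the neighbouring Supra-Supra nick.
#'
#' Supra oligos are coding-strand substrings of the final chimera; Infra
#' oligos are template-strand (reverse-complement) substrings. All staples
#' are 5'-phosphorylated.
#'
#' @param left_frag,right_frag Coding-strand sequences of the flanking dsDNA
#'   fragments.
#' @param insert Insert sequence (may be `""` for Class I).
#' @param junction_id Identifier carried into the oligo sheet.
#' @param params [class_params()].
#' @return A `junction_design`: list with `junction_id`, `insert_sequence`,
#'   `assembly_class`, `left_fragment`, `right_fragment` and a `staples`
#'   tibble (`junction_id`, `role`, `index`, `sequence`,
#'   `phosphorylated_5p`).
#' @examples
#' jd <- design_staples("ATGGCTGCTGGTGCTGCTGGTCATCACGGT",
#'                      "GCTCCGGCTGGTTCTACCGCTCCGGCTTAA", "GGTTCTGGC")
#' tidy(jd)
#' @export
design_staples <- function(left_frag, right_frag, insert = "",
                           junction_id = "junction", params = class_params()) {
  assert_acgt(c(left_frag, right_frag), "fragment")
  if (nzchar(insert)) assert_acgt(insert, "insert")
  arm <- params$arm_len
  if (nchar(left_frag) < arm || nchar(right_frag) < arm)
    stop(sprintf("fragment shorter than arm_len (%d nt); cannot anneal", arm),
         call. = FALSE)
  n <- nchar(insert)
  cls <- classify_junction(n, params)
  larm <- substr(left_frag, nchar(left_frag) - arm + 1L, nchar(left_frag))
  rarm <- substr(right_frag, 1L, arm)
  mo <- params$max_oligo_len

  staple <- function(role, index, seq) {
    tibble::tibble(junction_id = junction_id, role = role, index = index,
                   sequence = seq, phosphorylated_5p = TRUE)
  }

  if (cls == "I") {
    staples <- staple("infra", 1L, revcomp(paste0(larm, rarm)))
  } else if (cls %in% c("II", "III")) {
    infra <- revcomp(paste0(larm, insert, rarm))
    if (nchar(infra) > mo)
      stop(sprintf("junction '%s': bridging Infra (%d nt) exceeds max_oligo_len (%d)",
                   junction_id, nchar(infra), mo), call. = FALSE)
    staples <- dplyr::bind_rows(staple("infra", 1L, infra),
                                staple("supra", 1L, insert))
  } else {
    # Class IV: tile the insert with three Supras; Infras reach over the
    # insert far enough to splint the internal Supra-Supra nicks.
    p1 <- round(n / 3)
    p2 <- round(2 * n / 3)
    c1 <- min(mo - arm, n)
    c2 <- min(mo - arm, n)
    seg_len <- c(p1, p2 - p1, n - p2)
    if (c1 < p1 + params$min_anneal || c2 < n - p2 + params$min_anneal ||
        any(seg_len > mo) || any(seg_len < 1L)) {
      stop(sprintf(
        "junction '%s': insert of %d nt is infeasible for 2 Infra + 3 Supra at max_oligo_len %d",
        junction_id, n, mo), call. = FALSE)
    }
    staples <- dplyr::bind_rows(
      staple("infra", 1L, revcomp(paste0(larm, substr(insert, 1L, c1)))),
      staple("infra", 2L, revcomp(paste0(substr(insert, n - c2 + 1L, n), rarm))),
      staple("supra", 1L, substr(insert, 1L, p1)),
      staple("supra", 2L, substr(insert, p1 + 1L, p2)),
      staple("supra", 3L, substr(insert, p2 + 1L, n))
    )
  }
  if (any(nchar(staples$sequence) > mo))
    stop(sprintf("junction '%s': staple exceeds max_oligo_len", junction_id),
         call. = FALSE)

  structure(
    list(junction_id = junction_id, insert_sequence = insert,
         assembly_class = cls, left_fragment = left_frag,
         right_fragment = right_frag, staples = staples, params = params),
    class = "junction_design"
  )
}

#' @export
print.junction_design <- function(x, ...) {
  cat(sprintf("<junction_design '%s'> class %s, insert %d nt, %d Infra + %d Supra\n",
              x$junction_id, x$assembly_class, nchar(x$insert_sequence),
              sum(x$staples$role == "infra"), sum(x$staples$role == "supra")))
  invisible(x)
}

#' Staple table of a junction design
#' @param x A `junction_design`.
#' @param ... Unused.
#' @return The `staples` tibble with an `assembly_class` column.
#' @method tidy junction_design
#' @export
tidy.junction_design <- function(x, ...) {
  dplyr::mutate(x$staples, assembly_class = x$assembly_class,
                length_nt = nchar(.data$sequence))
}

#' One-row summary of a junction design
#' @param x A `junction_design`.
#' @param ... Unused.
#' @method glance junction_design
#' @export
glance.junction_design <- function(x, ...) {
  tibble::tibble(junction_id = x$junction_id,
                 assembly_class = x$assembly_class,
                 insert_length_nt = nchar(x$insert_sequence),
                 n_infra = sum(x$staples$role == "infra"),
                 n_supra = sum(x$staples$role == "supra"))
}

#' Design staples for every distinct junction of an enumerated library
#'
#' A junction is identified by the (END variant, linker) pair on a given
#' DBD/LBD combination; this helper deduplicates the design manifest to
#' distinct junctions and designs each one.
#'
#' @param designs Tibble from [enumerate_chimeras()].
#' @param domains The `domain_set` behind the designs.
#' @param params [class_params()].
#' @return Tibble of staples (one row per oligo) across junctions, suitable
#'   as a synthesis order sheet.
#' @export
design_library_staples <- function(designs, domains, params = class_params()) {
  core_of <- stats::setNames(domains$dbds$core_cds, domains$dbds$name)
  ext_of <- stats::setNames(domains$ends$extension_cds, domains$ends$name)
  lnk_of <- stats::setNames(domains$linkers$cds, domains$linkers$name)
  lbd_of <- stats::setNames(domains$lbds$cds, domains$lbds$name)
  sp_of <- stats::setNames(domains$lbds$sp_codons, domains$lbds$name)

  junctions <- dplyr::distinct(designs, .data$dbd, .data$end, .data$linker,
                               .data$lbd, .data$sp_included)
  purrr::pmap(junctions, function(dbd, end, linker, lbd, sp_included) {
    body <- if (sp_included) lbd_of[[lbd]] else
      substr(lbd_of[[lbd]], sp_of[[lbd]] * 3L + 1L, nchar(lbd_of[[lbd]]))
    jid <- name_chimera(end, linker, lbd, sp_included, FALSE)
    jd <- design_staples(core_of[[dbd]], body,
                         paste0(ext_of[[end]], lnk_of[[linker]]),
                         junction_id = jid, params = params)
    tidy.junction_design(jd)
  }) |> dplyr::bind_rows()
}
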