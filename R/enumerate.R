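#' Canonical chimera nomenclature
#'
#' Builds the canonical name of a fusion design from its components, read
#' N- to C-terminal: `DBD-LNK-LBD_nSP-OD`. The leading token is the END
#' variant identifier (the CORE-only variant of a DBD is named after the DBD
#' itself, so CORE designs print as e.g. `LacI-GGBP-OD`). The `LNK` token is
#' omitted for `noLNK`, `_nSP` marks a ligand-binding domain stripped of its
#' native signal peptide, and `-OD` marks the oligomerization-domain fusion.
#' The grammar is bijective: [parse_chimera_name()] recovers the components.
#'
#' @param end END-variant name(s) (CORE entries carry the DBD name).
#' @param linker Linker name(s); `"noLNK"` for a direct junction.
#' @param lbd LBD name(s).
#' @param sp_included,od_included Logical vectors.
#' @return Character vector of canonical names.
#' @examples
#' name_chimera("LacI", "noLNK", "GGBP", TRUE, TRUE)    # "LacI-GGBP-OD"
#' name_chimera("LmrR", "noLNK", "BzdB1", FALSE, FALSE) # "LmrR-BzdB1_nSP"
#' @export
name_chimera <- function(end, linker, lbd, sp_included, od_included) {
  comp <- c(end, linker, lbd)
  if (any(grepl("-", comp, fixed = TRUE)))
    stop("component names must not contain '-'", call. = FALSE)
  lnk_tok <- ifelse(linker == "noLNK", "", paste0("-", linker))
  lbd_tok <- paste0(lbd, ifelse(sp_included, "", "_nSP"))
  od_tok <- ifelse(od_included, "-OD", "")
  paste0(end, lnk_tok, "-", lbd_tok, od_tok)
}

#' Parse canonical chimera names back to components
#'
#' Inverse of [name_chimera()].
#'
#' @param name Character vector of canonical names.
#' @return Tibble with columns `end`, `linker`, `lbd`, `sp_included`,
#'   `od_included`.
#' @export
parse_chimera_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)
  one <- function(p) {
    od <- length(p) > 1L && p[length(p)] == "OD"
    if (od) p <- p[-length(p)]
    if (!length(p) %in% c(2L, 3L))
      stop(sprintf("cannot parse chimera name '%s'",
                   paste(p, collapse = "-")), call. = FALSE)
    lbd_tok <- p[length(p)]
    sp <- !grepl("_nSP$", lbd_tok)
    tibble::tibble(
      end = p[1],
      linker = if (length(p) == 3L) p[2] else "noLNK",
      lbd = sub("_nSP$", "", lbd_tok),
      sp_included = sp, od_included = od
    )
  }
  dplyr::bind_rows(lapply(parts, one))
}

#' Enumerate every fusion-gene design allowed by a domain set
#'
#' Forms the full cartesian product END-variant x linker x LBD-variant x OD
#' state under the Nt-DBD-(LNK)-LBD-(OD) architecture, one row per design,
#' sorted by canonical name. `sequences = FALSE` gives a count/manifest mode
#' that skips CDS construction (the full library can exceed 1e5 designs).
#'
#' @param domains A `domain_set`.
#' @param include_od `"both"`, `"with"` or `"without"` — the OD fusion states
#'   to enumerate.
#' @param ends `"all"` or `"core_only"` (restricts to the length-0 CORE
#'   variant of each DBD, the "core chimera" microcosm).
#' @param sp `"both"`, `"with"` or `"without"` — signal-peptide states of the
#'   LBD.
#' @param sequences Build full CDS sequences? When `TRUE`, duplicate CDSs
#'   arising from colliding combinations are flagged in `dup_cds`.
#' @return Tibble with one row per design: `name`, `dbd`, `end`, `linker`,
#'   `lbd`, `sp_included`, `od_included`, `insert_length_nt`,
#'   `assembly_class`, and (with `sequences`) `cds` and `dup_cds`. The CDS is
#'   the arm-free concatenation CORE + END + LNK + (SP) + LBD body (+ OD).
#' @examples
#' ds <- make_domain_fixture(fixture_spec(seed = 1))
#' enumerate_chimeras(ds, include_od = "without", sequences = FALSE)
#' @export
enumerate_chimeras <- function(domains,
                               include_od = c("both", "with", "without"),
                               ends = c("all", "core_only"),
                               sp = c("both", "with", "without"),
                               sequences = TRUE) {
  stopifnot(inherits(domains, "domain_set"))
  include_od <- match.arg(include_od)
  ends <- match.arg(ends)
  sp <- match.arg(sp)

  end_tbl <- domains$ends
  if (ends == "core_only") end_tbl <- dplyr::filter(end_tbl, !nzchar(.data$extension_cds))
  od_states <- switch(include_od, both = c(TRUE, FALSE), with = TRUE,
                      without = FALSE)
  sp_states <- switch(sp, both = c(TRUE, FALSE), with = TRUE, without = FALSE)

  grid <- tidyr::expand_grid(
    end_i = seq_len(nrow(end_tbl)),
    lnk_i = seq_len(nrow(domains$linkers)),
    lbd_i = seq_len(nrow(domains$lbds)),
    sp_included = sp_states,
    od_included = od_states
  )
  out <- tibble::tibble(
    dbd = end_tbl$dbd[grid$end_i],
    end = end_tbl$name[grid$end_i],
    linker = domains$linkers$name[grid$lnk_i],
    lbd = domains$lbds$name[grid$lbd_i],
    sp_included = grid$sp_included,
    od_included = grid$od_included,
    insert_length_nt = nchar(end_tbl$extension_cds)[grid$end_i] +
      nchar(domains$linkers$cds)[grid$lnk_i]
  )
  out$name <- name_chimera(out$end, out$linker, out$lbd, out$sp_included,
                           out$od_included)
  out$assembly_class <- classify_junction(out$insert_length_nt)

  if (sequences) {
    lbd_body <- function(i, with_sp) {
      full <- domains$lbds$cds[i]
      if (with_sp) full else substr(full, domains$lbds$sp_codons[i] * 3L + 1L,
                                    nchar(full))
    }
    bodies_sp <- domains$lbds$cds
    bodies_nsp <- vapply(seq_len(nrow(domains$lbds)),
                         function(i) lbd_body(i, FALSE), character(1))
    core_of <- stats::setNames(domains$dbds$core_cds, domains$dbds$name)
    out$cds <- paste0(
      core_of[out$dbd],
      end_tbl$extension_cds[grid$end_i],
      domains$linkers$cds[grid$lnk_i],
      ifelse(out$sp_included, bodies_sp[grid$lbd_i], bodies_nsp[grid$lbd_i]),
      ifelse(out$od_included, domains$od_cds, "")
    )
    out$dup_cds <- duplicated(out$cds) | duplicated(out$cds, fromLast = TRUE)
  }

  dplyr::arrange(out, .data$name, .data$od_included) |>
    dplyr::relocate("name")
}

#' Write an enumerated library to FASTA + TSV manifest
#'
#' @param designs Output of [enumerate_chimeras()] with sequences.
#' @param fasta_path,manifest_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_design_manifest <- function(designs, fasta_path, manifest_path) {
  stopifnot("cds" %in% names(designs))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(designs$cds, designs$name)),
    fasta_path)
  readr::write_tsv(dplyr::select(designs, -"cds"), manifest_path)
  invisible(c(fasta = fasta_path, manifest = manifest_path))
}
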