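#' Assemble and validate a domain collection
#'
#' A domain set is the parameter table of the whole chimera library: the
#' DNA-binding domains (DBDs) with their length variants, the linker options,
#' the ligand-binding domains (LBDs) with their signal-peptide annotation, the
#' optional oligomerization domain (OD), and the vector homology arms used to
#' clone the assembled fusion genes.
#'
#' Conventions baked into the representation:
#' * Every DBD carries an ordered set of "END" variants — nucleotide
#'   extensions of its minimal "CORE" — and the CORE itself is recorded as an
#'   END variant of extension length 0 whose name equals the DBD name. The
#'   flat END list is what the combinatorial arithmetic counts.
#' * "No linker" is a first-class linker named `"noLNK"` with an empty CDS;
#'   it counts as one of the junction options.
#' * Signal peptides are stored as a codon count from the LBD start
#'   (internally 0-based half-open; all user-facing reports are 1-based
#'   inclusive amino-acid spans).
#'
#' @param dbds Tibble with columns `name`, `family`, `core_cds`,
#'   `operator_box`.
#' @param ends Tibble with columns `dbd`, `name`, `extension_cds`. Each DBD
#'   must contribute exactly one extension of length 0 (its CORE entry, named
#'   like the DBD).
#' @param linkers Tibble with columns `name`, `cds`; must contain exactly one
#'   empty-CDS entry named `"noLNK"`.
#' @param lbds Tibble with columns `name`, `cds`, `sp_codons` (signal-peptide
#'   length in codons, > 0), `ligand`.
#' @param od_cds Oligomerization-domain CDS (single string).
#' @param arms Named list with `rbs_arm_5p`, `end_arm_3p`, `od_arm_3p` —
#'   vector homology arms flanking the cloned fusion genes.
#' @return An object of class `domain_set`.
#' @examples
#' ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = c(2, 2),
#'                                        n_lnk = 2, n_lbd = 2, seed = 1))
#' glance(ds)
#' @export
domain_set <- function(dbds, ends, linkers, lbds, od_cds, arms) {
  dbds <- tibble::as_tibble(dbds)
  ends <- tibble::as_tibble(ends)
  linkers <- tibble::as_tibble(linkers)
  lbds <- tibble::as_tibble(lbds)
  x <- structure(
    list(dbds = dbds, ends = ends, linkers = linkers, lbds = lbds,
         od_cds = od_cds, arms = arms),
    class = "domain_set"
  )
  validate_domain_set(x)
}

#' Validate a domain set
#'
#' Checks frames, internal stop codons, name uniqueness, operator-box lengths,
#' signal-peptide spans and the structural conventions (one CORE entry per
#' DBD, exactly one `noLNK` linker). Errors name the offending record.
#'
#' @param x A `domain_set`.
#' @return `x`, invisibly usable (returned for chaining).
#' @export
validate_domain_set <- function(x) {
  stopifnot(inherits(x, "domain_set"))
  d <- x$dbds; e <- x$ends; l <- x$linkers; b <- x$lbds

  need <- function(tbl, cols, what) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) stop(sprintf("%s table lacks columns: %s", what,
                                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(d, c("name", "family", "core_cds", "operator_box"), "dbds")
  need(e, c("dbd", "name", "extension_cds"), "ends")
  need(l, c("name", "cds"), "linkers")
  need(b, c("name", "cds", "sp_codons", "ligand"), "lbds")

  dup_check <- function(nm, what) {
    dup <- nm[duplicated(nm)]
    if (length(dup)) stop(sprintf("duplicate %s name(s): %s", what,
                                  paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  dup_check(d$name, "DBD")
  dup_check(e$name, "END-variant")
  dup_check(l$name, "linker")
  dup_check(b$name, "LBD")

  check_cds <- function(seqs, names, what, allow_empty = TRUE) {
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      if (!allow_empty && !nzchar(s))
        stop(sprintf("%s '%s' has an empty CDS", what, names[i]), call. = FALSE)
      if (!nzchar(s)) next
      assert_acgt(s, sprintf("%s '%s'", what, names[i]))
      assert_frame(s, sprintf("%s '%s'", what, names[i]))
      if (has_internal_stop(s))
        stop(sprintf("%s '%s' contains an internal stop codon", what, names[i]),
             call. = FALSE)
    }
  }
  check_cds(d$core_cds, d$name, "DBD", allow_empty = FALSE)
  check_cds(e$extension_cds, e$name, "END variant")
  check_cds(l$cds, l$name, "linker")
  check_cds(b$cds, b$name, "LBD", allow_empty = FALSE)
  check_cds(x$od_cds, "OD", "OD")

  bad_op <- nchar(d$operator_box) < 6L
  if (any(bad_op))
    stop(sprintf("operator box shorter than 6 nt for DBD '%s'",
                 d$name[which(bad_op)[1]]), call. = FALSE)
  assert_acgt(d$operator_box, "operator box")

  unknown <- setdiff(e$dbd, d$name)
  if (length(unknown))
    stop(sprintf("END variants reference unknown DBD(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  core_counts <- table(factor(e$dbd[!nzchar(e$extension_cds)], levels = d$name))
  if (any(core_counts != 1L))
    stop(sprintf("each DBD needs exactly one length-0 (CORE) END entry; violated for: %s",
                 paste(names(core_counts)[core_counts != 1L], collapse = ", ")),
         call. = FALSE)

  n_nolnk <- sum(!nzchar(l$cds))
  if (n_nolnk != 1L || !"noLNK" %in% l$name[!nzchar(l$cds)])
    stop("linker table must contain exactly one empty entry named 'noLNK'",
         call. = FALSE)

  bad_sp <- b$sp_codons <= 0L | b$sp_codons * 3L >= nchar(b$cds)
  if (any(bad_sp))
    stop(sprintf("signal-peptide span invalid for LBD '%s' (must leave a non-empty body)",
                 b$name[which(bad_sp)[1]]), call. = FALSE)

  arms <- x$arms
  if (!all(c("rbs_arm_5p", "end_arm_3p", "od_arm_3p") %in% names(arms)))
    stop("arms must provide rbs_arm_5p, end_arm_3p and od_arm_3p", call. = FALSE)
  assert_acgt(unlist(arms), "homology arm")

  x
}

#' @export
print.domain_set <- function(x, ...) {
  g <- glance(x)
  cat("<domain_set>\n")
  cat(sprintf("  %d DBDs, %d END variants, %d linker options, %d LBDs (%d SP/nSP variants)\n",
              g$n_dbd, g$n_end_total, g$n_lnk_options, g$n_lbd, g$n_lbd_variants))
  cat(sprintf("  OD: %d nt; arms: %s\n", nchar(x$od_cds),
              paste(sprintf("%s=%dnt", names(x$arms), nchar(unlist(x$arms))),
                    collapse = ", ")))
  invisible(x)
}

#' One-row bookkeeping summary of a domain set
#'
#' Reports the counts that drive the combinatorial arithmetic of the library:
#' number of DBDs, total END variants (CORE-only entries included), linker
#' options (`noLNK` included), LBDs, and LBD variants (two per LBD: with and
#' without the native signal peptide).
#'
#' @param x A `domain_set`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance domain_set
#' @export
glance.domain_set <- function(x, ...) {
  tibble::tibble(
    n_dbd = nrow(x$dbds),
    n_end_total = nrow(x$ends),
    n_lnk_options = nrow(x$linkers),
    n_lbd = nrow(x$lbds),
    n_lbd_variants = 2L * nrow(x$lbds),
    od_len_nt = nchar(x$od_cds)
  )
}

#' All domain records of a set as one tidy table
#'
#' @param x A `domain_set`.
#' @param ... Unused.
#' @return Tibble with columns `kind`, `name`, `parent`, `cds`, `len_nt` plus
#'   kind-specific metadata columns.
#' @method tidy domain_set
#' @export
tidy.domain_set <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "dbd_core", name = x$dbds$name, parent = NA_character_,
                   cds = x$dbds$core_cds, family = x$dbds$family,
                   operator_box = x$dbds$operator_box),
    tibble::tibble(kind = "end", name = x$ends$name, parent = x$ends$dbd,
                   cds = x$ends$extension_cds),
    tibble::tibble(kind = "linker", name = x$linkers$name, parent = NA_character_,
                   cds = x$linkers$cds),
    tibble::tibble(kind = "lbd", name = x$lbds$name, parent = NA_character_,
                   cds = x$lbds$cds, sp_aa = x$lbds$sp_codons,
                   ligand = x$lbds$ligand),
    tibble::tibble(kind = "od", name = "OD", parent = NA_character_,
                   cds = x$od_cds)
  ) |>
    dplyr::mutate(len_nt = nchar(.data$cds), .after = "cds")
}

#' Load a domain set from FASTA + TSV metadata (+ optional YAML config)
#'
#' The FASTA file holds every nucleotide sequence (DBD COREs, END extensions,
#' linkers, LBDs, OD) keyed by identifier; the TSV sidecar declares each
#' record's kind and metadata. Signal-peptide spans are given in the TSV as
#' 1-based inclusive amino-acid coordinates (`sp_aa_start`, `sp_aa_end`, e.g.
#' 1 and 23 for a 23-residue peptide) and converted to internal codon counts.
#'
#' @param fasta_path FASTA of all domain sequences. Records that denote an
#'   empty sequence (CORE END entries, the `noLNK` linker) may be omitted from
#'   the FASTA; they are created from the metadata.
#' @param metadata_path TSV with columns `id`, `kind`
#'   (`dbd`/`end`/`linker`/`lbd`/`od`), `parent` (owning DBD, for ENDs),
#'   `family`, `sp_aa_start`, `sp_aa_end`, `ligand`, `operator_box`.
#' @param config_path Optional YAML with `arms:` (named arm sequences) and
#'   `enzymes:` (forbidden-site list); defaults from [default_arms()] when
#'   absent.
#' @return A validated `domain_set`.
#' @seealso [write_domain_set()] for the inverse.
#' @export
load_domain_set <- function(fasta_path, metadata_path, config_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seq_tbl <- tibble::tibble(id = names(seqs),
                            seq = unname(as.character(seqs)))
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (!all(c("id", "kind") %in% names(meta)))
    stop("metadata must have at least 'id' and 'kind' columns", call. = FALSE)
  for (col in c("parent", "family", "sp_aa_start", "sp_aa_end", "ligand",
                "operator_box")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  unknown <- setdiff(seq_tbl$id, meta$id)
  if (length(unknown))
    stop(sprintf("FASTA record(s) missing from metadata: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  meta <- dplyr::left_join(meta, seq_tbl, by = "id") |>
    dplyr::mutate(seq = dplyr::coalesce(.data$seq, ""))

  pick <- function(k) dplyr::filter(meta, .data$kind == k)
  dbd_m <- pick("dbd"); end_m <- pick("end"); lnk_m <- pick("linker")
  # a CORE entry shares its DBD's identifier; its extension is empty by
  # definition, never the DBD's own FASTA record
  end_m$seq[!is.na(end_m$parent) & end_m$id == end_m$parent] <- ""
  lbd_m <- pick("lbd"); od_m <- pick("od")
  if (nrow(od_m) != 1L) stop("metadata must declare exactly one 'od' record",
                             call. = FALSE)
  bad_sp <- is.na(lbd_m$sp_aa_start) | is.na(lbd_m$sp_aa_end)
  if (any(bad_sp))
    stop(sprintf("LBD '%s' lacks sp_aa_start/sp_aa_end metadata",
                 lbd_m$id[which(bad_sp)[1]]), call. = FALSE)
  sp_start <- as.integer(lbd_m$sp_aa_start)
  if (any(sp_start != 1L))
    stop(sprintf("signal peptide of LBD '%s' does not start at residue 1",
                 lbd_m$id[which(sp_start != 1L)[1]]), call. = FALSE)

  if (is.null(config_path)) {
    arms <- default_arms()
  } else {
    cfg <- yaml::read_yaml(config_path)
    arms <- cfg$arms %||% default_arms()
  }

  domain_set(
    dbds = tibble::tibble(name = dbd_m$id, family = dbd_m$family,
                          core_cds = dbd_m$seq, operator_box = dbd_m$operator_box),
    ends = tibble::tibble(dbd = end_m$parent, name = end_m$id,
                          extension_cds = end_m$seq),
    linkers = tibble::tibble(name = lnk_m$id, cds = lnk_m$seq),
    lbds = tibble::tibble(name = lbd_m$id, cds = lbd_m$seq,
                          sp_codons = as.integer(lbd_m$sp_aa_end),
                          ligand = lbd_m$ligand),
    od_cds = od_m$seq[1],
    arms = arms
  )
}

#' Write a domain set to FASTA + TSV (round-trips with [load_domain_set()])
#'
#' @param x A `domain_set`.
#' @param fasta_path,metadata_path,config_path Output paths; the YAML config
#'   (arms) is written only when `config_path` is given.
#' @return Invisibly, the paths written.
#' @export
write_domain_set <- function(x, fasta_path, metadata_path, config_path = NULL) {
  td <- tidy.domain_set(x)
  meta <- tibble::tibble(
    id = c(x$dbds$name, x$ends$name, x$linkers$name, x$lbds$name, "OD"),
    kind = c(rep("dbd", nrow(x$dbds)), rep("end", nrow(x$ends)),
             rep("linker", nrow(x$linkers)), rep("lbd", nrow(x$lbds)), "od"),
    parent = c(rep(NA, nrow(x$dbds)), x$ends$dbd,
               rep(NA, nrow(x$linkers) + nrow(x$lbds) + 1L)),
    family = c(x$dbds$family,
               rep(NA, nrow(x$ends) + nrow(x$linkers) + nrow(x$lbds) + 1L)),
    sp_aa_start = c(rep(NA, nrow(x$dbds) + nrow(x$ends) + nrow(x$linkers)),
                    rep(1L, nrow(x$lbds)), NA),
    sp_aa_end = c(rep(NA, nrow(x$dbds) + nrow(x$ends) + nrow(x$linkers)),
                  x$lbds$sp_codons, NA),
    ligand = c(rep(NA, nrow(x$dbds) + nrow(x$ends) + nrow(x$linkers)),
               x$lbds$ligand, NA),
    operator_box = c(x$dbds$operator_box,
                     rep(NA, nrow(x$ends) + nrow(x$linkers) + nrow(x$lbds) + 1L))
  )
  seqs <- c(stats::setNames(x$dbds$core_cds, x$dbds$name),
            stats::setNames(x$ends$extension_cds, x$ends$name),
            stats::setNames(x$linkers$cds, x$linkers$name),
            stats::setNames(x$lbds$cds, x$lbds$name),
            stats::setNames(x$od_cds, "OD"))
  seqs <- seqs[nzchar(seqs)]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  readr::write_tsv(meta, metadata_path)
  if (!is.null(config_path)) {
    yaml::write_yaml(list(arms = x$arms), config_path)
  }
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}

#' Default vector homology arms
#'
#' The 30-mer 5' consensus-RBS arm and the two 3' arms (OD fusion and
#' polylinker, i.e. no-OD cloning) carried by the expression vectors.
#'
#' @return Named list of three sequences.
#' @export
default_arms <- function() {
  list(
    rbs_arm_5p = "CGGTACCCGGGTGACCTAAGGAGGTAAATA",
    end_arm_3p = "GATCCTCTAGAGTGGACCTGCAGGCATGCA",
    od_arm_3p  = "AAAAGAAAAACCACCCTGGCGCCCAATACG"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
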