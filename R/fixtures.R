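# Seeded generators for every input the workflow consumes: domain sets with
# paper-scale counts, a sigma-70 scaffold, junction amplicon reads, and
# sort-seq enrichment trajectories.

# Reference names for the regulator / binding-protein panels emulated by the
# fixture (families and signal-peptide lengths as tabulated for the real
# domains); sequences are always synthetic.
FIXTURE_DBD_NAMES <- c("ArgR", "FL11", "DeoR", "LacI", "TreR", "FadR", "TtgV",
                       "CbnR", "CueR", "MetJ", "ModE", "LmrR", "TtgR", "QacR",
                       "Xre")
FIXTURE_DBD_FAMILIES <- c("ArgR", "AsnC/Lrp", "DeoR", "LacI/GalR", "LacI/GalR",
                          "GntR", "IclR", "LysR", "MerR", "MetJ", "ModE",
                          "PadR", "TetR", "TetR", "Xre")
FIXTURE_LBD_NAMES <- c("GGBP", "RPA0668", "RPA4029", "RPA0985", "ADP71087",
                       "KAI94709", "ABE44898", "ABE38823", "EYC50849",
                       "ABD68043", "AHF85493", "CAK09396", "AEK56128",
                       "BzdB1", "BAE51678")
FIXTURE_LBD_SP_AA <- c(23L, 31L, 27L, 22L, 31L, 31L, 30L, 27L, 25L, 24L, 20L,
                       20L, 29L, 30L, 41L)
FIXTURE_LBD_LIGANDS <- c("Glucose", "Benzoate", "4-OH-benzoate",
                         "4-OH-benzoate", "Benzoate", "Benzoate", "Benzoate",
                         "4-OH-benzoate", "4-OH-benzoate", "4-OH-benzoate",
                         "4-OH-benzoate", "4-OH-benzoate", "4-OH-benzoate",
                         "Benzoate", "Benzoate")

# The operator box native to the fixture scaffold (a lac-type palindrome
# downstream of the transcription start site).
FIXTURE_NATIVE_OPERATOR <- "AATTGTGAGCGGATAACAATT"

#' Specify a synthetic domain-set fixture
#'
#' @param n_dbd Number of DBDs (up to 15 named panel entries, then generic
#'   names).
#' @param ends_per_dbd Integer vector (recycled to `n_dbd`): END variants per
#'   DBD, *counting* the length-0 CORE entry.
#' @param n_lnk Number of linker options, counting `noLNK`.
#' @param end_len_range,lnk_len_range Nucleotide length range (multiples of 3)
#'   for non-zero END extensions and linkers. Both endpoints are guaranteed to
#'   occur in the generated set when enough entries exist.
#' @param n_lbd Number of LBDs (each later yields an SP and a no-SP variant).
#' @param core_len_range,lbd_len_range CDS length ranges (nt) for DBD COREs
#'   and complete LBDs (signal peptide included).
#' @param od_len OD CDS length (nt).
#' @param avoid_motifs Motifs every generated sequence must be free of (both
#'   strands); defaults to the Type IIS motifs so no scrub is ever needed.
#' @param seed Mandatory integer seed; the fixture is a pure function of the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_dbd = 3, ends_per_dbd = 3, n_lnk = 3,
                         end_len_range = c(3L, 120L),
                         lnk_len_range = c(3L, 123L),
                         n_lbd = 3, core_len_range = c(90L, 150L),
                         lbd_len_range = c(240L, 360L), od_len = 60L,
                         avoid_motifs = type_iis_enzymes()$motif,
                         seed) {
  if (missing(seed)) stop("fixture_spec requires an explicit seed", call. = FALSE)
  ends_per_dbd <- rep_len(as.integer(ends_per_dbd), n_dbd)
  if (any(ends_per_dbd < 1L))
    stop("every DBD needs at least its CORE entry (ends_per_dbd >= 1)", call. = FALSE)
  for (r in list(end_len_range, lnk_len_range, core_len_range, lbd_len_range,
                 od_len)) {
    if (any(r %% 3L != 0L))
      stop("all fixture lengths must be divisible by 3", call. = FALSE)
  }
  structure(list(n_dbd = n_dbd, ends_per_dbd = ends_per_dbd, n_lnk = n_lnk,
                 end_len_range = as.integer(end_len_range),
                 lnk_len_range = as.integer(lnk_len_range),
                 n_lbd = n_lbd, core_len_range = as.integer(core_len_range),
                 lbd_len_range = as.integer(lbd_len_range),
                 od_len = as.integer(od_len), avoid_motifs = avoid_motifs,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' The paper-scale fixture specification
#'
#' Count-matched to the published library: 15 DBDs contributing 119 END
#' variants in total (every CORE counted, on average eight per DBD), 19
#' junction options (`noLNK` included), 15 LBDs (30 SP/nSP variants), END
#' extensions spanning 3-120 nt and linkers up to 123 nt — so junction
#' inserts span 3-243 nt and the full enumeration reaches 135,660 designs.
#'
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
paper_scale_spec <- function(seed = 20260101L) {
  fixture_spec(n_dbd = 15, ends_per_dbd = c(rep(8L, 14), 7L), n_lnk = 19,
               end_len_range = c(3L, 120L), lnk_len_range = c(3L, 123L),
               n_lbd = 15, seed = seed)
}

#' @noRd
len_grid <- function(n, range) {
  # n lengths, multiples of 3, covering both endpoints when n >= 2
  if (n == 0L) return(integer(0))
  if (n == 1L) return(range[2])
  grid <- seq(range[1], range[2], by = 3L)
  idx <- unique(round(seq(1L, length(grid), length.out = n)))
  lens <- grid[idx]
  if (length(lens) < n) lens <- c(lens, sample(grid, n - length(lens), replace = TRUE))
  sort(lens)
}

#' Generate a synthetic, validated domain set
#'
#' Sequences are drawn codon-by-codon from the 61 sense codons and
#' rejection-sampled until free of the configured restriction motifs, so
#' every fixture passes validation with zero scrub operations. Deterministic
#' under the spec's seed. The DBD at the LacI panel position (when present)
#' carries the scaffold's native operator box, making it the cognate
#' repressor of the fixture scaffold from [make_scaffold_fixture()].
#'
#' @param spec A [fixture_spec()] (e.g. [paper_scale_spec()]).
#' @param dir Optional directory: when given, FASTA/TSV/YAML files plus a
#'   JSON manifest (spec + seed) are written there.
#' @return A validated `domain_set`.
#' @examples
#' ds <- make_domain_fixture(fixture_spec(seed = 42))
#' glance(ds)
#' @export
make_domain_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  avoid <- spec$avoid_motifs

  n_dbd <- spec$n_dbd
  dbd_names <- if (n_dbd <= length(FIXTURE_DBD_NAMES)) {
    FIXTURE_DBD_NAMES[seq_len(n_dbd)]
  } else {
    c(FIXTURE_DBD_NAMES, sprintf("DBD%02d", seq_len(n_dbd - length(FIXTURE_DBD_NAMES))))
  }
  families <- rep_len(FIXTURE_DBD_FAMILIES, n_dbd)

  scaffold <- make_scaffold_fixture()
  operators <- character(n_dbd)
  for (i in seq_len(n_dbd)) {
    if (dbd_names[i] == "LacI") {
      operators[i] <- FIXTURE_NATIVE_OPERATOR
    } else {
      repeat {
        op <- random_dna(sample(14:18, 1))
        if (!grepl(op, scaffold$sequence, fixed = TRUE)) break
      }
      operators[i] <- op
    }
  }

  core_lens <- sample(seq(spec$core_len_range[1], spec$core_len_range[2], by = 3L),
                      n_dbd, replace = TRUE)
  dbds <- tibble::tibble(
    name = dbd_names, family = families,
    core_cds = vapply(core_lens, random_cds, character(1), avoid = avoid),
    operator_box = operators
  )

  # END variants: one CORE (length 0) per DBD plus extensions; the pooled
  # extension lengths cover the configured range endpoints.
  n_ext <- spec$ends_per_dbd - 1L
  ext_lens_pool <- len_grid(sum(n_ext), spec$end_len_range)
  ends <- list(tibble::tibble(dbd = dbd_names, name = dbd_names,
                              extension_cds = ""))
  pool_i <- 0L
  for (i in seq_len(n_dbd)) {
    if (n_ext[i] == 0L) next
    lens <- ext_lens_pool[pool_i + seq_len(n_ext[i])]
    pool_i <- pool_i + n_ext[i]
    ends[[length(ends) + 1L]] <- tibble::tibble(
      dbd = dbd_names[i],
      name = sprintf("%s_E%02d", dbd_names[i], seq_len(n_ext[i])),
      extension_cds = vapply(lens, random_cds, character(1), avoid = avoid)
    )
  }
  ends <- dplyr::bind_rows(ends) |> dplyr::arrange(.data$dbd, .data$name)

  n_real_lnk <- spec$n_lnk - 1L
  lnk_lens <- len_grid(n_real_lnk, spec$lnk_len_range)
  linkers <- dplyr::bind_rows(
    tibble::tibble(name = "noLNK", cds = ""),
    tibble::tibble(name = sprintf("LNK%02d", seq_len(n_real_lnk)),
                   cds = vapply(lnk_lens, random_cds, character(1), avoid = avoid))
  )

  n_lbd <- spec$n_lbd
  lbd_names <- if (n_lbd <= length(FIXTURE_LBD_NAMES)) {
    FIXTURE_LBD_NAMES[seq_len(n_lbd)]
  } else {
    c(FIXTURE_LBD_NAMES, sprintf("LBD%02d", seq_len(n_lbd - length(FIXTURE_LBD_NAMES))))
  }
  sp_aa <- rep_len(FIXTURE_LBD_SP_AA, n_lbd)
  ligands <- rep_len(FIXTURE_LBD_LIGANDS, n_lbd)
  lbd_grid <- seq(spec$lbd_len_range[1], spec$lbd_len_range[2], by = 3L)
  lbd_lens <- pmax(sample(lbd_grid, n_lbd, replace = TRUE), (sp_aa + 10L) * 3L)
  lbds <- tibble::tibble(
    name = lbd_names,
    cds = vapply(lbd_lens, random_cds, character(1), avoid = avoid),
    sp_codons = sp_aa, ligand = ligands
  )

  ds <- domain_set(dbds = dbds, ends = ends, linkers = linkers, lbds = lbds,
                   od_cds = random_cds(spec$od_len, avoid = avoid),
                   arms = default_arms())

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_domain_set(ds, file.path(dir, "domains.fasta"),
                     file.path(dir, "domains.tsv"),
                     file.path(dir, "config.yaml"))
    jsonlite::write_json(
      list(generator = "make_domain_fixture", spec = unclass(spec)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }
  ds
}

#' Synthetic sigma-70 promoter scaffold
#'
#' A Ptac-like scaffold with consensus -35 (TTGACA) and -10 (TATAAT)
#' hexamers, a 17-nt spacer, and a lac-type operator box downstream of the
#' transcription start site — the native operator that the fixture's
#' LacI-position DBD recognizes.
#'
#' @return A [promoter_scaffold()] object.
#' @export
make_scaffold_fixture <- function() {
  upstream <- "CTGAAATGAGCTG"                       # -35 context
  spacer <- "TTAGGCACCCCAGGC"                       # 15 of the 17 spacer nt
  seq <- paste0(upstream, "TTGACA", spacer, "AT", "TATAAT",
                "GTGTGG", "A", FIXTURE_NATIVE_OPERATOR, "TCACACAGGAAACAGCT")
  m35_start <- nchar(upstream) + 1L
  m10_start <- m35_start + 6L + 17L
  tss <- m10_start + 6L + 6L
  promoter_scaffold(seq, minus35_start = m35_start, minus10_start = m10_start,
                    tss_pos = tss,
                    native_operator = FIXTURE_NATIVE_OPERATOR)
}
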