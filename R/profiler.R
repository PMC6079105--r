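#' Build the junction-barcode reference for a design library
#'
#' The junction amplicon spans the 3' region of the DBD, the full END and
#' LNK insert, and the 5' region of the LBD (signal peptide included when
#' present) — enough to identify DBD-CORE, DBD-END, LNK, LBD-SP and LBD. The
#' OD lies outside the amplified region, so designs differing only in OD
#' state share a barcode; such collisions are recorded and reported.
#'
#' @param designs Design manifest from [enumerate_chimeras()] (sequences not
#'   required).
#' @param domains The `domain_set` behind the designs.
#' @param flank_len Bases taken from the DBD 3' end and from the LBD 5' end
#'   (default 20). Flanks longer than a component are truncated with a
#'   warning.
#' @return A `junction_reference`: list with `entries` (tibble: `barcode`,
#'   `design` — representative canonical name, `members` — all design names
#'   sharing the barcode, `n_members`), `collisions` (entries with more than
#'   one member) and `flank_len`.
#' @export
build_reference <- function(designs, domains, flank_len = 20L) {
  stopifnot(inherits(domains, "domain_set"))
  if (nrow(designs) == 0L) stop("empty design manifest", call. = FALSE)
  core_of <- stats::setNames(domains$dbds$core_cds, domains$dbds$name)
  ext_of <- stats::setNames(domains$ends$extension_cds, domains$ends$name)
  lnk_of <- stats::setNames(domains$linkers$cds, domains$linkers$name)
  lbd_of <- stats::setNames(domains$lbds$cds, domains$lbds$name)
  sp_of <- stats::setNames(domains$lbds$sp_codons, domains$lbds$name)

  cores <- core_of[designs$dbd]
  left <- substr(cores, pmax(1L, nchar(cores) - flank_len + 1L), nchar(cores))
  bodies <- ifelse(designs$sp_included, lbd_of[designs$lbd],
                   substr(lbd_of[designs$lbd],
                          sp_of[designs$lbd] * 3L + 1L,
                          nchar(lbd_of[designs$lbd])))
  if (any(nchar(cores) < flank_len) || any(nchar(bodies) < flank_len))
    warning("flank_len exceeds a component length; flank truncated",
            call. = FALSE)
  right <- substr(bodies, 1L, pmin(flank_len, nchar(bodies)))
  barcode <- paste0(left, ext_of[designs$end], lnk_of[designs$linker], right)

  entries <- tibble::tibble(barcode = barcode, name = designs$name) |>
    dplyr::arrange(.data$name) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(design = dplyr::first(.data$name),
                     members = list(.data$name),
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$design)
  structure(
    list(entries = entries,
         collisions = dplyr::filter(entries, .data$n_members > 1L),
         flank_len = flank_len),
    class = "junction_reference"
  )
}

#' @export
print.junction_reference <- function(x, ...) {
  cat(sprintf("<junction_reference> %d barcodes (%d collided), flank %d nt\n",
              nrow(x$entries), nrow(x$collisions), x$flank_len))
  invisible(x)
}

#' @noRd
mismatch_candidates <- function(reads, barcodes, max_mismatch) {
  # For each read: number of barcodes within max_mismatch and the index of
  # the best one. Substitution-only model: only equal-length pairs compare.
  n <- length(reads)
  n_hit <- integer(n)
  best <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  read_len <- nchar(reads)
  bc_len <- nchar(barcodes)
  for (L in unique(read_len)) {
    ri <- which(read_len == L)
    bi <- which(bc_len == L)
    if (length(bi) == 0L) next
    rm <- matrix(unlist(strsplit(reads[ri], "")), nrow = length(ri),
                 byrow = TRUE)
    for (b in bi) {
      bc <- strsplit(barcodes[b], "")[[1]]
      d <- rowSums(rm != matrix(bc, nrow = length(ri), ncol = L, byrow = TRUE))
      ok <- d <= max_mismatch
      n_hit[ri] <- n_hit[ri] + ok
      upd <- ok & d < best_d[ri]
      best[ri][upd] <- b
      best_d[ri][upd] <- d[upd]
    }
  }
  list(n_hit = n_hit, best = best)
}

#' Classify junction amplicon reads into per-chimera counts
#'
#' Assigns each read (or read pair) to the unique reference barcode within
#' `max_mismatch` substitutions. Reads matching two or more barcodes equally
#' validly are ambiguous; reads matching none are unassigned; for pairs, the
#' two mates must agree on a single entry or the pair is ambiguous. Reads
#' are counted per fragment/pair, never per mate.
#'
#' @param reads Character vector of reads (single-end), or a list of two
#'   equal-length character vectors `list(mate1, mate2)` for paired data,
#'   with mate 1 reading the barcode 5' end forward and mate 2 the 3' end in
#'   reverse complement.
#' @param ref A [build_reference()] result.
#' @param max_mismatch Substitution tolerance per read (default 2).
#' @param library_id Label carried into the table.
#' @return An `abundance_tbl`: tibble with one row per reference entry
#'   (`design`, `barcode`, `read_count`, `frequency` — fraction of assigned
#'   reads, `library_id`), with totals in `attr(, "totals")` satisfying
#'   assigned + ambiguous + unassigned = total input reads.
#' @export
classify_reads <- function(reads, ref, max_mismatch = 2L,
                           library_id = "library") {
  stopifnot(inherits(ref, "junction_reference"))
  if (nrow(ref$entries) == 0L) stop("empty reference", call. = FALSE)
  barcodes <- ref$entries$barcode
  paired <- is.list(reads) && !is.data.frame(reads)

  if (!paired) {
    reads <- as.character(reads)
    n_total <- length(reads)
    cand <- mismatch_candidates(reads, barcodes, max_mismatch)
    assigned_idx <- cand$best[cand$n_hit == 1L]
    n_ambiguous <- sum(cand$n_hit > 1L)
    n_unassigned <- sum(cand$n_hit == 0L)
  } else {
    stopifnot(length(reads) == 2L, length(reads[[1]]) == length(reads[[2]]))
    m1 <- as.character(reads[[1]])
    m2 <- as.character(reads[[2]])
    n_total <- length(m1)
    # compare each mate against the equally-long barcode prefix / suffix
    cand1 <- mate_candidates(m1, barcodes, max_mismatch, side = "prefix")
    cand2 <- mate_candidates(revcomp(m2), barcodes, max_mismatch,
                             side = "suffix")
    both <- purrr::map2(cand1, cand2, intersect)
    hits <- lengths(both)
    assigned_idx <- as.integer(unlist(both[hits == 1L]))
    n_ambiguous <- sum(hits > 1L)
    n_unassigned <- sum(hits == 0L)
  }

  counts <- tabulate(assigned_idx, nbins = nrow(ref$entries))
  n_assigned <- sum(counts)
  out <- tibble::tibble(
    design = ref$entries$design,
    barcode = barcodes,
    read_count = counts,
    frequency = if (n_assigned > 0) counts / n_assigned else rep(0, length(counts)),
    library_id = library_id
  )
  structure(out,
            class = c("abundance_tbl", class(out)),
            totals = list(total = n_total, assigned = n_assigned,
                          ambiguous = n_ambiguous, unassigned = n_unassigned))
}

#' @noRd
mate_candidates <- function(mates, barcodes, max_mismatch, side) {
  n <- length(mates)
  out <- vector("list", n)
  len <- nchar(mates)
  bc_len <- nchar(barcodes)
  for (L in unique(len)) {
    ri <- which(len == L)
    bi <- which(bc_len >= L)
    if (length(bi) == 0L) { out[ri] <- list(integer(0)); next }
    rm <- matrix(unlist(strsplit(mates[ri], "")), nrow = length(ri),
                 byrow = TRUE)
    hit_mat <- matrix(FALSE, nrow = length(ri), ncol = length(bi))
    for (j in seq_along(bi)) {
      b <- bi[j]
      piece <- if (side == "prefix") substr(barcodes[b], 1L, L) else
        substr(barcodes[b], bc_len[b] - L + 1L, bc_len[b])
      bc <- strsplit(piece, "")[[1]]
      d <- rowSums(rm != matrix(bc, nrow = length(ri), ncol = L, byrow = TRUE))
      hit_mat[, j] <- d <= max_mismatch
    }
    for (k in seq_along(ri)) out[[ri[k]]] <- bi[hit_mat[k, ]]
  }
  out
}

#' Totals of an abundance table
#' @param x An `abundance_tbl`.
#' @param ... Unused.
#' @return One-row tibble: total, assigned, ambiguous, unassigned reads and
#'   the assignment rate.
#' @method glance abundance_tbl
#' @export
glance.abundance_tbl <- function(x, ...) {
  t <- attr(x, "totals")
  tibble::tibble(total = t$total, assigned = t$assigned,
                 ambiguous = t$ambiguous, unassigned = t$unassigned,
                 assignment_rate = if (t$total > 0) t$assigned / t$total else NA_real_)
}

#' Compare pre- and post-enrichment abundance tables
#'
#' @param pre,post `abundance_tbl`s built against the same reference.
#' @param theta Abundance threshold on the post-enrichment frequency
#'   (default 0.005, i.e. the 0.5% reporting level).
#' @param pseudo Pseudo-frequency added to both sides of the fold change;
#'   defaults to 1 / (assigned reads in the smaller library).
#' @return An `enrichment_report` tibble: `design`, `freq_pre`, `freq_post`,
#'   `log2_fold_change`, `passes_abundance_threshold` (`freq_post >= theta`).
#'   Designs absent (zero count) in both libraries are omitted.
#' @export
compare_enrichment <- function(pre, post, theta = 0.005, pseudo = NULL) {
  stopifnot(inherits(pre, "abundance_tbl"), inherits(post, "abundance_tbl"))
  if (!identical(pre$design, post$design) || !identical(pre$barcode, post$barcode))
    stop("abundance tables were built against different references", call. = FALSE)
  if (is.null(pseudo)) {
    n_min <- min(attr(pre, "totals")$assigned, attr(post, "totals")$assigned)
    pseudo <- if (n_min > 0) 1 / n_min else 1e-6
  }
  out <- tibble::tibble(
    design = pre$design,
    freq_pre = pre$frequency,
    freq_post = post$frequency,
    log2_fold_change = log2((post$frequency + pseudo) / (pre$frequency + pseudo)),
    passes_abundance_threshold = post$frequency >= theta
  ) |>
    dplyr::filter(.data$freq_pre > 0 | .data$freq_post > 0)
  structure(out, class = c("enrichment_report", class(out)),
            theta = theta, pseudo = pseudo)
}
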