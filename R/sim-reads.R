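#' Simulate junction amplicon reads with known composition
#'
#' Draws template molecules from the given design frequencies (one
#' multinomial draw of `n_reads`), then applies independent per-base
#' substitution errors. Each read spans its template end to end. The truth
#' table records the realized template composition — the ground truth a
#' classifier should recover.
#'
#' @param templates Tibble with columns `design` and `barcode` (e.g.
#'   `entries` of a [build_reference()]), plus a `frequency` column, or a
#'   separate `frequencies` vector.
#' @param n_reads Number of reads (> 0).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param frequencies Optional numeric vector overriding
#'   `templates$frequency`; must sum to 1.
#' @param paired Emit a mate pair per template (mate 1 = forward first half,
#'   mate 2 = reverse complement of the second half) instead of one
#'   full-length read.
#' @param seed Mandatory integer seed.
#' @return List with `reads` (character vector, or `list(mate1, mate2)`),
#'   `truth` (tibble: `design`, `true_count`, `true_frequency` — realized
#'   composition) and `read_design` (per-read true design).
#' @export
simulate_reads <- function(templates, n_reads, error_rate = 0,
                           frequencies = NULL, paired = FALSE, seed) {
  if (missing(seed)) stop("simulate_reads requires an explicit seed", call. = FALSE)
  if (n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  freq <- frequencies %||% templates$frequency
  if (is.null(freq)) stop("design frequencies required", call. = FALSE)
  if (abs(sum(freq) - 1) > 1e-8)
    stop("frequencies must sum to 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)

  set.seed(seed)
  idx <- sample.int(nrow(templates), n_reads, replace = TRUE, prob = freq)
  reads <- templates$barcode[idx]
  if (error_rate > 0) reads <- mutate_reads(reads, error_rate)

  truth <- tibble::tibble(
    design = templates$design,
    true_count = tabulate(idx, nbins = nrow(templates))
  ) |>
    dplyr::mutate(true_frequency = .data$true_count / n_reads)

  if (paired) {
    L <- nchar(reads)
    half <- L %/% 2L
    reads <- list(mate1 = substr(reads, 1L, half),
                  mate2 = revcomp(substr(reads, half + 1L, L)))
  }
  list(reads = reads, truth = truth, read_design = templates$design[idx])
}

#' @noRd
mutate_reads <- function(reads, error_rate) {
  bases <- c("A", "C", "G", "T")
  out <- reads
  for (L in unique(nchar(reads))) {
    ri <- which(nchar(reads) == L)
    m <- matrix(unlist(strsplit(reads[ri], "")), nrow = length(ri),
                byrow = TRUE)
    flip <- matrix(stats::runif(length(m)) < error_rate, nrow = nrow(m))
    if (any(flip)) {
      # substitute with one of the three other bases, uniformly
      cur <- match(m[flip], bases)
      m[flip] <- bases[((cur - 1L + sample.int(3L, sum(flip), replace = TRUE)) %% 4L) + 1L]
    }
    out[ri] <- apply(m, 1L, paste, collapse = "")
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads Character vector (or `list(mate1, mate2)`) from
#'   [simulate_reads()].
#' @param path Output path; for paired reads two files `_R1`/`_R2` are
#'   derived from it.
#' @param quality_char Constant Phred character for all bases.
#' @return Invisibly, the path(s) written.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  write_one <- function(r, p) {
    s <- Biostrings::DNAStringSet(r)
    names(s) <- sprintf("read%06d", seq_along(r))
    Biostrings::writeXStringSet(s, p, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  strrep(quality_char, nchar(r))))
    p
  }
  if (is.list(reads)) {
    p1 <- sub("(\\.[^.]+)?$", "_R1.fastq", path)
    p2 <- sub("(\\.[^.]+)?$", "_R2.fastq", path)
    invisible(c(write_one(reads[[1]], p1), write_one(reads[[2]], p2)))
  } else {
    invisible(write_one(reads, path))
  }
}
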