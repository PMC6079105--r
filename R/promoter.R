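#' Define a sigma-70 promoter scaffold
#'
#' Records the scaffold sequence with its -35 and -10 hexamers and the
#' transcription start site. Coordinates are supplied 1-based (position of
#' the first hexamer base / of the +1 base) and stored internally as 0-based
#' half-open intervals; printed reports are 1-based inclusive.
#'
#' @param sequence Scaffold sequence (uppercase ACGT).
#' @param minus35_start,minus10_start 1-based positions of the first base of
#'   each hexamer.
#' @param tss_pos 1-based position of the transcription start site.
#' @param native_operator Optional operator box already present in the
#'   scaffold (the scaffold's cognate repressor binds it).
#' @return A `promoter_scaffold` object with recorded spacer length.
#' @export
promoter_scaffold <- function(sequence, minus35_start, minus10_start, tss_pos,
                              native_operator = NULL) {
  assert_acgt(sequence, "scaffold")
  m35 <- c(minus35_start - 1L, minus35_start + 5L)  # 0-based half-open
  m10 <- c(minus10_start - 1L, minus10_start + 5L)
  tss <- tss_pos - 1L
  if (!(m35[2] <= m10[1] && m10[2] <= tss))
    stop("scaffold requires -35 before -10 before the TSS", call. = FALSE)
  if (tss >= nchar(sequence))
    stop("TSS outside the scaffold sequence", call. = FALSE)
  if (!is.null(native_operator) &&
      !grepl(native_operator, sequence, fixed = TRUE))
    stop("declared native operator does not occur in the scaffold", call. = FALSE)
  structure(
    list(sequence = sequence, minus35 = m35, minus10 = m10, tss = tss,
         spacer_len = m10[1] - m35[2], native_operator = native_operator),
    class = "promoter_scaffold"
  )
}

#' @export
print.promoter_scaffold <- function(x, ...) {
  cat(sprintf("<promoter_scaffold> %d nt; -35 at %d-%d, -10 at %d-%d (spacer %d nt), TSS at %d\n",
              nchar(x$sequence), x$minus35[1] + 1L, x$minus35[2],
              x$minus10[1] + 1L, x$minus10[2], x$spacer_len, x$tss + 1L))
  invisible(x)
}

#' @noRd
hexamers_of <- function(seq, scaffold) {
  list(m35 = substr(seq, scaffold$minus35[1] + 1L, scaffold$minus35[2]),
       m10 = substr(seq, scaffold$minus10[1] + 1L, scaffold$minus10[2]))
}

#' Graft an operator box into a promoter scaffold
#'
#' Incorporates a repressor's operator into the scaffold so that bound
#' repressor occludes transcription, while RNA polymerase recognition is
#' preserved: the -35/-10 hexamers may differ from the scaffold in at most
#' `max_hexamer_mut` positions each, and the -35/-10 spacing never changes
#' (all placements substitute bases; nothing is inserted).
#'
#' Placements are tried in preference order and the first that satisfies all
#' constraints is returned:
#' 1. native: the operator already occurs verbatim in the scaffold
#'    (`unchanged = TRUE`, the scaffold's own promoter);
#' 2. spacer: substitution between the hexamers, when the operator fits;
#' 3. downstream: substitution starting right after the -10 hexamer, running
#'    toward (and past) the TSS as needed;
#' 4. overlapping: substitution at any position, allowing up to
#'    `max_hexamer_mut` mutations per hexamer (minimum-mutation, then
#'    leftmost, placement wins).
#'
#' @param scaffold A [promoter_scaffold()].
#' @param operator Operator box sequence (>= 6 nt).
#' @param dbd Name attached to the design (reporting only).
#' @param max_hexamer_mut Per-hexamer substitution budget (default 2).
#' @return One-row tibble: `dbd`, `sequence`, `region` (`native`, `spacer`,
#'   `downstream` or `overlapping`), `op_start` (1-based), `hexamer_mutations`,
#'   `spacer_len`, `unchanged`.
#' @section Errors:
#' If no placement satisfies the constraints, the error lists each
#' placement's violation.
#' @export
design_promoter <- function(scaffold, operator, dbd = NA_character_,
                            max_hexamer_mut = 2L) {
  stopifnot(inherits(scaffold, "promoter_scaffold"))
  assert_acgt(operator, "operator")
  if (nchar(operator) < 6L)
    stop("operator box must be at least 6 nt", call. = FALSE)
  seq0 <- scaffold$sequence
  op_len <- nchar(operator)
  failures <- character(0)

  finish <- function(seq, region, op_start, unchanged = FALSE) {
    hx0 <- hexamers_of(seq0, scaffold)
    hx <- hexamers_of(seq, scaffold)
    muts <- hamming(hx0$m35, hx$m35) + hamming(hx0$m10, hx$m10)
    tibble::tibble(dbd = dbd, sequence = seq, region = region,
                   op_start = op_start, hexamer_mutations = muts,
                   spacer_len = scaffold$spacer_len, unchanged = unchanged)
  }

  # 1. native occurrence
  nat <- regexpr(operator, seq0, fixed = TRUE)
  if (nat[1] != -1L)
    return(finish(seq0, "native", as.integer(nat[1]), unchanged = TRUE))
  failures <- c(failures, "native: operator not present in scaffold")

  try_place <- function(start) {
    # 1-based start; pure substitution
    if (start < 1L || start + op_len - 1L > nchar(seq0)) return(NULL)
    cand <- str_sub_replace(seq0, start, start + op_len - 1L, operator)
    hx0 <- hexamers_of(seq0, scaffold)
    hx <- hexamers_of(cand, scaffold)
    if (hamming(hx0$m35, hx$m35) > max_hexamer_mut) return(NULL)
    if (hamming(hx0$m10, hx$m10) > max_hexamer_mut) return(NULL)
    cand
  }

  # 2. spacer substitution (between the hexamers), left-aligned
  sp_start <- scaffold$minus35[2] + 1L  # 1-based first spacer base
  if (op_len <= scaffold$spacer_len) {
    cand <- try_place(sp_start)
    if (!is.null(cand)) return(finish(cand, "spacer", sp_start))
    failures <- c(failures, "spacer: placement violates hexamer constraints")
  } else {
    failures <- c(failures,
                  sprintf("spacer: operator (%d nt) longer than spacer (%d nt)",
                          op_len, scaffold$spacer_len))
  }

  # 3. downstream of -10, toward and past the TSS (spacer untouched)
  ds_start <- scaffold$minus10[2] + 1L
  cand <- try_place(ds_start)
  if (!is.null(cand)) return(finish(cand, "downstream", ds_start))
  failures <- c(failures, "downstream: operator runs past the scaffold end")

  # 4. hexamer-overlapping placement, minimum mutations then leftmost; the
  #    operator footprint must intersect the polymerase contact region
  #    (-35 start through the TSS) or binding could not occlude transcription
  core_lo <- scaffold$minus35[1] + 1L
  core_hi <- scaffold$tss + 1L
  best <- NULL
  for (start in seq_len(nchar(seq0) - op_len + 1L)) {
    if (start + op_len - 1L < core_lo || start > core_hi) next
    cand <- try_place(start)
    if (is.null(cand)) next
    hx0 <- hexamers_of(seq0, scaffold)
    hx <- hexamers_of(cand, scaffold)
    muts <- hamming(hx0$m35, hx$m35) + hamming(hx0$m10, hx$m10)
    if (is.null(best) || muts < best$muts) best <- list(cand = cand,
                                                        start = start,
                                                        muts = muts)
  }
  if (!is.null(best))
    return(finish(best$cand, "overlapping", best$start))
  failures <- c(failures,
                sprintf("overlapping: no placement within %d mutations per hexamer",
                        max_hexamer_mut))

  stop(sprintf("operator cannot be placed (DBD %s):\n  %s", dbd,
               paste(failures, collapse = "\n  ")), call. = FALSE)
}

#' Build the reporter-promoter panel for a DBD collection
#'
#' One promoter design per DBD, grafting each DBD's operator box into the
#' shared scaffold. The design whose operator is already native to the
#' scaffold comes back `unchanged = TRUE` (the scaffold's own promoter);
#' per-DBD infeasibilities are recorded, not fatal.
#'
#' @param scaffold A [promoter_scaffold()].
#' @param dbds Tibble with columns `name` and `operator_box` (e.g.
#'   `domain_set$dbds`), or a `domain_set`.
#' @param max_hexamer_mut Per-hexamer substitution budget.
#' @return Tibble, one row per DBD, as in [design_promoter()] plus a
#'   `status` column (`"ok"` or the failure message); failed rows carry `NA`
#'   sequences. Ordered as the input.
#' @examples
#' ds <- make_domain_fixture(fixture_spec(n_dbd = 4, seed = 7))
#' build_promoter_panel(make_scaffold_fixture(), ds)
#' @export
build_promoter_panel <- function(scaffold, dbds, max_hexamer_mut = 2L) {
  if (inherits(dbds, "domain_set")) dbds <- dbds$dbds
  if (nrow(dbds) == 0L) {
    return(tibble::tibble(dbd = character(0), sequence = character(0),
                          region = character(0), op_start = integer(0),
                          hexamer_mutations = integer(0),
                          spacer_len = integer(0), unchanged = logical(0),
                          status = character(0)))
  }
  purrr::map2(dbds$name, dbds$operator_box, function(nm, op) {
    res <- tryCatch(design_promoter(scaffold, op, dbd = nm,
                                    max_hexamer_mut = max_hexamer_mut),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(dbd = nm, sequence = NA_character_,
                     region = NA_character_, op_start = NA_integer_,
                     hexamer_mutations = NA_integer_,
                     spacer_len = NA_integer_, unchanged = NA,
                     status = "infeasible")
    } else {
      dplyr::mutate(res, status = "ok")
    }
  }) |> dplyr::bind_rows()
}
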