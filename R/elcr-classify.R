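#' Default eLCR class and geometry parameters
#'
#' @param t_23 Insert length (nt) splitting Class III ("short Infra",
#'   inserts up to `t_23`) from Class II ("long Infra"); default 33, the
#'   midpoint of the 3-66 nt two-oligo range.
#' @param ii_iii_max Largest insert handled by the two-oligo (one Infra, one
#'   Supra) scheme; longer inserts are Class IV. Default 66 nt.
#' @param arm_len Annealing bases a staple extends over each flanking
#'   fragment at a junction (default 25).
#' @param max_oligo_len Synthesis length cap per staple oligo (default 130).
#' @param min_anneal Minimum exact-complement overlap treated as a stable
#'   annealing event in assembly simulation (default 10).
#' @return Named list of parameters.
#' @export
class_params <- function(t_23 = 33L, ii_iii_max = 66L, arm_len = 25L,
                         max_oligo_len = 130L, min_anneal = 10L) {
  stopifnot(t_23 > 0, ii_iii_max > t_23, arm_len >= min_anneal)
  list(t_23 = as.integer(t_23), ii_iii_max = as.integer(ii_iii_max),
       arm_len = as.integer(arm_len), max_oligo_len = as.integer(max_oligo_len),
       min_anneal = as.integer(min_anneal))
}

#' Assign a junction insert to an eLCR assembly class
#'
#' Class I: direct DBD-LBD connection (no insert), assembled with a single
#' bridging Infra. Classes III and II: inserts of 3-66 nt assembled with one
#' Infra plus one Supra (III "short Infra" up to `t_23` nt, II "long Infra"
#' above it). Class IV: inserts over 66 nt, assembled with two Infra and
#' three Supra staples.
#'
#' @param insert_length_nt Integer vector of insert lengths (END + LNK
#'   nucleotides between DBD-CORE and LBD); must be non-negative multiples
#'   of 3.
#' @param params [class_params()].
#' @return Character vector in `c("I","II","III","IV")`.
#' @examples
#' classify_junction(c(0, 3, 33, 36, 66, 69))
#' @export
classify_junction <- function(insert_length_nt, params = class_params()) {
  insert_length_nt <- as.integer(insert_length_nt)
  if (any(insert_length_nt < 0L))
    stop("insert length must be non-negative", call. = FALSE)
  if (any(insert_length_nt %% 3L != 0L))
    stop("insert length must be a multiple of 3 (in-frame insert)", call. = FALSE)
  dplyr::case_when(
    insert_length_nt == 0L ~ "I",
    insert_length_nt <= params$t_23 ~ "III",
    insert_length_nt <= params$ii_iii_max ~ "II",
    TRUE ~ "IV"
  )
}

#' Staple-count table per assembly class
#'
#' @return Tibble with `assembly_class`, `n_infra`, `n_supra`.
#' @export
class_staple_counts <- function() {
  tibble::tibble(
    assembly_class = c("I", "II", "III", "IV"),
    n_infra = c(1L, 1L, 1L, 2L),
    n_supra = c(0L, 1L, 1L, 3L)
  )
}
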