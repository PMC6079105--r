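#' Specify a sort-seq enrichment simulation
#'
#' Models the iterated positive-sorting screen: each round, cells are sampled
#' from the population, each cell is recovered with probability equal to its
#' design's induction fitness, and the recovered pool is renormalized. The
#' single negative sort at the start is modeled as a filter multiplying
#' initial frequencies by a per-design repression-competence flag.
#'
#' @param frequencies Initial design frequencies (summing to 1), or `NULL` to
#'   draw them from a symmetric Dirichlet.
#' @param n_designs Number of designs when drawing frequencies.
#' @param dirichlet_alpha Concentration of the Dirichlet draw.
#' @param fitness Per-design induction fitness in `[0, 1]` (probability a
#'   sorted cell carrying the design is recovered).
#' @param repression_competent Logical per-design flag applied as the
#'   negative-sort filter (default all `TRUE`).
#' @param rounds Number of positive-sorting rounds (>= 1).
#' @param cells_per_round Cells sampled each round; `Inf` for the exact
#'   infinite-sample recursion.
#' @param sorted_fraction Fraction of cells the sorter can recover, in
#'   `(0, 1]` (scales every fitness).
#' @param seed Mandatory integer seed.
#' @return An `enrichment_sim_spec` list.
#' @export
enrichment_sim_spec <- function(frequencies = NULL, n_designs = NULL,
                                dirichlet_alpha = 1, fitness,
                                repression_competent = NULL, rounds = 4L,
                                cells_per_round = 1e6, sorted_fraction = 1,
                                seed) {
  if (missing(seed)) stop("enrichment_sim_spec requires an explicit seed",
                          call. = FALSE)
  if (is.null(frequencies) && is.null(n_designs))
    stop("give frequencies or n_designs", call. = FALSE)
  if (!is.null(frequencies) && abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must sum to 1", call. = FALSE)
  if (any(fitness < 0 | fitness > 1))
    stop("fitness values must lie in [0, 1]", call. = FALSE)
  if (sorted_fraction <= 0 || sorted_fraction > 1)
    stop("sorted_fraction must lie in (0, 1]", call. = FALSE)
  if (rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  n <- length(fitness)
  if (!is.null(frequencies) && length(frequencies) != n)
    stop("frequencies and fitness lengths differ", call. = FALSE)
  structure(list(frequencies = frequencies, n_designs = n,
                 dirichlet_alpha = dirichlet_alpha, fitness = fitness,
                 repression_competent = repression_competent %||% rep(TRUE, n),
                 rounds = as.integer(rounds),
                 cells_per_round = cells_per_round,
                 sorted_fraction = sorted_fraction, seed = as.integer(seed)),
            class = "enrichment_sim_spec")
}

#' Simulate per-round frequency trajectories of an enrichment screen
#'
#' @param spec An [enrichment_sim_spec()].
#' @return An `enrichment_sim` tibble: `round` (0 = post-negative-sort input
#'   population), `design`, `frequency`. With `cells_per_round = Inf` the
#'   trajectory follows the exact selection recursion
#'   f' = f * w / sum(f * w).
#' @examples
#' spec <- enrichment_sim_spec(frequencies = c(0.5, 0.5),
#'                             fitness = c(0.9, 0.1), rounds = 3,
#'                             cells_per_round = Inf, seed = 1)
#' simulate_enrichment(spec)
#' @export
simulate_enrichment <- function(spec) {
  stopifnot(inherits(spec, "enrichment_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_designs
  f <- spec$frequencies
  if (is.null(f)) {
    g <- stats::rgamma(n, shape = spec$dirichlet_alpha)
    f <- g / sum(g)
  }
  f <- f * spec$repression_competent
  if (sum(f) == 0) stop("negative sort removed every design", call. = FALSE)
  f <- f / sum(f)
  w <- spec$fitness * spec$sorted_fraction
  designs <- sprintf("design%03d", seq_len(n))

  traj <- list(tibble::tibble(round = 0L, design = designs, frequency = f))
  for (r in seq_len(spec$rounds)) {
    if (is.infinite(spec$cells_per_round)) {
      sel <- f * w
      if (sum(sel) == 0) stop("selection eliminated every design", call. = FALSE)
      f <- sel / sum(sel)
    } else {
      cells <- as.vector(stats::rmultinom(1, size = spec$cells_per_round,
                                          prob = f))
      kept <- stats::rbinom(n, size = cells, prob = w)
      if (sum(kept) == 0) stop("no cells recovered in a sorting round",
                               call. = FALSE)
      f <- kept / sum(kept)
    }
    traj[[r + 1L]] <- tibble::tibble(round = r, design = designs, frequency = f)
  }
  out <- dplyr::bind_rows(traj)
  structure(out, class = c("enrichment_sim", class(out)))
}
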