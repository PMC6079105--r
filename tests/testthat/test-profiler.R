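small_ref <- function(seed = 303) {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = 2, n_lnk = 2,
                                         n_lbd = 2, seed = seed))
  en <- enumerate_chimeras(ds, include_od = "without", sequences = FALSE)
  list(ds = ds, en = en, ref = build_reference(en, ds, flank_len = 20))
}

test_that("the reference has one entry per design and records OD collisions", {
  x <- small_ref()
  expect_equal(nrow(x$ref$entries), nrow(x$en))
  expect_equal(nrow(x$ref$collisions), 0L)
  # enumerating both OD states folds OD-only pairs onto one barcode
  en2 <- enumerate_chimeras(x$ds, include_od = "both", sequences = FALSE)
  ref2 <- build_reference(en2, x$ds, flank_len = 20)
  expect_equal(nrow(ref2$entries), nrow(x$en))
  expect_true(all(ref2$entries$n_members == 2L))
  expect_equal(nrow(ref2$collisions), nrow(ref2$entries))
  expect_true(all(vapply(ref2$collisions$members, length, integer(1)) == 2L))
})

test_that("barcodes span DBD 3' flank, insert and LBD 5' flank", {
  x <- small_ref()
  row <- x$en[x$en$linker != "noLNK" & x$en$sp_included, ][1, ]
  core <- x$ds$dbds$core_cds[x$ds$dbds$name == row$dbd]
  lbd <- x$ds$lbds$cds[x$ds$lbds$name == row$lbd]
  want <- paste0(substr(core, nchar(core) - 19, nchar(core)),
                 x$ds$ends$extension_cds[x$ds$ends$name == row$end],
                 x$ds$linkers$cds[x$ds$linkers$name == row$linker],
                 substr(lbd, 1, 20))
  expect_identical(x$ref$entries$barcode[x$ref$entries$design == row$name], want)
})

test_that("an over-long flank is truncated with a warning", {
  x <- small_ref()
  expect_warning(build_reference(x$en, x$ds, flank_len = 1000L), "truncated")
})

test_that("error-free reads at exact multiples recover frequencies exactly", {
  x <- small_ref()
  tpl <- x$ref$entries[1:4, ]
  freq <- c(0.5, 0.3, 0.15, 0.05)
  reads <- rep(tpl$barcode, freq * 200)
  ab <- classify_reads(reads, x$ref, max_mismatch = 2)
  got <- ab$frequency[match(tpl$design, ab$design)]
  expect_equal(got, freq)
  expect_equal(sum(ab$frequency), 1)
  g <- glance(ab)
  expect_equal(g$assigned, 200L)
  expect_equal(g$unassigned + g$ambiguous, 0L)
})

test_that("reads from unreferenced junctions are unassigned, never miscounted", {
  x <- small_ref()
  set.seed(1)
  stray <- vapply(nchar(x$ref$entries$barcode[1]), rand_dna, character(1))
  ab <- classify_reads(c(x$ref$entries$barcode[1], stray), x$ref)
  g <- glance(ab)
  expect_equal(g$assigned, 1L)
  expect_equal(g$unassigned, 1L)
  expect_equal(g$total, g$assigned + g$ambiguous + g$unassigned)
})

test_that("classification with max_mismatch 0 equals exact-hash assignment", {
  x <- small_ref()
  sim <- simulate_reads(dplyr::mutate(x$ref$entries,
                                      frequency = rep(1 / dplyr::n(), dplyr::n())),
                        n_reads = 3000, error_rate = 0.01, seed = 11)
  ab <- classify_reads(sim$reads, x$ref, max_mismatch = 0)
  # oracle: direct dictionary lookup
  hit <- match(sim$reads, x$ref$entries$barcode)
  oracle <- tabulate(hit[!is.na(hit)], nbins = nrow(x$ref$entries))
  expect_identical(ab$read_count, oracle)
  expect_equal(glance(ab)$unassigned, sum(is.na(hit)))
})

test_that("noisy reads recover the realized composition within 3 sigma", {
  x <- small_ref()
  tpl <- x$ref$entries[1:3, ]
  freq <- c(0.5, 0.3, 0.2)
  sim <- simulate_reads(dplyr::mutate(tpl, frequency = freq), n_reads = 10000,
                        error_rate = 0.01, seed = 21)
  ab <- classify_reads(sim$reads, x$ref, max_mismatch = 5)
  got <- ab$frequency[match(tpl$design, ab$design)]
  truth <- sim$truth$true_frequency
  sigma <- sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(got - truth) <= 3 * sigma + 0.01))
  expect_equal(glance(ab)$total, 10000L)
})

test_that("read-count conservation holds across noise levels", {
  x <- small_ref()
  for (e in c(0, 0.01, 0.05)) {
    sim <- simulate_reads(dplyr::mutate(x$ref$entries,
                                        frequency = rep(1 / dplyr::n(), dplyr::n())),
                          n_reads = 2000, error_rate = e, seed = 31)
    g <- glance(classify_reads(sim$reads, x$ref))
    expect_equal(g$assigned + g$ambiguous + g$unassigned, 2000L)
  }
})

test_that("paired reads must agree on a single entry", {
  x <- small_ref()
  tpl <- x$ref$entries
  sim <- simulate_reads(dplyr::mutate(tpl, frequency = rep(1 / nrow(tpl), nrow(tpl))),
                        n_reads = 1000, error_rate = 0, paired = TRUE, seed = 41)
  ab <- classify_reads(sim$reads, x$ref, max_mismatch = 1)
  expect_equal(glance(ab)$total, 1000L)
  expect_gt(glance(ab)$assigned, 0L)
  truth_counts <- sim$truth$true_count[match(ab$design, sim$truth$design)]
  assigned <- glance(ab)$assigned
  # assigned pairs follow the truth (ambiguous pairs drop whole designs'
  # reads only when two barcodes share a flank-length prefix/suffix)
  expect_true(all(ab$read_count <= truth_counts))
  # a discordant pair is ambiguous or unassigned, never assigned
  bc <- tpl$barcode[1:2]
  half <- nchar(bc) %/% 2
  mixed <- list(substr(bc[1], 1, half[1]),
                chimeraforge:::revcomp(substr(bc[2], nchar(bc[2]) - half[2] + 1,
                                              nchar(bc[2]))))
  ab2 <- classify_reads(mixed, x$ref, max_mismatch = 0)
  expect_equal(glance(ab2)$assigned, 0L)
})

test_that("an empty reference is refused", {
  x <- small_ref()
  empty <- x$ref
  empty$entries <- empty$entries[0, ]
  expect_error(classify_reads("ACGT", empty), "empty reference")
})

test_that("enrichment comparison computes pseudo-counted fold changes", {
  x <- small_ref()
  tpl <- x$ref$entries
  n <- nrow(tpl)
  pre_reads <- rep(tpl$barcode, rep(10, n))
  post_counts <- rep(10, n); post_counts[1] <- 200; post_counts[2] <- 0
  post_reads <- rep(tpl$barcode, post_counts)
  pre <- classify_reads(pre_reads, x$ref, library_id = "pre")
  post <- classify_reads(post_reads, x$ref, library_id = "post")
  er <- compare_enrichment(pre, post, theta = 0.005, pseudo = 1e-6)
  r1 <- er[er$design == tpl$design[1], ]
  expect_equal(r1$log2_fold_change,
               log2((r1$freq_post + 1e-6) / (r1$freq_pre + 1e-6)))
  expect_gt(r1$log2_fold_change, 0)
  expect_true(r1$passes_abundance_threshold)
  # present pre, absent post: large negative fold change bounded by pseudo
  r2 <- er[er$design == tpl$design[2], ]
  expect_lt(r2$log2_fold_change, 0)
  expect_gte(r2$log2_fold_change, log2(1e-6 / (r2$freq_pre + 1e-6)))
  expect_false(r2$passes_abundance_threshold)
  # flag definition: exactly freq_post >= theta
  expect_identical(er$passes_abundance_threshold, er$freq_post >= 0.005)
})

test_that("identical abundance tables give zero fold change everywhere", {
  x <- small_ref()
  reads <- rep(x$ref$entries$barcode, 5)
  ab <- classify_reads(reads, x$ref)
  er <- compare_enrichment(ab, ab)
  expect_true(all(er$log2_fold_change == 0))
})

test_that("tables from different references cannot be compared", {
  x <- small_ref(303)
  y <- small_ref(304)
  ab1 <- classify_reads(x$ref$entries$barcode, x$ref)
  ab2 <- classify_reads(y$ref$entries$barcode, y$ref)
  expect_error(compare_enrichment(ab1, ab2), "different references")
})
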