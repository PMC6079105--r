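test_that("the paper-scale fixture reproduces the published counts", {
  ds <- make_domain_fixture(paper_scale_spec(seed = 1))
  g <- glance(ds)
  expect_equal(g$n_dbd, 15L)
  expect_equal(g$n_end_total, 119L)
  expect_equal(g$n_lnk_options, 19L)
  expect_equal(g$n_lbd_variants, 30L)
  ext <- nchar(ds$ends$extension_cds)
  expect_equal(range(ext[ext > 0]), c(3L, 120L))
  lnk <- nchar(ds$linkers$cds)
  expect_equal(max(lnk), 123L)
})

test_that("fixtures are deterministic under the seed and motif-free", {
  spec <- fixture_spec(n_dbd = 3, ends_per_dbd = 2, n_lnk = 3, n_lbd = 3,
                       seed = 2718)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  ds1 <- make_domain_fixture(spec, dir = td1)
  ds2 <- make_domain_fixture(spec, dir = td2)
  expect_identical(ds1, ds2)
  expect_identical(readLines(file.path(td1, "domains.fasta")),
                   readLines(file.path(td2, "domains.fasta")))
  expect_true(file.exists(file.path(td1, "manifest.json")))
  # every sequence scrubs to itself: zero scrub operations needed
  for (s in c(ds1$dbds$core_cds, ds1$lbds$cds, ds1$od_cds))
    expect_identical(scrub_restriction_sites(s), s)
})

test_that("length constraints are validated on the spec", {
  expect_error(fixture_spec(lnk_len_range = c(4, 10), seed = 1),
               "divisible by 3")
  expect_error(fixture_spec(seed = 1, ends_per_dbd = 0), "CORE")
  expect_error(fixture_spec(n_dbd = 1), "seed")
})

test_that("read simulation honours composition, errors and determinism", {
  tpl <- tibble::tibble(design = c("a", "b", "c"),
                        barcode = c(strrep("ACGT", 15), strrep("GGCA", 15),
                                    strrep("TTCG", 15)),
                        frequency = c(0.5, 0.3, 0.2))
  sim1 <- simulate_reads(tpl, 5000, error_rate = 0, seed = 5)
  sim2 <- simulate_reads(tpl, 5000, error_rate = 0, seed = 5)
  expect_identical(sim1$reads, sim2$reads)
  # error-free reads are exact reference sequences
  expect_true(all(sim1$reads %in% tpl$barcode))
  # multinomial draw within 3 sigma of expectation
  for (i in 1:3) {
    p <- tpl$frequency[i]
    expect_lt(abs(sim1$truth$true_count[i] - 5000 * p),
              3 * sqrt(5000 * p * (1 - p)) + 1)
  }
  expect_equal(sum(sim1$truth$true_frequency), 1)
  # errors perturb reads at roughly the requested rate
  sim3 <- simulate_reads(tpl, 2000, error_rate = 0.02, seed = 6)
  mism <- mapply(function(r, d) {
    bc <- tpl$barcode[tpl$design == d]
    sum(strsplit(r, "")[[1]] != strsplit(bc, "")[[1]])
  }, sim3$reads, sim3$read_design)
  rate <- sum(mism) / (2000 * 60)
  expect_lt(abs(rate - 0.02), 0.005)
})

test_that("invalid read-simulation inputs are refused", {
  tpl <- tibble::tibble(design = "a", barcode = "ACGTACGT", frequency = 0.9)
  expect_error(simulate_reads(tpl, 10, seed = 1), "sum to 1")
  tpl$frequency <- 1
  expect_error(simulate_reads(tpl, 0, seed = 1), "positive")
  expect_error(simulate_reads(tpl, 10), "seed")
})

test_that("FASTQ output round-trips through Biostrings", {
  tpl <- tibble::tibble(design = "a", barcode = strrep("ACGT", 10),
                        frequency = 1)
  sim <- simulate_reads(tpl, 10, error_rate = 0, seed = 2)
  td <- withr::local_tempdir()
  write_reads_fastq(sim$reads, file.path(td, "reads.fastq"))
  back <- Biostrings::readDNAStringSet(file.path(td, "reads.fastq"),
                                       format = "fastq")
  expect_equal(as.character(back, use.names = FALSE), sim$reads)
})

test_that("a single fit design takes over after one round in infinite-sample mode", {
  spec <- enrichment_sim_spec(frequencies = c(0.25, 0.25, 0.25, 0.25),
                              fitness = c(1, 0, 0, 0), rounds = 1,
                              cells_per_round = Inf, seed = 1)
  traj <- simulate_enrichment(spec)
  final <- traj[traj$round == 1, ]
  expect_equal(final$frequency, c(1, 0, 0, 0))
})

test_that("equal fitness leaves expected frequencies unchanged", {
  f0 <- c(0.4, 0.35, 0.25)
  spec <- enrichment_sim_spec(frequencies = f0, fitness = rep(0.6, 3),
                              rounds = 5, cells_per_round = Inf, seed = 1)
  traj <- simulate_enrichment(spec)
  expect_equal(traj$frequency[traj$round == 5], f0)
})

test_that("the selection recursion multiplies frequency ratios by the fitness ratio", {
  spec <- enrichment_sim_spec(frequencies = c(0.5, 0.5),
                              fitness = c(0.9, 0.1), rounds = 4,
                              cells_per_round = Inf, seed = 1)
  traj <- simulate_enrichment(spec)
  for (r in 1:4) {
    fr <- traj$frequency[traj$round == r]
    prev <- traj$frequency[traj$round == r - 1]
    expect_equal((fr[1] / fr[2]) / (prev[1] / prev[2]), 9, tolerance = 1e-9)
  }
})

test_that("finite sampling converges on the infinite-sample recursion", {
  f0 <- c(0.6, 0.3, 0.1)
  w <- c(0.2, 0.5, 0.9)
  exact <- simulate_enrichment(enrichment_sim_spec(
    frequencies = f0, fitness = w, rounds = 3, cells_per_round = Inf, seed = 1))
  finite <- simulate_enrichment(enrichment_sim_spec(
    frequencies = f0, fitness = w, rounds = 3, cells_per_round = 2e6, seed = 2))
  expect_equal(finite$frequency[finite$round == 3],
               exact$frequency[exact$round == 3], tolerance = 0.01)
})

test_that("the negative sort removes repression-incompetent designs", {
  spec <- enrichment_sim_spec(frequencies = c(0.5, 0.5), fitness = c(0.5, 0.5),
                              repression_competent = c(TRUE, FALSE),
                              rounds = 1, cells_per_round = Inf, seed = 1)
  traj <- simulate_enrichment(spec)
  expect_equal(traj$frequency[traj$round == 0], c(1, 0))
})

test_that("invalid enrichment specs are refused", {
  expect_error(enrichment_sim_spec(frequencies = c(0.5, 0.6),
                                   fitness = c(1, 1), seed = 1), "sum to 1")
  expect_error(enrichment_sim_spec(frequencies = c(0.5, 0.5),
                                   fitness = c(2, 1), seed = 1), "\\[0, 1\\]")
  expect_error(enrichment_sim_spec(frequencies = c(0.5, 0.5),
                                   fitness = c(1, 1), sorted_fraction = 0,
                                   seed = 1), "sorted_fraction")
})
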