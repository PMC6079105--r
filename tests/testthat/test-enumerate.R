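test_that("design counts match the brute-force product on random small sets", {
  for (seed in 1:4) {
    n_dbd <- sample(1:3, 1)
    ds <- make_domain_fixture(fixture_spec(
      n_dbd = n_dbd, ends_per_dbd = sample(1:3, n_dbd, replace = TRUE),
      n_lnk = sample(1:3, 1), n_lbd = sample(1:3, 1), seed = seed * 31))
    g <- glance(ds)
    # oracle: explicit cartesian product of component identities
    oracle <- nrow(expand.grid(end = ds$ends$name, lnk = ds$linkers$name,
                               lbd = ds$lbds$name, sp = c(TRUE, FALSE),
                               od = c(TRUE, FALSE)))
    en <- enumerate_chimeras(ds, include_od = "both", sequences = FALSE)
    expect_equal(nrow(en), oracle)
    expect_equal(nrow(en),
                 g$n_end_total * g$n_lnk_options * g$n_lbd_variants * 2L)
    expect_equal(anyDuplicated(en$name), 0L)
  }
})

test_that("a 1x1x1 set without OD yields the two SP states", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 1, ends_per_dbd = 1, n_lnk = 1,
                                         n_lbd = 1, seed = 9))
  en <- enumerate_chimeras(ds, include_od = "without")
  expect_equal(nrow(en), 2L)
  expect_setequal(en$sp_included, c(TRUE, FALSE))
})

test_that("canonical names parse back to their components", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = 2, n_lnk = 2,
                                         n_lbd = 2, seed = 21))
  en <- enumerate_chimeras(ds, sequences = FALSE)
  parsed <- parse_chimera_name(en$name)
  expect_identical(parsed$end, en$end)
  expect_identical(parsed$linker, en$linker)
  expect_identical(parsed$lbd, en$lbd)
  expect_identical(parsed$sp_included, en$sp_included)
  expect_identical(parsed$od_included, en$od_included)
  # and re-naming reproduces the names (bijection)
  expect_identical(
    name_chimera(parsed$end, parsed$linker, parsed$lbd, parsed$sp_included,
                 parsed$od_included),
    en$name)
})

test_that("hyphens in component names are rejected", {
  expect_error(name_chimera("Lac-I", "noLNK", "GGBP", TRUE, TRUE), "hyphen|'-'")
})

test_that("emitted CDSs are in frame with no internal stops", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = 2, n_lnk = 2,
                                         n_lbd = 2, seed = 33))
  en <- enumerate_chimeras(ds)
  expect_true(all(nchar(en$cds) %% 3 == 0))
  expect_false(any(vapply(en$cds, chimeraforge:::has_internal_stop, logical(1))))
  # structural identity: CDS is the concatenation of its parts
  row <- en[en$linker != "noLNK" & en$sp_included & !en$od_included, ][1, ]
  expect_identical(
    row$cds,
    paste0(ds$dbds$core_cds[ds$dbds$name == row$dbd],
           ds$ends$extension_cds[ds$ends$name == row$end],
           ds$linkers$cds[ds$linkers$name == row$linker],
           ds$lbds$cds[ds$lbds$name == row$lbd]))
  # nSP designs drop exactly the signal-peptide codons
  r2 <- en[!en$sp_included & !en$od_included & en$lbd == row$lbd &
             en$end == row$end & en$linker == row$linker, ][1, ]
  sp_nt <- ds$lbds$sp_codons[ds$lbds$name == row$lbd] * 3L
  expect_equal(nchar(row$cds) - nchar(r2$cds), sp_nt)
})

test_that("colliding CDS sequences are emitted and flagged", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 1, ends_per_dbd = 2, n_lnk = 2,
                                         n_lbd = 1, seed = 41))
  # force a collision: END extension equals a linker CDS
  ds$linkers$cds[2] <- ds$ends$extension_cds[nzchar(ds$ends$extension_cds)][1]
  en <- enumerate_chimeras(ds, include_od = "without", sp = "with")
  dup <- en[en$dup_cds, ]
  expect_gte(nrow(dup), 2L)
  expect_true(any(duplicated(dup$cds)))
  expect_equal(anyDuplicated(en$name), 0L)
})

test_that("insert length is the END plus LNK nucleotide count", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = 3, n_lnk = 3,
                                         n_lbd = 1, seed = 55))
  en <- enumerate_chimeras(ds, sequences = FALSE)
  ext <- setNames(nchar(ds$ends$extension_cds), ds$ends$name)
  lnk <- setNames(nchar(ds$linkers$cds), ds$linkers$name)
  expect_identical(en$insert_length_nt,
                   unname(ext[en$end] + lnk[en$linker]))
})

test_that("the design manifest writes FASTA and TSV", {
  ds <- make_domain_fixture(fixture_spec(seed = 61))
  en <- enumerate_chimeras(ds, include_od = "without")
  td <- withr::local_tempdir()
  write_design_manifest(en, file.path(td, "lib.fasta"), file.path(td, "lib.tsv"))
  fa <- Biostrings::readDNAStringSet(file.path(td, "lib.fasta"))
  expect_equal(length(fa), nrow(en))
  expect_identical(as.character(fa[[1]]), en$cds[1])
})
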