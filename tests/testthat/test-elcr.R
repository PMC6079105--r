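test_that("junction classification follows the insert-length class scheme", {
  expect_identical(classify_junction(0L), "I")
  expect_identical(classify_junction(3L), "III")
  expect_identical(classify_junction(33L), "III")
  expect_identical(classify_junction(36L), "II")
  expect_identical(classify_junction(66L), "II")
  expect_identical(classify_junction(69L), "IV")   # smallest codon multiple > 66
  expect_error(classify_junction(-3L), "non-negative")
  expect_error(classify_junction(4L), "multiple of 3")
  # class is non-decreasing in insert length under the defaults
  cls <- classify_junction(seq(0L, 243L, 3L))
  expect_true(all(diff(match(cls, c("I", "III", "II", "IV"))) >= 0))
})

test_that("staple counts match the class table for inserts 0 to 243", {
  set.seed(77)
  left <- rand_cds(90); right <- rand_cds(90)
  counts <- class_staple_counts()
  for (n in seq(0L, 243L, 3L)) {
    jd <- design_staples(left, right, if (n) rand_dna(n) else "")
    want <- counts[counts$assembly_class == jd$assembly_class, ]
    expect_equal(sum(jd$staples$role == "infra"), want$n_infra)
    expect_equal(sum(jd$staples$role == "supra"), want$n_supra)
  }
})

test_that("staples have the documented strandedness and geometry", {
  set.seed(13)
  left <- rand_cds(90); right <- rand_cds(90); ins <- rand_dna(120)
  jd <- design_staples(left, right, ins)
  final <- paste0(left, ins, right)
  st <- tidy(jd)
  # Supra = coding-strand substrings; Infra = template-strand substrings
  for (s in st$sequence[st$role == "supra"])
    expect_true(grepl(s, final, fixed = TRUE))
  for (s in st$sequence[st$role == "infra"])
    expect_true(grepl(s, chimeraforge:::revcomp(final), fixed = TRUE))
  # the three Supras tile the insert exactly, no gap, no overlap
  expect_identical(paste(st$sequence[st$role == "supra"], collapse = ""), ins)
  expect_true(all(nchar(st$sequence) <= jd$params$max_oligo_len))
  expect_true(all(st$phosphorylated_5p))
})

test_that("fragments shorter than the annealing arm are rejected", {
  expect_error(design_staples("ACGTACGT", strrep("ACGT", 20)),
               "shorter than arm_len")
})

test_that("a correct Class I design reconstructs the chimera exactly", {
  set.seed(5)
  left <- rand_cds(75); right <- rand_cds(81)
  jd <- design_staples(left, right, "")
  prod <- simulate_assembly(c(left, right), jd, cycles = 2)
  expect_equal(nrow(prod), 1L)
  expect_identical(prod$product, paste0(left, right))
})

test_that("a one-nucleotide gap at a nick yields no full-length product", {
  set.seed(6)
  left <- rand_cds(75); right <- rand_cds(81)
  jd <- design_staples(left, right, "")
  # delete the base of the splint that abuts the nick: gap, unligatable
  broken <- jd$staples
  s <- broken$sequence[1]
  arm <- jd$params$arm_len
  broken$sequence[1] <- paste0(substr(s, 1, arm - 1), substr(s, arm + 1, nchar(s)))
  prod <- simulate_assembly(c(left, right), broken, cycles = 4)
  expect_equal(nrow(prod), 0L)
})

test_that("the product set grows monotonically with cycles; Class IV needs several", {
  set.seed(7)
  left <- rand_cds(90); right <- rand_cds(90); ins <- rand_dna(120)
  jd <- design_staples(left, right, ins)
  prods <- lapply(1:4, function(k)
    simulate_assembly(c(left, right), jd, cycles = k)$product)
  for (k in 2:4) expect_true(all(prods[[k - 1]] %in% prods[[k]]))
  expect_equal(length(prods[[1]]), 0L)   # one cycle cannot chain all nicks
  expect_identical(prods[[4]], paste0(left, ins, right))
})

test_that("designed staples reconstruct random junctions across all classes", {
  set.seed(99)
  for (n in c(0L, 3L, 15L, 33L, 45L, 66L, 69L, 150L, 243L)) {
    left <- rand_cds(sample(seq(60, 120, 3), 1))
    right <- rand_cds(sample(seq(60, 120, 3), 1))
    jd <- design_staples(left, right, if (n) rand_dna(n) else "")
    expect_true(verify_junction_design(jd, cycles = 6),
                label = sprintf("insert %d nt (class %s)", n, jd$assembly_class))
  }
})

test_that("library-wide staple design covers every distinct junction", {
  ds <- make_domain_fixture(fixture_spec(n_dbd = 2, ends_per_dbd = 2, n_lnk = 2,
                                         n_lbd = 2, seed = 15))
  en <- enumerate_chimeras(ds, include_od = "without", sequences = FALSE)
  sheet <- design_library_staples(en, ds)
  n_junctions <- nrow(dplyr::distinct(en, dbd, end, linker, lbd, sp_included))
  expect_equal(length(unique(sheet$junction_id)), n_junctions)
  expect_true(all(sheet$role %in% c("supra", "infra")))
})
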