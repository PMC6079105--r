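# deterministic random-sequence helpers used across tests

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_cds <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0)
  sense <- setdiff(
    apply(expand.grid(b <- c("A", "C", "G", "T"), b, b), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_nt / 3, replace = TRUE), collapse = "")
}

tiny_domain_set <- function(seed = 101, ...) {
  make_domain_fixture(fixture_spec(seed = seed, ...))
}

translate_via_biostrings <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}
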