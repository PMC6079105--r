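# chimeraforge

Design tooling for combinatorial libraries of **chimeric bacterial
transcription factors** — fusion proteins of the form

```
Nt — DBD — (LNK) — LBD — (OD) — Ct
```

where a DNA-binding domain (DBD) taken from a transcriptional repressor is
fused, optionally through a linker (LNK), to a periplasmic binding protein
acting as ligand-binding domain (LBD), optionally extended by an
oligomerization domain (OD). Each DBD contributes several length variants
(its minimal "CORE" plus extended "ENDS"), and each LBD enters with and
without its native signal peptide (SP/nSP). A library built from 119
DBD-END variants, 19 junction options, 30 LBD variants and an OD toggle
spans 119 × 19 × 30 × 2 = 135,660 distinct fusion genes.

The package implements the dry-lab side of building and screening such a
library:

* **Domain registry** — load/validate domain collections (FASTA + TSV),
  with codon-aware *silent* removal of forbidden Type IIS restriction sites
  (`scrub_restriction_sites()`): minimal synonymous substitutions,
  deterministic tie-breaking, identical translation guaranteed.
* **Enumeration** — every admissible fusion gene with a canonical,
  bijectively parseable name (`LacI-GGBP-OD`, `LmrR-BzdB1_nSP`, ...),
  in-frame CDS construction and per-junction insert metrics
  (`enumerate_chimeras()`, `name_chimera()`).
* **eLCR staple design** — enhanced ligase-chain-reaction assembly:
  junctions are classed by insert length (Class I: direct join, one Infra
  staple; Classes II/III: 3–66 nt insert, one Infra + one Supra; Class IV:
  >66 nt, two Infra + three Supra), Supra/Infra oligos are designed per
  junction (`design_staples()`), and every design can be verified in silico
  by a cycle-wise melt/anneal/ligate simulation (`simulate_assembly()`) and
  by the Type IIS + streptavidin + USER adapter-processing round trip
  (`simulate_adapter_processing()`).
* **Reporter promoters** — each DBD's operator box is grafted into a σ70
  promoter scaffold while preserving the −35/−10 hexamers (≤2 substitutions
  each) and their spacing (`build_promoter_panel()`).
* **Junction profiling** — mismatch-tolerant classification of
  junction-spanning amplicon reads into per-chimera abundance tables and
  pre/post-enrichment comparisons at the 0.5 % reporting threshold
  (`build_reference()`, `classify_reads()`, `compare_enrichment()`).
* **Synthetic fixtures** — seeded generators for every input the workflow
  consumes, including a count-matched paper-scale domain set, read
  simulation with known composition, and sort-seq enrichment trajectories.

All user-facing functions take and return tidy data frames; results carry
`tidy()`/`glance()` summaries and `autoplot()` methods.

## Worked example

```r
library(chimeraforge)

ds <- make_domain_fixture(paper_scale_spec(seed = 1))
glance(ds)
#> # A tibble: 1 × 6
#>   n_dbd n_end_total n_lnk_options n_lbd n_lbd_variants od_len_nt
#>   <int>       <int>         <int> <int>          <int>     <int>
#> 1    15         119            19    15             30        60

nrow(enumerate_chimeras(ds, include_od = "both", sequences = FALSE))
#> [1] 135660
nrow(enumerate_chimeras(ds, include_od = "without",
                        ends = "core_only", sp = "with", sequences = FALSE))
#> [1] 4275

# staples for the longest (Class IV) junction, then verify in silico
end_i <- which.max(nchar(ds$ends$extension_cds))   # 120-nt END
lnk_i <- which.max(nchar(ds$linkers$cds))          # 123-nt LNK
jd <- design_staples(ds$dbds$core_cds[1], ds$lbds$cds[1],
                     insert = paste0(ds$ends$extension_cds[end_i],
                                     ds$linkers$cds[lnk_i]),
                     junction_id = "demo")
glance(jd)
#> # A tibble: 1 × 5
#>   junction_id assembly_class insert_length_nt n_infra n_supra
#>   <chr>       <chr>                     <int>   <int>   <int>
#> 1 demo        IV                          243       2       3
verify_junction_design(jd)
#> [1] TRUE

# reporter-promoter panel: 14 operator-grafted designs + the scaffold itself
panel <- build_promoter_panel(make_scaffold_fixture(), ds)
table(panel$unchanged)
#> FALSE  TRUE
#>    14     1
```

The enumeration reports 135,660 possible fusion genes (67,830 per
expression-vector context) and 4,275 "core chimeras"; the Class IV junction
gets its 2 Infra + 3 Supra staples and the assembly simulation reconstructs
the intended CDS exactly; the 15-DBD promoter panel yields 14 modified
promoters plus one unchanged (the scaffold's cognate repressor).

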