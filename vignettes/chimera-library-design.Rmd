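---
title: "Designing and verifying chimeric transcription-factor libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying chimeric transcription-factor libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraforge)
library(dplyr)
```

## The design problem

A chimeric bacterial transcription factor couples a repressor's DNA-binding
domain (DBD) to a periplasmic binding protein serving as ligand-binding
domain (LBD): the DBD keeps binding its operator, while derepression is now
controlled by the LBD's small-molecule ligand. Because the functional
boundary of a DBD is rarely known, each DBD enters the library as a minimal
CORE plus several C-terminally extended END variants; DBD and LBD may be
bridged by linkers (LNK) of varying length and flexibility; each LBD enters
with and without its native signal peptide (SP/nSP); and a C-terminal
oligomerization domain (OD) may or may not be fused. The library is the full
cartesian product

$$N = n_\mathrm{END} \times n_\mathrm{LNK} \times n_\mathrm{LBD\,variants}
      \times n_\mathrm{OD\ states},$$

which at the scale modeled here is $119 \times 19 \times 30 \times 2 =
135{,}660$ fusion genes, $67{,}830$ per expression-vector (OD) context, with
a "core chimera" microcosm of $15 \times 19 \times 15 = 4{,}275$ designs.

Two counting conventions make this arithmetic exact, and we adopt both as
representation invariants:

* the CORE-only variant of each DBD is an END extension of length zero, so
  "END variants" is a single flat list (119 entries across 15 DBDs,
  consistent with roughly eight variants per DBD);
* "no linker" is a first-class junction option named `noLNK` with an empty
  CDS, counted among the 19 linker options.

Whether the published counts intended these exact conventions is not
decidable from the prose; the alternatives (no-LNK in addition to 19
linkers, COREs not counted among the ENDS) fail to reproduce the printed
totals, which is why we fixed them this way.

Nomenclature is `DBD-LNK-LBD_nSP-OD`, with the LNK token omitted for
`noLNK`, `_nSP` marking a stripped signal peptide and `-OD` the
oligomerization fusion. The grammar as published omits the END variant,
which would make names non-unique across END variants; we therefore let the
leading token be the END-variant identifier, and name each CORE entry after
its DBD — CORE-only designs (the only ones with published names) then print
exactly as expected, e.g. `LacI-GGBP-OD`, while extended variants remain
distinguishable and every name parses back to its components.

## Assembly classes and staple design

Enhanced LCR (eLCR) assembles each fusion gene from two dsDNA fragments
(DBD-CORE side, LBD side) plus single-stranded staple oligonucleotides.
*Supra* staples run with the coding strand, *Infra* staples with the
template strand. The insert between CORE and LBD (END + LNK nucleotides,
0–243 nt at paper scale) determines the assembly class:

| class | insert (nt) | staples |
|-------|------------|---------|
| I     | 0          | 1 Infra |
| III   | 3 – `t_23` | 1 short Infra + 1 Supra |
| II    | `t_23` – 66 | 1 long Infra + 1 Supra |
| IV    | > 66       | 2 Infra + 3 Supra |

Parameters (all in `class_params()`):

* `t_23 = 33` nt — the II/III boundary. The source material only states
  that both classes live in the 3–66 nt range and differ in Infra length;
  the midpoint is the natural split and it is configurable because nothing
  observable in this package depends on it (both classes get the same
  staple multiset).
* `ii_iii_max = 66` nt — the largest insert the two-oligo scheme handles.
* `arm_len = 25` nt — bases a staple anneals over each flanking fragment.
  Typical LCR bridging half-sites are 20–30 nt at Taq-ligase temperatures;
  25 is the midpoint and keeps every staple within synthesis limits.
* `max_oligo_len = 130` nt — array-synthesis cap. The per-domain base
  counts inside the published oligos are not recoverable from text, so the
  cap is configuration with a default matching common microarray platforms.
* `min_anneal = 10` nt — the shortest overlap the assembly simulator treats
  as a stable annealing event (staples shorter than this, e.g. a 3-nt
  Supra, are held in the nick by their splint and anneal over their full
  length).

Geometry: Supra staples carry insert sequence only — the fragments supply
the rest of the coding strand, so the three Class IV Supras tile the insert
exactly, abutting without gap or overlap. Infra staples are junction
bridges; in Classes II/III one Infra spans arm + insert-complement + arm,
and in Class IV the two Infras extend from their fragment arm over the
insert as far as the length cap allows (`max_oligo_len - arm_len`), which
is what lets them splint the internal Supra–Supra nicks. Whether the
published "long Infra" of Class II carries insert complement beyond its
arms is unstated; carrying it is the only choice that lets a single Infra
splint both insert nicks, so we adopt it.

## Assembly and adapter-processing simulation

`simulate_assembly()` models the thermal program as discrete species-level
cycles: melt everything, anneal exact reverse-complement overlaps of at
least `min_anneal` bases, ligate abutting 5′-phosphate/3′-OH nicks held by
a splint. Every species is treated as present in excess, so the species
pool — and therefore the product set — grows monotonically with cycles; a
strand ligated in one cycle serves as splint in later ones, which is how
the coding strand assembled in early cycles templates its complement (and
how Class IV designs need ≥ 3 cycles while Class I completes in one).
Thermodynamics are deliberately out of scope: annealing is exact-complement
with a minimum overlap, with no mismatch tolerance, Tm model or ramp-rate
dependence, because the temperature optimization of the real protocol is
empirical. A *full-length product* is a ligated strand that runs from the
left fragment's terminus to the right fragment's terminus (tracked by piece
provenance, canonicalized to coding-strand orientation). For long Class IV
inserts the template strand necessarily retains a central gap — the two
Infras cannot tile a 243-nt insert under the 130-nt cap — matching the
protocol, where assembly products are PCR-amplified so only one contiguous
strand is needed.

Adapter processing (`simulate_adapter_processing()`) inverts amplicon
construction exactly: Type IIS digestion (BsmFI `GGGAC` 10/14 for Supra
pools, BspQI `GCTCTTC` 1/4 for Infra pools — offsets from the enzymes'
standard definitions, kept in `type_iis_enzymes()`, not in code) removes
the non-biotinylated end; streptavidin capture plus alkaline denaturation
leaves the biotinylated strand; USER cleavage at the uracil mark releases
the payload. The 3′ adapters place the recognition site on the template
strand with a spacer equal to the enzyme's coding-strand cut offset, so the
cut lands exactly on the payload boundary. Biotin and uracil are metadata,
never sequence characters. The published adapter sequences are not printed;
the defaults here are synthetic sequences satisfying the motif and mark
invariants.

Restriction-site scrubbing (`scrub_restriction_sites()`) is what guarantees
payloads enter this pipeline with exactly one recognition site (the
adapter's): every forbidden motif occurrence, on either strand, is removed
by the smallest number of synonymous codon substitutions, ties broken by
the lexicographically smallest sequence — deterministic without a seed.
Substitutions that would create a new site elsewhere are rejected.
Sequences where no synonymous substitution can clear a site (e.g. a motif
pinned on Met/Trp codons) raise an error naming the position.

## Reporter promoters

`design_promoter()` grafts an operator box into a σ70 scaffold by pure
substitution — never insertion — so the −35/−10 spacing is preserved by
construction. Placements are tried in a fixed preference order: native
occurrence (the scaffold's own repressor; `unchanged = TRUE`), the spacer,
the region downstream of −10 (running past the transcription start site if
the operator is longer — the alternative, stretching the spacer, would
change polymerase recognition), and finally hexamer-overlapping placement
with at most `max_hexamer_mut = 2` substitutions per hexamer, minimizing
mutations and breaking ties leftmost. Placements outside the polymerase
contact region (upstream of −35 or past the TSS entirely) are not
considered, since bound repressor there could not occlude initiation.
Promoter *activity* is not predicted; the panel reports hexamer mutations
and placement region as proxies only, and basal-strength matching remains a
wet-lab concern.

## Junction profiling

The junction amplicon spans the DBD 3′ flank, the full END + LNK insert and
the LBD 5′ flank (`flank_len = 20` nt per side by default) — enough to
identify every component except the OD, which lies outside the amplified
region; designs differing only in OD state therefore share a barcode and
are reported as collisions. Classification is bounded-mismatch matching
rather than an external aligner call: it is bit-reproducible and
dependency-free, and the barcode design makes alignment trivial. A read is
assigned to the unique barcode within `max_mismatch` substitutions;
matching several barcodes makes it ambiguous, none unassigned, and mates of
a pair must agree. Counts are per fragment/pair. The conservation identity
assigned + ambiguous + unassigned = total holds on every run.

Two analysis choices deserve explanation:

* **Mismatch budget.** The library default is `max_mismatch = 2`, suitable
  for short amplicons. For full-length junction amplicons (40–280 nt) at a
  per-base error of 0.005, a 280-nt read carries more than two errors ~17 %
  of the time, and since dropout then depends on barcode length it would
  bias recovered frequencies. The binomial error model puts
  $P(>5 \text{ errors} \mid 280\,\mathrm{nt}) < 0.5\,\%$, so the recovery
  analyses in this package classify with `max_mismatch = 5`.
* **What "recovery" means.** Parameter-recovery runs compare recovered
  frequencies against the *realized* template composition recorded in the
  simulator's truth table, not against the pre-sampling probabilities:
  multinomial sampling noise at 50,000 reads over 100 designs is ~0.016
  total-variation distance by itself and is a property of the draw, not of
  the classifier. Against the realized truth, mean TVD across seeded runs
  is well below 0.01.

Enrichment comparison uses `log2((f_post + p)/(f_pre + p))` with a
pseudo-frequency defaulting to one over the smaller library's assigned
count, and flags designs at the 0.5 % post-selection abundance threshold
(`theta = 0.005`).

## What the synthetic fixtures emulate — and what they do not

`make_domain_fixture()` draws codon-valid sequences (61 sense codons,
uniform) with rejection sampling against the Type IIS motifs, so every
fixture validates with zero scrub operations. The paper-scale preset
reproduces the published *counts and length ranges* — 15 DBDs, 119 END
variants (8 per DBD, 7 for the last), 19 junction options, 15 LBDs with the
tabulated signal-peptide lengths, END extensions 3–120 nt, linkers up to
123 nt — using the real regulator and binding-protein *names* but synthetic
sequences throughout. Real domains have amino-acid composition bias,
repeats and GC structure that uniform codon draws do not; consequently,
passing tests demonstrate the correctness of the combinatorial, geometric
and counting logic, not robustness to repeat-induced mis-annealing or
homology-driven barcode collisions in real libraries. Likewise the read
simulator applies uniform substitution errors (no indels, no quality decay
along the read, no chimeric PCR artifacts), and the enrichment simulator
reduces sorting to a per-design recovery probability — one negative sort as
a competence filter, then iterated positive sorts — with no growth-rate or
toxicity dynamics beyond that flag. Its infinite-sample mode follows the
exact recursion $f' = f w / \sum f w$ and is used as the closed-form oracle
for the finite-sample sampler.

## Problem sizes and numerical choices

Test and acceptance runs use: full 135,660-design enumeration in
count-only mode (sequence construction is deferred — the manifest is the
expensive object, not the strings); 200 randomly parameterized junctions
across all four classes for the assembly oracle; 1,000 adapter round-trips
(500 per enzyme); ten seeded 50,000-read × 100-design recovery simulations.
These sizes keep the whole suite within a few minutes while leaving every
statistical margin wide (the recovery criterion passes by more than an
order of magnitude). Degenerate inputs are rejected rather than coerced:
IUPAC ambiguity codes, out-of-frame CDSs, internal stop codons and
non-codon-multiple insert lengths all raise errors naming the offending
record.

## Known limitations

* The real scaffold, operator placements, adapter and linker sequences of
  the published system are not reproduced — all sequence-level agreement is
  with synthetic fixtures; only counts, class structure and geometry are
  comparable to the published figures.
* The total number of synthesized oligos of the published library (223,170)
  depends on the real END/LNK length tables and is not reproducible here.
* The assembly simulator is species-level and deterministic: it verifies
  design correctness (can the intended product form, and is it unique at
  the species level), not yield, ligase kinetics or misassembly rates.
* Paired-end classification compares each mate against barcode
  prefixes/suffixes of the mate's length; reads longer than their barcode
  region (adapter read-through) are not modeled.
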