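---
title: "Designing cross-species intron-spanning genic markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cross-species intron-spanning genic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronspan)
```

## The marker-design problem

Many crop species lack the genomic resources for sequencing-based
genotyping, and PCR markers anchored in orthologous genes remain the
practical route to transferring genetic information from well-characterised
reference genomes to their under-studied relatives. Two opposing constraints
shape such markers. The primers must sit in sequence conserved enough to
anneal in *both* species — which means coding exons, where purifying
selection keeps divergence low. The amplicon, however, must capture enough
polymorphism to be informative within low-diversity germplasm — which means
introns, where divergence and indel accumulation are much faster. An
intron-spanning genic marker reconciles the two: exonic primers flanking at
least one intron, so the product is amplifiable across species yet
polymorphic within them.

`intronspan` implements this design logic as a pipeline of five stages:

1. **Gene structure.** Exon–intron junctions are taken from a GFF3
   annotation (`junctions_from_annotation()`) or recovered by spliced
   anchoring of the CDS onto its own genomic sequence (`map_junctions()`).
2. **Ortholog alignment.** The two species' CDSs are globally aligned
   (`global_align_cds()`), and both junction sets are projected onto
   alignment columns (`build_pair_structure()`).
3. **Conserved blocks.** Maximal gapless runs that avoid every junction
   column of either species, carrying at most a fixed number of mismatch
   columns, become the primer template regions (`conserved_blocks()`).
4. **Primer pairs.** Windows inside blocks are enumerated in both
   orientations, annotated with per-species melting temperatures and
   cross-species mismatches, paired under intron-spanning and product-size
   constraints, scored and ranked (`enumerate_primers()`, `pair_primers()`).
5. **Validation in silico.** Electronic PCR maps each primer onto whole
   genomes with bounded mismatches and classifies each pair as specific
   (one locus), non-specific (two or more) or non-amplifying
   (`run_ehtpcr()`); downstream, SNPs between parental amplicons are screened
   for restriction-site differences to yield CAPS markers (`find_caps()`).

## Coordinate conventions

All internal coordinates are 0-based half-open, including alignment columns
and BED output; GFF3 input and the human-readable report columns are the
only 1-based surfaces. Per-gene sequences always live on the coding strand,
so primer design never sees strand; genome-scale operations (electronic PCR)
work in forward-strand coordinates with explicit strand flags on hits.
A junction "at column *j*" means the intron interrupts that species' CDS
between columns *j − 1* and *j*.

## Junction recovery by spliced anchoring

A CDS and its own genomic locus are near-identical in exons, so a full
spliced dynamic program is unnecessary. `map_junctions()` instead finds
maximal exact anchor matches (k-mer seeded, default `anchor_k = 16`), chains
them colinearly by dynamic programming to maximise matched CDS coverage
(ties broken toward the leftmost genomic placement), and fails if coverage
falls below `min_coverage = 0.95`. Genomic gaps shorter than
`min_intron = 20` bp are treated as alignment noise rather than introns.
Because the true junction is ambiguous whenever the intron's start
coincidentally continues the next exon's sequence, each junction is then
slid within `refine_window = 10` bp to prefer canonical `GT..AG`, then
`GC..AG`, dinucleotides; if no canonical placement validates, the unshifted
chain boundary stands. On simulated multi-exon genes this recovers every
junction exactly in well over 95% of cases; the residual failures are genes
whose junction neighbourhood offers a competing canonical placement.

One representational limit is deliberate: exon blocks do not admit indels
within a block, so a chain whose genomic gap exceeds its CDS gap by less
than `min_intron` cannot be represented and is an error rather than a
silent merge. Genes with real sub-20-bp introns or exonic indels against
their own annotation fall outside the supported data class.

## Alignment and conserved blocks

`global_align_cds()` is an affine-gap Needleman–Wunsch (Gotoh) aligner with
defaults `match = +2`, `mismatch = −3`, `gap_open = −12`, `gap_extend = −2`
(a gap of length *L* scores `gap_open + (L−1)·gap_extend`), chosen for
coding DNA at roughly 70–95% identity. The traceback is deterministic:
diagonal, then up, then left on ties. The implementation is compiled (Rcpp);
tests verify score equality against an independent affine-gap implementation
and that the returned alignment reproduces both inputs and its own score.

Conserved blocks are maximal runs of gap-free columns, split structurally at
every junction column of either species — implementing "primers may not
cross splice junctions" as a property of the search space rather than a
post-filter. Runs are then partitioned so no block exceeds
`max_mismatches_per_block` (default 3, mirroring the per-primer mismatch
ceiling). The partition uses a recursive median-mismatch split: while a
segment holds too many mismatch columns, its median mismatch column is
removed and both sides are split recursively. Because the cut tree depends
only on the mismatch positions — not on the ceiling — lowering the ceiling
refines the same partition, so blocks are simultaneously disjoint *and*
nested across ceilings. A greedy left-to-right cut satisfies neither
requirement at once, which is why it was rejected.

## Primer enumeration, filters and scoring

Every window of length 18–24 nt inside every block is a candidate in both
orientations. The primer sequence is taken from the template species
(species A by default); melting temperature is computed per species against
that species' own allele, because the primer physically anneals to each
genome separately. Tm uses two-state nearest-neighbor thermodynamics with
the unified parameter set, an entropic monovalent-salt correction
(`ΔS + 0.368·(N−1)·ln[Na+]`) and `CT/4` for primer excess; defaults are
250 nM primer and 50 mM Na⁺.

Hard filters reject candidates with more than 3 cross-species mismatches,
any mismatch within 5 nt of the 3' end, or two mismatches at adjacent
positions — the mismatch geometries that most reliably kill extension.
An AT-rich 3' end (no G/C in the terminal 5 nt) is flagged by default and
optionally filtered, since the evidence there is weaker. GC content
(35–65%) and Tm bounds (55–62 °C, template species) complete the filters.

Pairs require the forward primer strictly upstream of the reverse, at least
one intron between them *in each species*, per-species genomic product sizes
within 300–2000 bp, and a template-species Tm difference of at most 3 °C.
The ranking score is a transparent linear penalty,

```
score = 100 − [ 3·mm_total + 8·mm_3' + (|Tm_fw−58| + |Tm_rv−58|)
                + 2·|Tm_fw−Tm_rv| + |mean(product) − 800|/100 ]
```

so a mismatch-free pair at the optimal Tm and preferred product size scores
exactly 100, and a single 3'-window mismatch costs exactly 11. The weights
are package choices (exposed in `primer_params()`), picked so that mismatch
geometry dominates Tm polish, which dominates product-size preference. Ties
break on fewer mismatches, then smaller inter-species product-size
difference, then leftmost forward primer — fully deterministic.
`refine_pairs()` is a pure filter over an existing result (never adds,
warns on looser criteria, re-ranks survivors), and the first report page
holds the top-scoring `min(60, n)` pairs.

## Electronic PCR

`run_ehtpcr()` follows a three-step workflow: deduplicate the primer pool,
map every unique primer onto each genome, and combine forward/reverse hits
into virtual amplicons. Mapping is *ungapped*: all positions on both strands
within Hamming distance `max_mismatches` (default 5) — primer annealing
across an indel essentially never primes, and the ungapped contract is
exhaustively testable against a brute-force scanner. Amplicons require
correctly oriented hits on one chromosome with a size between the summed
primer lengths and `max_product_size` (default 5000 bp; a package choice —
thermocycling extension times bound real products, but no universal ceiling
exists). A pair's status per genome is `specific` exactly when its distinct
amplicon intervals number one, `non_specific` at two or more.

Five mismatches on an 18–19-mer is permissive: the expected number of
chance Hamming-≤5 windows within a product-length neighbourhood of a true
site is of order one, independent of genome size, so short primers are
intrinsically prone to over-predicted side products at this tolerance. That
is a faithful property of mismatch-bounded mapping, not an artifact; the
`anchor3` option (require a mismatch-free 3' terminus, default off) is
provided for users who want annealing-realistic stringency.

## CAPS markers

`call_snps()` aligns two parental amplicon sequences with the same affine
aligner and reports substitution columns; indel runs are recorded separately
and never counted as SNPs. `find_caps()` digests both alleles with every
enzyme in a small editable table of common 6-cutters (top-strand and
reverse-complement site matches, palindromic sites canonicalised to avoid
double counting) and emits the enzymes whose fragment-length multisets
differ, annotated with the SNPs or indels overlapping a differential site.
Fragment lengths always sum to the sequence length. Partial digestion,
star activity and methylation sensitivity are not modelled; the shipped
enzyme table is a self-contained working set, not a catalogue.

## The simulator, and what passing tests do and do not show

`simulate_ortholog_pair()` generates an ancestral multi-exon gene (canonical
`GT..AG` introns, CDS length kept a multiple of 3) and derives two
descendants by independent per-site substitution — slow in exons, fast in
introns — plus short geometric indels (mean 3 bp) inside introns only, never
touching the splice dinucleotides. The stated identities are realised
*between the two descendants*: divergence is split over both lineages by
solving `d = 2p − (4/3)p²` for the per-lineage substitution probability, so
a setting of 0.97 yields a measured between-species exon identity of
0.97 ± 0.01 rather than an approximation. Defaults are 2–10 exons of
60–400 bp, introns of 80–2000 bp, exon identity 0.97, intron identity 0.60,
intron indel rate 0.02/bp, and 3 kb of random background on each side of
the gene — values representative of closely related plant ortholog pairs.
Each call consumes a single explicitly seeded RNG stream and leaves the
global RNG untouched, so every fixture is byte-reproducible.
`plant_paralog()` inserts a mutated copy of the gene span downstream of the
gene (so the original annotation remains valid), the canonical stress test
for amplification specificity.

The simulator deliberately omits several features of real genomes:
transition/transversion bias, codon structure within exons, repeat and
transposon landscapes, paralog families with partial-domain conservation,
and assembly gaps (`N` runs). Passing tests therefore demonstrate that the
algorithms are correct on their stated data class — uniform-background
genomes with canonical splice sites — not that wet-lab success rates on any
particular germplasm will match. Test and acceptance problem sizes (50 kb
mapping genomes, 100 simulated genes, 60-pair report pages) were chosen as
the smallest scales at which every contract is exercised with comfortable
statistical margins.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ortholog_pair(sim_params(seed = 1, n_exons = 4))
des <- design_markers(sim$a$gene, sim$b$gene)
glance(des)
tidy(des) |> first_page(10)
run_ehtpcr(first_page(tidy(des), 60),
           list(A = sim$a$genome, B = sim$b$genome))$report
autoplot(des)
```

## Known limitations

- The aligner is exact but quadratic; genes beyond ~10 kb of CDS are slow.
- Junction mapping assumes the CDS matches its locus near-perfectly; it is
  a placement tool, not a cross-species spliced aligner.
- Electronic PCR models primer binding as bounded Hamming distance, not
  annealing thermodynamics; it over-predicts products for short primers at
  high mismatch tolerance (see above).
- Primer-dimer and hairpin screening is out of scope, as is degenerate
  primer design.
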