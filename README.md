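# ssrmine

In-silico mining and characterization of polymorphic simple sequence repeat
(SSR, microsatellite) markers from a draft genome assembly plus low-coverage
resequencing reads of other accessions.

Marker developers working on crops with a reference assembly and a handful of
resequenced cultivars face the same funnel over and over: find perfect tandem
repeats in the assembly, cut out each repeat with enough flank for primers,
align pooled reads from the other accessions, keep the loci where reads show
variation in repeat-unit number but conserved flanks, check that primers can
be placed, and then — once the markers are genotyped on a diversity panel —
characterize them with the standard diversity statistics, cluster the panel,
and test Mendelian segregation in a mapping population. `ssrmine` implements
that whole funnel as composable R functions with a thin command-line layer,
plus a deterministic simulator that generates every input with known ground
truth so each stage can be validated end to end.

## What it computes

**Repeat detection.** Maximal perfect tandem repeats of 1–8 bp motifs, with
per-motif-length minimum unit counts (defaults: mono 10, di 6, tri 5,
tetra/penta/hexa 4, hepta/octa 3). A run reportable under several periods is
reported only under its shortest period; motifs are pooled into canonical
families under cyclic rotation and reverse complement (e.g. AAG/CTT).

**Spanning-read genotyping.** Instead of visual inspection of alignments,
a read "spans" a repeat when it contains the *k*-mer of flank immediately
left and right of the repeat (k = 15, ≤ 1 mismatch each); the repeat-unit
count in the read is the anchor-to-anchor gap divided by the motif length.
Each locus is then classified from its spanning reads: `not_polymorphic`,
`slightly_polymorphic` (variation in < 2% of reads), `clearly_polymorphic`,
plus `no_coverage` and `poor_alignment` guard states.

**Diversity statistics.** For a loci × accessions table of co-dominant
allele sizes:

- expected heterozygosity (gene diversity) `He = 1 − Σ pᵢ²`
- observed heterozygosity `Ho` = heterozygous genotypes / typed genotypes
- polymorphism information content
  `PIC = 1 − Σ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²` (Botstein), always ≤ He
- null-allele frequency by maximum likelihood under the null-allele model
  (a null heterozygote appears homozygous, a null homozygote fails to
  amplify); the sign is unconstrained, so heterozygote excess gives a
  negative estimate
- private alleles (alleles carried by exactly one accession)

**Clustering and segregation.** Binary allele-presence encoding, three
distance options (shared-allele, simple matching, Dice), neighbor-joining
and UPGMA dendrograms with Newick output; expected pseudo-testcross
segregation class (1:1, 1:1:1:1, 1:2:1) from the parental genotypes and
Pearson chi-square goodness of fit for the seedling counts.

## Worked example

Simulate a small study — 12 repeat loci (a third with A/T-only motifs, which
leave the funnel early), 7 resequenced cultivars at 20× with a repeat-unit
variant planted at three loci in 3 of the 7 cultivars — and run the funnel:

```r
library(ssrmine)

genome <- make_genome(n_loci = 12, motifs = c("ATG", "AAG", "AAT"), seed = 42)
reads  <- make_reads(genome, n_cultivars = 7,
                     variant_loci = genome$truth$locus_id[c(1, 4, 7)],
                     n_variant_cultivars = 3, coverage = 20, seed = 43)
report <- run_funnel(genome$sequences, reads$reads_by_locus)
report
#> SSR marker-discovery funnel
#>   input_loci               12
#>   after_at_removal         8
#>   after_fragment_filters   8
#>   no_coverage              0
#>   poor_alignment           0
#>   not_polymorphic          5
#>   slightly_polymorphic     0
#>   clearly_polymorphic      3
#>   primer_feasible          3
```

The four A/T-only loci are removed first; the three planted variant loci —
and no others — come out `clearly_polymorphic`, e.g.:

```r
subset(report$classification, status == "clearly_polymorphic")[1, ]
#>            locus_id              status n_aligned_reads n_spanning n_variant variant_fraction
#> 1 contig001_ssr0001 clearly_polymorphic             871         81        29        0.3580247
```

81 of the 871 aligned reads span the repeat; 29 of them carry a different
unit count, matching the 3/7 variant-cultivar share. Characterizing a
simulated 20-locus × 50-accession diversity panel:

```r
panel <- make_genotype_table(n_loci = 20, n_accessions = 50, seed = 44)
st <- diversity_stats(panel$table)
head(st, 3)
#>   locus_id n_alleles     He   Ho       PIC       f_null n_typed
#> 1 locus001         6 0.6916 0.70 0.6413568 -0.006296187      50
#> 2 locus002         4 0.6264 0.52 0.5601955  0.093221584      50
#> 3 locus003         5 0.5230 0.56 0.4863009 -0.020115557      50
summarize_diversity(st)$per_stat
#>   statistic         mean         min        max
#> 1 n_alleles  3.700000000  2.00000000 6.00000000
#> 2        He  0.552280000  0.27180000 0.81560000
#> 3        Ho  0.574000000  0.28000000 0.80000000
#> 4       PIC  0.487912826  0.23990238 0.78927348
#> 5    f_null -0.006528135 -0.08232388 0.09322158
```

PIC ≤ He at every locus, Ho tracks He (the panel is drawn under
Hardy–Weinberg), and the null-allele estimates scatter around zero because
no null allele was planted. A dendrogram and a segregation test:

```r
tree <- genotype_tree(panel$table, method = "nj")   # ape "phylo" object
chi_square_fit(c(80, 58), "1:1_female")
#> $chi2
#> [1] 3.507246
#> $df
#> [1] 1
#> $p_value
#> [1] 0.06110093
```

The same stages are available from a shell via the bundled CLI
(`inst/cli/ssrmine.R`): `find`, `extract`, `classify`, `primercheck`,
`stats`, `tree`, `segtest` and `simulate`, reading and writing FASTA,
SAM/BAM, TSV and Newick.

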