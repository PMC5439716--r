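---
title: "Mining polymorphic SSR markers in silico: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining polymorphic SSR markers in silico: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmine)
```

`ssrmine` turns a common marker-development workflow into tested code: mine
perfect tandem repeats from a draft assembly, select loci whose repeat-unit
number varies among resequenced accessions, screen their flanks for primer
placement, and characterize the resulting markers on a diversity panel and
a mapping population. This vignette explains the model behind each stage,
the tunable parameters and their defaults, the numerical choices, and what
the accompanying simulator does and does not emulate.

## Perfect-repeat detection

A repeat locus is a maximal run of a 1–8 bp motif repeated in perfect
tandem. Detection slides a period-*p* self-match over the sequence
(`s[i] == s[i+p]`), so a maximal run of matches of length *L* corresponds
to a tandem region of length *L + p*; the locus keeps only the
`floor((L+p)/p)` complete units, anchored at the leftmost character of the
run — partial trailing units never count. Three rules disambiguate:

* **Shortest period wins.** An A homopolymer is also a perfect (AA)n and
  (AAA)n run; it is reported only at period 1. Operationally a period-*p*
  candidate is discarded when its motif is itself a whole number of copies
  of a shorter string. For runs of at least two units this is equivalent to
  the "smallest period" rule (by the Fine–Wilf periodicity argument).
* **N never matches.** An N terminates every run; repeats on either side of
  an N are reported separately.
* **Leftmost anchoring.** Within one run, only the leftmost phase is
  reported, so (ATG)₅ is not additionally reported as (TGA)₄ one base in.

Minimum unit counts are per motif length and configurable
(`ssr_search_config()`), with defaults mono 10, di 6, tri 5, tetra, penta
and hexa 4 — the thresholds conventional for MISA-style genome scans. No
convention exists for hepta- and octanucleotide repeats; the default is 3
units, chosen so that the shortest reportable locus (21 bp) still exceeds
any shorter-period locus it could be confused with, and it is exposed in
the configuration rather than fixed.

Motifs are pooled into families under cyclic rotation and reverse
complement; the canonical representative is the lexicographically smallest
string in that orbit (so CTT, TTC, TCT, AAG, AGA and GAA are all "AAG").
This is the grouping used by the MISA statistics tools. Note that a motif
and its plain (unreversed) complement can fall in *different* families:
TAG canonicalizes to ACT, not to ATC, because complementation alone is not
in the orbit. Published family labels that pair a motif with its
complement are a looser labelling of the same biology.

Compound and interrupted repeats are deliberately out of scope: the mining
procedure this package implements uses perfect repeats only, because
allele sizes at perfect repeats are interpretable as unit-count changes.

## Fragment extraction and filtering

Each locus is excised with up to 250 bp of flank on either side (clipped at
contig ends), giving the reference fragment used for alignment and primer
design. Filters, applied in order with the first failure recorded as the
rejection reason:

| filter | default | rationale |
|---|---|---|
| `min_length` | 400 bp | shorter fragments leave too little unique sequence for reliable read alignment and primer placement |
| `min_flank` | 60 bp per side | room for a 27 nt primer plus placement slack; the mining convention only says flanks must be "sufficient", so the number is a package choice and is configurable |
| `min_flank_gc` | 0.20 | flanks of very low G+C cannot host a primer near a 60 °C annealing target; configurable, `NULL` disables |

Fragments that are exact duplicates or reverse complements of an earlier
fragment (assemblies contain both) are removed, keeping the first
occurrence in input order.

## Spanning-read repeat-unit counts

Visual inspection of alignment browsers — "variation in repeat number,
conserved flanks" — is replaced by a deterministic surrogate. For each
fragment the *anchors* are the `anchor_k` = 15 bases of flank immediately
adjacent to the repeat on each side. A read (searched on both strands)
yields a call only when both anchors occur exactly once, in order, with at
most `max_anchor_mismatch` = 1 mismatch each; the unit count is the
anchor-to-anchor gap divided by the motif length. The defaults trade off
two error modes: shorter anchors produce chance matches (a 15-mer has a
~5·10⁻⁷ per-position chance match even before mismatch tolerance), longer
anchors discard reads clipped near the repeat. Gaps that are not a whole
number of units are recorded as `non_integral` rather than rounded.

Classification of a locus from its calls:

* `no_coverage` — no aligned reads at all;
* `poor_alignment` — reads align but fewer than `min_spanning` = 8 span the
  repeat, or more than half of aligned reads have mapping quality 0 (the
  alignment cannot support a verdict);
* `not_polymorphic` — spanning reads but no variant evidence;
* `slightly_polymorphic` — variant evidence in fewer than
  `slight_threshold` = 2% of reads;
* `clearly_polymorphic` — at or above 2%.

Two choices deserve notice. First, the 2% denominator is ambiguous in the
workflow this automates (all reads vs reads informative about the repeat);
the package defaults to *spanning reads* — the reads that could have shown
variation — and `denominator = "aligned"` selects the other reading.
Second, a single `non_integral` read is treated as indel sequencing noise;
it counts as variant evidence only when at least two reads agree on the
same gap length (`min_nonintegral_support` = 2). Reads are consumed as a
pooled multi-accession set without per-accession attribution, matching the
pooled-alignment design; per-cultivar genotyping from pooled reads is a
non-goal.

## Primer feasibility

This stage is a triage, not a designer: it asks whether *any* primer pair
could be placed, leaving actual design to a thermodynamics-aware tool.
Windows of 18–27 nt in the flanks are screened on GC fraction (0.30–0.70)
and the GC-count melting-temperature approximation

\[ T_m = 64.9 + 41\,(n_{GC} - 16.4)/\ell \]

against a 60 ± 5 °C target, and window pairs are kept when the implied
product — forward-window start to reverse-window end, which necessarily
contains the whole repeat — falls in 90–400 bp. Loci with no feasible pair
are flagged, not dropped. The GC bounds and Tm tolerance are package
defaults (the underlying workflow states only length, temperature and
product-size ranges) and are configurable.

## Diversity statistics

Allele frequencies count two copies from a homozygote and one of each from
a heterozygote; missing calls are excluded listwise per locus. On those
frequencies:

* `He = 1 − Σ pᵢ²` is the plain gene diversity, used *without*
  small-sample correction because that is the form conventionally reported
  for SSR characterization panels; the `2n/(2n−1)` corrected variant is
  available behind `corrected = TRUE` for comparison with software that
  applies it.
* `PIC = 1 − Σ pᵢ² − Σᵢ<ⱼ 2 pᵢ² pⱼ²` (Botstein's marker informativeness),
  computed via the power-sum identity
  `Σᵢ<ⱼ 2pᵢ²pⱼ² = (Σpᵢ²)² − Σpᵢ⁴`; tests verify it against the explicit
  pair sum and the `PIC ≤ He` bound on random frequency vectors.
* `Ho` is the heterozygote fraction among typed accessions.

Accessions showing one amplicon are treated as homozygotes (the
alternative — heterozygote with a null — cannot be distinguished in a size
table); loci where any accession shows three or more amplicons cannot be
represented in the genotype table at all and are excluded from
characterization upstream.

**Null-allele frequency.** Under the null-allele model a null heterozygote
*i/0* types as an apparent homozygote *i/i* and a null homozygote *0/0*
fails, so conditional on amplification

\[ P(i/i) = \frac{p_i^2 + 2 p_i p_0}{1 - p_0^2}, \qquad
   P(i/j) = \frac{2 p_i p_j}{1 - p_0^2}. \]

The package maximizes this likelihood numerically over the visible
frequencies (softmax-parameterized) and the null frequency \(p_0\).
\(p_0\) is *not* constrained to be nonnegative: the likelihood remains
well-defined for moderately negative \(p_0\) (all class probabilities
positive, enforced by penalty), and a negative estimate is the
conventional signature of heterozygote *excess*. Optimization starts from
the moment estimator \((H_e - H_o)/(H_e + H_o)\) and the observed
frequencies, runs Nelder–Mead to convergence and polishes with BFGS,
keeping the better optimum. Monomorphic loci return `NA` (the model is
unidentified). A genotyping-failure rate is deliberately not co-estimated:
the genotype table records only final calls, not repeated amplification
failures, so failure and null-homozygosity are confounded there; excluding
missing calls via the conditional likelihood sidesteps the confound at the
cost of using slightly less information. Forward simulations at 10,000
diploids recover planted null frequencies of 0, 0.1 and 0.3 with absolute
bias below 0.02.

## Distances and dendrograms

Genotypes are binarized to one presence column per observed
(locus, allele); an accession missing a locus gets an all-zero block,
recorded as missing rather than as absence. Distances:

* `shared_allele` (default) — 1 minus the per-locus Dice share
  `2|A∩B|/(|A|+|B|)` averaged over loci scored in both accessions; closest
  in spirit to the allele-sharing distances used by SSR characterization
  software and insensitive to how many alleles other loci segregate;
* `simple_matching` — mismatched columns over scored columns, the natural
  metric on the published binary encoding;
* `dice` — set Dice over the whole allele profile.

The exact distance used in the workflow this package automates is not
recorded anywhere, so no single published dendrogram can be reproduced
bit-exactly; cluster membership, not topology identity, is the meaningful
comparison. Tree construction delegates to the standard phylogenetics
stack: Saitou–Nei neighbor joining (`ape::nj`; exact on additive
distances, negative branch lengths kept unless `clamp = TRUE`) and UPGMA
(`phangorn::upgma`; ultrametric by construction, ties resolved by the
deterministic agglomeration order). Newick output reparses to an
isomorphic tree.

## Segregation

For a cross of outbred heterozygous parents, the expected class follows
from the parental genotypes alone: ab×ab → 1:2:1, ab×cd and ab×ac →
1:1:1:1, ab×cc → 1:1 (informative parent noted), aa×bb → none. Fit is
Pearson's chi-square against the class proportions with
df = classes − 1 and no continuity correction — at the typical population
size (~138 seedlings) expected counts are ≥ 34, squarely in the regime
where the plain statistic is standard. Null alleles are not modelled in
class prediction (a suspected null segregation pattern must be caught by
inspection); distorted transmission is reported descriptively via
per-allele transmission frequencies.

## The simulator, and what passing tests mean

`make_genome` plants one repeat per contig between rejection-sampled
random flanks: a contig is accepted only when the detector finds exactly
the planted repeat at exactly the planted coordinates, which guarantees no
accidental above-threshold repeat and no chance extension of the planted
one. `make_reads` gives each cultivar either the reference haplotype or
one differing *only* in repeat-unit count, draws uniform-start single-end
reads, optionally applies uniform substitution errors, and pools
everything without attribution. `make_genotype_table` draws diploid
genotypes under Hardy–Weinberg from per-locus Dirichlet frequencies with
an optional null allele (null homozygotes → missing; null heterozygotes →
apparent homozygotes). Everything is a pure function of its integer seed
(R's Mersenne–Twister, one stream per fixture, recorded in the manifest),
and every fixture ships a ground-truth manifest that the end-to-end tests
assert against.

The simulator intentionally omits: indel and quality-dependent errors,
GC-amplification bias, paired-end fragment geometry, alignment ambiguity
from repetitive genomic context, PCR stutter, and linkage between loci
(panel genotypes are drawn independently per locus). Perfect recall and
precision on simulated panels therefore demonstrate that the *logic* of
spanning-read counting and classification is correct under the stated
read model — not that real pooled alignments, with indels and mapping
artifacts, will be called with the same accuracy. The substitution-error
scenarios (0.5% per base) probe robustness of the anchor matching, not a
calibrated Illumina error model.

Test and validation problem sizes are chosen to exercise each property at
the smallest scale that makes the property non-trivial: oracle equivalence
on one hundred 10 kb sequences across all motif lengths, caller
precision/recall on a 200-locus, 7-cultivar, 20× panel, null-allele
recovery on 10,000-diploid cohorts, tree reconstruction on 8-taxon
matrices, and a 132 × 50 characterization panel mirroring a typical
published marker set.

## Degenerate inputs and numerical conventions

* Coordinates are 1-based inclusive everywhere, the R and MISA reporting
  convention; there is no internal 0-based representation to translate.
* Empty sequence → empty locus table; invalid characters are an error, not
  silently skipped.
* All-missing locus → error from frequency-based statistics (not a silent
  zero); monomorphic locus → He = PIC = 0, null frequency `NA`.
* Frequency vectors are validated to sum to 1 within 1e−8.
* Ties: primer windows are ordered by (start, end); duplicate fragments
  keep the first occurrence in input order; UPGMA ties follow `hclust`'s
  deterministic agglomeration.
* A locus at a contig edge keeps its truncated flank through extraction and
  is then handled by the flank filters, so edge loci are rejected with a
  reason rather than mis-extracted.

## Known limitations

Read alignment itself is out of scope (any aligner producing SAM/BAM
against the fragment references works); per-cultivar genotyping from
pooled reads is not attempted; primer screening is feasibility-only (no
dimer/hairpin thermodynamics); linkage-map construction beyond per-locus
segregation tests is out of scope; and the published-panel comparison
requires a transcription of the original per-accession allele-size table,
which ships with the package only as a documented layout, not as data.
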