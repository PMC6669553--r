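---
title: "Methods: annotating and comparing circular baculovirus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and comparing circular baculovirus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculoscan)
```

baculoscan implements the desk-scale computational workflow used to
characterize a newly sequenced nucleopolyhedrovirus (NPV) genome: structural
ORF annotation on a circular chromosome, discovery of the two repeat classes
that organize baculovirus genomes (tandem direct repeats and homologous
regions), classification of intrapopulation single-nucleotide variants,
marker-gene species demarcation under the Kimura 2-parameter (K2P) model,
and reciprocal-best-hit (RBH) gene-content comparison across related
genomes. This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Coordinates and the circular topology

All coordinates are 0-based half-open internally; 1-based inclusive
coordinates appear only at format boundaries (GenBank in, GFF3 out). A
feature crossing the origin of a circular genome is stored *unwrapped*, with
`end > L`, so its length is always `end - start`; it is wrapped into a
two-part location only on output (two GFF3 lines sharing one `ID`). This
keeps every length computation single-valued and makes rotation invariance
(a property every stage is tested for) mechanical.

## ORF annotation

An ORF is a maximal ATG-to-stop span with at least `min_aa` codons (stop
codon excluded; default 50 aa, the conventional baculovirus annotation
floor). Within one stop-to-stop frame segment only the 5'-most ATG defines
the ORF; nested ATGs are not separate candidates, matching standard ORF
callers and keeping counts stable. Circular genomes are scanned on the
doubled sequence so origin-spanning ORFs are found; calls sharing a stop
codon are reduced to the longest, and duplicates from the second copy are
removed modulo the genome length, so each ORF is reported exactly once.

The annotation criterion is deliberately liberal: a candidate is kept unless
at least `max_overlap` (default 50%) of *its own* length lies inside an
already-retained ORF. Retention is greedy in decreasing length order (ties:
smaller start, then plus strand), which makes the per-ORF rule
deterministic; overlap is measured on genome coordinates irrespective of
strand. The boundary is inclusive — exactly 50% overlap discards the
shorter candidate.

Homology labelling is a pairwise Smith–Waterman (BLOSUM62, gap open 11,
extend 1, the classic protein-search scoring) of each ORF against a
user-supplied reference set, not an external database search. The default
acceptance score of 60 was chosen from a null simulation: local alignment
scores of unrelated random 300-residue proteins under this scoring
concentrate near 37 with a 99th percentile near 52, so 60 sits above the
null while genuine homologs at the divergences seen within a genus score in
the hundreds. ORFs below threshold are labelled `unique`; `core_gene`
flags hits to the caller's core-gene list (the 38 genes conserved in all
sequenced baculovirus genomes).

## Repeat regions

Tandem arrays are found by k-mer seeding: exact k-mer recurrences at spacing
`d` (`min_unit <= d <= max_unit`) propose candidate periods; a candidate is
slid left to the array start and extended unit-by-unit while each unit stays
at or above `min_identity` (default 85%) to the running consensus, with a
fractional trailing copy counted by exact prefix match. Overlapping reports
are resolved by span (10-nt buckets), then by *smallest period* — an array
of period `p` is equally reportable at `2p`, `3p`, ..., and `p` is the
canonical description. Detection is wrap-aware and deterministic. The
detector is validated on planted arrays (unit 10–100 nt, 3–10 copies, up to
5% divergence) with a 95% recovery requirement; heavily diverged arrays can
be reported at a harmonic when single copies fall below the identity floor,
which is the known failure mode at the edge of that envelope.

Homologous regions (hrs) — the clusters of short imperfect repeats that
serve as replication origins and enhancers in baculovirus genomes — are
detected by projecting all hits of user-supplied core motifs (both strands,
up to 1 mismatch by default) onto the genome and single-linkage clustering
with gap `<= window` (default 2 kb). A cluster becomes an hr when it holds
at least `min_hits` hits. The library default is 2 (an hr by definition
repeats its core), but the full-genome pipeline default is 3: an 11-nt core
at one mismatch has an expected handful of chance hits in a 120-kb genome,
so chance *pairs* occur while genuine hrs carry seven or more hits. Naming
is positional from the origin, with regions closer than `group_gap`
(default 15 kb) sharing a number and differing in letter (`hr1a`, `hr1b`,
...), reproducing the field's naming style without its unstated rule.

Motif counts default to exact match, both strands, overlapping occurrences,
wrap included; each convention is a flag, since published counts rarely
state theirs.

## Variant classification

SNVs arrive as VCF (allele frequency from `INFO/AF`) or delimited tables;
indels are rejected with a counted warning. Each variant is mapped to every
retained ORF covering it (wrap-aware); on minus-strand ORFs the alleles are
complemented before the codon — rebuilt from the genome — is substituted
and both versions translated. Stop gain/loss folds into non-synonymous,
matching the two-way coding split used in genome reports. Because the
liberal overlap criterion permits double coverage, a variant under two ORFs
is annotated per ORF with the primary effect taken from the longest; the
summary counts each SNV once via the primary row. Frequency summaries use
the sample (n−1) standard deviation, reported as percent to one decimal;
both coding-only and all-variant summaries are returned because published
mean ± sd figures are usually computed over coding SNVs without saying so.

## Species demarcation

For an aligned pair, sites with a gap or `N` in either sequence are removed
(pairwise deletion — the choice that uses the most data; complete deletion
is not offered because marker sets here are small), transitions `P` and
transversions `Q` are counted as proportions, and

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q).

When a log argument is non-positive the distance is saturated: it is
returned as `Inf` with `defined = FALSE`, and classified as
`different_species` with a `saturated` flag, since saturation itself
evidences deep divergence. The demarcation rule on marker genes (lef-8,
lef-9, polh) calls distinct species above 0.05 substitutions/site and the
same species below 0.015; values between or exactly at a bound are
`indeterminate`. Only the upper bound is routinely printed in genome
reports; both are configurable.

The distance-based companion tree is canonical neighbor joining with two
fixed conventions: ties in the Q criterion break by lexicographic
taxon-pair order, and a negative branch length is clamped to zero with the
deficit moved to its sister branch so path lengths are preserved. On
additive matrices NJ recovers the generating tree exactly (topology and
lengths), which the tests assert for 4–8 taxa against an independent
implementation.

## Gene-content comparison

Orthology is strict RBH: `x` and `y` pair only if each is the other's
unique best local-alignment hit, both passing the score threshold and
covering at least 50% of the shorter protein; ties for best produce no
pair, which is the conservative choice when paralogs (for instance the
*bro* multigene family) duplicate scores. Pairs merge by single linkage
into groups, adding edges in decreasing score order and dropping any edge
that would place two genes of one genome into one group. Unpaired genes
are singletons. The Venn partition assigns each group to the exact genome
subset it touches; counts over all subsets sum to the number of groups by
construction. Locus context (for instance the iap-3/tmk locus between the
ac30-like and fgf anchors) returns the genes strictly between two unique
anchor labels along the shorter arc, oriented from the first anchor, and is
rotation-invariant.

## The synthetic study

`simulate_genome()` emulates the architecture every stage assumes, and its
defaults are the study conditions: a circular 122,075-bp genome at G+C
0.509 carrying 153 ORFs of 50–400 codons (one spanning the origin), five hr
loci built from the four hr core motifs (7–8 copies each at 5% motif
divergence in 0.5–1.3-kb windows), and two direct repeats — a 10-nt unit
and the four-copy 68-nt unit one substitution from exact. Each planted ORF
is written as an in-frame stop guard, ATG, random non-stop codons, and a
stop, so the planted start is provably the 5'-most ATG of its segment and
recovery can be asserted at exact coordinates. Feature blocks are laid out
around the circle with multinomially distributed background gaps; repeat
blocks are spread evenly between ORF blocks so two planted hrs never fall
into one clustering window. `simulate_variants()` places 203 SNVs by
default — 180 coding of which 92 synonymous, enforced by codon-aware
alternate-base choice — with frequencies from a normal (mean 0.38, sd
0.046) clipped to (0.01, 0.99), mirroring the mean ± sd reporting style of
population-sequencing summaries. `simulate_divergence()` evolves sequences
site-wise under the exact K80 transition probabilities at a requested
branch length and transition:transversion ratio.

What the generator does *not* emulate: real codon usage and promoter
structure (background codons are i.i.d. at the target G+C, which raises
realized G+C by roughly 0.5 point on coding-dense designs since stop codons
are AT-rich and excluded), gene-length and strand clustering, nested and
overlapping real gene arrangements beyond chance, sequencing error, indels
and recombination. Chance background ORFs do arise at the geometric-tail
rate and are deliberately left in: planted-truth tests assert recovery of
the planted set, not absence of extras, and the overlap filter is exercised
against exactly this background. Passing on synthetic data therefore
demonstrates correctness of the algorithms under the stated statistical
structure, not end-to-end fidelity to any particular real genome.

## Problem sizes and determinism

The test suite runs the full-scale synthetic study only where the quantity
demands it; property tests use 3–60-kb genomes, 5–10-kb marker pairs, and
100-replicate estimator panels, keeping the default suite around four
minutes on one core. All generators take explicit integer seeds and use R's
default RNG only; identical seeds give byte-identical output. The
acceptance script (`scripts/acceptance.R`) re-runs the full study at the
default (study-scale) conditions from a single seed in about half a minute.

## Known limitations

GenBank parsing covers LOCUS/FEATURES/ORIGIN with CDS, gene and
repeat_region keys and single- or two-part locations — enough for viral
records, not the full flat-file grammar. hr clustering does not merge
across the origin (none of the target genome's hrs straddle it; rotation
tests cover the ORF and repeat scanners, which do). Tandem-repeat scoring
is identity-based, not the published tool's alignment score, so reported
boundaries can differ by a few bases at diverged array edges. RBH
orthology collapses multi-copy families to at most one member per genome
per group; collapsed versus uncollapsed accounting of such families is the
caller's choice of input labels.
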