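---
title: "Comparative genomics of chloroviruses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of chloroviruses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorocomp)
```

Chloroviruses are large dsDNA viruses (family *Phycodnaviridae*) that infect
chlorella-like green algae. Isolates group by the algal host they infect —
NC64A, Pbi or SAG viruses — and the three host groups differ in genome-wide
nucleotide composition (median GC near 40, 45 and 49%), gene order, and gene
content. `chlorocomp` implements the comparative pipeline for such genome
sets: ortholog families, family conservation categories, ancestral-repertoire
reconstruction, compositional detection of recently acquired genes, and
gene-order colinearity — together with a synthetic-genome generator that
provides complete ground truth, so every stage is testable without any
database download.

## Annotated genomes

Genomes are held as ordered contigs plus an ordered gene table. Internally
all coordinates are 0-based half-open; GenBank and GFF3 use 1-based inclusive
coordinates, converted only at the I/O boundary, so interval arithmetic never
needs special cases. Minus-strand coding sequences are stored
strand-resolved (5'→3'). Translation uses the standard genetic code;
internal stop codons are tolerated with a warning because deposited viral
ORFs occasionally contain them. Host-group labels always come from a
metadata table — hosts are determined experimentally, never inferred from
sequence.

```{r}
gs <- generate_genome_set(synthetic_design(seed = 1))
gs$genomes[[1]]
group_gc_summary(gs$genomes)
```

## The synthetic-genome generator

`synthetic_design()` describes the study conditions the generator emulates:

* **Host groups.** Three groups with GC targets 0.40 / 0.45 / 0.49, matching
  the observed group medians. Four genomes per group by default — enough for
  every presence/absence category to be well defined while keeping runs fast.
* **Families.** Each family starts from one random ancestor protein. Group
  copies apply a per-site amino-acid substitution probability (default 0.15),
  genome copies a further 0.03, giving within-group identities near 94% and
  between-group identities near 70% — the regime where reciprocal best hits
  are expected to recover families exactly. Categories (core, host-specific,
  opposite-pattern, scattered, singleton) are laid down as presence sets and
  kept as truth tables.
* **Gene lengths** are log-normal in codons (median 250, log-sd 0.4),
  truncated to 60–2000 codons; 60 codons is the ORF floor used when the
  genomes were annotated, and 250 codons matches the observed ratio of
  genome size to gene count.
* **Nucleotide emission.** Proteins are back-translated through a codon
  model that weights synonymous codons by `exp(theta * GC(codon))`, with
  `theta` solved per genome so that the *expected* coding GC equals the
  design target. This makes the generator's GC unbiased (a law-of-large-
  numbers test at ±2 points is meaningful) while leaving codon choice
  otherwise uninformative — the compositional signal the pipeline detects is
  nucleotide bias, not codon optimality. Intergenic spacers (20–200 bp) use
  the same target composition.
* **Alien genes** (the HGT ground truth) are ordinary family members whose
  nucleotide sequence is re-emitted through a model offset by a chosen
  number of GC points (default +10). The protein is unchanged, so family
  structure stays intact; only the composition is foreign — exactly the
  signature a compositional detector should see.
* **Gene order** is conserved within a group up to a configurable number of
  segment inversions and independently permuted between groups, mirroring
  the observed dot-plot pattern.
* **Determinism.** All randomness flows from the single design seed through
  per-genome sub-seeds; the same seed yields byte-identical files.

What the generator does *not* emulate: realistic phylogenetic branch
lengths, recombination, assembly gaps, codon-usage preferences beyond GC,
and amino-acid composition bias. Tests passing on synthetic data therefore
demonstrate algorithmic correctness under the designed signal, not
performance on every real-data pathology.

## Ortholog families

Pairwise protein similarity comes from Smith–Waterman local alignment
(BLOSUM62, affine gaps 11/1) with a Karlin–Altschul-style e-value
`E = K m n exp(-lambda S)` using the standard gapped parameters
(`lambda = 0.267`, `K = 0.041`); hits at e-value ≥ 1e-5 are discarded, the
same threshold the dot-plots use. A 12-column tabular file from an external
aligner can be imported instead for full-scale runs — the internal engine
exists so that tests need no external binary.

Families are the connected components (single linkage) of the
reciprocal-best-hit graph, where best hits are by alignment score with ties
broken by lower e-value, longer alignment, then subject id. In-paralogs —
within-genome duplicates arising after lineage divergence — join a cluster
when their score with some member exceeds every score between that member
and the rest of the cluster; all candidates are judged against the original
clusters in a single pass, which keeps the outcome independent of input
order. Remaining proteins become singletons; outgroup genomes may join the
clustering but never produce singletons of the focal set.

```{r}
fams <- build_families(proteomes(gs$genomes))
fams
```

## Conservation categories and the ancestral repertoire

The family-by-genome count matrix supports five mutually exclusive
categories, applied in precedence order: `core` (present in every genome),
`host_specific:g` (all of group g, nothing else), `opposite:g` (absent from
g, present everywhere else), `singleton` (one member overall), and
`scattered`. With only two host groups a host-specific pattern is also an
opposite pattern; precedence resolves it as host-specific.

The ancestral repertoire uses the parsimony rule induced by the root of the
virus phylogeny, which separates NC64A viruses from Pbi + SAG viruses: a
family is ancestral iff it occurs on both sides of that split. Families
supported by external evidence (sister-group relationships to other
nucleocytoplasmic large DNA viruses in published trees) can be force-flagged
via `extra_evidence`; identifying them requires manual tree reading and is
deliberately out of scope. The rule is monotone (adding a member can never
make a family non-ancestral) and every core family satisfies it.

```{r}
fm <- classify_families(build_matrix(fams, data.frame(
  genome_id = vapply(gs$genomes, function(g) g$genome_id, ""),
  host_group = vapply(gs$genomes, function(g) g$host_group, ""))))
table(fm$category)
```

`select_single_copy_core()` returns the families with exactly one member in
every genome (including outgroups when supplied) — the markers used for
concatenated-alignment phylogeny.

### The chance-ORF null

To ask how many open reading frames longer than 300 bp could arise by
chance, `orfan_chance_null()` shuffles the concatenated coding sequence of
the non-ORFan genes (preserving mononucleotide composition) and scans all
six frames for ATG-initiated, stop-terminated ORFs above the threshold. The
published description of this randomization is terse, so the implemented
conventions are explicit and returned with the result: the shuffle unit is
the concatenated non-ORFan CDS; an ATG start is required; nested starts
count separately; ORF length runs from the ATG through the stop codon. A
geometric/Poisson closed form (each ATG survives L codons without a stop
with probability `(1 - p_stop)^L`) reproduces the simulated counts on iid
sequence, which is the property the suite asserts. Counts from other
readings of the procedure (for example, shuffling only intergenic DNA and
counting ORFs outside annotated genes) can differ substantially, so the
published "<1 ORF per genome" figure is reported but not asserted.

## The compositional deviation index

For each genome, a non-homogeneous Markov model of order `k = 5` is trained
on the coding sequences of its ancestral families: `P0` holds the
frequencies of the k-tuples that open an ORF, and three transition matrices
`P1, P2, P3` give the probability of the next nucleotide conditional on the
preceding k-tuple, indexed by the codon position (1/2/3) of the tuple's
first nucleotide. Training uses pseudocount `alpha = 0.5` per
(tuple, nucleotide) cell: with `4^5 = 1024` contexts per frame and typical
training sets of 1–3·10^5 tuples, unseen contexts are inevitable and a zero
probability would send every novel ORF to `-Inf`.

An ORF's log-likelihood is
`log P0(j_1) + sum_t log P^f(i_{t+k} | j_t)` with `f` cycling 1, 2, 3; the
opening tuple sits at codon position 1, and `f` is the codon position of
the tuple's first nucleotide — one consistent reading of the published
indexing. Windows containing ambiguity codes contribute zero; ORFs shorter
than `k + 1` usable nucleotides get an explicit `NA` with flag `"short"`.

The CDI standardizes the ORF's log-likelihood against `n_rand = 100`
model-emitted random sequences of the same length:

`CDI = (logL(ORF) - mean(logL(rand))) / sd(logL(rand))`

All arithmetic is in log space. The published formula is written on raw
probabilities, which underflow for any realistic ORF length; standardizing
log-likelihoods preserves the defining property that model-like sequences
have expected CDI 0 and is the only numerically viable reading. A null SD
of zero (degenerate model) yields a flagged `NA`, never a fake score.

Calibration and interpretation:

* For ORFs *emitted from the model itself*, CDI has mean ≈ 0 and SD ≈ 1,
  at all lengths — the suite verifies this at lengths 150–1500 nt and the
  acceptance script recomputes it at 999 nt.
* Real (or back-translated synthetic) ORFs are not Markov-emitted
  sequences: genes *in* the training set score somewhat above 0 and
  held-out native genes score below it. CDI is therefore a relative index —
  the informative quantity is the contrast between gene categories, which
  is how it is used: alien genes score far below native ones, the gap
  growing monotonically with the compositional offset (the suite checks
  offsets of 0/4/8/12 GC points and requires AUROC ≥ 0.9 at 10 points for
  genes ≥ 300 nt).
* Deviant ORFs can in principle deviate in either direction; reporting is
  two-sided, with the left tail as the HGT-like direction on the synthetic
  evidence.

Group-level comparisons use the Kruskal–Wallis omnibus test plus all
pairwise two-sided Wilcoxon rank-sum tests with Holm family-wise correction
(a widely available stand-in for joint-ranking all-pairs procedures), and a
named long (>300 bp) versus short (<300 bp) ORFan contrast.

```{r, eval = FALSE}
model <- train_codon_model(ancestral_cds_of_one_genome, k = 5, alpha = 0.5)
res <- compute_cdi(all_cds_of_that_genome, model, n_rand = 100, seed = 1)
head(res[order(res$cdi), ])
```

## Gene order and colinearity

Dot-plots work on gene ranks (order indices), not nucleotide coordinates, so
block length is a gene count. One dot per hit below e-value 1e-5; same
orientation black, reverse orientation grey, mutual best hits larger —
`render_dotplot()` writes the SVG markup directly, making output
byte-stable. Colinear blocks are maximal strictly monotone chains (ascending
or descending) extracted longest-first by dynamic programming, with at most
`max_gap = 3` intervening unmatched genes between consecutive matches on
either axis; the gap default is a package choice, since the published block
statistic does not state one, and it is exposed as a parameter. Ties between
equal-length chains are resolved on the sorted unordered gene-pair keys,
which makes block extraction symmetric in the two genomes.

Reference-guided contig ordering anchors each contig by its genes' best hits
into the reference: contigs sort by the median reference rank of their
anchors, orient by majority strand agreement (ties keep the original
orientation), and unanchored contigs are appended last and flagged. The
operation is idempotent, and with no anchors at all the assembly is returned
unchanged with a warning — the honest outcome for assemblies that share no
long-range colinearity with any reference.

## Full-scale benchmarks

Family counts for the real 41-genome set (531 multi-member clusters, 155
core families, 290 rule-ancestral families, 64% identity for the most
divergent DNA-polymerase pair) require the deposited GenBank records and a
full all-vs-all similarity search. They are tracked as benchmark targets
with a ±5% tolerance (`benchmark_targets()` / `check_benchmarks()`) to be
evaluated when those inputs are available, rather than asserted in the unit
suite.

## Problem sizes and numerical choices

The suite and the acceptance script run on desk-scale problems chosen as the
smallest sizes at which each statistical property is sharp: family recovery
on 6 genomes × 15 families; CDI calibration on 500 ORFs of 999 nt with 100
randomizations per ORF (Monte-Carlo standard error ≈ 0.045 on the mean, so
the ±0.1 calibration band is ≈ 2 standard errors); alien detection on one
genome of 200 genes with 15% aliens; oracle-equivalence checks on 200 random
instances per operation. Likelihood sums are accumulated in double
precision in log space; transition-row normalization holds to machine
precision by construction. Chain simulation for the CDI null is vectorized
across randomizations, which is what keeps 50,000 chains of length 999
within seconds.
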