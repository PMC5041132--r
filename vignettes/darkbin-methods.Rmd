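---
title: "Single-sample metagenome deconvolution: models and design choices"
author: "darkbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample metagenome deconvolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkbin)
```

## The problem

Shotgun sequencing of a host animal and its microbial associates yields a
mixed assembly: one eukaryotic host genome (often hundreds of Mbp),
plus contigs from every bacterium present, some of which may be so
divergent from reference databases that most of their genes have no
homologs at all.  The standard route to separating such assemblies --
differential coverage across many replicate samples -- fails when the
interesting organisms occur in a single sample only.  `darkbin`
implements a single-sample alternative built from sequential
simplification steps, each removing or explaining one slice of the
assembly:

1. **Taxonomic filtering.**  ORFs are classified from protein homology
   hits; contigs inherit a taxonomy by per-rank majority vote; everything
   not called Bacteria at the kingdom rank is removed.
2. **Shared-contig identification.**  Contigs that also have read
   coverage in a second sample (host tissue plus any genuinely shared
   symbiont) are split off by depth/breadth thresholds.
3. **Marker anchoring and mixture binning.**  Contigs carrying bacterial
   single-copy marker genes are clustered in (GC%, coverage) space with
   Gaussian mixture models and BIC component selection.
4. **Composition-based assignment.**  Remaining contigs are handed to the
   mixture clusters via tetranucleotide frequencies on a toroidal
   self-organizing map, gated by a distance percentile.
5. **Reporting**, plus optional **iterative targeted reassembly** of a
   bin and **RPKMO** normalization of metatranscriptome counts.

Every stage is exposed as ordinary R functions; `run_pipeline()`
orchestrates them and records a single disposition (removed / shared /
binned / unassigned) for every contig.

## ORF and contig taxonomy

ORF classification uses a windowed lowest common ancestor: hits are
pre-filtered at an e-value of 1e-5 (a conventional BLASTP noise floor),
hits with bitscore at least 90% of the best retained hit are kept
(`window = 0.1`, the usual MEGAN-style top-score window), and the LCA of
their taxa is returned.  Both values are exposed because neither is
canonical.

Contig taxonomy walks ranks from kingdom downward.  At each rank every
classified ORF projects its taxon to that rank (ORFs classified above the
rank abstain), the plurality taxon wins only when it strictly beats every
rival, and descent continues only among ORFs consistent with the winner.
Ties stop the walk, leaving the contig undecided at that rank -- a
conservative rule that sends genuinely ambiguous contigs to the
"unclassified" bucket rather than guessing.  Votes are unweighted (one
ORF, one vote); weighting by bitscore would let a single strong
horizontally-transferred gene overrule several weak native ones, which is
precisely what majority voting is meant to prevent.  Whether per-rank
descent or a single-rank vote better matches historical practice is
genuinely open; per-rank descent was chosen because it makes the output
(a root-to-node path with per-rank vote fractions) self-documenting.

Contigs with zero ORFs cannot vote and are removed by the kingdom filter,
but flagged separately (`reason = "no_orfs"`) so composition-based
assignment could rescue them in a later pass.

## Shared-contig partition

"Coverage in the second sample" needs an operational definition; the
defaults are mean depth >= 1.0 and covered fraction >= 0.5, both
inclusive and both exposed (`min_depth`, `min_fraction`).  When coverage
is computed from a SAM alignment, only primary mapped records count --
secondary and supplementary alignments would let a single shared repeat
drag a whole contig into the shared pool.

## Mixture binning

Features are GC on the 0--100 scale and log10 coverage, each standardized
to zero mean and unit variance.  Coverage is log-transformed because
depth noise is multiplicative (a lognormal perturbation around each
organism's mean), so clusters are closer to Gaussian on the log scale;
`log_coverage = FALSE` disables it.

Mixtures are fitted by EM via **mclust** for each candidate component
count (default `k_range = 1:15`, capped at n/2), and the fit minimizing
BIC is selected.  Covariances are unconstrained (mclust's `"VVV"`):
GC-coverage clusters are elongated, and restricting to spherical or
diagonal families makes BIC shave one elongated cloud into two spurious
components at small n.  Mixture fitting runs on marker-containing contigs
only -- markers guarantee the contig is long enough and bacterial, and
the marker profile later scores each cluster's completeness and
redundancy.  Contigs join their argmax-responsibility component only when
that responsibility reaches `min_posterior` (default 0.5); exact ties
break to the lowest component index so results are deterministic.

## Tetranucleotide SOM assignment

Composition vectors count all overlapping 4-mers, folded under
reverse-complement equivalence into 136 canonical classes and normalized
to frequencies; folding makes `tnf(s)` exactly strand-invariant.  Vectors
are computed per contig (no fixed-length windowing) for contigs of at
least `min_length = 3000` bp -- below that, 4-mer sampling noise
dominates the genome signal.

The map is a batch-trained toroidal grid (toroidal to avoid edge
distortion), sized to about `5 * sqrt(n)` neurons, near-square.
Prototypes initialize on the plane of the first two principal components,
so training starts from a poor but deterministic configuration and the
mean quantization error decreases monotonically as the Gaussian
neighborhood shrinks geometrically from half the grid to 0.5 over the
epochs (default 40).

Neurons are labeled by majority vote of the marker contigs mapping to
them, with ties left unlabeled.  Neurons that no marker contig maps to
inherit the label of the nearest labeled neuron in prototype space; on a
sparsely labeled map most neurons sit between labeled ones, and without
this propagation the bulk of queries would land on unlabeled neurons and
stay unassigned regardless of how cleanly the map is organized.  The
safeguard against over-assignment is the distance gate, not label
scarcity: a query inherits its best-matching unit's cluster only if its
distance to the prototype is within the `distance_percentile` (default
95) of the labeled contigs' own distances in that cluster.  Contigs from
a genome absent from every cluster fall outside every cluster's radius
and stay unassigned.

## Iterative targeted reassembly

Read recruitment is exact canonical 31-mer matching against the current
contig set rather than full alignment: it is dependency-free, and for
deciding "does this read belong near these contigs" shared-k-mer
semantics suffice.  If either mate of a pair is recruited, both are,
which is what lets each round reach about one insert length beyond the
current contig ends.  The internal assembler is greedy
overlap-layout: seed at the highest-multiplicity unused read, extend both
ends by maximal unique overlaps of at least 50 bp, stop on ambiguity.
Circularity is detected when the extension re-encounters the contig's
5'-end 50-mer, at which point the second lap is trimmed.  Repeats longer
than the minimum overlap are out of scope for the internal mode (a
documented limitation -- real data should use `mode = "external"` with a
production assembler).  Iteration stops when the relative change in total
assembled length drops below `tol = 0.005` or after `max_iter = 10`
rounds.

## RPKMO

For a bin's gene g with read count c and length L,

    RPKMO_g = c / ((L / 1000) * (T / 1e6)),   T = sum of c over the bin's ORFs

Because T sums over annotated protein-coding ORFs only, rRNA reads --
which can dominate a metatranscriptome unpredictably -- never enter the
normalizer.  The definition implies the conservation identity
`sum(RPKMO * L / 1000) == 1e6` for any bin, which the tests exploit as an
algebraic oracle.  "Unassigned" is a first-class functional category so
category shares always total 100%.  Multi-mapped reads are assumed
counted once to their best alignment upstream of this module.

## 16S novelty calls

Rank cutoffs (species 98.7, genus 94.5, family 86.5, order 82.0, class
78.5, phylum 75.0 percent identity) follow the Yarza-style ladder; the
deepest rank whose cutoff the identity reaches (inclusive) is assignable,
and the implied novelty is the rank below it.  Cutoff-based calls are
deliberately modest: they cannot substitute for tree placement, and a
caller reporting "novel at phylum level or above" says only that the
sequence is below every cutoff.

## The synthetic community generator

The generator emits genomes from seeded Markov chains (order 2 by
default) whose per-context emission probabilities are constrained so that
P(G or C) equals the target GC at every position -- realized GC is
unbiased at any length, while the context-specific G-vs-C and A-vs-T
splits give each genome its own tetranucleotide signature.  Contig
lengths are lognormal (median 8 kb, sigma 0.7, floor 1 kb), giving an N50
spread comparable to real mixed assemblies; coverage noise is
multiplicative lognormal with sigma 0.15, which keeps GC-coverage clouds
separated about as well as real single-sample bins.  ORFs tile contigs;
each genome's `divergence` sets the fraction of its ORFs with *no*
classifiable hit, emulating dark-matter genomes where only ~20% of genes
have homologs; 40 toy single-copy markers are planted once per genome
(duplications injectable); expression counts are negative binomial with a
lognormal rate.

The default community (`default_community()`) emulates the study design
the pipeline targets: seven sample-unique bacteria whose GC% and mean
coverages follow the published bin table of a bryozoan ovicell
metagenome (GC 20.9--60.3%, coverage 2.3--27.2x), one shared symbiont
present in both samples, and one eukaryotic host in both samples.
Genome lengths (60--300 kb) are desk-scale stand-ins preserving the
real bins' ordering; the problem sizes used throughout the tests
(60--400 kb genomes, ~100--200 contigs, 20 kb reassembly targets) were
chosen so the full validation suite runs in minutes on one CPU while
every statistical property of interest (cluster separation, percentile
radii, recruitment reach) still has enough data to be stable.

What the generator does *not* emulate -- and what passing tests therefore
do not show about real data: sequencing error beyond uniform
substitution, chimeric and misassembled contigs, strain-level mixtures,
repeat families longer than the assembler's minimum overlap, GC-dependent
coverage bias, and hit tables produced by real aligners against real
databases (hits here go to the true genus of a four-rank toy taxonomy).
The pipeline's behavior on those phenomena must be established against
real assemblies.

## Degenerate inputs and tie rules

Single-contig feature sets cannot be standardized and are an error; EM
fits that degenerate at some k are skipped with a warning and excluded
from BIC selection; exact posterior ties break to the lowest component
index; neuron-label ties leave the neuron unlabeled; majority-vote ties
stop the rank walk; threshold comparisons are inclusive (`>=`)
throughout, so a value exactly at a cutoff passes.

## Limitations

Assignment accuracy of the SOM stage depends on how many labeled contigs
each cluster has: per-cluster acceptance radii are empirical percentiles,
and with fewer than ~10 labeled contigs per cluster the radius estimate
is noisy enough to unassign a noticeable fraction of genuine members.
The internal reassembler is for toy validation and bin polishing on clean
data only.  Kingdom filtering removes contigs whose ORFs are entirely
unclassifiable; a highly divergent genome fragmented into many short
contigs would lose those pieces unless the composition stage rescues
them.
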