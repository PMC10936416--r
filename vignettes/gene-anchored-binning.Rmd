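---
title: "Gene-anchored MAG recovery: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-anchored MAG recovery: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchormag)
```

## The model

`anchormag` recovers genome bins from an assembled metagenome by working
outward from marker genes rather than clustering all contigs at once. The
target markers are the genes of the anaerobic benzoyl-CoA degradation
pathway, in particular the class-I, ATP-dependent benzoyl-CoA reductase
subunits *bcrABCD* that catalyze the dearomatization step. Contigs
carrying such a subunit seed ("anchor") a bin; the rest of the genome is
recruited by compositional similarity.

The compositional statistic is the trinucleotide proportion signature:
for a contig $c$, $t(c) \in \mathbb{R}^{64}$ holds the fraction of each
3-mer among all overlapping 3-bp windows, taken on the strand as written.
Two assumptions underpin the method:

* **Within-genome homogeneity.** Oligonucleotide composition is
  approximately constant along a genome, so contigs of one organism have
  highly correlated signatures. This holds well for kilobase-scale
  contigs; it degrades for very short fragments (hence the candidate
  length floor) and for compositionally atypical regions (rRNA operons,
  recently transferred islands).
* **Between-genome separation.** Different community members differ in
  composition enough that Pearson's $R$ between their signatures stays
  below the binning threshold. This is an ecological assumption, not a
  guarantee; closely related strains will merge.

Membership is decided by $R(t(c), t(a)) > 0.95$ against an anchor
signature $t(a)$. Correlation is computed on the raw proportion vectors —
not standardized columns — because the signature is already a probability
distribution and the correlation itself centers and scales; this is also
what the common scientific-computing defaults do for two plain vectors.

A coverage consistency step follows: contigs whose assembler depth falls
outside a symmetric fold band around the anchor median are removed. This
replaces manual inspection of per-contig depths with a reproducible rule.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_length_bp` | 7000 (strict >) | bp | anchor must be long enough for a stable signature and a credible reductase locus |
| `min_coverage` | 5 (strict >) | x depth | anchors from barely covered contigs are unreliable |
| `min_contig_bp` | 1000 (inclusive ≥) | bp | candidate universe floor; below this the 64-vector is too noisy |
| `r_threshold` | 0.95 (strict >) | Pearson R | the binning decision boundary |
| `cov_fold` | 2.5 | fold | symmetric coverage band `[ref/2.5, ref*2.5]`; wide enough for assembler depth noise, tight enough to drop repeats and mis-binned contigs |
| `link_threshold` | 0.5 | similarity | single-linkage cut for grouping similar bins |
| `majority_fraction` | 0.5 (strict >) | fraction | housekeeping gene must be in the focal bin and a strict majority of references |
| `max_size_mbp`, `min_completeness`, `max_contamination` | 8 / 50 / 5 | Mbp, % | chimera/quality rejection; the size cutoff is exposed configuration because "too large for one genome" has no canonical number |

The first four defaults are the method's stated operating point and the
test suite asserts them verbatim; the remainder are this package's own
reproducibility decisions, each overridable through `default_run_config()`.

Boundary semantics are deliberate and tested: the anchor filters and the
R threshold are **strict** inequalities, while the candidate floor is
**inclusive** at 1,000 bp.

## The synthetic community generator

Real validation data for this workflow are multi-gigabase metagenomes;
the generator instead emulates the features the method actually consumes:

* **Composition.** Each genome is an order-2 Markov chain over
  {A,C,G,T}. The 16x4 transition matrix fixes the trinucleotide
  distribution at stationarity, so compositional separability is a
  controlled parameter. `stationary_trimer_signature()` and
  `stationary_gc()` give closed-form oracles the tests compare sampled
  genomes against. The default three genomes use GC 0.45/0.35/0.65 plus
  per-genome log-normal tilts (sd 0.35) of the transition rows; their
  pairwise stationary-signature correlations sit far below the 0.95
  binning threshold while split-half correlations within one genome sit
  above it (the separability property test exercises this across 20
  seeds).
* **Abundance structure.** Mean coverages 20/10/6 with log-normal
  per-contig noise (CV 0.15) give a long-tailed community in which the
  pathway-carrying genome is the rarest member — the regime the method is
  designed for.
* **Contig structure.** Log-normal fragment lengths (median 8 kb,
  sigma 0.7 on the log scale) truncated below at 1 kb, tiling the genome
  exactly, with SPAdes-style headers carrying the coverage.
* **Annotations.** Planted pathway genes with canonical symbols and
  realistic product strings (class-I subunits forced onto >7 kb contigs
  so mining can anchor), plus filler "hypothetical protein" CDS at 1 per
  kb so per-million-CDS normalization has a realistic denominator.

Genome sizes are 300–400 kb — large enough for tens of contigs per genome
and stable signatures, small enough that the whole suite and the
acceptance script run in minutes on one CPU; replicate analyses use ten
communities and topology checks use twenty random six-taxon trees.

What the generator does **not** emulate: sequencing error, chimeric
assembly joins, strain mixtures, shared mobile elements, and
between-genome compositional convergence. Passing the synthetic recovery
test therefore shows the pipeline is correct and well-calibrated under
its own assumptions, not that every real community separates this
cleanly.

## Numerical and degenerate-input choices

* Windows containing any non-ACGT character are skipped entirely, keeping
  each signature a true distribution over the 64 trimers; a contig with
  no valid window (all-N, or shorter than 3 bp) raises a
  degenerate-signature error rather than returning NaNs.
* Zero-variance signatures (mathematically possible only for pathological
  sequences) raise an undefined-correlation error.
* N50 uses the standard convention: the length at which the descending
  cumulative sum first reaches half the total; the result is always a
  member of the length multiset. Medians use R's midpoint convention.
* GC% excludes ambiguity codes from numerator and denominator, so N-rich
  contigs do not bias the estimate.
* Neighbor joining clamps negative branch lengths to zero; ties in the
  distance matrix resolve deterministically by label order via the
  underlying implementation.
* The k-mer placement distance is `-(1/k) ln(2j/(1+j))` with `j` the
  Jaccard index of the two k-mer sets (k = 12); disjoint sets map to a
  configurable cap (default 1) instead of infinity.
* All generator randomness flows from one top-level seed; derived
  sub-seeds stay far below 2^31.

## Design decisions where the design was open

* **Full 64-dimensional signatures**, no reverse-complement collapsing:
  the statistic is defined over all 64 trimers, and strand-specific
  signatures preserve information that canonicalization would average
  away.
* **Coverage cleaning as a fold band** around the anchor median,
  with anchors never removed: an automated, parameterized substitute for
  human judgment; 2.5-fold keeps typical assembler depth scatter while
  rejecting order-of-magnitude outliers.
* **Bin comparison metrics.** Within one assembly, bins are compared by
  the Jaccard index of member sets; across assemblies member sets are
  incomparable, so the anchors' signature correlation, rescaled to
  [0, 1] by `(r+1)/2`, is used instead. Single linkage at 0.5 then
  partitions the bins.
* **Pathway completeness** counts enzymatic steps, not gene symbols: the
  dearomatization step is satisfied by any class-I subunit or by the
  class-II *bamB*, and reductase presence is additionally reported as its
  own flag. "Near-complete" means exactly one step missing.
* **Placement stand-in.** The multilocus step uses alignment-free k-mer
  distances and neighbor joining rather than an external aligner and
  maximum-likelihood inference. This keeps placement fully reproducible
  inside the package and is intended as a qualitative neighborhood
  placement, not a substitute for a supported phylogeny.
* **Nucleotide concatenates** by default for the placement (an amino-acid
  mode would need gene translation conventions the inputs do not
  guarantee); concatenation order is the selected gene order, stable
  across runs.
* **Coverage dialect.** SPAdes-style header coverages are the default; a
  sidecar table overrides them when supplied, accommodating recomputed
  read depths without changing the interface.

## Known limitations

* Anchors on short or low-coverage contigs are discarded by design; a
  genome whose only reductase locus assembles onto a 5 kb contig will not
  be recovered.
* Correlation binning cannot separate strains or close congeners; such
  genomes arrive as one merged bin that the coverage filter may or may
  not split.
* Completeness/contamination are consumed, never computed — without
  external scores, bins are "unevaluable" rather than quality-classified,
  and chimera flagging falls back to the size rule alone.
* The placement tree has no support values and should be read as a
  neighborhood statement only.
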