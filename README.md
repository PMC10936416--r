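# anchormag

Gene-anchored recovery of metagenome-assembled genomes (MAGs) by
trinucleotide-signature correlation.

## The problem

Anaerobic degraders of monoaromatic compounds — organisms running the
benzoyl-CoA pathway — tend to sit in the long, low-abundance tail of
subsurface microbial communities, where generic binning of assembled
metagenomes often misses them. `anchormag` implements a targeted
alternative: instead of clustering all contigs, it first mines the
assembly's gene annotations for class-I benzoyl-CoA reductase subunits
(*bcrABCD*), takes the contigs carrying them as **anchors**, and then
recruits the rest of the genome by compositional similarity to those
anchors. The package is aimed at microbial ecologists working with
annotated contig assemblies (SPAdes-style FASTA plus Prokka-style GFF3)
who want a reproducible, scriptable version of this workflow, together
with a synthetic-community generator that makes every stage testable
without any external data.

## The method

For a contig $c$, let $t(c) \in \mathbb{R}^{64}$ be its trinucleotide
proportion signature: the fraction of each of the 64 possible 3-mers among
all overlapping 3-bp windows (windows containing ambiguous bases are
skipped; no reverse-complement collapsing). Signatures are approximately
constant across one genome, so they act as a compositional fingerprint.

1. **Mine.** Scan annotations for benzoyl-CoA pathway genes. A contig is
   an anchor if it carries a *bcrABCD* hit, its length exceeds 7 kbp, and
   its coverage exceeds 5.
2. **Bin.** For every contig $c$ with at least 1,000 bp, compute Pearson's
   correlation $R(t(c), t(a))$ against each anchor $a$; contigs with
   $R > 0.95$ join the anchor's bin. Mutually correlated anchors share a
   bin.
3. **Clean.** Remove members whose coverage falls outside a 2.5-fold band
   around the anchor median coverage (a reproducible stand-in for manual
   depth inspection).
4. **Characterize.** Per bin: total length, contig count, mean/median
   length, N50, maximum contig length, GC content; tallies of pathway
   genes; completeness of the route from benzoyl-CoA to
   3-hydroxypimeloyl-CoA (complete / near-complete / partial / absent);
   MIMAG-style draft quality from externally supplied
   completeness/contamination scores; and a chimera flag.
5. **Place (optional).** Select housekeeping genes present in the bin and
   a strict majority of reference genomes, concatenate them, compute
   alignment-free k-mer distances, and build a neighbor-joining tree.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
package's default synthetic community (three Markov-chain genomes at mean
coverages 20/10/6; the rare GC-rich genome carries the full pathway):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_mine.R
Rscript analysis/03_bin.R
Rscript analysis/04_characterize.R
Rscript analysis/05_mlsa.R
```

Stage 2 prints the mining result:

```
pathway gene hits: 8 on 6 contigs
bcrABCD per million CDS: 3777.1 (total CDS 1059)
anchors passing >7 kbp and coverage >5: 2
[1] "NODE_82_length_8440_cov_6.04679" "NODE_88_length_7811_cov_5.98631"
```

— eight planted pathway genes were found, and the two long, sufficiently
covered contigs carrying bcr subunits became anchors. Stage 3 bins against
them and scores the bin against the generator's ground truth:

```
GenomeBin 'bin_1': 41 contigs (2 anchors), R > 0.95, assembly 'contigs'
      bin_id   genome_id precision_bp recall_bp     f1_bp
bin_1  bin_1 gBcrCarrier            1 0.9935933 0.9967864
```

i.e. the bin contains only contigs of the bcr-carrying genome and captures
99.4% of its base pairs. Stage 4 reports the bin the way MAG tables are
usually printed:

```
      bin_id total_length_mbp total_contigs n50_mbp gc_percent total_bcr_subunits pathway_class
bin_1  bin_1              0.3            41    0.01       65.5                  4      complete
```

The four bcr subunits and all ring-opening genes landed in the bin, so the
benzoyl-CoA pathway is classified complete. In-memory equivalents:

```r
library(anchormag)
sim <- simulate_community(seed = 42L)
res <- run_pipeline(assembly = sim$assembly)
evaluate_bins(res$bins, sim$truth)
report_table(res$reports)
```

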