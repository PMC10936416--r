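#!/usr/bin/env Rscript
# Stage 1 — generate the default synthetic community.
#
# Three order-2 Markov genomes (GC 0.45 / 0.35 / 0.65, mean coverages
# 20 / 10 / 6) are sampled, fragmented into contigs with lognormal lengths,
# and annotated with planted benzoyl-CoA pathway genes plus filler CDS
# calls. The rare, GC-rich genome carries the full pathway including all
# four class-I reductase subunits — the genome the pipeline is meant to
# recover. Files (FASTA + GFF3 + truth labels) go to results/community/.

library(anchormag)

seed <- 42L
sim <- simulate_community(seed = seed)
dir <- "results/community"
write_community(sim, dir)

asm <- sim$assembly
cat(sprintf("community (seed %d): %d contigs, %.2f Mbp, %d CDS\n",
            seed, nrow(asm$contigs), sum(asm$contigs$length) / 1e6,
            asm$total_cds))
print(table(sim$truth$contig_genome$genome_id))
cat("planted pathway genes:\n")
print(sim$truth$planted)
cat("wrote", dir, "\n")
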