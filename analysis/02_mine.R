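#!/usr/bin/env Rscript
# Stage 2 — mine the annotations for benzoyl-CoA pathway genes and select
# anchor contigs.
#
# The annotation descriptions are searched for class-I benzoyl-CoA
# reductase subunits (bcrABCD) and the other pathway genes; contigs
# carrying a bcr subunit, longer than 7 kbp and with coverage above 5
# become binning anchors. Marker frequency is normalized per million CDS.

library(anchormag)

asm <- read_contigs("results/community/contigs.fasta")
asm <- set_annotations(asm, read_annotations("results/community/annotations.gff3"))
mined <- mine_anchors(asm)

dir.create("results/mining", showWarnings = FALSE, recursive = TRUE)
write.table(mined$hits, "results/mining/hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(contig_id = mined$anchor_set$anchors),
            "results/mining/anchors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("pathway gene hits: %d on %d contigs\n", nrow(mined$hits),
            length(unique(mined$hits$contig_id))))
print(table(mined$hits$pathway_gene))
cat(sprintf("bcrABCD per million CDS: %.1f (total CDS %d)\n",
            hits_per_million_cds(mined$hits, asm$total_cds), asm$total_cds))
cat(sprintf("anchors passing >7 kbp and coverage >5: %d\n",
            length(mined$anchor_set$anchors)))
print(mined$anchor_set$anchors)
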