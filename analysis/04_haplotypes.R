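#!/usr/bin/env Rscript
# Mitochondrial D-loop haplotypes: collapse the alignment, tabulate
# per-population counts, and build the minimum-spanning haplotype
# network.

library(lakestream)

dir.create("results", showWarnings = FALSE)
aln_raw <- read_fasta_alignment("results/data/dloop.fasta")
# population of each sequence is encoded in its id (site_seqNNN)
pop_map <- setNames(sub("_seq[0-9]+$", "", names(aln_raw$seqs)),
                    names(aln_raw$seqs))
aln <- alignment(aln_raw$seqs, pop_map)

tab <- collapse_haplotypes(aln)
net <- mst_network(tab)
write_haplotype_tables(tab, net, "results/haplotype_counts.tsv",
                       "results/haplotype_network_edges.tsv")

print(tab)
print(net)
cat(sprintf("predominant haplotype carries %d of %d sequences (%.0f%%)\n",
            max(rowSums(tab$counts)), sum(tab$counts),
            100 * max(rowSums(tab$counts)) / sum(tab$counts)))
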