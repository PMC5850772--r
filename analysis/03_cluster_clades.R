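#!/usr/bin/env Rscript
# Hierarchically cluster the clones (complete linkage, Euclidean on log2
# ratios), pick the number of primary clades by the within-group
# sum-of-squares elbow, and export the dendrogram.

library(cladecall)

out <- "results"
tab <- read_tsv_header(file.path(out, "expression_matrix.tsv"))
m <- as.matrix(tab[, -1]); rownames(m) <- tab$clone

dend <- cluster_profiles(m)
asg <- select_clade_count(dend, m)

meta <- list(stage = "cluster")
write_tsv_header(data.frame(clone = names(asg$clades),
                            clade = letters[asg$clades]),
                 file.path(out, "clades.tsv"), meta)
write_tsv_header(asg$trace, file.path(out, "clade_trace.tsv"), meta)
writeLines(dendrogram_newick(dend), file.path(out, "dendrogram.nwk"))

cat(sprintf("selected k = %d primary clades (cut height %.2f)\n",
            asg$k, asg$cut_height))
print(asg$trace)
cat("clade sizes:\n")
print(table(clade = letters[asg$clades]))
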