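#!/usr/bin/env Rscript
# Turn the raw Ct table into ancestor-relative log2 expression ratios,
# internally normalised to ACT1, with replicate standard errors.

library(cladecall)

out <- "results"
ct <- read_tsv_header(file.path(out, "ct_table.tsv"))
mat <- build_expression_matrix(ct, ancestor = "ancestor")

meta <- list(stage = "quantify")
lg <- cbind(clone = rownames(mat$log2), as.data.frame(mat$log2))
write_tsv_header(lg, file.path(out, "expression_matrix.tsv"), meta)
se <- cbind(clone = rownames(mat$se), as.data.frame(mat$se))
write_tsv_header(se, file.path(out, "expression_matrix.se.tsv"), meta)

cat(sprintf("expression matrix: %d clones x %d genes\n",
            nrow(mat$log2), ncol(mat$log2)))
cat("per-gene log2 ratio ranges:\n")
print(round(apply(mat$log2, 2, range), 2))
cat(sprintf("median replicate SE: %.3f log2 units\n", median(mat$se)))
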