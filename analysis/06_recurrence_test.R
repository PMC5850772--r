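#!/usr/bin/env Rscript
# Is the same gene hit in more independent clones than chance allows?
# Exact binomial recurrence test over the simulated mutation table,
# under both the per-mutation and per-clone nulls.

library(cladecall)

out <- "results"
mut <- read_tsv_header(file.path(out, "mutations.tsv"))
genes <- read_tsv_header(file.path(out, "gene_lengths.tsv"))
lens <- setNames(genes$length_bp, genes$gene)
G <- 12e6

for (null in c("per_mutation", "per_clone")) {
  res <- test_recurrence(mut, lens, G, null = null)
  cat(sprintf("\nnull = %s (n = %s):\n", null,
              if (nrow(res)) res$n[1] else "-"))
  print(transform(res, p_value = signif(p_value, 3),
                  adjusted_p = signif(adjusted_p, 3),
                  p_hit = signif(p_hit, 3)))
  write_tsv_header(res, file.path(out, paste0("recurrence_", null, ".tsv")),
                   list(stage = "recurrence", null = null))
}
cat("\ngenes under simulated positive selection should dominate the top;\n")
cat("with per-gene hit probabilities ~1e-4, double-digit recurrent hits\n")
cat("give vanishing exact binomial tails.\n")
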