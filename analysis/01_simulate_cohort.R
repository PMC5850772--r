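#!/usr/bin/env Rscript
# Simulate the raffinose-evolution cohort: 92 evolved clones (27 haploid-,
# 32 diploid-, 33 tetraploid-derived) spanning nine driver-mutation
# classes, measured on the five-gene glucose-inducible qRT-PCR panel in
# triplicate reactions for each of two biological replicates, plus a
# neutral-with-selection mutation table for the recurrence analysis.

library(cladecall)

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
meta <- list(seed = seed, stage = "simulate")
write_tsv_header(cohort$ct, file.path(out, "ct_table.tsv"), meta)
write_tsv_header(cohort$truth, file.path(out, "truth_labels.tsv"), meta)

cat(sprintf("cohort: %d clones + ancestor, %d Ct records\n",
            nrow(cohort$truth) - 1L, nrow(cohort$ct)))
print(table(ploidy = cohort$truth$ploidy[cohort$truth$clone != "ancestor"]))

# mutational target: the six recurrently hit driver genes inside a 12 Mb
# callable genome; IPT1 and MOT3 get strong positive selection so the
# recurrence analysis has true signal to find
genes <- data.frame(
  gene = c("SNF3", "RGT2", "MTH1", "RGT1", "IPT1", "MOT3"),
  length_bp = c(2655, 2292, 1302, 3513, 1584, 1473),
  weight = c(60, 10, 40, 10, 50, 50))
mut_cfg <- mutation_sim_config(genes, target_length = 12e6,
                               mean_mutations = 6, seed = seed)
mut <- generate_mutation_table(mut_cfg, n_clones = 92)
write_tsv_header(mut, file.path(out, "mutations.tsv"), meta)
write_tsv_header(genes, file.path(out, "gene_lengths.tsv"), meta)
cat(sprintf("mutation table: %d mutations in %d clones (%d genic)\n",
            nrow(mut), length(unique(mut$clone)),
            sum(mut$gene != "intergenic")))
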