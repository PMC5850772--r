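#!/usr/bin/env Rscript
# Predict each clone's adaptive driver mutation from clade co-membership
# with genotyped clones, withholding 21 clones (3 haploid-, 9 diploid-,
# 9 tetraploid-derived) as a validation set.

library(cladecall)

out <- "results"
seed <- 1L
tab <- read_tsv_header(file.path(out, "expression_matrix.tsv"))
m <- as.matrix(tab[, -1]); rownames(m) <- tab$clone
truth_tab <- read_tsv_header(file.path(out, "truth_labels.tsv"))
truth <- setNames(truth_tab$class, truth_tab$clone)[rownames(m)]

held_out <- holdout_split(truth_tab, seed = seed + 1000L)
labels <- truth; labels[held_out] <- NA

fit <- predict_cohort(m, labels)
meta <- list(seed = seed, stage = "predict")
write_tsv_header(fit$predictions, file.path(out, "predictions.tsv"), meta)
write_tsv_header(fit$label_map, file.path(out, "clade_labels.tsv"), meta)

pred <- fit$predictions
ev <- evaluate_predictions(pred[pred$clone %in% held_out, ], truth)
cat(sprintf("clades: k = %d; hold-out clones: %d\n",
            fit$assignment$k, length(held_out)))
cat(sprintf("hold-out prediction accuracy: %d/%d (%.1f%%)\n",
            round(ev$accuracy * ev$n), ev$n, 100 * ev$accuracy))
print(ev$confusion)
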