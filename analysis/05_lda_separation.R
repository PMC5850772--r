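#!/usr/bin/env Rscript
# Linear discriminant analysis of the expression panel, grouping the
# clones either by adaptive mutation or by ancestral ploidy, with 95%
# confidence ellipses: does the driver or the ploidy organise the
# expression space?

library(cladecall)

out <- "results"
tab <- read_tsv_header(file.path(out, "expression_matrix.tsv"))
m <- as.matrix(tab[, -1]); rownames(m) <- tab$clone
truth_tab <- read_tsv_header(file.path(out, "truth_labels.tsv"))
keep <- truth_tab$clone %in% rownames(m)
mg <- setNames(truth_tab$class[keep], truth_tab$clone[keep])
pg <- setNames(truth_tab$ploidy[keep], truth_tab$clone[keep])

rep <- separation_report(m, mg, pg)
print(rep)
cat("per-class CV accuracy, mutation grouping:\n")
print(round(rep$mutation$cv$per_class, 3))
cat("per-class CV accuracy, ploidy grouping:\n")
print(round(rep$ploidy$cv$per_class, 3))

sc <- rep$mutation$fit$scores
write_tsv_header(data.frame(clone = rownames(sc), ld1 = sc[, 1],
                            ld2 = sc[, 2], class = mg[rownames(sc)]),
                 file.path(out, "lda_scores_mutation.tsv"),
                 list(stage = "lda"))
ov <- rbind(cbind(grouping = "mutation", rep$mutation$overlap),
            cbind(grouping = "ploidy", rep$ploidy$overlap))
write_tsv_header(ov, file.path(out, "ellipse_overlap.tsv"),
                 list(stage = "lda"))
cat(sprintf("mean pairwise ellipse overlap: mutation %.3f, ploidy %.3f\n",
            mean(rep$mutation$overlap$overlap),
            mean(rep$ploidy$overlap$overlap)))

pdf(file.path(out, "lda_scores.pdf"), width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
for (side in c("mutation", "ploidy")) {
  fit <- rep[[side]]$fit
  grp <- if (side == "mutation") mg else pg
  cols <- setNames(seq_along(fit$classes), fit$classes)
  plot(fit$scores, col = cols[grp[rownames(fit$scores)]], pch = 19,
       cex = 0.7, main = paste("grouped by", side),
       xlab = "LD1", ylab = "LD2")
  for (cl in names(rep[[side]]$ellipses))
    lines(ellipse_boundary(rep[[side]]$ellipses[[cl]]), col = cols[cl])
}
invisible(dev.off())
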