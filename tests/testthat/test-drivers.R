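# clade labeling by majority vote and clade-co-membership prediction

test_that("clade labels follow the majority with support and conflict counts", {
  asg <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L),
                  c("c1", "c2", "c3", "c4", "c5", "c6"))
  lm <- label_clades(asg, c(c1 = "MTH1", c2 = "MTH1", c3 = "SNF3",
                            c4 = "RGT2"))
  expect_equal(lm$class[lm$clade == 1], "MTH1")
  expect_equal(lm$n_support[lm$clade == 1], 2L)
  expect_equal(lm$n_conflict[lm$clade == 1], 1L)
  expect_equal(lm$class[lm$clade == 2], "RGT2")
  expect_equal(lm$n_support[lm$clade == 2], 1L)
  expect_true(lm$abstain[lm$clade == 3])     # no labeled member
  expect_error(label_clades(asg, c(zz = "MTH1")), "absent")
})

test_that("majority vote agrees with exhaustive enumeration on all small multisets", {
  classes <- c("A", "B", "C")
  for (n_lab in 1:4) {
    combos <- expand.grid(rep(list(classes), n_lab), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      lab <- unlist(combos[r, ], use.names = FALSE)
      asg <- setNames(rep(1L, n_lab), paste0("c", seq_len(n_lab)))
      lm <- label_clades(asg, setNames(lab, names(asg)))
      # enumeration oracle: explicit counts
      counts <- sapply(classes, function(cl) sum(lab == cl))
      top <- max(counts)
      winners <- names(counts)[counts == top]
      if (length(winners) == 1L) {
        expect_equal(lm$class, winners)
        expect_equal(lm$n_support, top)
        expect_equal(lm$n_conflict, as.integer(n_lab - top))
      } else {
        expect_true(lm$abstain)
      }
    }
  }
})

test_that("predictions carry the clade label, support fraction and UNDETERMINED", {
  asg <- setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d"))
  lm <- label_clades(asg, c(a = "MTH1", b = "MTH1", c = "SNF3"))
  pred <- predict_drivers(asg, lm, c("c", "d"))
  expect_equal(pred$predicted_class, c("MTH1", "UNDETERMINED"))
  expect_equal(pred$support, c(2 / 3, NA))
  expect_error(predict_drivers(asg, lm, "nope"), "absent")
})

test_that("evaluation counts match a hand-tallied confusion fixture", {
  pred <- data.frame(clone = c("a", "b", "c", "d", "e"),
                     predicted_class = c("X", "X", "Y", "UNDETERMINED", "Y"),
                     stringsAsFactors = FALSE)
  truth <- c(a = "X", b = "Y", c = "Y", d = "X", e = "Y")
  ev <- evaluate_predictions(pred, truth)
  expect_equal(ev$accuracy, 3 / 5)          # a, c, e correct
  expect_equal(ev$per_class[["X"]], 1 / 2)
  expect_equal(ev$per_class[["Y"]], 2 / 3)
  ev2 <- evaluate_predictions(pred, truth, count_undetermined = FALSE)
  expect_equal(ev2$accuracy, 3 / 4)
  expect_equal(ev2$n, 4L)
  all_und <- data.frame(clone = "a", predicted_class = "UNDETERMINED")
  expect_equal(evaluate_predictions(all_und, truth)$accuracy, 0)
  expect_error(evaluate_predictions(pred, c(a = "X")), "no truth")
})

test_that("an unlabeled clone identical to a labeled one gets the same call", {
  sig <- default_signatures()
  zero <- signature_set(sig$mean_log2, 0)
  cnt <- matrix(c(3L, 3L, 3L), 1,
                dimnames = list("2N", c("SNF3_high", "MTH1", "HXT67_amp")))
  coh <- generate_cohort(cohort_config(counts = cnt, tech_sd = 0, seed = 2),
                         zero)
  mat <- build_expression_matrix(coh$ct, "ancestor")
  truth <- setNames(coh$truth$class, coh$truth$clone)
  truth <- truth[rownames(mat$log2)]
  lab <- truth
  lab[c(1, 4, 7)] <- NA                      # one unlabeled per class
  fit <- predict_cohort(mat$log2, lab, k = 3)
  ev <- evaluate_predictions(fit, truth)
  expect_equal(ev$accuracy, 1)
})

test_that("zero-noise cohorts are predicted perfectly for unique signatures", {
  sig <- default_signatures()
  zero <- signature_set(sig$mean_log2, 0)
  coh <- generate_cohort(cohort_config(tech_sd = 0, seed = 6), zero)
  mat <- build_expression_matrix(coh$ct, "ancestor")
  truth <- setNames(coh$truth$class, coh$truth$clone)
  truth <- truth[rownames(mat$log2)]
  hold <- holdout_split(coh$truth, seed = 6)
  lab <- truth; lab[hold] <- NA
  fit <- predict_cohort(mat, lab)
  ev <- evaluate_predictions(
    fit$predictions[fit$predictions$clone %in% hold, ], truth)
  expect_equal(ev$accuracy, 1)
})

test_that("label-holdout LOOCV equals the brute-force pipeline re-run oracle", {
  cnt <- matrix(c(4L, 4L, 4L, 4L), 1,
                dimnames = list("2N", c("SNF3_high", "MTH1",
                                        "HXT67_amp", "MOT3")))
  coh <- generate_cohort(cohort_config(counts = cnt, seed = 10))
  mat <- build_expression_matrix(coh$ct, "ancestor")
  truth <- setNames(coh$truth$class, coh$truth$clone)
  truth <- truth[rownames(mat$log2)]
  cv <- predict_loocv(mat, truth, k = 3)
  # oracle: re-run the entire prediction pipeline per held-out label
  oracle <- vapply(names(truth), function(cl) {
    fit <- predict_cohort(mat, truth[setdiff(names(truth), cl)], k = 3)
    fit$predictions$predicted_class[fit$predictions$clone == cl]
  }, character(1))
  expect_identical(setNames(cv$detail$predicted, cv$detail$clone), oracle)
  expect_equal(cv$accuracy, mean(oracle == truth))
})

test_that("re-predicting from a fixed assignment is deterministic", {
  set.seed(20)
  X <- toy_clusters(rbind(c(0, 0, 0), c(5, 5, 0), c(0, 5, 5)),
                    n_per = 4, sd = 0.2)
  lab <- setNames(rep(c("A", "B", "C"), each = 4), rownames(X))[c(1:2, 5:6, 9:10)]
  hc <- cluster_profiles(X)
  asg <- select_clade_count(hc, X, k = 3)
  lm1 <- label_clades(asg, lab)
  lm2 <- label_clades(asg, lab)
  expect_identical(lm1, lm2)
  expect_identical(predict_drivers(asg, lm1), predict_drivers(asg, lm2))
  # adding a clone consistent with the majority never flips the label
  lab2 <- c(lab, setNames("A", rownames(X)[3]))
  lm3 <- label_clades(asg, lab2)
  expect_equal(lm3$class[lm3$clade == asg$clades[[rownames(X)[3]]]],
               lm1$class[lm1$clade == asg$clades[[rownames(X)[3]]]])
})
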