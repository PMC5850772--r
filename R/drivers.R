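# Clade-based prediction of the adaptive driver mutation: label each
# primary clade by majority vote over its genotyped members, then assign
# every unlabeled clone its clade's label.

.as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("clone", "class") %in% names(labels)))
      .stop2("label table needs columns 'clone' and 'class'")
    labels <- setNames(as.character(labels$class), labels$clone)
  }
  if (is.null(names(labels))) .stop2("labels must be named by clone")
  labels[!is.na(labels)]
}

.majority_vote <- function(lab) {
  # returns list(class, n_support, n_conflict); ties or no labels abstain
  if (!length(lab))
    return(list(class = NA_character_, n_support = 0L, n_conflict = 0L))
  tb <- sort(table(lab), decreasing = TRUE)
  if (length(tb) > 1L && tb[1L] == tb[2L])
    return(list(class = NA_character_, n_support = as.integer(tb[1L]),
                n_conflict = as.integer(sum(tb) - tb[1L])))
  list(class = names(tb)[1L], n_support = as.integer(tb[1L]),
       n_conflict = as.integer(sum(tb) - tb[1L]))
}

#' Label clades by the known drivers of genotyped members
#'
#' Per clade, the driver-mutation classes of its genotyped (labeled)
#' members are tallied and the majority class becomes the clade label.
#' Clades with no labeled member, or with a tied vote, ABSTAIN.
#'
#' @param assignment a `clade_assignment` from [select_clade_count()], or
#'   a named integer vector clone -> clade.
#' @param labels named character vector (or data.frame clone, class) of
#'   known driver classes for a subset of clones; `NA` entries are
#'   ignored.
#' @return data.frame with one row per clade: clade, class (`NA` on
#'   abstain), n_support, n_conflict, abstain.
#' @export
label_clades <- function(assignment, labels) {
  clades <- if (inherits(assignment, "clade_assignment"))
    assignment$clades else assignment
  labels <- .as_label_vector(labels)
  unknown <- setdiff(names(labels), names(clades))
  if (length(unknown))
    .stop2("labels refer to clones absent from the assignment: ",
           paste(unknown, collapse = ", "))
  ids <- sort(unique(clades))
  rows <- lapply(ids, function(cl) {
    mem <- names(clades)[clades == cl]
    v <- .majority_vote(labels[intersect(mem, names(labels))])
    data.frame(clade = cl, class = v$class, n_support = v$n_support,
               n_conflict = v$n_conflict,
               abstain = is.na(v$class), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict driver mutations for unlabeled clones
#'
#' Each clone receives its clade's majority label with a support fraction
#' (labeled members agreeing / labeled members in the clade); clones in
#' abstaining clades are `UNDETERMINED` with support `NA`.
#'
#' @inheritParams label_clades
#' @param label_map output of [label_clades()].
#' @param clones clone ids to predict; default all clones without a label.
#' @return data.frame: clone, clade, predicted_class, support.
#' @export
predict_drivers <- function(assignment, label_map, clones = NULL) {
  clades <- if (inherits(assignment, "clade_assignment"))
    assignment$clades else assignment
  if (is.null(clones)) clones <- names(clades)
  missing_cl <- setdiff(clones, names(clades))
  if (length(missing_cl))
    .stop2("clones absent from the assignment: ",
           paste(missing_cl, collapse = ", "))
  idx <- match(clades[clones], label_map$clade)
  n_lab <- label_map$n_support[idx] + label_map$n_conflict[idx]
  support <- ifelse(n_lab > 0, label_map$n_support[idx] / n_lab, NA_real_)
  pred <- ifelse(label_map$abstain[idx], "UNDETERMINED",
                 label_map$class[idx])
  support[label_map$abstain[idx]] <- NA_real_
  data.frame(clone = clones, clade = unname(clades[clones]),
             predicted_class = pred, support = support,
             stringsAsFactors = FALSE)
}

#' Cluster, label and predict in one step
#'
#' The full expression-to-genotype prediction: cluster the profiles with
#' complete linkage, select the number of primary clades (elbow rule
#' unless `k` is forced), label clades by majority vote of the genotyped
#' clones, and predict every clone's driver from clade co-membership.
#'
#' When a clade's genotyped members disagree beyond `conflict_threshold`
#' (fraction of labeled members outside the majority class), an optional
#' second-level cut splits that clade into as many sub-clades as it has
#' distinct labels, and the vote is repeated within each sub-clade. A
#' sub-clade with no genotyped member inherits the label of the nearest
#' labeled sub-clade (centroid distance), falling back to the parent
#' clade's majority when the vote there is tied. This mirrors resolving a
#' mixed clade into its sub-clades (e.g. a distinct sub-clade of MTH1
#' mutants inside a predominantly SNF3 clade) before reading off the
#' prediction.
#'
#' @param x profile matrix or `expression_matrix`.
#' @param labels known driver classes (named vector or data.frame); clones
#'   absent or `NA` are treated as ungenotyped.
#' @param k optional forced clade count; default automatic elbow rule.
#' @param k_max scan limit for the automatic rule.
#' @param metric clustering metric, see [cluster_profiles()].
#' @param refine enable the second-level cut of conflicted clades.
#' @param conflict_threshold minimum conflict fraction triggering
#'   refinement (default 0.05: any genuine minority label triggers it).
#' @return list of class `driver_prediction`: `predictions` (data.frame
#'   clone, clade, subclade, predicted_class, support), `assignment`,
#'   `label_map`, `dendrogram`.
#' @export
predict_cohort <- function(x, labels, k = NULL, k_max = NULL,
                           metric = "euclidean", refine = TRUE,
                           conflict_threshold = 0.05) {
  if (inherits(x, "expression_matrix")) x <- x$log2
  labels <- .as_label_vector(labels)
  dend <- cluster_profiles(x, metric = metric)
  assignment <- select_clade_count(dend, x, k_max = k_max, k = k)
  label_map <- label_clades(assignment, labels)
  pred <- predict_drivers(assignment, label_map)
  pred$subclade <- NA_integer_

  if (refine) {
    for (r in seq_len(nrow(label_map))) {
      cl <- label_map$clade[r]
      n_lab <- label_map$n_support[r] + label_map$n_conflict[r]
      if (n_lab == 0L) next
      conflict <- label_map$n_conflict[r] / n_lab
      mem <- names(assignment$clades)[assignment$clades == cl]
      mem_lab <- labels[intersect(mem, names(labels))]
      m <- length(unique(mem_lab))
      if (m < 2L || conflict <= conflict_threshold || length(mem) < 3L)
        next
      sub_dend <- cluster_profiles(x[mem, , drop = FALSE], metric = metric)
      sub <- cutree(sub_dend, k = min(m, length(mem)))
      parent_vote <- .majority_vote(mem_lab)
      sub_ids <- sort(unique(sub))
      votes <- lapply(sub_ids, function(sc)
        .majority_vote(labels[intersect(mem[sub == sc], names(labels))]))
      centroids <- t(vapply(sub_ids, function(sc)
        colMeans(x[mem[sub == sc], , drop = FALSE]), numeric(ncol(x))))
      labeled_sub <- which(!vapply(votes, function(v)
        v$n_support + v$n_conflict == 0L, logical(1)))
      for (si in seq_along(sub_ids)) {
        sc <- sub_ids[si]
        smem <- mem[sub == sc]
        v <- votes[[si]]
        if (v$n_support + v$n_conflict == 0L && length(labeled_sub)) {
          # unlabeled sub-clade: inherit from the nearest labeled one
          dd <- vapply(labeled_sub, function(lj)
            sqrt(sum((centroids[si, ] - centroids[lj, ])^2)), numeric(1))
          v <- votes[[labeled_sub[which.min(dd)]]]
        }
        if (is.na(v$class)) v <- parent_vote
        ii <- match(smem, pred$clone)
        pred$predicted_class[ii] <- if (is.na(v$class)) "UNDETERMINED" else
          v$class
        pred$support[ii] <- if (v$n_support + v$n_conflict > 0)
          v$n_support / (v$n_support + v$n_conflict) else NA_real_
        pred$subclade[ii] <- sc
      }
    }
  }
  structure(list(predictions = pred[, c("clone", "clade", "subclade",
                                        "predicted_class", "support")],
                 assignment = assignment, label_map = label_map,
                 dendrogram = dend),
            class = "driver_prediction")
}

#' @export
print.driver_prediction <- function(x, ...) {
  cat("driver prediction over", nrow(x$predictions), "clones in",
      x$assignment$k, "clades\n")
  print(table(predicted = x$predictions$predicted_class))
  invisible(x)
}

#' Score predictions against known truth
#'
#' @param predictions data.frame with columns clone, predicted_class (as
#'   produced by [predict_drivers()] or [predict_cohort()]).
#' @param truth named character vector (or data.frame clone, class) of
#'   true classes covering every predicted clone.
#' @param count_undetermined if `TRUE` (default) `UNDETERMINED`
#'   predictions count as incorrect; if `FALSE` they are excluded.
#' @return list with `accuracy`, `per_class` (named accuracy vector),
#'   `n`, `confusion` (table truth x predicted).
#' @export
evaluate_predictions <- function(predictions, truth,
                                 count_undetermined = TRUE) {
  if (inherits(predictions, "driver_prediction"))
    predictions <- predictions$predictions
  truth <- .as_label_vector(truth)
  miss <- setdiff(predictions$clone, names(truth))
  if (length(miss))
    .stop2("no truth label for: ", paste(miss, collapse = ", "))
  tr <- truth[predictions$clone]
  pr <- predictions$predicted_class
  keep <- if (count_undetermined) rep(TRUE, length(pr)) else
    pr != "UNDETERMINED"
  ok <- pr[keep] == tr[keep]
  per_class <- vapply(split(ok, tr[keep]), mean, numeric(1))
  list(accuracy = if (any(keep)) mean(ok) else NA_real_,
       per_class = per_class, n = sum(keep),
       confusion = table(truth = tr[keep], predicted = pr[keep]))
}

#' Leave-one-label-out accuracy of clade prediction
#'
#' For each genotyped clone in turn, its label is hidden, clade labels are
#' recomputed from the remaining genotyped clones, and the hidden clone is
#' re-predicted. Clustering does not depend on the labels, so the
#' dendrogram is computed once; re-running the full pipeline per held-out
#' clone gives identical results.
#'
#' @inheritParams predict_cohort
#' @return list with `accuracy` and `detail` (data.frame clone, truth,
#'   predicted).
#' @export
predict_loocv <- function(x, labels, k = NULL, k_max = NULL,
                          metric = "euclidean", refine = TRUE,
                          conflict_threshold = 0.05) {
  if (inherits(x, "expression_matrix")) x <- x$log2
  labels <- .as_label_vector(labels)
  dend <- cluster_profiles(x, metric = metric)
  assignment <- select_clade_count(dend, x, k_max = k_max, k = k)
  clades <- assignment$clades
  sub_dend_cache <- list()

  predict_one <- function(cl, lab2) {
    my_clade <- clades[[cl]]
    mem <- names(clades)[clades == my_clade]
    mem_lab <- lab2[intersect(mem, names(lab2))]
    v <- .majority_vote(mem_lab)
    n_lab <- v$n_support + v$n_conflict
    conflict <- if (n_lab > 0) v$n_conflict / n_lab else 1
    m <- length(unique(mem_lab))
    if (refine && m >= 2L && conflict > conflict_threshold &&
        length(mem) >= 3L) {
      key <- as.character(my_clade)
      if (is.null(sub_dend_cache[[key]]))
        sub_dend_cache[[key]] <<- cluster_profiles(x[mem, , drop = FALSE],
                                                   metric = metric)
      sub <- cutree(sub_dend_cache[[key]], k = min(m, length(mem)))
      sub_ids <- sort(unique(sub))
      votes <- lapply(sub_ids, function(sc)
        .majority_vote(lab2[intersect(mem[sub == sc], names(lab2))]))
      si <- match(sub[[cl]], sub_ids)
      sv <- votes[[si]]
      if (sv$n_support + sv$n_conflict == 0L) {
        labeled_sub <- which(vapply(votes, function(vv)
          vv$n_support + vv$n_conflict > 0L, logical(1)))
        if (length(labeled_sub)) {
          centroids <- t(vapply(sub_ids, function(sc)
            colMeans(x[mem[sub == sc], , drop = FALSE]), numeric(ncol(x))))
          dd <- vapply(labeled_sub, function(lj)
            sqrt(sum((centroids[si, ] - centroids[lj, ])^2)), numeric(1))
          sv <- votes[[labeled_sub[which.min(dd)]]]
        }
      }
      if (is.na(sv$class)) sv <- v
      v <- sv
    }
    if (is.na(v$class)) "UNDETERMINED" else v$class
  }

  detail <- do.call(rbind, lapply(names(labels), function(cl) {
    data.frame(clone = cl, truth = unname(labels[cl]),
               predicted = predict_one(cl, labels[setdiff(names(labels), cl)]),
               stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(detail$predicted == detail$truth), detail = detail)
}
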