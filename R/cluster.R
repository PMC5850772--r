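# Hierarchical clustering of clone expression profiles and selection of
# the number of primary clades.
#
# Agglomeration is written out explicitly (Lance-Williams update for
# complete linkage) so that ties in inter-cluster distance are resolved by
# a fixed, documented rule -- merge the pair whose (lexicographically
# sorted) smallest leaf labels compare lowest -- making the clade
# partition invariant under permutation of the input rows. The result is
# a standard "hclust" object, so cutree(), cophenetic() and plotting all
# apply.

.dist_matrix <- function(x, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(x, method = "euclidean"))
  } else {
    d <- 1 - stats::cor(t(x))
    diag(d) <- 0
    d
  }
}

#' Complete-linkage clustering of expression profiles
#'
#' @param x numeric matrix (clones x genes) of log2 ratios, or an
#'   `expression_matrix` from [build_expression_matrix()].
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation of profiles).
#' @return An object of class `hclust`. A single-row input returns a
#'   degenerate single-leaf object (no merges) of class
#'   `c("hclust_leaf", "hclust")`.
#' @export
cluster_profiles <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (inherits(x, "expression_matrix")) x <- x$log2
  if (!is.matrix(x) || !is.numeric(x)) .stop2("'x' must be a numeric matrix")
  if (anyNA(x)) .stop2("profile matrix contains missing values")
  if (is.null(rownames(x))) rownames(x) <- sprintf("obs%03d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) .stop2("clone labels must be unique")
  n <- nrow(x)
  labels <- rownames(x)
  if (n == 1L)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L, labels = labels,
                          method = "complete", dist.method = metric),
                     class = c("hclust_leaf", "hclust")))

  D <- .dist_matrix(x, metric)
  active <- seq_len(n)              # active cluster slots
  node_of <- -seq_len(n)            # hclust code of each slot
  min_lab <- labels                 # lexicographically smallest leaf label
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  Dw <- D; diag(Dw) <- Inf

  for (step in seq_len(n - 1L)) {
    sub <- Dw[active, active, drop = FALSE]
    m <- min(sub)
    hits <- which(sub == m, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    if (nrow(hits) > 1L) {
      keys <- apply(hits, 1L, function(h) {
        labs <- sort(c(min_lab[active[h[1L]]], min_lab[active[h[2L]]]))
        paste(labs, collapse = "\r")
      })
      hits <- hits[order(keys)[1L], , drop = FALSE]
    }
    i <- active[hits[1L, 1L]]; j <- active[hits[1L, 2L]]
    a <- node_of[i]; b <- node_of[j]
    # hclust convention: singletons (negative) before clusters, else by value
    merge[step, ] <- if (a < 0 && b < 0) sort(c(a, b)) else
      if (a * b < 0) c(min(a, b), max(a, b)) else sort(c(a, b))
    height[step] <- m
    # complete-linkage Lance-Williams update into slot i
    upd <- pmax(Dw[i, ], Dw[j, ])
    Dw[i, ] <- upd; Dw[, i] <- upd
    Dw[i, i] <- Inf
    node_of[i] <- step
    min_lab[i] <- min(min_lab[i], min_lab[j])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }

  ord <- .leaf_order(merge, height, labels)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "complete",
                 dist.method = metric),
            class = "hclust")
}

# leaf ordering: at each internal node the tighter (lower-height) child
# is placed first; ties broken by smallest contained leaf label
.leaf_order <- function(merge, height, labels) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0) return(-node)
    kids <- merge[node, ]
    info <- lapply(kids, function(k) {
      leaves <- expand(k)
      list(leaves = leaves,
           h = if (k < 0) 0 else height[k],
           lab = min(labels[leaves]))
    })
    o <- order(vapply(info, `[[`, numeric(1), "h"),
               vapply(info, `[[`, character(1), "lab"))
    c(info[[o[1L]]]$leaves, info[[o[2L]]]$leaves)
  }
  expand(nrow(merge))
}

#' Within-group sum of squares for a partition
#'
#' @param x numeric matrix of profiles.
#' @param groups integer/factor vector assigning each row to a group.
#' @return Total within-group sum of squared Euclidean deviations from
#'   group centroids.
#' @export
wgss <- function(x, groups) {
  if (inherits(x, "expression_matrix")) x <- x$log2
  sum(vapply(split(seq_len(nrow(x)), groups), function(ix)
    sum(scale(x[ix, , drop = FALSE], scale = FALSE)^2), numeric(1)))
}

#' Select the number of primary clades
#'
#' Computes the within-group sum of squares (WGSS) of the dendrogram cut
#' at k = 1..k_max and selects k by the elbow rule: maximise the second
#' forward difference `WGSS(k-1) - 2 WGSS(k) + WGSS(k+1)` over
#' 2 <= k <= k_max - 1 (ties resolved to the smallest k). A forced `k`
#' bypasses the rule but the full trace is still returned so the
#' automatic choice can be inspected.
#'
#' Clade ids 1..k are assigned in dendrogram left-to-right order.
#'
#' @param dend an `hclust` object from [cluster_profiles()].
#' @param x the profile matrix the dendrogram was built from.
#' @param k_max largest k to scan (default `min(10, n)`).
#' @param k optional forced clade count.
#' @return A list of class `clade_assignment`: `k`, `clades` (named
#'   integer vector clone -> clade), `cut_height`, and `trace`
#'   (data.frame k, wgss, elbow_stat).
#' @export
select_clade_count <- function(dend, x, k_max = NULL, k = NULL) {
  if (inherits(x, "expression_matrix")) x <- x$log2
  n <- length(dend$labels)
  if (is.null(k_max)) k_max <- min(10L, n)
  if (k_max > n) .stop2("'k_max' cannot exceed the number of clones")
  if (is.null(k) && k_max < 3L)
    .stop2("automatic selection needs k_max >= 3; force a clade count with 'k'")
  if (n == 1L) {
    cl <- setNames(1L, dend$labels)
    return(structure(list(k = 1L, clades = cl, cut_height = 0,
                          trace = data.frame(k = 1L, wgss = 0,
                                             elbow_stat = NA_real_)),
                     class = "clade_assignment"))
  }
  ks <- seq_len(k_max)
  w <- vapply(ks, function(kk) wgss(x, cutree(dend, kk)), numeric(1))
  elbow <- rep(NA_real_, k_max)
  if (k_max >= 3L) {
    mid <- 2:(k_max - 1L)
    elbow[mid] <- w[mid - 1L] - 2 * w[mid] + w[mid + 1L]
  }
  k_sel <- if (is.null(k)) {
    mid <- 2:(k_max - 1L)
    mid[which.max(elbow[mid])]
  } else {
    if (k < 1L || k > n) .stop2("forced 'k' must lie in [1, n]")
    as.integer(k)
  }
  ct <- cutree(dend, k_sel)
  # renumber clades left-to-right along the dendrogram leaf order
  pos <- vapply(split(match(dend$labels, dend$labels[dend$order]), ct),
                min, numeric(1))
  new_id <- match(ct, as.integer(names(sort(pos))))
  clades <- setNames(as.integer(new_id), dend$labels)
  cut_height <- if (k_sel == 1L) Inf else if (k_sel > length(dend$height))
    0 else sort(dend$height, decreasing = TRUE)[k_sel - 1L]
  structure(list(k = k_sel, clades = clades, cut_height = cut_height,
                 trace = data.frame(k = ks, wgss = w, elbow_stat = elbow)),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat("clade assignment: k =", x$k, "\n")
  print(table(clade = x$clades))
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' Leaves carry clone ids; branch lengths are differences of merge
#' heights, so the tree is ultrametric with leaf depth equal to the root
#' merge height. Round-trips through a Newick parser (e.g.
#' `ape::read.tree`) up to topology and branch lengths.
#'
#' @param dend an `hclust` object.
#' @param digits significant digits for branch lengths.
#' @return A single Newick string, terminated by ";".
#' @export
dendrogram_newick <- function(dend, digits = 10) {
  if (length(dend$labels) == 1L) return(paste0(dend$labels, ";"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  build <- function(node, parent_h) {
    if (node < 0) {
      paste0(dend$labels[-node], ":", fmt(parent_h))
    } else {
      h <- dend$height[node]
      paste0("(", build(dend$merge[node, 1L], h), ",",
             build(dend$merge[node, 2L], h), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  paste0("(", build(dend$merge[root, 1L], h), ",",
         build(dend$merge[root, 2L], h), ");")
}
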