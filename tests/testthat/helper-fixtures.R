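# shared fixtures: tiny Ct tables and toy profile matrices, all built in
# code so tests are self-contained

# Ct table from a named list clone -> gene -> vector of per-bio-rep mean
# Cts; each bio rep gets `n_tech` identical (or jittered) reactions
make_ct <- function(values, n_tech = 1L, jitter = 0) {
  rows <- list()
  for (cl in names(values)) for (g in names(values[[cl]])) {
    cts <- values[[cl]][[g]]
    for (b in seq_along(cts)) for (t in seq_len(n_tech)) {
      rows[[length(rows) + 1L]] <- data.frame(
        clone = cl, gene = g, bio_rep = b, tech_rep = t,
        ct = cts[b] + if (jitter > 0) rnorm(1, 0, jitter) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# profile matrix of k well-separated point clusters (optionally exact)
toy_clusters <- function(centers, n_per, sd = 0, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rep(centers[i, ], each = n_per), n_per) +
      matrix(rnorm(n_per * ncol(centers), 0, sd), n_per)))
  rownames(X) <- sprintf("p%02d", seq_len(nrow(X)))
  colnames(X) <- paste0("g", seq_len(ncol(X)))
  X
}

# independent naive complete-linkage: recomputes every inter-cluster
# distance from the raw distance matrix at every step (no Lance-Williams
# update), same lexicographic tie rule
naive_complete_linkage <- function(x) {
  D <- as.matrix(dist(x))
  labels <- rownames(x)
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
      if (is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = d, key = key)
      }
    }
    heights <- c(heights, best$d)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
    part <- integer(nrow(x))
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(p) {
  as.integer(factor(p, levels = unique(p)))
}
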