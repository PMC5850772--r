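# Parallel-evolution recurrence testing: is the same gene hit in more
# independent clones than expected under a neutral placement null?

#' Exact binomial upper-tail probability of recurrent hits
#'
#' `P(X >= k)` for `X ~ Binomial(n, p_hit)`: the probability that at
#' least `k` of `n` neutral trials fall in the gene of interest.
#'
#' @param k observed hits (distinct clones).
#' @param n number of trials under the chosen null.
#' @param p_hit per-trial probability of hitting the gene.
#' @return Upper-tail p-value in `[0, 1]`.
#' @export
binomial_recurrence <- function(k, n, p_hit) {
  .check_scalar_num(k, "k", 0); .check_scalar_num(n, "n", 0)
  .check_scalar_num(p_hit, "p_hit", 0, 1)
  if (k > n) .stop2("'k' cannot exceed 'n'")
  if (k == 0) return(1)
  pbinom(k - 1, size = n, prob = p_hit, lower.tail = FALSE)
}

#' Gene-level recurrence test across a mutation cohort
#'
#' For every gene mutated in at least two distinct clones, tests whether
#' that many independent hits are surprising under a neutral,
#' length-proportional placement null. Two nulls are available:
#' \describe{
#'   \item{per_mutation}{each of the cohort's `n` total mutations is a
#'     trial hitting the gene with probability
#'     `gene_length / target_length`.}
#'   \item{per_clone}{each of the `n_clones` clones is a trial; a clone
#'     hits the gene with probability
#'     `1 - (1 - gene_length/target_length)^m` where `m` is the mean
#'     mutation count per clone.}
#' }
#' Multiple mutations of a gene within one clone count once toward `k`
#' (recurrence means independent lineages). P-values are adjusted across
#' tested genes (Benjamini-Hochberg by default).
#'
#' @param mutations data.frame with columns clone, gene (rows with gene
#'   `"intergenic"` count toward the mutation total but are not tested).
#' @param gene_lengths named numeric vector, gene -> length in bp.
#' @param target_length total mutational target length in bp.
#' @param null `"per_mutation"` (default) or `"per_clone"`.
#' @param n_clones number of clones in the cohort; defaults to the number
#'   of distinct clones in `mutations`.
#' @param adjust multiplicity correction method (`"BH"` default,
#'   `"bonferroni"` supported; any `p.adjust` method accepted).
#' @return data.frame: gene, k, n, p_hit, p_value, adjusted_p, ordered by
#'   p_value. Zero rows when no gene reaches k >= 2.
#' @export
test_recurrence <- function(mutations, gene_lengths, target_length,
                            null = c("per_mutation", "per_clone"),
                            n_clones = NULL, adjust = "BH") {
  null <- match.arg(null)
  if (!is.data.frame(mutations) ||
      !all(c("clone", "gene") %in% names(mutations)))
    .stop2("'mutations' needs columns clone and gene")
  .check_scalar_num(target_length, "target_length", 1)
  genic <- mutations[mutations$gene != "intergenic", , drop = FALSE]
  if (nrow(genic)) {
    miss <- setdiff(unique(genic$gene), names(gene_lengths))
    if (length(miss))
      .stop2("no length for mutated gene(s): ", paste(miss, collapse = ", "))
    if (max(gene_lengths[unique(genic$gene)]) > target_length)
      .stop2("'target_length' must be at least the largest gene length")
  }
  if (is.null(n_clones)) n_clones <- length(unique(mutations$clone))
  total_mut <- nrow(mutations)

  k_by_gene <- tapply(genic$clone, genic$gene,
                      function(cl) length(unique(cl)))
  k_by_gene <- k_by_gene[k_by_gene >= 2L]
  empty <- data.frame(gene = character(0), k = integer(0), n = integer(0),
                      p_hit = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE)
  if (!length(k_by_gene)) return(empty)

  frac <- gene_lengths[names(k_by_gene)] / target_length
  if (null == "per_mutation") {
    n <- total_mut
    p_hit <- frac
  } else {
    n <- n_clones
    p_hit <- 1 - (1 - frac)^(total_mut / n_clones)
  }
  pv <- vapply(seq_along(k_by_gene), function(i)
    binomial_recurrence(k_by_gene[[i]], n, p_hit[[i]]), numeric(1))
  out <- data.frame(gene = names(k_by_gene),
                    k = as.integer(k_by_gene), n = as.integer(n),
                    p_hit = unname(p_hit), p_value = pv,
                    adjusted_p = p.adjust(pv, method = adjust),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
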