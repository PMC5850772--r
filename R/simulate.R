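#' Configuration for synthetic cohort generation
#'
#' Defines the replicate design and the qPCR measurement model used to
#' convert true log2 expression ratios into cycle-threshold values.
#' Each clone is measured for every panel gene and the reference gene in
#' `n_bio` biological replicates of `n_tech` technical reactions (default
#' triplicate reactions for each of two biological replicates). A clone's
#' true log2 ratio for a gene is drawn once per biological replicate from
#' the class signature; it is converted to a Ct value via the primer
#' efficiency model
#' \deqn{Ct = B_g - r / \log_2(1 + E_g)}
#' where \eqn{B_g} is the ancestor's baseline Ct for gene g and \eqn{E_g}
#' the amplification efficiency (E = 1 means perfect doubling, so one
#' cycle corresponds to one log2 unit). Gaussian technical noise (in
#' cycles) is then added per reaction.
#'
#' @param counts integer matrix of clone counts, ploidies x classes
#'   (rows named e.g. "1N", "2N", "4N"), as in [default_cohort_counts()];
#'   or a named vector of per-class counts (all assigned ploidy "2N").
#' @param n_bio,n_tech biological / technical replicates per clone.
#' @param baseline_ct named numeric vector of ancestor baseline Ct values,
#'   one per panel gene plus the reference gene.
#' @param efficiencies named numeric vector of per-primer amplification
#'   efficiencies in (0, 1], same names as `baseline_ct`.
#' @param tech_sd technical Ct noise standard deviation, in cycles.
#' @param reference_gene name of the normalisation gene.
#' @param seed integer seed; together with the configuration it fully
#'   determines the generated cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(counts = default_cohort_counts(),
                          n_bio = 2L, n_tech = 3L,
                          baseline_ct = c(HXT2 = 22, HXT3 = 21, HXT4 = 22,
                                          HXT6_7 = 20, SUC2 = 24, ACT1 = 15),
                          efficiencies = NULL,
                          tech_sd = 0.25,
                          reference_gene = reference_gene_default(),
                          seed = 1L) {
  if (!is.matrix(counts)) {
    if (is.null(names(counts))) .stop2("'counts' vector must be named by class")
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list("2N", names(counts)))
  }
  if (any(counts < 0) || any(counts != round(counts)))
    .stop2("clone counts must be non-negative integers")
  .check_scalar_num(n_bio, "n_bio", 1); .check_scalar_num(n_tech, "n_tech", 1)
  .check_scalar_num(tech_sd, "tech_sd", 0)
  if (is.null(efficiencies))
    efficiencies <- setNames(rep(1, length(baseline_ct)), names(baseline_ct))
  if (!all(names(baseline_ct) %in% names(efficiencies)))
    .stop2("'efficiencies' must cover every gene in 'baseline_ct'")
  if (any(efficiencies <= 0) || any(efficiencies > 1))
    .stop2("amplification efficiencies must lie in (0, 1]")
  if (!reference_gene %in% names(baseline_ct))
    .stop2("'baseline_ct' must include the reference gene")
  structure(list(counts = counts, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), baseline_ct = baseline_ct,
                 efficiencies = efficiencies, tech_sd = tech_sd,
                 reference_gene = reference_gene, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic qRT-PCR cohort
#'
#' Draws a cohort of evolved clones plus the ancestor reference strain.
#' For each clone and biological replicate, per-gene true log2 ratios are
#' sampled from the clone's class signature; Ct values follow the
#' efficiency model of [cohort_config()] with technical noise per
#' reaction. The ancestor's true ratios are identically zero (the ratio
#' definition forces this), so its expected Ct equals the configured
#' baseline.
#'
#' @param config a [cohort_config()].
#' @param signatures a [signature_set()]; every class named in
#'   `config$counts` must be present.
#' @param ancestor_id clone identifier used for the ancestor strain.
#' @return A list with `ct` (data.frame: clone, gene, bio_rep, tech_rep,
#'   ct) and `truth` (data.frame: clone, ploidy, class; the ancestor row
#'   has ploidy "2N" and class "ancestor").
#' @export
generate_cohort <- function(config, signatures = default_signatures(),
                            ancestor_id = "ancestor") {
  stopifnot(inherits(config, "cohort_config"),
            inherits(signatures, "signature_set"))
  counts <- config$counts
  genes <- colnames(signatures$mean_log2)
  unknown <- setdiff(colnames(counts), rownames(signatures$mean_log2))
  if (length(unknown))
    .stop2("classes not present in the signature set: ",
           paste(unknown, collapse = ", "))
  if (!all(genes %in% names(config$baseline_ct)))
    .stop2("'baseline_ct' must cover every panel gene in the signature set")

  set.seed(config$seed)
  ploidy <- rep(rownames(counts)[row(counts)], counts)
  class <- rep(colnames(counts)[col(counts)], counts)
  n <- length(class)
  clone <- sprintf("evo%03d", seq_len(n))
  truth <- data.frame(clone = c(clone, ancestor_id),
                      ploidy = c(ploidy, "2N"),
                      class = c(class, "ancestor"),
                      stringsAsFactors = FALSE)

  all_genes <- c(genes, config$reference_gene)
  lf <- log2(1 + config$efficiencies[all_genes])
  base <- config$baseline_ct[all_genes]
  nb <- config$n_bio; nt <- config$n_tech
  recs <- vector("list", n + 1L)
  for (i in seq_len(n + 1L)) {
    id <- if (i <= n) clone[i] else ancestor_id
    mu <- if (i <= n) signatures$mean_log2[class[i], ] else
      setNames(numeric(length(genes)), genes)
    sdv <- if (i <= n) signatures$sd_log2[class[i], ] else
      setNames(numeric(length(genes)), genes)
    # per-bio-replicate true ratios; reference gene is unchanged by design
    r <- rbind(matrix(rnorm(length(genes) * nb, mu, sdv),
                      nrow = length(genes), ncol = nb),
               0)
    true_ct <- base - r / lf
    df <- expand.grid(tech_rep = seq_len(nt), bio_rep = seq_len(nb),
                      gene = all_genes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df$ct <- true_ct[cbind(match(df$gene, all_genes), df$bio_rep)] +
      rnorm(nrow(df), 0, config$tech_sd)
    df$clone <- id
    recs[[i]] <- df[, c("clone", "gene", "bio_rep", "tech_rep", "ct")]
  }
  ct <- do.call(rbind, recs)
  rownames(ct) <- NULL
  list(ct = ct, truth = truth)
}

#' Configuration for the neutral mutation simulator
#'
#' Describes the mutational target used by the recurrence-test simulations:
#' a set of genes with lengths inside a larger target (the remainder is
#' intergenic/other sequence), a mean mutation count per clone, and
#' optional per-gene selection weights that multiply the neutral,
#' length-proportional hit probability.
#'
#' @param genes data.frame with columns `gene` and `length_bp` (and
#'   optionally `weight`, default 1).
#' @param target_length total mutational target in bp; must be at least
#'   the summed gene lengths.
#' @param mean_mutations mean mutations per clone (Poisson).
#' @param seed integer seed.
#' @return A list of class `mutation_sim_config`.
#' @export
mutation_sim_config <- function(genes, target_length, mean_mutations = 2,
                                seed = 1L) {
  if (!is.data.frame(genes) || !nrow(genes) ||
      !all(c("gene", "length_bp") %in% names(genes)))
    .stop2("'genes' must be a non-empty data.frame with columns gene, length_bp")
  if (any(genes$length_bp <= 0)) .stop2("gene lengths must be positive")
  if (is.null(genes$weight)) genes$weight <- 1
  if (any(genes$weight < 0)) .stop2("selection weights must be non-negative")
  .check_scalar_num(target_length, "target_length", sum(genes$length_bp))
  .check_scalar_num(mean_mutations, "mean_mutations", 0)
  structure(list(genes = genes, target_length = target_length,
                 mean_mutations = mean_mutations, seed = as.integer(seed)),
            class = "mutation_sim_config")
}

#' Simulate a per-clone mutation table
#'
#' Each clone acquires `Poisson(mean_mutations)` mutations. A mutation
#' falls in gene g with probability proportional to
#' `length_bp(g) * weight(g)`, and into intergenic/other target sequence
#' with probability proportional to the remaining length (weight 1).
#' Genic mutations get a 1-based position uniform within the gene and a
#' type drawn from a fixed coding-change distribution; intergenic
#' mutations are recorded with gene `"intergenic"`.
#'
#' @param config a [mutation_sim_config()].
#' @param n_clones number of clones to simulate.
#' @return data.frame with columns clone, gene, position, type.
#' @export
generate_mutation_table <- function(config, n_clones) {
  stopifnot(inherits(config, "mutation_sim_config"))
  .check_scalar_num(n_clones, "n_clones", 1)
  set.seed(config$seed)
  g <- config$genes
  inter_len <- config$target_length - sum(g$length_bp)
  wts <- c(g$length_bp * g$weight, inter_len)
  cats <- c(g$gene, "intergenic")
  lens <- c(g$length_bp, max(inter_len, 1))
  types <- c(nonsynonymous = 0.6, synonymous = 0.2,
             nonsense = 0.1, frameshift = 0.1)

  m <- rpois(n_clones, config$mean_mutations)
  total <- sum(m)
  if (total == 0L)
    return(data.frame(clone = character(0), gene = character(0),
                      position = integer(0), type = character(0),
                      stringsAsFactors = FALSE))
  clone <- rep(sprintf("mut%05d", seq_len(n_clones)), m)
  idx <- sample.int(length(cats), total, replace = TRUE, prob = wts)
  position <- 1L + floor(runif(total) * lens[idx])
  type <- ifelse(cats[idx] == "intergenic", "intergenic",
                 sample(names(types), total, replace = TRUE, prob = types))
  data.frame(clone = clone, gene = cats[idx],
             position = as.integer(position), type = type,
             stringsAsFactors = FALSE)
}

#' Seeded hold-out split for prediction validation
#'
#' Selects clones whose class labels are hidden for the prediction twin:
#' by default 3 haploid-, 9 diploid- and 9 tetraploid-derived evolved
#' clones (21 in total), sampled uniformly within each ploidy from clones
#' whose class is not excluded.
#'
#' @param truth data.frame with columns clone, ploidy, class (as from
#'   [generate_cohort()]); the ancestor row is ignored.
#' @param n_per_ploidy named integer vector, ploidy -> number held out.
#' @param exclude_classes classes never held out (default the
#'   ancestor-like clones, which carry no adaptive driver).
#' @param seed integer seed making the split reproducible.
#' @return character vector of held-out clone ids.
#' @export
holdout_split <- function(truth,
                          n_per_ploidy = c(`1N` = 3L, `2N` = 9L, `4N` = 9L),
                          exclude_classes = c("ancestor", "ancestor_like"),
                          seed = 1L) {
  stopifnot(all(c("clone", "ploidy", "class") %in% names(truth)))
  pool <- truth[!truth$class %in% exclude_classes, , drop = FALSE]
  set.seed(seed)
  out <- character(0)
  for (pl in names(n_per_ploidy)) {
    cand <- pool$clone[pool$ploidy == pl]
    n <- n_per_ploidy[[pl]]
    if (length(cand) < n)
      .stop2("not enough clones of ploidy ", pl, " to hold out ", n)
    out <- c(out, sample(cand, n))
  }
  out
}
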