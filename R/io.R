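# Plain-TSV input/output with provenance headers, and the end-to-end
# pipeline driver used by the analysis scripts.

#' Write a table as TSV with a provenance header
#'
#' Tables are written tab-separated with `#`-prefixed header lines
#' carrying arbitrary key-value metadata (typically the seed and a
#' configuration hash), so every output is self-describing and diffable.
#'
#' @param x data.frame to write.
#' @param path output file.
#' @param meta named list/vector of header metadata.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("#%s: %s", k, format(meta[[k]])), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()]
#'
#' @param path file to read.
#' @return data.frame; header metadata is attached as attribute `"meta"`.
#' @export
read_tsv_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", lines[h])
    i <- regexpr(":", kv, fixed = TRUE)
    if (i > 0)
      meta[[substr(kv, 1, i - 1)]] <- trimws(substring(kv, i + 1))
  }
  df <- read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                collapse = "\n"),
                   sep = "\t", stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

# small deterministic content hash (polynomial rolling hash over the
# deparsed object; kept in double precision to stay exact below 2^53)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full expression-to-genotype pipeline
#'
#' Composes the stages quantify -> cluster -> select clades -> label ->
#' predict, optionally followed by the LDA separation report (when ploidy
#' information is supplied) and the recurrence test (when a mutation
#' table is supplied). All outputs are written to `out_dir` as headered
#' TSVs plus a Newick dendrogram and a manifest.
#'
#' @param ct Ct table (data.frame clone, gene, bio_rep, tech_rep, ct).
#' @param labels known driver classes for genotyped clones (named vector
#'   or data.frame clone, class).
#' @param ancestor ancestor clone id in `ct`.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param panel,reference_gene,efficiencies,se_mode see
#'   [build_expression_matrix()].
#' @param k,k_max,metric,refine,conflict_threshold see [predict_cohort()].
#' @param ploidy optional named vector clone -> ploidy enabling the LDA
#'   report.
#' @param mutations,gene_lengths,target_length,recurrence_null optional
#'   inputs enabling the recurrence test.
#' @param seed seed recorded in output headers (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `pipeline_result` with elements `matrix`,
#'   `prediction`, and (when enabled) `separation`, `recurrence`,
#'   `manifest`.
#' @export
run_pipeline <- function(ct, labels, ancestor = "ancestor", out_dir = NULL,
                         panel = panel_genes(),
                         reference_gene = reference_gene_default(),
                         efficiencies = NULL, se_mode = "bio_sem",
                         k = NULL, k_max = NULL, metric = "euclidean",
                         refine = TRUE, conflict_threshold = 0.05,
                         ploidy = NULL,
                         mutations = NULL, gene_lengths = NULL,
                         target_length = NULL,
                         recurrence_null = "per_mutation",
                         seed = NA_integer_) {
  cfg <- list(ancestor = ancestor, panel = panel,
              reference_gene = reference_gene, se_mode = se_mode,
              k = k, k_max = k_max, metric = metric, refine = refine,
              conflict_threshold = conflict_threshold,
              recurrence_null = recurrence_null, seed = seed)
  hash <- config_hash(cfg)
  meta <- list(config_hash = hash, seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stop2(sprintf("[%s] %s", name, conditionMessage(e))))
  }
  mat <- stage("quantify",
               build_expression_matrix(ct, ancestor, panel, reference_gene,
                                       efficiencies, se_mode))
  fit <- stage("predict",
               predict_cohort(mat, labels, k = k, k_max = k_max,
                              metric = metric, refine = refine,
                              conflict_threshold = conflict_threshold))
  sep <- NULL
  if (!is.null(ploidy)) {
    sep <- stage("lda", {
      mg <- .as_label_vector(labels)
      full <- setNames(fit$predictions$predicted_class,
                       fit$predictions$clone)
      full[names(mg)] <- mg
      separation_report(mat, full, ploidy[rownames(mat$log2)])
    })
  }
  rec <- NULL
  if (!is.null(mutations)) {
    if (is.null(gene_lengths) || is.null(target_length))
      .stop2("[recurrence] gene_lengths and target_length are required")
    rec <- stage("recurrence",
                 test_recurrence(mutations, gene_lengths, target_length,
                                 null = recurrence_null))
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(out_dir, f)
    lg <- as.data.frame(mat$log2)
    lg <- cbind(clone = rownames(mat$log2), lg)
    write_tsv_header(lg, out("expression_matrix.tsv"), meta)
    se <- cbind(clone = rownames(mat$se), as.data.frame(mat$se))
    write_tsv_header(se, out("expression_matrix.se.tsv"), meta)
    asg <- data.frame(clone = names(fit$assignment$clades),
                      clade = unname(fit$assignment$clades))
    write_tsv_header(asg, out("clades.tsv"), meta)
    write_tsv_header(fit$assignment$trace, out("clade_trace.tsv"), meta)
    write_tsv_header(fit$predictions, out("predictions.tsv"), meta)
    writeLines(dendrogram_newick(fit$dendrogram), out("dendrogram.nwk"))
    if (!is.null(rec)) write_tsv_header(rec, out("recurrence.tsv"), meta)
    files <- c("expression_matrix.tsv", "expression_matrix.se.tsv",
               "clades.tsv", "clade_trace.tsv", "predictions.tsv",
               "dendrogram.nwk",
               if (!is.null(rec)) "recurrence.tsv")
    manifest <- data.frame(file = files, stringsAsFactors = FALSE)
    write_tsv_header(manifest, out("manifest.tsv"), meta)
  }
  structure(list(matrix = mat, prediction = fit, separation = sep,
                 recurrence = rec, manifest = manifest,
                 config_hash = hash),
            class = "pipeline_result")
}
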