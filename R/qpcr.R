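# Relative quantification of qRT-PCR panels: standard curves,
# efficiency-corrected ancestor-relative log2 ratios, replicate error.

.check_ct_table <- function(ct) {
  need <- c("clone", "gene", "bio_rep", "tech_rep", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct)))
    .stop2("a Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct))) .stop2("Ct table contains non-finite Ct values")
  invisible(ct)
}

# tech-replicate means per (clone, gene, bio_rep); returns data.frame
.bio_means <- function(ct, clone, gene) {
  sub <- ct[ct$clone == clone & ct$gene == gene, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  agg <- aggregate(ct ~ bio_rep, data = sub, FUN = mean)
  agg[order(agg$bio_rep), , drop = FALSE]
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(dilution) over a serial dilution
#' of template. The primer amplification efficiency follows from the slope
#' as `E = 10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' -1/log10(2) = -3.3219 and E = 1. The linear range is reported as the
#' widest contiguous window of distinct dilutions whose refit r-squared
#' reaches `r2_threshold`.
#'
#' @param dilutions positive dilution fractions, one per Ct value.
#' @param ct_values measured Ct values (cycles).
#' @param r2_threshold minimum r-squared for the linear range (default 0.99).
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `linear_range`, `valid`.
#'   A non-negative slope yields `valid = FALSE` with a warning rather
#'   than an error.
#' @export
fit_standard_curve <- function(dilutions, ct_values, r2_threshold = 0.99) {
  if (length(dilutions) != length(ct_values))
    .stop2("'dilutions' and 'ct_values' must have equal length")
  if (any(dilutions <= 0)) .stop2("dilutions must be positive fractions")
  if (length(unique(dilutions)) < 3L)
    .stop2("at least 3 distinct dilutions are required to fit a standard curve")
  x <- log10(dilutions)
  r_squared <- function(fit, y) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    1 - sum(fit$residuals^2) / tss
  }
  fit <- lm(ct_values ~ x)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  r2 <- r_squared(fit, ct_values)
  valid <- is.finite(slope) && slope < 0
  if (!valid)
    warning("standard curve has non-negative slope; efficiency is undefined",
            call. = FALSE)
  eff <- if (valid) 10^(-1 / slope) - 1 else NA_real_

  dl <- sort(unique(dilutions))
  lin <- c(min(dl), max(dl))
  if (valid && length(dl) > 3L) {
    found <- FALSE
    for (win in rev(seq(3L, length(dl)))) {
      for (s in seq_len(length(dl) - win + 1L)) {
        keep <- dilutions >= dl[s] & dilutions <= dl[s + win - 1L]
        f <- lm(ct_values[keep] ~ log10(dilutions[keep]))
        if (r_squared(f, ct_values[keep]) >= r2_threshold) {
          lin <- c(dl[s], dl[s + win - 1L]); found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  structure(list(slope = slope, intercept = intercept, efficiency = eff,
                 r_squared = r2, linear_range = lin, valid = valid,
                 r2_threshold = r2_threshold),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: slope", format(x$slope, digits = 5),
      "intercept", format(x$intercept, digits = 5),
      "\n  efficiency", format(x$efficiency, digits = 4),
      " r^2", format(x$r_squared, digits = 4),
      if (!x$valid) " [INVALID: non-negative slope]" else "", "\n")
  invisible(x)
}

#' Ancestor-relative log2 expression ratio for one clone and gene
#'
#' Efficiency-corrected relative quantification, internally normalised to
#' the reference gene. Within each biological replicate technical
#' replicates are averaged first; the per-biological-replicate log2 ratio
#' is
#' \deqn{r_b = \Delta Ct_{ref,b} \log_2(1+E_{ref}) -
#'             \Delta Ct_{gene,b} \log_2(1+E_{gene})}
#' with \eqn{\Delta Ct_{x,b} = Ct_x(clone, b) - \bar{Ct}_x(ancestor)},
#' and the reported ratio is the mean of \eqn{r_b} over biological
#' replicates. With all efficiencies 1 this reduces to the classical
#' 2^-ddCt model. The default standard error is the standard error of the
#' per-biological-replicate ratios (`se_mode = "bio_sem"`); the
#' alternative `"quadrature"` propagates the technical-replicate standard
#' errors of all four Ct means in quadrature.
#'
#' @param ct Ct table (columns clone, gene, bio_rep, tech_rep, ct).
#' @param clone,ancestor clone identifiers present in `ct`.
#' @param gene target gene; `reference_gene` the normalisation gene.
#' @param efficiencies named per-gene amplification efficiencies; genes
#'   absent from the vector default to 1.
#' @param se_mode `"bio_sem"` (default) or `"quadrature"`.
#' @return list with `log2_ratio`, `se`, `n_bio`.
#' @export
relative_expression <- function(ct, clone, ancestor, gene,
                                reference_gene = reference_gene_default(),
                                efficiencies = NULL,
                                se_mode = c("bio_sem", "quadrature")) {
  .check_ct_table(ct)
  se_mode <- match.arg(se_mode)
  eff <- function(g) {
    e <- if (!is.null(efficiencies) && g %in% names(efficiencies))
      efficiencies[[g]] else 1
    if (e <= 0) .stop2("efficiency for ", g, " must be positive")
    e
  }
  lg <- log2(1 + eff(gene)); lr <- log2(1 + eff(reference_gene))

  need <- list(c(clone, gene), c(clone, reference_gene),
               c(ancestor, gene), c(ancestor, reference_gene))
  bm <- lapply(need, function(p) .bio_means(ct, p[1L], p[2L]))
  miss <- vapply(bm, is.null, logical(1))
  if (any(miss))
    .stop2("missing Ct data for ",
           paste(vapply(need[miss], function(p)
             paste0(p[1L], "/", p[2L]), character(1)), collapse = ", "))

  anc_gene <- mean(bm[[3L]]$ct); anc_ref <- mean(bm[[4L]]$ct)
  cg <- bm[[1L]]; cr <- bm[[2L]]
  common <- intersect(cg$bio_rep, cr$bio_rep)
  if (!length(common))
    .stop2("no shared biological replicates for ", clone,
           " between ", gene, " and ", reference_gene)
  rg <- cg$ct[match(common, cg$bio_rep)]
  rr <- cr$ct[match(common, cr$bio_rep)]
  rb <- (rr - anc_ref) * lr - (rg - anc_gene) * lg
  n_bio <- length(rb)
  log2_ratio <- mean(rb)

  if (se_mode == "bio_sem") {
    se <- if (n_bio > 1L) sd(rb) / sqrt(n_bio) else 0
  } else {
    sem <- function(pair) {
      sub <- ct[ct$clone == pair[1L] & ct$gene == pair[2L], , drop = FALSE]
      v <- tapply(sub$ct, sub$bio_rep, mean)
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
    }
    se <- sqrt(lg^2 * (sem(need[[1L]])^2 + sem(need[[3L]])^2) +
               lr^2 * (sem(need[[2L]])^2 + sem(need[[4L]])^2))
  }
  list(log2_ratio = log2_ratio, se = se, n_bio = n_bio)
}

#' Build the clones x genes expression matrix
#'
#' Applies [relative_expression()] over every clone in the Ct table
#' (except the ancestor) and every panel gene. Row order follows first
#' appearance in the Ct table; column order follows `panel`. Any clone
#' missing any panel gene aborts with a message listing all gaps.
#'
#' @inheritParams relative_expression
#' @param panel character vector of panel genes (columns).
#' @param clones optional explicit clone set and ordering.
#' @return An object of class `expression_matrix`: list with `log2`
#'   (clones x genes), `se` (same shape) and `n_bio`.
#' @export
build_expression_matrix <- function(ct, ancestor,
                                    panel = panel_genes(),
                                    reference_gene = reference_gene_default(),
                                    efficiencies = NULL,
                                    se_mode = c("bio_sem", "quadrature"),
                                    clones = NULL) {
  .check_ct_table(ct)
  se_mode <- match.arg(se_mode)
  if (is.null(clones)) clones <- setdiff(unique(ct$clone), ancestor)
  if (!length(clones)) .stop2("no clones to quantify")
  have <- unique(ct[, c("clone", "gene")])
  gaps <- character(0)
  for (cl in c(clones, ancestor)) {
    for (g in c(panel, reference_gene)) {
      if (!any(have$clone == cl & have$gene == g))
        gaps <- c(gaps, paste0(cl, ":", g))
    }
  }
  if (length(gaps))
    .stop2("missing panel measurements for ", paste(gaps, collapse = ", "))

  m <- matrix(NA_real_, length(clones), length(panel),
              dimnames = list(clones, panel))
  s <- m
  nb <- m
  for (cl in clones) for (g in panel) {
    r <- relative_expression(ct, cl, ancestor, g, reference_gene,
                             efficiencies, se_mode)
    m[cl, g] <- r$log2_ratio; s[cl, g] <- r$se; nb[cl, g] <- r$n_bio
  }
  structure(list(log2 = m, se = s, n_bio = nb), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$log2), "clones x", ncol(x$log2),
      "genes (ancestor-relative log2 ratios)\n")
  print(head(round(x$log2, 3)))
  if (nrow(x$log2) > 6L) cat("...\n")
  invisible(x)
}
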