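# Fisher linear discriminant analysis of the expression panel, with
# chi-square confidence ellipses and a mutation-vs-ploidy separation
# report.

#' Fit Fisher linear discriminants
#'
#' Discriminant axes solve the generalized eigenproblem of between-class
#' versus within-class scatter: maximise `w' Sb w / w' Sw w`. The
#' within-class scatter is ridge-regularised as
#' `Sw + lambda * mean(diag(Sw)) * I` so that small classes on a
#' five-gene panel cannot make it singular. Axes are unit-norm, ordered
#' by decreasing discriminant eigenvalue, with a deterministic sign
#' convention (largest-magnitude loading positive).
#'
#' Classification (for cross-validation and the separation report) uses
#' the Gaussian rule with the pooled within-class covariance and, by
#' default, class-proportional priors.
#'
#' @param x numeric matrix (clones x genes) or `expression_matrix`.
#' @param grouping named factor/character vector mapping clones to
#'   classes; names must cover the rows of `x` (unnamed vectors are taken
#'   in row order).
#' @param lambda ridge coefficient for the within-class scatter
#'   (default 1e-6).
#' @param prior `"proportional"` (default) or `"uniform"`.
#' @return Object of class `fisher_lda`: class means, pooled scatter,
#'   `axes` (genes x axes), `eigenvalues`, per-clone `scores` on up to
#'   the first two axes, `degenerate` flag.
#' @export
fit_lda <- function(x, grouping, lambda = 1e-6,
                    prior = c("proportional", "uniform")) {
  prior <- match.arg(prior)
  if (inherits(x, "expression_matrix")) x <- x$log2
  if (!is.null(names(grouping)) && !is.null(rownames(x))) {
    miss <- setdiff(rownames(x), names(grouping))
    if (length(miss)) .stop2("no grouping for: ", paste(miss, collapse = ", "))
    grouping <- grouping[rownames(x)]
  }
  g <- factor(as.character(grouping))
  if (length(g) != nrow(x)) .stop2("grouping length must match rows of 'x'")
  cnt <- table(g)
  if (length(cnt) < 2L) .stop2("need at least 2 classes")
  if (any(cnt < 2L))
    .stop2("classes with a single member: ",
           paste(names(cnt)[cnt < 2L], collapse = ", "))
  .fit_lda_impl(x, g, lambda, prior)
}

.fit_lda_impl <- function(x, g, lambda, prior) {
  p <- ncol(x); n <- nrow(x)
  lev <- levels(g)
  means <- t(vapply(lev, function(l) colMeans(x[g == l, , drop = FALSE]),
                    numeric(p)))
  grand <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (l in lev) {
    xi <- x[g == l, , drop = FALSE]
    d <- sweep(xi, 2L, means[l, ])
    Sw <- Sw + crossprod(d)
    db <- means[l, ] - grand
    Sb <- Sb + nrow(xi) * tcrossprod(db)
  }
  Swr <- Sw + lambda * mean(diag(Sw)) * diag(p)
  R <- chol(Swr)
  Ri <- backsolve(R, diag(p))
  sym <- crossprod(Ri, Sb %*% Ri)
  e <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  n_axes <- min(p, length(lev) - 1L)
  axes <- Ri %*% e$vectors[, seq_len(n_axes), drop = FALSE]
  # unit norm + sign convention
  for (j in seq_len(ncol(axes))) {
    axes[, j] <- axes[, j] / sqrt(sum(axes[, j]^2))
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(x)
  colnames(axes) <- paste0("LD", seq_len(ncol(axes)))
  eigenvalues <- e$values[seq_len(n_axes)]
  degenerate <- max(eigenvalues) < 1e-10

  sc_axes <- axes[, seq_len(min(2L, n_axes)), drop = FALSE]
  scores <- sweep(x, 2L, grand) %*% sc_axes
  rownames(scores) <- rownames(x)

  priors <- if (prior == "proportional") as.numeric(table(g)) / n else
    rep(1 / length(lev), length(lev))
  names(priors) <- lev
  structure(list(classes = lev, means = means, grand_mean = grand,
                 Sw = Sw, Sw_reg = Swr, Sb = Sb, lambda = lambda,
                 axes = axes, eigenvalues = eigenvalues,
                 scores = scores, priors = priors, n = n,
                 pooled_cov = Swr / (n - length(lev)),
                 degenerate = degenerate),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat("Fisher LDA:", length(x$classes), "classes,", ncol(x$axes),
      "discriminant axes\n  eigenvalues:",
      format(x$eigenvalues, digits = 4), "\n")
  if (x$degenerate) cat("  [degenerate: no discriminative axis]\n")
  invisible(x)
}

#' Classify observations with a fitted discriminant model
#'
#' @param object a `fisher_lda` fit.
#' @param newdata matrix of observations (same genes as the training
#'   matrix).
#' @param ... unused.
#' @return character vector of predicted classes.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_matrix")) newdata <- newdata$log2
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Sinv <- solve(object$pooled_cov)
  disc <- vapply(object$classes, function(l) {
    m <- object$means[l, ]
    drop(newdata %*% Sinv %*% m) - drop(m %*% Sinv %*% m) / 2 +
      log(object$priors[[l]])
  }, numeric(nrow(newdata)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1L)
  object$classes[max.col(disc, ties.method = "first")]
}

#' Leave-one-out cross-validated accuracy of the discriminant model
#'
#' Refits the model without each clone in turn and classifies the held-out
#' clone. Classes reduced to a single member during refitting are allowed
#' (their within-class scatter contribution is zero).
#'
#' @inheritParams fit_lda
#' @return list with `accuracy`, `per_class`, `predicted`.
#' @export
lda_cv_accuracy <- function(x, grouping, lambda = 1e-6,
                            prior = c("proportional", "uniform")) {
  prior <- match.arg(prior)
  if (inherits(x, "expression_matrix")) x <- x$log2
  if (!is.null(names(grouping)) && !is.null(rownames(x)))
    grouping <- grouping[rownames(x)]
  g <- factor(as.character(grouping))
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- factor(as.character(g[-i]))
    fit <- .fit_lda_impl(x[-i, , drop = FALSE], gi, lambda, prior)
    pred[i] <- predict(fit, x[i, , drop = FALSE])
  }
  ok <- pred == as.character(g)
  list(accuracy = mean(ok),
       per_class = vapply(split(ok, g), mean, numeric(1)),
       predicted = setNames(pred, rownames(x)))
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Ellipse centred on the sample mean with shape from the sample
#' covariance, scaled by `sqrt(qchisq(level, df = 2))` (known-covariance
#' chi-square convention; set `scaling = "F"` for the Hotelling
#' small-sample variant).
#'
#' @param scores numeric matrix with two columns (e.g. LD1, LD2).
#' @param level coverage level in (0, 1), default 0.95.
#' @param scaling `"chisq"` (default) or `"F"`.
#' @return Object of class `confidence_ellipse`: `center`, `semi_axes`
#'   (major, minor), `angle` (radians of the major axis), `level`,
#'   `cov`, `n`.
#' @export
confidence_ellipse <- function(scores, level = 0.95,
                               scaling = c("chisq", "F")) {
  scaling <- match.arg(scaling)
  .check_scalar_num(level, "level", 1e-12, 1 - 1e-12)
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) .stop2("'scores' must have exactly 2 columns")
  n <- nrow(scores)
  if (n < 3L) .stop2("need at least 3 points for a confidence ellipse")
  ctr <- colMeans(scores)
  S <- cov(scores)
  if (!is.finite(det(S)) || det(S) <= 1e-300)
    .stop2("singular score covariance; ellipse undefined")
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) .stop2("singular score covariance; ellipse undefined")
  c2 <- if (scaling == "chisq") qchisq(level, df = 2) else
    2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  semi <- sqrt(e$values * c2)
  angle <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  structure(list(center = ctr, semi_axes = semi, angle = angle,
                 level = level, cov = S, n = n, c2 = c2),
            class = "confidence_ellipse")
}

#' Points on the boundary of a confidence ellipse
#'
#' @param ellipse a `confidence_ellipse`.
#' @param n_points number of boundary points.
#' @return matrix with columns x, y.
#' @export
ellipse_boundary <- function(ellipse, n_points = 100L) {
  t <- seq(0, 2 * pi, length.out = n_points)
  u <- rbind(ellipse$semi_axes[1L] * cos(t), ellipse$semi_axes[2L] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2L, 2L)
  sweep(t(rot %*% u), 2L, ellipse$center, `+`)
}

#' Test whether points fall inside a confidence ellipse
#'
#' @param ellipse a `confidence_ellipse`.
#' @param points matrix with two columns.
#' @return logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  points <- as.matrix(points)
  mahalanobis(points, ellipse$center, ellipse$cov) <= ellipse$c2
}

#' Overlap area of two confidence ellipses
#'
#' Numeric integration on a regular grid over the union bounding box.
#'
#' @param e1,e2 `confidence_ellipse` objects.
#' @param grid_n grid resolution per axis (default 200).
#' @return Overlap area (score-space units squared).
#' @export
ellipse_overlap <- function(e1, e2, grid_n = 200L) {
  bb <- function(e) {
    r <- max(e$semi_axes)
    c(e$center[1L] - r, e$center[1L] + r, e$center[2L] - r, e$center[2L] + r)
  }
  b1 <- bb(e1); b2 <- bb(e2)
  xs <- seq(min(b1[1L], b2[1L]), max(b1[2L], b2[2L]), length.out = grid_n)
  ys <- seq(min(b1[3L], b2[3L]), max(b1[4L], b2[4L]), length.out = grid_n)
  cell <- diff(xs[1:2]) * diff(ys[1:2])
  pts <- cbind(rep(xs, times = grid_n), rep(ys, each = grid_n))
  inside <- ellipse_contains(e1, pts) & ellipse_contains(e2, pts)
  sum(inside) * cell
}

#' Compare class separation under mutation vs ploidy groupings
#'
#' Fits the discriminant model under both groupings of the same clones,
#' reports leave-one-out cross-validated accuracy (overall and per
#' class), pairwise confidence-ellipse overlap areas in the first two
#' discriminant dimensions, and a flag that is `TRUE` when every
#' mutation-class accuracy exceeds every ploidy-class accuracy.
#'
#' @param x profile matrix or `expression_matrix`.
#' @param mutation_groups,ploidy_groups named class vectors over the same
#'   clones.
#' @param level ellipse coverage level.
#' @param lambda,prior passed to [fit_lda()].
#' @return list of class `separation_report`.
#' @export
separation_report <- function(x, mutation_groups, ploidy_groups,
                              level = 0.95, lambda = 1e-6,
                              prior = "proportional") {
  if (inherits(x, "expression_matrix")) x <- x$log2
  mg <- .as_label_vector(mutation_groups)
  pg <- .as_label_vector(ploidy_groups)
  if (!setequal(names(mg), rownames(x)) || !setequal(names(pg), rownames(x)))
    .stop2("groupings must cover exactly the clones in the matrix")

  one <- function(groups) {
    fit <- fit_lda(x, groups, lambda = lambda, prior = prior)
    cv <- lda_cv_accuracy(x, groups, lambda = lambda, prior = prior)
    ell <- list()
    for (l in fit$classes) {
      sc <- fit$scores[names(groups)[groups == l], , drop = FALSE]
      if (nrow(sc) >= 3L && ncol(sc) == 2L) {
        e <- try(confidence_ellipse(sc, level = level), silent = TRUE)
        if (!inherits(e, "try-error")) ell[[l]] <- e
      }
    }
    ov <- NULL
    if (length(ell) >= 2L) {
      prs <- combn(names(ell), 2L)
      ov <- data.frame(class1 = prs[1L, ], class2 = prs[2L, ],
                       overlap = apply(prs, 2L, function(p)
                         ellipse_overlap(ell[[p[1L]]], ell[[p[2L]]])),
                       stringsAsFactors = FALSE)
    }
    list(fit = fit, cv = cv, ellipses = ell, overlap = ov)
  }
  mut <- one(mg); plo <- one(pg)
  flag <- min(mut$cv$per_class) > max(plo$cv$per_class)
  structure(list(mutation = mut, ploidy = plo,
                 mutation_better_everywhere = flag),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("LDA separation report\n",
      " by mutation: CV accuracy", round(x$mutation$cv$accuracy, 3), "\n",
      " by ploidy:   CV accuracy", round(x$ploidy$cv$accuracy, 3), "\n",
      " every mutation class beats every ploidy class:",
      x$mutation_better_everywhere, "\n")
  invisible(x)
}
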