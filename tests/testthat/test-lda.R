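# Fisher discriminants, confidence ellipses, separation report

test_that("a single informative gene aligns the first discriminant axis", {
  set.seed(41)
  n <- 20
  X <- matrix(0.7, 2 * n, 5)                # all other genes constant
  X[, 3] <- c(rnorm(n, 0, 0.05), rnorm(n, 4, 0.05))
  rownames(X) <- sprintf("c%02d", seq_len(2 * n))
  colnames(X) <- paste0("g", 1:5)
  g <- rep(c("lo", "hi"), each = n)
  fit <- fit_lda(X, g)
  expect_gte(abs(fit$axes[3, 1]), 0.999)
  expect_equal(unname(predict(fit, X)), g)
})

test_that("eigenvalues and axes match a dense generalized-eigen oracle", {
  set.seed(42)
  n_per <- 8
  shifts <- rbind(c(0, 0, 0, 0, 0), c(3, 1, 0, -1, 0), c(0, -2, 2, 1, 1))
  X <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per * 5), n_per, 5) +
      matrix(rep(shifts[i, ], each = n_per), n_per)))
  rownames(X) <- sprintf("c%02d", 1:24); colnames(X) <- paste0("g", 1:5)
  g <- rep(c("a", "b", "c"), each = n_per)
  fit <- fit_lda(X, g, lambda = 1e-6)
  # oracle: unsymmetrized eigenproblem of solve(Sw_reg) %*% Sb
  eo <- eigen(solve(fit$Sw_reg) %*% fit$Sb)
  vals <- Re(eo$values[1:2])
  expect_equal(fit$eigenvalues, vals, tolerance = 1e-8)
  for (j in 1:2) {
    v <- Re(eo$vectors[, j]); v <- v / sqrt(sum(v^2))
    expect_equal(abs(sum(v * fit$axes[, j])), 1, tolerance = 1e-8)
  }
  # and against the reference implementation's scaling directions
  m <- MASS::lda(X, grouping = g)
  for (j in 1:2) {
    v <- m$scaling[, j] / sqrt(sum(m$scaling[, j]^2))
    expect_equal(abs(sum(v * fit$axes[, j])), 1, tolerance = 1e-6)
  }
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  set.seed(43)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("c%02d", 1:n), paste0("g", 1:5)))
  g <- rep(c("a", "b", "c"), each = n / 3)
  B <- 200
  accs <- replicate(B, {
    gp <- setNames(sample(g), rownames(X))
    lda_cv_accuracy(X, gp, prior = "uniform")$accuracy
  })
  se <- sd(accs) / sqrt(B)
  # leave-one-out at chance level carries a small O(1/n) negative bias;
  # allow it explicitly on top of the Monte-Carlo band
  expect_lt(abs(mean(accs) - 1 / 3), 3 * se + 0.01)
})

test_that("degenerate groupings are rejected or flagged", {
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("c%02d", 1:10), c("g1", "g2")))
  expect_error(fit_lda(X, c(rep("a", 9), "b")), "single member.*b")
  set.seed(44)
  Xc <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("c%02d", 1:20), c("g1", "g2")))
  same <- rep(c("a", "b"), each = 10)
  fit <- fit_lda(Xc[c(1:10, 1:10), ] + 0, same)   # identical class clouds
  expect_true(fit$degenerate)
})

test_that("an isotropic unit-variance cloud gives the closed-form 95% radius", {
  set.seed(45)
  raw <- matrix(rnorm(400), 200, 2)
  # whiten so the sample covariance is exactly the identity
  raw <- sweep(raw, 2, colMeans(raw))
  W <- solve(chol(cov(raw)))
  sc <- raw %*% W
  e <- confidence_ellipse(sc, level = 0.95)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-8)
})

test_that("ellipse coverage matches its nominal level by Monte Carlo", {
  set.seed(46)
  n <- 100000
  z <- matrix(rnorm(2 * n), n, 2)
  A <- rbind(c(1.5, 0.6), c(0, 0.8))        # correlated Gaussian
  pts <- z %*% A
  e <- confidence_ellipse(pts, level = 0.95)
  cov_frac <- mean(ellipse_contains(e, pts))
  expect_lt(abs(cov_frac - 0.95), 0.005)
})

test_that("degenerate ellipse inputs error", {
  expect_error(confidence_ellipse(rbind(c(0, 0), c(1, 1))), "at least 3")
  line <- cbind(1:5, 2 * (1:5))              # rank-1 covariance
  expect_error(confidence_ellipse(line), "singular")
})

test_that("far-separated ellipses have zero overlap; coincident ones their area", {
  set.seed(47)
  a <- matrix(rnorm(200), 100, 2)
  e1 <- confidence_ellipse(a)
  e2 <- confidence_ellipse(sweep(a, 2, c(100, 100), `+`))
  expect_equal(ellipse_overlap(e1, e2), 0)
  self <- ellipse_overlap(e1, e1, grid_n = 400)
  expect_equal(self, pi * prod(e1$semi_axes), tolerance = 0.02)
})

test_that("grouping by the signal beats grouping by an independent factor", {
  # expression depends only on the mutation class; "ploidy" is assigned
  # independently, so the mutation grouping must cross-validate better
  set.seed(48)
  coh <- generate_cohort(cohort_config(seed = 48))
  mat <- build_expression_matrix(coh$ct, "ancestor")
  truth <- coh$truth[coh$truth$clone != "ancestor", ]
  mg <- setNames(truth$class, truth$clone)
  pg <- setNames(sample(c("1N", "2N", "4N"), nrow(truth), replace = TRUE),
                 truth$clone)
  rep <- separation_report(mat, mg, pg)
  expect_gt(rep$mutation$cv$accuracy, rep$ploidy$cv$accuracy)
  expect_true(rep$mutation_better_everywhere)
  # identical groupings give identical accuracies
  rep2 <- separation_report(mat, mg, mg)
  expect_equal(rep2$mutation$cv$accuracy, rep2$ploidy$cv$accuracy)
})

test_that("discriminant scores are invariant to per-gene affine rescaling", {
  set.seed(49)
  X <- toy_clusters(rbind(c(0, 0, 0), c(4, 0, 2), c(0, 4, -2)),
                    n_per = 8, sd = 0.5)
  g <- rep(c("a", "b", "c"), each = 8)
  f1 <- fit_lda(X, g, lambda = 0)
  X2 <- X; X2[, 2] <- X2[, 2] * 7 + 3
  f2 <- fit_lda(X2, g, lambda = 0)
  for (j in 1:2)
    expect_equal(abs(stats::cor(f1$scores[, j], f2$scores[, j])), 1,
                 tolerance = 1e-6)
})
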