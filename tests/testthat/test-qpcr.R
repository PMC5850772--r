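# quantification: standard curves, efficiency-corrected ratios, error
# propagation

test_that("perfect 2-fold dilution series gives slope -1/log10(2) and E = 1", {
  dil <- 2^-(0:4)
  ct <- 20 + (0:4)          # one cycle per 2-fold dilution
  sc <- fit_standard_curve(dil, ct)
  expect_equal(sc$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(sc$efficiency, 1, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-9)
  expect_true(sc$valid)
  expect_equal(sc$linear_range, c(min(dil), max(dil)))
})

test_that("flat Ct across dilutions flags an invalid curve instead of failing", {
  expect_warning(sc <- fit_standard_curve(c(1, 0.1, 0.01), c(20, 20, 20)),
                 "non-negative slope")
  expect_false(sc$valid)
  expect_true(is.na(sc$efficiency))
})

test_that("noisy dilution series matches the closed-form OLS solution", {
  set.seed(11)
  dil <- rep(10^-(0:4), each = 2)
  x <- log10(dil)
  ct <- 18 - 3.45 * x + rnorm(length(x), 0, 0.2)
  sc <- fit_standard_curve(dil, ct)
  # independent closed-form least squares
  sl <- sum((x - mean(x)) * (ct - mean(ct))) / sum((x - mean(x))^2)
  ic <- mean(ct) - sl * mean(x)
  expect_equal(sc$slope, sl, tolerance = 1e-9)
  expect_equal(sc$intercept, ic, tolerance = 1e-9)
  expect_error(fit_standard_curve(c(1, 0.5), c(20, 21)), "3 distinct")
})

test_that("relative expression is zero for identical Ct and one for a one-cycle drop", {
  ct <- make_ct(list(
    anc = list(HXT2 = c(22, 22), ACT1 = c(15, 15)),
    same = list(HXT2 = c(22, 22), ACT1 = c(15, 15)),
    up2 = list(HXT2 = c(21, 21), ACT1 = c(15, 15))), n_tech = 3L)
  r0 <- relative_expression(ct, "same", "anc", "HXT2")
  expect_equal(r0$log2_ratio, 0)
  expect_equal(r0$se, 0)
  r1 <- relative_expression(ct, "up2", "anc", "HXT2")
  expect_equal(r1$log2_ratio, 1)
})

test_that("efficiency-corrected ratio matches the direct-ratio oracle to 1e-12", {
  set.seed(21)
  vals <- list(
    anc = list(HXT3 = c(21.3, 21.7), ACT1 = c(15.2, 14.9)),
    evo = list(HXT3 = c(19.1, 19.6), ACT1 = c(15.4, 15.1)))
  ct <- make_ct(vals, n_tech = 2L, jitter = 0.1)
  eff <- c(HXT3 = 0.9, ACT1 = 1.0)
  r <- relative_expression(ct, "evo", "anc", "HXT3", "ACT1", eff)
  # oracle: per bio replicate, form the ratio (1+E_ref)^dCt_ref /
  # (1+E_gene)^dCt_gene directly, then take log2 and average
  bio_mean <- function(cl, g) {
    sub <- ct[ct$clone == cl & ct$gene == g, ]
    tapply(sub$ct, sub$bio_rep, mean)
  }
  anc_g <- mean(bio_mean("anc", "HXT3")); anc_r <- mean(bio_mean("anc", "ACT1"))
  rb <- sapply(1:2, function(b) {
    dg <- bio_mean("evo", "HXT3")[[b]] - anc_g
    dr <- bio_mean("evo", "ACT1")[[b]] - anc_r
    log2((1 + eff[["ACT1"]])^dr / (1 + eff[["HXT3"]])^dg)
  })
  expect_equal(r$log2_ratio, mean(rb), tolerance = 1e-12)
  expect_equal(r$se, sd(rb) / sqrt(2), tolerance = 1e-12)
})

test_that("swapping clone and ancestor negates the ratio exactly", {
  set.seed(31)
  vals <- list(
    a = list(HXT2 = c(22.1, 21.8), ACT1 = c(15.0, 15.3)),
    b = list(HXT2 = c(20.4, 20.9), ACT1 = c(15.2, 14.8)))
  ct <- make_ct(vals, n_tech = 3L, jitter = 0.05)
  fwd <- relative_expression(ct, "b", "a", "HXT2")
  rev <- relative_expression(ct, "a", "b", "HXT2")
  expect_equal(fwd$log2_ratio, -rev$log2_ratio, tolerance = 1e-12)
})

test_that("increasing gene efficiency increases ratio magnitude for fixed dCt < 0", {
  ct <- make_ct(list(
    anc = list(HXT4 = c(22, 22), ACT1 = c(15, 15)),
    evo = list(HXT4 = c(19, 19), ACT1 = c(15, 15))))
  mags <- sapply(c(0.7, 0.85, 1.0), function(e)
    abs(relative_expression(ct, "evo", "anc", "HXT4",
                            efficiencies = c(HXT4 = e, ACT1 = 1))$log2_ratio))
  expect_true(all(diff(mags) > 0))
})

test_that("quadrature error mode matches hand propagation of technical SEMs", {
  vals <- list(
    anc = list(HXT2 = c(22.0, 22.4), ACT1 = c(15.0, 15.2)),
    evo = list(HXT2 = c(20.1, 20.7), ACT1 = c(15.1, 14.9)))
  ct <- make_ct(vals, n_tech = 1L)
  r <- relative_expression(ct, "evo", "anc", "HXT2", se_mode = "quadrature")
  sem <- function(v) sd(v) / sqrt(length(v))
  want <- sqrt(sem(c(20.1, 20.7))^2 + sem(c(22.0, 22.4))^2 +
               sem(c(15.1, 14.9))^2 + sem(c(15.0, 15.2))^2)
  expect_equal(r$se, want, tolerance = 1e-12)
})

test_that("matrix construction round-trips a zero-noise cohort exactly", {
  sig <- default_signatures()
  zero_sig <- signature_set(sig$mean_log2, 0)
  cnt <- matrix(c(2L, 2L), 1,
                dimnames = list("2N", c("SNF3_high", "HXT67_amp")))
  coh <- generate_cohort(cohort_config(counts = cnt, tech_sd = 0, seed = 3),
                         zero_sig)
  mat <- build_expression_matrix(coh$ct, "ancestor")
  for (cl in rownames(mat$log2)) {
    truth <- coh$truth$class[coh$truth$clone == cl]
    expect_equal(unname(mat$log2[cl, ]),
                 unname(sig$mean_log2[truth, ]), tolerance = 1e-12)
  }
  expect_true(all(mat$se == 0))
})

test_that("a clone identical to the ancestor yields an all-zero row", {
  genes <- c(panel_genes(), "ACT1")
  vals <- list(anc = setNames(lapply(genes, function(g) c(20, 20)), genes),
               cl1 = setNames(lapply(genes, function(g) c(20, 20)), genes))
  ct <- make_ct(vals, n_tech = 2L)
  mat <- build_expression_matrix(ct, "anc")
  expect_equal(unname(mat$log2["cl1", ]), rep(0, 5))
})

test_that("missing panel measurements abort with every gap listed", {
  vals <- list(anc = list(HXT2 = c(20, 20), HXT3 = c(20, 20),
                          HXT4 = c(20, 20), HXT6_7 = c(20, 20),
                          SUC2 = c(20, 20), ACT1 = c(15, 15)),
               cl1 = list(HXT2 = c(20, 20), ACT1 = c(15, 15)))
  ct <- make_ct(vals)
  err <- expect_error(build_expression_matrix(ct, "anc"), "missing panel")
  expect_match(conditionMessage(err), "cl1:HXT3")
  expect_match(conditionMessage(err), "cl1:SUC2")
})
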