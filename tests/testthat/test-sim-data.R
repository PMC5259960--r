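# Genotype simulator, phenotype models, noise calibration, decomposition.

test_that("simulated genotype frequencies follow Hardy-Weinberg", {
  # p = 0.5: classes (0.25, 0.5, 0.25); p = 0.2 (causal): (0.64, 0.32, 0.04)
  n <- 1e5
  g <- simulate_genotypes(n, gene_sizes = c(1, 1), rho = 0,
                          maf_causal = 0.2, causal_snps = 2, seed = 7)
  g$values[, 1] <- g$values[, 1]  # col 1 has random MAF; test causal col 2
  tab2 <- tabulate(g$values[, 2], 3) / n
  hwe2 <- c(0.64, 0.32, 0.04)
  for (k in 1:3) {
    se <- sqrt(hwe2[k] * (1 - hwe2[k]) / n)
    expect_lt(abs(tab2[k] - hwe2[k]), 4 * se)
  }
  # chi-square goodness of fit on a fresh column at p = 0.5 via forced MAF
  g5 <- simulate_genotypes(n, gene_sizes = 1, rho = 0, maf_causal = 0.5,
                           causal_snps = 1, seed = 8)
  tab5 <- tabulate(g5$values[, 1], 3)
  chi <- sum((tab5 - n * c(0.25, 0.5, 0.25))^2 / (n * c(0.25, 0.5, 0.25)))
  expect_lt(chi, qchisq(0.999, df = 2))
})

test_that("within-gene latent correlation is rho, across-gene is null", {
  n <- 4000
  g <- simulate_genotypes(n, gene_sizes = c(5, 5), rho = 0.8, seed = 3)
  cm <- cor(g$values)
  within <- cm[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  across <- cm[1:5, 6:10]
  # genotype-scale correlation is attenuated by discretization but must be
  # clearly separated
  expect_gt(mean(within), 0.5)
  expect_lt(mean(abs(across)), 3 / sqrt(n) + 0.02)
})

test_that("simulate_genotypes validates arguments and is reproducible", {
  expect_ggee_error(simulate_genotypes(600, c(3, 0)), "ggee_invalid_argument")
  expect_ggee_error(simulate_genotypes(600, 3, rho = 1), "ggee_invalid_argument")
  expect_ggee_error(simulate_genotypes(600, 3, maf_causal = 0.7),
                    "ggee_invalid_argument")
  expect_ggee_error(simulate_genotypes(1, 3), "ggee_invalid_argument")
  a <- simulate_genotypes(50, c(2, 3), seed = 5)
  b <- simulate_genotypes(50, c(2, 3), seed = 5)
  expect_identical(a$values, b$values)
  expect_true(all(a$values %in% 1:3))
  expect_equal(nrow(a$gene_map), 2)
  expect_equal(unname(a$gene_map$end - a$gene_map$start + 1L), c(2L, 3L))
})

test_that("standardized_sum centers and scales, is scale-invariant", {
  v <- standardized_sum(matrix(c(1, 2, 3), 3, 1))
  expect_equal(mean(v), 0)
  expect_equal(var(v), 1)
  expect_equal(v, (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  m <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(standardized_sum(cbind(m, m)), standardized_sum(m))
  # brute-force oracle on a random matrix
  set.seed(9)
  r <- matrix(rnorm(150), 50, 3)
  s <- rowSums(r)
  expect_equal(standardized_sum(r), (s - mean(s)) / sd(s))
  expect_ggee_error(standardized_sum(matrix(1, 5, 2)), "ggee_degenerate_input")
})

test_that("sigma2_from_r2 matches the closed form and its limits", {
  # direct algebra: r2 = 0.5, SS = 10, n = 102 -> 0.1
  sig <- sqrt(10 / 101)
  signal <- scale(rnorm(102))[, 1] * sig * sqrt(101 / 102)
  signal <- signal - mean(signal)
  signal <- signal * sqrt(10 / sum(signal^2))
  expect_equal(sigma2_from_r2(signal, 0.5), 0.1)
  # r2 -> 1 gives sigma2 -> 0
  expect_lt(sigma2_from_r2(signal, 1 - 1e-9), 1e-8)
  # two-path check: independent recomputation of the printed formula
  set.seed(11)
  z <- rnorm(100)
  ss <- sum((z - mean(z))^2)
  expect_equal(sigma2_from_r2(z, 0.3), (0.3 - 1) * ss / (0.3 * (2 - 100)))
  expect_gt(sigma2_from_r2(z, 0.3), 0)
  expect_ggee_error(sigma2_from_r2(rep(1, 10), 0.5), "ggee_degenerate_input")
  expect_ggee_error(sigma2_from_r2(z, 1.2), "ggee_invalid_argument")
})

test_that("phenotype models build the stated components", {
  geno <- study_geno(seed = 21)
  # OME: y = sum of beta * standardized sums + noise, no interactions
  sim <- simulate_phenotype(geno, sim_setting("OME"), r2 = 0.5, seed = 2)
  tr <- sim$truth
  expect_equal(ncol(tr$interaction_components), 0)
  expect_equal(ncol(tr$main_components), 2)
  m1 <- standardized_sum(geno$values[, 1:2])
  expect_equal(unname(tr$main_components[, 1]), m1)
  resid <- sim$y - 2 * rowSums(tr$main_components)
  expect_equal(sd(resid), sqrt(tr$sigma2), tolerance = 0.15)
  # NE: pure noise
  simn <- simulate_phenotype(geno, sim_setting("NE"), seed = 3)
  expect_equal(ncol(simn$truth$main_components), 0)
  expect_lt(abs(mean(simn$y)), 0.2)
  # wang interaction component: standardized sum of the 4 causal products
  sima <- simulate_phenotype(geno, sim_setting("A"), r2 = 0.7, seed = 4)
  w <- pairwise_products(geno$values[, 1:2], geno$values[, 7:8])$w
  expect_equal(unname(sima$truth$interaction_components[, 1]),
               standardized_sum(w))
  # pca interaction component: standardized product of first PCs
  simb <- simulate_phenotype(geno, sim_setting("B"), r2 = 0.7, seed = 5)
  c1 <- pca_gene_components(geno$values[, 1:6], 1)[, 1]
  c2 <- pca_gene_components(geno$values[, 7:12], 1)[, 1]
  prod <- c1 * c2
  expect_equal(unname(simb$truth$interaction_components[, 1]),
               (prod - mean(prod)) / sd(prod))
})

test_that("empirical R2 is calibrated to the target", {
  r2s <- replicate(25, {
    geno <- study_geno(seed = sample.int(1e6, 1))
    sim <- simulate_phenotype(geno, sim_setting("A"), r2 = 0.7)
    comps <- cbind(sim$truth$main_components,
                   sim$truth$interaction_components)
    summary(lm(sim$y ~ comps))$r.squared
  })
  expect_lt(abs(mean(r2s) - 0.7), 0.03)
})

test_that("variance decomposition matches an OLS oracle", {
  geno <- study_geno(seed = 31)
  # interaction-only: p_I exactly 100, p_M exactly 0
  sim <- simulate_phenotype(geno, sim_setting("E"), r2 = 0.5, seed = 6)
  d <- variance_decomposition(sim$y, sim$truth)
  expect_identical(unname(d), c(100, 0))
  # main-only: p_I exactly 0
  simo <- simulate_phenotype(geno, sim_setting("OME"), r2 = 0.5, seed = 7)
  do_ <- variance_decomposition(simo$y, simo$truth)
  expect_identical(unname(do_[1]), 0)
  # orthogonal three-component oracle: p_I ~ 33.3, p_M ~ 66.7
  set.seed(8)
  n <- 2000
  comps <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n - 1)
  y <- rowSums(comps)
  truth <- structure(list(main_components = comps[, 1:2, drop = FALSE],
                          interaction_components = comps[, 3, drop = FALSE]),
                     class = "ggee_truth")
  dd <- variance_decomposition(y, truth)
  # oracle by explicit normal equations
  r2o <- function(X) {
    b <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
    1 - sum((y - cbind(1, X) %*% b)^2) / sum((y - mean(y))^2)
  }
  expect_equal(unname(dd["p_I"]),
               100 * r2o(comps[, 3, drop = FALSE]) / r2o(comps), tolerance = 1e-10)
  expect_equal(unname(dd["p_I"]), 100 / 3, tolerance = 0.5)
  expect_equal(unname(dd["p_M"]), 200 / 3, tolerance = 0.5)
})

test_that("setting table encodes the effect layouts", {
  a <- sim_setting("A")
  expect_equal(a$phenotype_model, "wang")
  expect_equal(a$main_genes, c(1L, 2L))
  expect_equal(a$interaction_pairs, list(c(1L, 2L)))
  expect_equal(sim_setting("D")$interaction_pairs, list(c(3L, 4L)))
  expect_equal(sim_setting("D")$phenotype_model, "pca")
  expect_length(sim_setting("OME")$interaction_pairs, 0)
  expect_length(sim_setting("NE")$main_genes, 0)
  expect_equal(sim_setting("E")$coefficient, 2)
  s25 <- sim_setting_25()
  expect_length(s25$interaction_pairs, 4)
})

test_that("wang model requires two causal SNPs per causal gene", {
  g1 <- simulate_genotypes(50, c(1, 3), seed = 2)
  expect_ggee_error(simulate_phenotype(g1, sim_setting("A"), r2 = 0.5),
                    "ggee_invalid_argument")
  expect_ggee_error(
    simulate_phenotype(study_geno(50), sim_setting("A"), r2 = 1.5),
    "ggee_invalid_argument")
})
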