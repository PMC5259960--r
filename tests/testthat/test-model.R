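# Group lasso solver, penalty selection, screen-and-clean, BH adjustment.

test_that("lambda at or above lambda_max zeroes every group", {
  d <- random_design(n = 80, sizes = c(4, 3, 5), seed = 21, signal = 0.7)
  lmax <- lambda_max(d)
  fit <- group_lasso_fit(d, lmax * 1.000001)
  expect_true(all(fit$coefficients == 0))
  fit2 <- group_lasso_fit(d, lmax * 0.95)
  expect_gt(sum(abs(fit2$coefficients)), 0)
})

test_that("unpenalized fit equals ordinary least squares", {
  d <- random_design(n = 100, sizes = c(3, 2, 4), seed = 22, signal = 0.5)
  fit <- group_lasso_fit(d, 0)
  yc <- d$y - mean(d$y)
  ols <- solve(crossprod(d$x), crossprod(d$x, yc))
  expect_equal(unname(fit$coefficients), as.numeric(ols), tolerance = 1e-6)
})

test_that("single orthonormal group matches the soft-threshold closed form", {
  set.seed(23)
  n <- 50
  x <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))  # orthonormal columns
  y <- rnorm(n) + x %*% c(2, -1, 0.5, 0)
  groups <- data.frame(label = "g1", type = "main", start = 1, end = 4,
                       weight = 2)
  d <- structure(list(x = x, y = as.numeric(y), family = "gaussian",
                      groups = groups), class = "ggee_design")
  yc <- d$y - mean(d$y)
  a <- crossprod(x, yc)
  for (lam in c(0.1, 0.5, 2)) {
    fit <- group_lasso_fit(d, lam)
    shrink <- max(0, 1 - lam * 2 / sqrt(sum(a^2)))
    expect_equal(unname(fit$coefficients), as.numeric(a * shrink),
                 tolerance = 1e-6)
    # second-solver oracle
    ista <- ista_group_lasso(x, d$y, groups, lam)
    expect_equal(unname(fit$coefficients), ista, tolerance = 1e-5)
  }
})

test_that("solver passes KKT certification and matches a second solver", {
  set.seed(24)
  for (i in 1:50) {
    sizes <- sample(1:4, sample(2:4, 1), replace = TRUE)
    d <- random_design(n = 40, sizes = sizes, seed = 1000 + i,
                       signal = runif(1, 0, 1))
    lam <- runif(1, 0.05, 0.6) * lambda_max(d)
    fit <- group_lasso_fit(d, lam)
    expect_true(kkt_check(d, fit, tol = 1e-5))
    ista <- ista_group_lasso(d$x, d$y, d$groups, lam)
    expect_equal(unname(fit$coefficients), ista, tolerance = 1e-4)
  }
})

test_that("objective is nonincreasing along the sweeps", {
  d <- random_design(n = 60, sizes = c(5, 4, 3), seed = 25, signal = 0.8)
  fit <- group_lasso_fit(d, 0.3 * lambda_max(d))
  tr <- fit$objective
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("cross-validation selection is deterministic and sane", {
  d <- random_design(n = 90, sizes = c(4, 4, 4), seed = 26, signal = 0.6)
  # single-value grid returns that value
  expect_equal(as.numeric(select_lambda_cv(d, grid = 0.42, seed = 1)), 0.42)
  l1 <- select_lambda_cv(d, seed = 7)
  l2 <- select_lambda_cv(d, seed = 7)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_ggee_error(select_lambda_cv(d, k = 1), "ggee_invalid_argument")
})

test_that("noise phenotypes select larger penalties than strong signals", {
  # CV-minimum selection on pure noise is itself noisy, so the ordering
  # holds with high but not certain probability (~0.95 at this size).
  wins <- 0
  trials <- 40
  for (i in seq_len(trials)) {
    set.seed(3000 + i)
    n <- 100
    x <- scale(matrix(rnorm(n * 9), n, 9))
    groups <- data.frame(label = paste0("g", 1:3), type = "main",
                         start = c(1, 4, 7), end = c(3, 6, 9),
                         weight = sqrt(3))
    mk <- function(y) structure(list(x = x, y = y, family = "gaussian",
                                     groups = groups), class = "ggee_design")
    dn <- mk(rnorm(n))
    ds <- mk(as.numeric(x[, 1:3] %*% rep(2, 3)) + rnorm(n))
    grid <- max(lambda_max(dn), lambda_max(ds)) * 10^seq(0, -3, length.out = 30)
    ln <- as.numeric(select_lambda_cv(dn, grid = grid, seed = i, k = 10))
    ls <- as.numeric(select_lambda_cv(ds, grid = grid, seed = i, k = 10))
    if (ln >= ls) wins <- wins + 1
  }
  expect_gte(wins / trials, 0.85)
})

test_that("bh_adjust matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(27)
  p <- runif(20)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p))
  expect_ggee_error(bh_adjust(c(0.5, 1.2)), "ggee_invalid_argument")
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("screen_and_clean respects the permutation floor and contracts", {
  d <- random_design(n = 60, sizes = c(3, 3, 3), seed = 28, signal = 1.5)
  rep <- screen_and_clean(d, B = 19, split_seed = 5)
  praw <- rep$table$p
  praw <- praw[!is.na(praw)]
  expect_true(all(praw >= 1 / 20))
  expect_true(all(praw <= 1))
  adj <- rep$table$p_adjusted
  expect_true(all(adj[!is.na(adj)] >= praw))
  # screened groups are exactly the report's candidates
  expect_setequal(rep$table$group[rep$table$screened], rep$candidates)
})

test_that("an overwhelming group is found significant", {
  hits <- 0
  for (i in 1:30) {
    d <- random_design(n = 120, sizes = c(3, 3, 3), seed = 4000 + i,
                       signal = 3)
    rep <- screen_and_clean(d, B = 99, split_seed = i)
    tab <- rep$table
    hits <- hits + isTRUE(tab$significant[tab$group == "gene1"])
  }
  expect_gte(hits / 30, 0.95)
})

test_that("empty screening yields a valid no-discovery report", {
  # pure noise with a harsh fixed penalty grid: nothing screened
  d <- random_design(n = 50, sizes = c(3, 3), seed = 29, signal = 0)
  rep <- screen_and_clean(d, B = 19, split_seed = 2,
                          grid = lambda_max(d) * 10)
  expect_length(rep$candidates, 0)
  expect_true(all(!rep$table$significant))
  expect_true(all(is.na(rep$table$p)))
})

test_that("raw permutation p-values are super-uniform under the null", {
  # many nulls on a fixed small design; pool raw p-values
  praw <- c()
  for (i in 1:60) {
    d <- random_design(n = 50, sizes = c(3, 3), seed = 5000 + i, signal = 0)
    rep <- screen_and_clean(d, B = 39, split_seed = i,
                            grid = lambda_max(d) * 10^seq(0, -1, length.out = 10))
    p <- rep$table$p
    praw <- c(praw, p[!is.na(p)])
  }
  if (length(praw) >= 50) {
    emp <- mean(praw <= 0.05)
    mc <- sqrt(0.05 * 0.95 / length(praw))
    expect_lte(emp, 0.05 + 3 * mc + 1 / 40)
  } else succeed("too few screened nulls to assess; selection was empty")
})

test_that("binomial family fits and cleans without error", {
  set.seed(30)
  geno <- tiny_geno(n = 120, sizes = c(3, 3), seed = 31)
  eta <- scale(geno$values[, 1]) * 1.5
  y <- rbinom(120, 1, plogis(as.numeric(eta)))
  iset <- build_interaction_design(geno, y, "ggee")
  d <- grouped_design(geno, iset, y, family = "binomial")
  lam <- select_lambda_cv(d, k = 3, seed = 2,
                          grid = lambda_max(d) * c(0.5, 0.2, 0.05))
  fit <- group_lasso_fit(d, as.numeric(lam))
  expect_true(is.finite(fit$intercept))
  # unpenalized logistic fit matches glm
  fit0 <- group_lasso_fit(d, 0)
  ref <- glm(y ~ d$x, family = binomial())
  expect_equal(unname(fit0$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-3)
})
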