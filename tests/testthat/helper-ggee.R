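# Shared fixture builders. Everything is generated in code; no data files.

# Small genotype object with deterministic content.
tiny_geno <- function(n = 40, sizes = c(3, 2, 4), seed = 42, rho = 0.5) {
  simulate_genotypes(n, sizes, rho = rho, causal_snps = c(1, 2),
                     seed = seed)
}

# Standard six-gene study-scale genotypes.
study_geno <- function(n = 600, seed = 1, causal_genes = c(1, 2)) {
  causal <- unlist(lapply(causal_genes, function(g) (g - 1) * 6 + 1:2))
  simulate_genotypes(n, rep(6, 6), rho = 0.8, maf_causal = 0.2,
                     causal_snps = causal, seed = seed)
}

# Random grouped design (gaussian) for solver tests: k groups of random
# sizes, optional true signal in the first group.
random_design <- function(n = 60, sizes = c(3, 2, 4), seed = 1,
                          signal = 0) {
  set.seed(seed)
  p <- sum(sizes)
  x <- matrix(rnorm(n * p), n, p)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  y <- rnorm(n)
  if (signal != 0)
    y <- y + x[, starts[1]:ends[1], drop = FALSE] %*% rep(signal, sizes[1])
  gm <- data.frame(gene_id = paste0("gene", seq_along(sizes)),
                   start = starts, end = ends)
  groups <- data.frame(label = gm$gene_id, type = "main",
                       start = starts, end = ends, weight = sqrt(sizes),
                       stringsAsFactors = FALSE)
  structure(list(x = scale(x), y = as.numeric(y), family = "gaussian",
                 groups = groups, geno = NULL, iset = NULL),
            class = "ggee_design")
}

# Independent slow solver for the group lasso: proximal gradient (ISTA) on
# the full coefficient vector. Used as an oracle against the coordinate
# solver.
ista_group_lasso <- function(x, y, groups, lambda, iters = 20000,
                             tol = 1e-12) {
  yc <- y - mean(y)
  p <- ncol(x)
  L <- max(svd(x, nu = 0, nv = 0)$d)^2
  b <- rep(0, p)
  for (i in seq_len(iters)) {
    grad <- -as.numeric(crossprod(x, yc - x %*% b))
    z <- b - grad / L
    bnew <- z
    for (g in seq_len(nrow(groups))) {
      jj <- groups$start[g]:groups$end[g]
      nz <- sqrt(sum(z[jj]^2))
      thr <- lambda * groups$weight[g] / L
      bnew[jj] <- if (nz <= thr) 0 else z[jj] * (1 - thr / nz)
    }
    if (max(abs(bnew - b)) < tol) { b <- bnew; break }
    b <- bnew
  }
  b
}

expect_ggee_error <- function(expr, class) {
  expect_error(expr, class = class)
}
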