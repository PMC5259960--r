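# Two-stage screen-and-clean inference: group lasso screening on one data
# half, group-structured ridge plus permutation p-values on the other.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: order the m raw p-values increasingly, multiply by
#' m / rank, enforce monotonicity from the largest down, and cap at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_invalid("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj <- pvals[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Group-weighted ridge: minimize ||y - X th||^2 + lam * sum_g w_g ||th_g||^2,
# i.e. a diagonal penalty with entry w_g on every column of group g.
# Returns the hat-style matrix H with th = H %*% y for fast permutation
# refits.
ridge_solver <- function(x, pen_diag, lam) {
  A <- crossprod(x)
  diag(A) <- diag(A) + lam * pen_diag
  solve(A, t(x))
}

# Pick the ridge penalty by k-fold CV on squared error (gaussian).
ridge_cv <- function(x, y, pen_diag, k = 5, seed = 1,
                     grid = 10^seq(3, -4, length.out = 30)) {
  n <- nrow(x)
  k <- min(k, n)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  err <- matrix(NA_real_, k, length(grid))
  for (fold in seq_len(k)) {
    tr <- which(folds != fold); te <- which(folds == fold)
    xt <- x[tr, , drop = FALSE]; yt <- y[tr]
    A0 <- crossprod(xt); b0 <- crossprod(xt, yt)
    for (j in seq_along(grid)) {
      A <- A0
      diag(A) <- diag(A) + grid[j] * pen_diag
      th <- tryCatch(solve(A, b0), error = function(e) NULL)
      if (is.null(th)) { err[fold, j] <- Inf; next }
      err[fold, j] <- mean((y[te] - x[te, , drop = FALSE] %*% th)^2)
    }
  }
  grid[which.min(colMeans(err))]
}

#' Screen-and-clean group significance testing
#'
#' Stage 1 (screen): a random half of the observations is used to fit the
#' weighted group lasso with a cross-validation-selected penalty; groups
#' with nonzero coefficient blocks become candidates. Stage 2 (clean): on
#' the held-out half, a ridge regression restricted to the candidate
#' groups — with each block's quadratic penalty scaled by the same group
#' weights — is fitted, and each candidate group's statistic is the squared
#' Euclidean norm of its ridge coefficient block.
#'
#' The permutation null (`perm = "group"`, default) permutes the rows of
#' the tested group's columns only, refitting the ridge each time: this
#' breaks that group's association with the response and the other
#' candidates while leaving their joint fit intact, so each group is tested
#' conditionally on the others. `perm = "phenotype"` instead permutes the
#' cleaning-half response, which tests every group against the global null;
#' it is markedly more conservative for correlated candidates. In both
#' schemes \eqn{p = (1 + \#\{stat_b \ge stat\})/(B + 1)} and
#' Benjamini-Hochberg adjustment is applied across candidates. Groups never
#' screened receive no p-value and are reported non-significant.
#'
#' @param design a [grouped_design] over all groups.
#' @param alpha significance level for the adjusted p-values.
#' @param B number of permutations (>= 1).
#' @param split_seed seed for the half-split (and derived CV/permutation
#'   seeds).
#' @param cv_folds folds for the screening-stage penalty selection.
#' @param grid optional penalty grid for the screening stage.
#' @param perm permutation scheme, `"group"` or `"phenotype"`.
#' @param half1 optional explicit screening-half indices (used by the
#'   leak-free pipeline, which must build interaction variables from the
#'   same half).
#' @return An object of class `ggee_clean_report`: data.frame `table` with
#'   columns group, type, screened, statistic, p, p_adjusted, significant;
#'   plus `lambda`, `ridge_lambda`, `B`, `alpha`, `split` (indices),
#'   `candidates`.
#' @export
screen_and_clean <- function(design, alpha = 0.05, B = 999, split_seed = 1,
                             cv_folds = 5, grid = NULL,
                             perm = c("group", "phenotype"), half1 = NULL) {
  perm <- match.arg(perm)
  stopifnot(inherits(design, "ggee_design"))
  if (B < 1) stop_invalid("B must be >= 1")
  n <- nrow(design$x)
  seeds <- derive_seeds(split_seed, 3)
  if (is.null(half1)) half1 <- split_half(design$y, design$family, seeds[1])
  half2 <- setdiff(seq_len(n), half1)

  d1 <- design_rows(design, half1)
  lam <- select_lambda_cv(d1, k = cv_folds, grid = grid, seed = seeds[2])
  sfit <- group_lasso_fit(d1, as.numeric(lam))
  candidates <- sfit$selected_groups

  g <- design$groups
  tab <- data.frame(group = g$label, type = g$type,
                    screened = g$label %in% candidates,
                    statistic = NA_real_, p = NA_real_,
                    p_adjusted = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  ridge_lam <- NA_real_
  if (length(candidates)) {
    ci <- which(g$label %in% candidates)
    cols <- unlist(lapply(ci, function(i) g$start[i]:g$end[i]))
    pen <- unlist(lapply(ci, function(i)
      rep(g$weight[i], g$end[i] - g$start[i] + 1L)))
    x2 <- design$x[half2, cols, drop = FALSE]
    y2 <- design$y[half2]
    y2c <- y2 - mean(y2)
    ridge_lam <- ridge_cv(x2, y2c, pen, k = cv_folds, seed = seeds[3])
    H <- ridge_solver(x2, pen, ridge_lam)
    th <- as.numeric(H %*% y2c)
    # block boundaries inside the candidate-column subspace
    lens <- vapply(ci, function(i) as.integer(g$end[i] - g$start[i] + 1L), 0L)
    stop_at <- cumsum(lens); start_at <- stop_at - lens + 1L
    stat_of <- function(theta) vapply(seq_along(ci), function(j)
      sum(theta[start_at[j]:stop_at[j]]^2), 0)
    obs <- stat_of(th)
    n2 <- length(half2)
    perm_stats <- if (perm == "phenotype") {
      ps <- with_seed(seeds[3] + 1L, {
        vapply(seq_len(B), function(b) stat_of(as.numeric(H %*% sample(y2c))),
               numeric(length(ci)))
      })
      matrix(ps, nrow = length(ci))
    } else {
      pimat <- with_seed(seeds[3] + 1L,
                         vapply(seq_len(B), function(b) sample.int(n2),
                                integer(n2)))
      ridge_perm_stats_cpp(x2, y2c, pen, ridge_lam,
                           as.integer(start_at - 1L), lens,
                           matrix(as.integer(pimat), n2, B))
    }
    praw <- vapply(seq_along(ci), function(j)
      (1 + sum(perm_stats[j, ] >= obs[j])) / (B + 1), 0)
    padj <- bh_adjust(praw)
    tab$statistic[ci] <- obs
    tab$p[ci] <- praw
    tab$p_adjusted[ci] <- padj
    tab$significant[ci] <- padj < alpha
  }
  structure(list(table = tab, lambda = as.numeric(lam),
                 ridge_lambda = ridge_lam, B = B, alpha = alpha,
                 perm = perm, split = half1, candidates = candidates),
            class = "ggee_clean_report")
}

split_half <- function(y, family, seed) {
  n <- length(y)
  with_seed(seed, {
    if (family == "binomial") {
      # stratified 50/50 split by class
      unlist(lapply(unique(y), function(cls) {
        i <- which(y == cls)
        sample(i, floor(length(i) / 2))
      }))
    } else sample(n, floor(n / 2))
  })
}

#' @export
print.ggee_clean_report <- function(x, ...) {
  cat(sprintf("Screen-and-clean: %d candidate group(s), B = %d, alpha = %.3g\n",
              length(x$candidates), x$B, x$alpha))
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("Significant groups:\n")
    print(sig[, c("group", "type", "statistic", "p", "p_adjusted")],
          row.names = FALSE)
  } else cat("No significant groups.\n")
  invisible(x)
}

#' Full epistasis scan: build interactions, screen, clean
#'
#' End-to-end pipeline on one dataset. In strict mode (default) the
#' half-split is drawn first and the interaction variables (Eigen-Epistasis
#' u vectors, PCA loadings, PLS weights, all standardization statistics)
#' are estimated on the screening half only, so the cleaning half's
#' phenotype never influences variable construction; otherwise variables
#' are built once on the full data.
#'
#' @param geno a [ggee_geno] object.
#' @param y phenotype vector.
#' @param method interaction construction: `"ggee"`, `"pca"`, `"pls"`.
#' @param q components per gene for pca/pls.
#' @param family model family.
#' @param alpha,B,cv_folds,grid,perm see [screen_and_clean].
#' @param seed master seed for split/CV/permutations.
#' @param strict build interaction weights on the screening half only.
#' @param interaction_weights see [grouped_design].
#' @return a `ggee_clean_report` (with the design in attribute `"design"`).
#' @export
epistasis_scan <- function(geno, y, method = c("ggee", "pca", "pls"), q = 1,
                           family = c("gaussian", "binomial"),
                           alpha = 0.05, B = 999, cv_folds = 5, grid = NULL,
                           perm = c("group", "phenotype"),
                           seed = 1, strict = TRUE,
                           interaction_weights = c("size", "nominal")) {
  method <- match.arg(method)
  family <- match.arg(family)
  n <- nrow(geno$values)
  seeds <- derive_seeds(seed, 1)
  half1 <- split_half(y, family, seeds[1])
  train_idx <- if (strict) half1 else NULL
  iset <- build_interaction_design(geno, y, method = method, q = q,
                                   train_idx = train_idx)
  design <- grouped_design(geno, iset, y, family = family,
                           train_idx = train_idx,
                           interaction_weights = interaction_weights)
  rep <- screen_and_clean(design, alpha = alpha, B = B, split_seed = seed,
                          cv_folds = cv_folds, grid = grid, perm = perm,
                          half1 = half1)
  attr(rep, "design") <- design
  rep
}
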