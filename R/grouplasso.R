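# Weighted Group Lasso over gene main-effect groups and gene-pair
# interaction groups, with cross-validated penalty selection.

#' Assemble the grouped penalized-regression design
#'
#' Combines the standardized SNP columns (one block per gene, penalty weight
#' \eqn{\sqrt{p_g}}) with the interaction columns (one block per gene pair,
#' penalty weight \eqn{\sqrt{p_r p_s}}) into a single design. The
#' interaction weight uses the nominal pairwise-product dimension
#' \eqn{p_r p_s} regardless of how many columns the construction actually
#' produced (one for the Eigen-Epistasis component, q^2 for PCA, q for PLS),
#' matching the estimation objective
#' \deqn{\sum_i (y_i - X_i\beta - Z_i\gamma)^2 + \lambda\Big[\sum_g
#'   \sqrt{p_g}\|\beta^g\|_2 + \sum_{rs}\sqrt{p_r p_s}\|\gamma^{rs}\|_2\Big].}
#'
#' @param geno a [ggee_geno] object.
#' @param iset a [build_interaction_design] result (may be NULL for a
#'   main-effects-only design).
#' @param y response vector: numeric trait (`gaussian`) or 0/1 labels
#'   (`binomial`).
#' @param family `"gaussian"` or `"binomial"`.
#' @param train_idx optional rows used for column standardization
#'   statistics (leak-free split mode).
#' @param interaction_weights `"size"` (default) weights each interaction
#'   block by the square root of its actual column count — the standard
#'   group-lasso convention, 1 for an Eigen-Epistasis component, q for PCA,
#'   sqrt(q) for PLS; `"nominal"` uses \eqn{\sqrt{p_r p_s}} as in the
#'   displayed objective, which reads the penalty at the dimension of the
#'   unreduced pairwise-product coefficient vector and penalizes the
#'   reduced constructions much more harshly.
#' @return An object of class `ggee_design`: `x` (full standardized
#'   matrix), `y`, `family`, `groups` (data.frame label, type, start, end,
#'   weight), plus the source objects.
#' @export
grouped_design <- function(geno, iset, y, family = c("gaussian", "binomial"),
                           train_idx = NULL,
                           interaction_weights = c("size", "nominal")) {
  family <- match.arg(family)
  interaction_weights <- match.arg(interaction_weights)
  stopifnot(inherits(geno, "ggee_geno"))
  n <- nrow(geno$values)
  if (length(y) != n) stop_invalid("y length must match individuals")
  if (!all(is.finite(geno$values)) || !all(is.finite(y)))
    stop_invalid("non-finite values in design or response")
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop_invalid("binomial family needs 0/1 response")

  xm <- standardize_cols(geno$values, train = train_idx)
  gm <- geno$gene_map
  sizes <- gm$end - gm$start + 1L
  groups <- data.frame(label = as.character(gm$gene_id), type = "main",
                       start = gm$start, end = gm$end,
                       weight = sqrt(sizes), stringsAsFactors = FALSE)
  x <- xm
  if (!is.null(iset) && ncol(iset$z) > 0) {
    stopifnot(inherits(iset, "ggee_interaction_set"))
    off <- ncol(xm)
    ig <- iset$groups
    iw <- if (interaction_weights == "size") sqrt(ig$end - ig$start + 1)
          else sqrt(ig$nominal_size)
    groups <- rbind(groups,
      data.frame(label = ig$pair_id, type = "interaction",
                 start = ig$start + off, end = ig$end + off,
                 weight = iw, stringsAsFactors = FALSE))
    x <- cbind(xm, iset$z)
  }
  structure(list(x = x, y = as.numeric(y), family = family, groups = groups,
                 geno = geno, iset = iset),
            class = "ggee_design")
}

#' @export
print.ggee_design <- function(x, ...) {
  cat(sprintf("GroupedDesign: %d obs, %d columns, %d groups (%d main + %d interaction), family %s\n",
              nrow(x$x), ncol(x$x), nrow(x$groups),
              sum(x$groups$type == "main"), sum(x$groups$type == "interaction"),
              x$family))
  invisible(x)
}

# Restrict a design to a subset of rows (standardization is NOT redone;
# the screening/cleaning stages share the full-data or train-only scaling).
design_rows <- function(design, idx) {
  out <- design
  out$x <- design$x[idx, , drop = FALSE]
  out$y <- design$y[idx]
  out
}

#' Smallest penalty that zeroes every group
#'
#' From the Karush-Kuhn-Tucker conditions of the weighted group lasso, all
#' blocks are zero iff \eqn{\lambda \ge \max_g \|X_g^T \tilde y\|_2 / w_g}
#' (gaussian: \eqn{\tilde y} the centered response; binomial: residual at
#' the intercept-only fit).
#'
#' @param design a [grouped_design].
#' @return scalar \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(design) {
  r0 <- if (design$family == "gaussian") design$y - mean(design$y)
        else design$y - mean(design$y)   # logistic gradient at null: y - ybar
  g <- design$groups
  max(vapply(seq_len(nrow(g)), function(i) {
    xg <- design$x[, g$start[i]:g$end[i], drop = FALSE]
    sqrt(sum(crossprod(xg, r0)^2)) / g$weight[i]
  }, 0))
}

default_lambda_grid <- function(design, nlambda = 50, min_ratio = 1e-3) {
  lmax <- lambda_max(design)
  lmax * 10^seq(0, log10(min_ratio), length.out = nlambda)
}

# Internal: gaussian path via the C++ solver. Returns p x L coefficient
# matrix plus convergence info. X columns as stored; y centered here.
fit_path_gaussian <- function(x, y, groups, lambdas, tol, maxit,
                              record_obj = FALSE, obs_weights = NULL) {
  yc <- y - mean(y)
  if (!is.null(obs_weights)) {
    sw <- sqrt(obs_weights)
    x <- x * sw
    yc <- yc * sw
  }
  grplasso_path_cpp(x, yc, as.integer(groups$start - 1L),
                    as.integer(groups$end - groups$start + 1L),
                    groups$weight, lambdas, tol, as.integer(maxit),
                    record_obj)
}

# Internal: binomial path by IRLS around the weighted gaussian solver.
# Working response and weights are refreshed until the coefficients settle.
fit_path_binomial <- function(x, y, groups, lambdas, tol, maxit,
                              irls_maxit = 25) {
  p <- ncol(x); L <- length(lambdas)
  beta <- matrix(0, p, L)
  conv <- integer(L)
  intercepts <- numeric(L)
  b <- rep(0, p); b0 <- stats::qlogis(mean(pmin(pmax(y, 1e-3), 1 - 1e-3)))
  for (l in seq_len(L)) {
    for (it in seq_len(irls_maxit)) {
      eta <- b0 + as.numeric(x %*% b)
      mu <- stats::plogis(eta)
      wq <- pmax(mu * (1 - mu), 1e-5)
      z <- eta + (y - mu) / wq
      # weighted centering absorbs the intercept
      wm_z <- sum(wq * z) / sum(wq)
      wm_x <- as.numeric(crossprod(x, wq)) / sum(wq)
      xs <- sweep(x, 2, wm_x, "-") * sqrt(wq)
      zs <- (z - wm_z) * sqrt(wq)
      fit <- grplasso_path_cpp(xs, zs, as.integer(groups$start - 1L),
                               as.integer(groups$end - groups$start + 1L),
                               groups$weight, lambdas[l], tol * 10,
                               as.integer(maxit), FALSE)
      bnew <- fit$beta[, 1]
      b0 <- wm_z - sum(wm_x * bnew)
      done <- max(abs(bnew - b)) < 1e-6
      b <- bnew
      if (done) break
    }
    beta[, l] <- b
    intercepts[l] <- b0
    conv[l] <- as.integer(it < irls_maxit || done)
  }
  list(beta = beta, converged = conv, intercepts = intercepts)
}

#' Fit the weighted group lasso at one penalty
#'
#' Gaussian family: minimizes \eqn{\frac12\|y - X\theta\|^2 + \lambda\sum_g
#' w_g \|\theta_g\|_2} by block coordinate descent with exact group updates;
#' blocks whose KKT cross-product norm falls below \eqn{\lambda w_g} are
#' exactly zero. Binomial family: penalized logistic likelihood via
#' iteratively reweighted least squares around the same solver.
#'
#' @param design a [grouped_design].
#' @param lambda penalty (>= 0).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param maxit maximum coordinate-descent sweeps.
#' @return An object of class `ggee_glfit`: `coefficients` (named vector),
#'   `beta` / `gamma` (main and interaction blocks), `intercept`, `lambda`,
#'   `selected_groups` (labels with nonzero blocks), `objective` (per-sweep
#'   trace, gaussian), `converged`.
#' @export
group_lasso_fit <- function(design, lambda, tol = 1e-8, maxit = 1e4) {
  stopifnot(inherits(design, "ggee_design"))
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  g <- design$groups
  if (design$family == "gaussian") {
    fit <- fit_path_gaussian(design$x, design$y, g, lambda, tol, maxit,
                             record_obj = TRUE)
    coefs <- fit$beta[, 1]
    intercept <- mean(design$y)
    objective <- fit$objective[[1]]
    converged <- fit$converged[1] == 1
  } else {
    fit <- fit_path_binomial(design$x, design$y, g, lambda, tol, maxit)
    coefs <- fit$beta[, 1]
    intercept <- fit$intercepts
    objective <- NULL
    converged <- fit$converged[1] == 1
  }
  if (!converged)
    warning("group lasso did not converge within maxit sweeps")
  names(coefs) <- colnames(design$x)
  norms <- vapply(seq_len(nrow(g)), function(i)
    sqrt(sum(coefs[g$start[i]:g$end[i]]^2)), 0)
  sel <- g$label[norms > 0]
  main_idx <- g$type == "main"
  structure(list(coefficients = coefs, intercept = intercept,
                 beta = coefs[seq_len(max(g$end[main_idx]))],
                 gamma = if (any(!main_idx))
                   coefs[min(g$start[!main_idx]):max(g$end[!main_idx])]
                 else numeric(0),
                 lambda = lambda, group_norms = setNames(norms, g$label),
                 selected_groups = sel, objective = objective,
                 converged = converged, family = design$family),
            class = "ggee_glfit")
}

#' @export
print.ggee_glfit <- function(x, ...) {
  cat(sprintf("Group lasso fit (lambda = %.4g): %d group(s) selected\n",
              x$lambda, length(x$selected_groups)))
  if (length(x$selected_groups))
    cat(" ", paste(x$selected_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Select the group-lasso penalty by k-fold cross-validation
#'
#' Splits observations into k folds (deterministically from `seed`), fits
#' the penalty path on each training set with warm starts, and returns the
#' grid value minimizing mean out-of-fold squared error (gaussian) or
#' deviance (binomial).
#'
#' @param design a [grouped_design].
#' @param k number of folds (>= 2).
#' @param grid penalty grid; default 50 log-spaced values from
#'   \eqn{\lambda_{max}} down to \eqn{10^{-3}\lambda_{max}}.
#' @param seed fold-assignment seed.
#' @param tol,maxit solver controls.
#' @return the selected penalty, with the full CV curve in attribute
#'   `"cv"` (data.frame lambda, mean error).
#' @export
select_lambda_cv <- function(design, k = 5, grid = NULL, seed = 1,
                             tol = 1e-4, maxit = 300) {
  stopifnot(inherits(design, "ggee_design"))
  n <- nrow(design$x)
  if (k < 2) stop_invalid("k must be >= 2")
  if (n < k) stop_invalid("fewer observations than folds")
  grid <- grid %||% default_lambda_grid(design)
  grid <- sort(grid, decreasing = TRUE)
  folds <- with_seed(seed, {
    if (design$family == "binomial") {
      f <- integer(n)
      for (cls in unique(design$y)) {
        i <- which(design$y == cls)
        f[i] <- sample(rep(seq_len(k), length.out = length(i)))
      }
      f
    } else sample(rep(seq_len(k), length.out = n))
  })
  err <- matrix(NA_real_, k, length(grid))
  for (fold in seq_len(k)) {
    tr <- which(folds != fold); te <- which(folds == fold)
    if (design$family == "gaussian") {
      fit <- fit_path_gaussian(design$x[tr, , drop = FALSE], design$y[tr],
                               design$groups, grid, tol, maxit)
      mu_tr <- mean(design$y[tr])
      pred <- design$x[te, , drop = FALSE] %*% fit$beta + mu_tr
      err[fold, ] <- colMeans((design$y[te] - pred)^2)
    } else {
      fit <- fit_path_binomial(design$x[tr, , drop = FALSE], design$y[tr],
                               design$groups, grid, tol, maxit)
      eta <- sweep(design$x[te, , drop = FALSE] %*% fit$beta, 2,
                   fit$intercepts, "+")
      mu <- stats::plogis(eta)
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      err[fold, ] <- colMeans(-2 * (design$y[te] * log(mu) +
                                      (1 - design$y[te]) * log(1 - mu)))
    }
  }
  cv <- colMeans(err)
  best <- grid[which.min(cv)]
  attr(best, "cv") <- data.frame(lambda = grid, error = cv)
  best
}

#' Check Karush-Kuhn-Tucker conditions of a group-lasso solution
#'
#' For every zero block the gradient norm must satisfy
#' \eqn{\|X_g^T r\| \le \lambda w_g + tol}; for every active block the
#' stationarity equation \eqn{X_g^T r = \lambda w_g \theta_g/\|\theta_g\|}
#' must hold to `tol`. Gaussian family only.
#'
#' @param design the [grouped_design] used for the fit.
#' @param fit a `ggee_glfit`.
#' @param tol slack.
#' @return logical; per-group diagnostics in attribute `"detail"`.
#' @export
kkt_check <- function(design, fit, tol = 1e-6) {
  stopifnot(design$family == "gaussian")
  g <- design$groups
  yc <- design$y - mean(design$y)
  r <- yc - as.numeric(design$x %*% fit$coefficients)
  scale_ref <- max(1, sqrt(sum(yc^2)))
  detail <- lapply(seq_len(nrow(g)), function(i) {
    xg <- design$x[, g$start[i]:g$end[i], drop = FALSE]
    bg <- fit$coefficients[g$start[i]:g$end[i]]
    grad <- as.numeric(crossprod(xg, r))
    if (sqrt(sum(bg^2)) == 0) {
      ok <- sqrt(sum(grad^2)) <= fit$lambda * g$weight[i] + tol * scale_ref
      list(label = g$label[i], active = FALSE, ok = ok)
    } else {
      resid <- grad - fit$lambda * g$weight[i] * bg / sqrt(sum(bg^2))
      list(label = g$label[i], active = TRUE,
           ok = sqrt(sum(resid^2)) <= tol * scale_ref)
    }
  })
  ok <- all(vapply(detail, `[[`, TRUE, "ok"))
  attr(ok, "detail") <- detail
  ok
}
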