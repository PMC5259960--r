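# Construction of gene-pair interaction variables: pairwise SNP products,
# the Eigen-Epistasis component, PCA products, and PLS components.

#' All pairwise products of the columns of two matrices
#'
#' Column (j, k) of the result is the elementwise product of column j of
#' `xr` and column k of `xs`; columns are ordered lexicographically in
#' (j, k) with j varying slowest. No centering or scaling is applied.
#'
#' @param xr numeric matrix n x p_r.
#' @param xs numeric matrix n x p_s.
#' @return An object of class `ggee_pair_products` with fields `w`
#'   (n x p_r p_s matrix) and `col_index` (data.frame mapping (j, k) to
#'   columns).
#' @export
pairwise_products <- function(xr, xs) {
  xr <- as.matrix(xr); xs <- as.matrix(xs)
  if (nrow(xr) != nrow(xs)) stop_invalid("xr and xs must have the same rows")
  if (ncol(xr) < 1 || ncol(xs) < 1) stop_invalid("need at least one column each")
  pr <- ncol(xr); ps <- ncol(xs)
  j <- rep(seq_len(pr), each = ps)
  k <- rep(seq_len(ps), times = pr)
  w <- xr[, j, drop = FALSE] * xs[, k, drop = FALSE]
  colnames(w) <- paste0(j, "x", k)
  structure(list(w = w, col_index = data.frame(j = j, k = k)),
            class = "ggee_pair_products")
}

#' Eigen-Epistasis component of a gene pair
#'
#' Among all unit vectors u, the linear combination W u of the pairwise SNP
#' products that maximizes the squared sample covariance with the phenotype.
#' The maximizer is the leading eigenvector of \eqn{W^T y y^T W}, which is
#' available in closed form as \eqn{u = W^T y / \|W^T y\|} (cost
#' O(n p_r p_s)). By default y and the columns of W are centered first so
#' the objective is a literal covariance; `center = FALSE` gives the raw
#' cross-product variant. The sign is fixed so that cov(z, y) >= 0.
#'
#' @param w a [pairwise_products] result (or plain matrix).
#' @param y numeric phenotype vector.
#' @param center center y and the columns of W first (default TRUE).
#' @return list with `u` (unit vector, length p_r p_s) and `z` (length-n
#'   interaction variable W u).
#' @export
eigen_epistasis <- function(w, y, center = TRUE) {
  W <- if (inherits(w, "ggee_pair_products")) w$w else as.matrix(w)
  if (nrow(W) != length(y)) stop_invalid("W rows must match length(y)")
  if (center) {
    W <- sweep(W, 2, colMeans(W), "-")
    y <- y - mean(y)
  }
  a <- as.numeric(crossprod(W, y))
  nrm <- sqrt(sum(a^2))
  if (nrm <= 1e-12 * max(1, sqrt(sum(y^2))))
    stop(errorCondition("phenotype orthogonal to all pairwise products; Eigen-Epistasis component undefined",
                        class = c("ggee_degenerate_pair", "ggee_error")))
  u <- a / nrm
  z <- as.numeric(W %*% u)
  if (sum(z * y) < 0) { u <- -u; z <- -z }
  list(u = u, z = z)
}

#' Principal-component scores of one gene
#'
#' Column-standardizes the gene submatrix (zero-variance columns are dropped
#' from the decomposition with a warning) and returns the scores on the
#' first q principal axes. Sign convention: within each axis the
#' largest-magnitude loading is positive.
#'
#' @param xg numeric matrix n x p_g of one gene's SNPs.
#' @param q number of components, 1 <= q <= min(n, p_g).
#' @return n x q score matrix with the loading matrix attached as
#'   attribute `"loadings"` (p_used x q) and the retained column indices as
#'   `"columns"`.
#' @export
pca_gene_components <- function(xg, q) {
  xg <- as.matrix(xg)
  n <- nrow(xg); p <- ncol(xg)
  if (q < 1 || q > min(n, p)) stop_invalid("q must be in [1, min(n, p_g)]")
  xs <- standardize_cols(xg)
  drop_cols <- attr(xs, "zero_variance")
  keep <- setdiff(seq_len(p), drop_cols)
  if (length(drop_cols)) {
    warning(sprintf("dropping %d zero-variance column(s) from PCA", length(drop_cols)))
    if (length(keep) < q) stop_invalid("q exceeds the number of non-constant columns")
    xs <- xs[, keep, drop = FALSE]
  }
  sv <- svd(xs, nu = 0, nv = q)
  v <- sv$v[, seq_len(q), drop = FALSE]
  for (k in seq_len(q)) {
    if (v[which.max(abs(v[, k])), k] < 0) v[, k] <- -v[, k]
  }
  scores <- xs %*% v
  colnames(scores) <- paste0("PC", seq_len(q))
  attr(scores, "loadings") <- v
  attr(scores, "columns") <- keep
  scores
}

#' PCA interaction columns for a gene pair
#'
#' All pairwise products of the two genes' component score matrices,
#' lexicographic in (j, k); with q components per gene this yields q^2
#' interaction columns (a single column when q = 1).
#'
#' @param cr,cs n x q component score matrices from [pca_gene_components].
#' @return n x q^2 matrix of products.
#' @export
pca_interactions <- function(cr, cs) {
  pairwise_products(cr, cs)$w
}

#' PLS interaction components for a gene pair
#'
#' Two-block partial least squares of the gene-r SNP matrix against
#' T = [y | X^s] (all columns standardized): component 1 is the X^r-side
#' score X^r u where (u, v) is the leading singular pair of the
#' cross-covariance of X^r with T; later components are obtained after
#' deflating both blocks on the preceding score. Scores are mutually
#' orthogonal under this deflation.
#'
#' @param xr,xs SNP matrices of genes r and s.
#' @param y phenotype vector.
#' @param q number of components.
#' @return n x q matrix of X^r-side scores.
#' @export
pls_interactions <- function(xr, xs, y, q = 1) {
  xr <- as.matrix(xr); xs <- as.matrix(xs)
  n <- nrow(xr)
  if (nrow(xs) != n || length(y) != n) stop_invalid("row mismatch")
  if (q < 1 || q > ncol(xr)) stop_invalid("q must be in [1, p_r]")
  X <- standardize_cols(xr)
  Tm <- standardize_cols(cbind(y = as.numeric(y), xs))
  scores <- matrix(NA_real_, n, q)
  for (comp in seq_len(q)) {
    M <- crossprod(X, Tm) / (n - 1)
    if (max(abs(M)) <= 1e-12)
      stop(errorCondition("zero cross-covariance; PLS component undefined",
                          class = c("ggee_degenerate_pair", "ggee_error")))
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    t1 <- as.numeric(X %*% u)
    scores[, comp] <- t1
    tt <- sum(t1^2)
    X <- X - t1 %*% crossprod(t1, X) / tt
    Tm <- Tm - t1 %*% crossprod(t1, Tm) / tt
  }
  colnames(scores) <- paste0("PLS", seq_len(q))
  scores
}

#' Build the full gene-pair interaction design
#'
#' Constructs one column group per unordered gene pair (r < s, in gene-map
#' order) by the requested method: `ggee` gives one Eigen-Epistasis column
#' per pair, `pca` gives q^2 principal-component product columns, `pls`
#' gives q partial-least-squares score columns. All columns are standardized
#' (mean 0, variance 1) for downstream penalized fitting. Pairs whose
#' construction is degenerate are excluded with a warning and recorded.
#'
#' When `train_idx` is supplied, every data-dependent ingredient (centering
#' and scaling statistics, Eigen-Epistasis u vectors, PCA loadings, PLS
#' weights) is estimated on those rows only and applied to all rows. This is
#' the leak-free mode used by the screen-and-clean split, where the cleaning
#' half's phenotype must not influence variable construction.
#'
#' @param geno a [ggee_geno] object with at least two genes.
#' @param y phenotype vector (used by `ggee` and `pls`).
#' @param method `"ggee"`, `"pca"`, or `"pls"`.
#' @param q components per gene for `pca` / `pls` (default 1).
#' @param center for `ggee`: center W and y before the cross-covariance.
#' @param train_idx optional row indices used to estimate all weights.
#' @return An object of class `ggee_interaction_set`: `z` (n x m matrix),
#'   `groups` (data.frame pair_id, gene_r, gene_s, start, end,
#'   nominal_size = p_r * p_s), `method`, `q`, `weights` (per-pair u vectors
#'   or loadings), `dropped` (character vector of degenerate pair ids).
#' @export
build_interaction_design <- function(geno, y, method = c("ggee", "pca", "pls"),
                                     q = 1, center = TRUE, train_idx = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(geno, "ggee_geno"))
  G <- nrow(geno$gene_map)
  if (G < 2) stop_invalid("need at least two genes")
  n <- nrow(geno$values)
  idx <- train_idx %||% seq_len(n)
  ids <- gene_ids(geno)
  pairs <- gene_pair_index(G)

  cols <- list(); grows <- list(); weights <- list(); dropped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    r <- pairs[i, "r"]; s <- pairs[i, "s"]
    pid <- paste(ids[r], ids[s], sep = ":")
    xr <- geno$values[, gene_cols(geno, r), drop = FALSE]
    xs <- geno$values[, gene_cols(geno, s), drop = FALSE]
    zi <- tryCatch(switch(method,
      ggee = {
        wp <- pairwise_products(xr, xs)
        W <- wp$w
        if (center) {
          mu <- colMeans(W[idx, , drop = FALSE])
          W <- sweep(W, 2, mu, "-")
        }
        yc <- y[idx] - if (center) mean(y[idx]) else 0
        a <- as.numeric(crossprod(W[idx, , drop = FALSE], yc))
        nrm <- sqrt(sum(a^2))
        if (nrm <= 1e-12 * max(1, sqrt(sum(yc^2))))
          stop(errorCondition("degenerate", class = "ggee_degenerate_pair"))
        u <- a / nrm
        if (sum((W[idx, , drop = FALSE] %*% u) * yc) < 0) u <- -u
        weights[[pid]] <- u
        matrix(W %*% u, n, 1)
      },
      pca = {
        cr <- pc_apply(xr, q, idx)
        cs <- pc_apply(xs, q, idx)
        weights[[pid]] <- list(r = attr(cr, "loadings"), s = attr(cs, "loadings"))
        pca_interactions(cr, cs)
      },
      pls = {
        sc <- pls_apply(xr, xs, y, q, idx)
        weights[[pid]] <- attr(sc, "weights")
        sc
      }),
      ggee_degenerate_pair = function(e) NULL)
    if (is.null(zi)) {
      dropped <- c(dropped, pid)
      next
    }
    zi <- standardize_cols(zi, train = idx)
    const <- attr(zi, "zero_variance")
    if (length(const) == ncol(zi)) {
      dropped <- c(dropped, pid)
      next
    }
    if (length(const)) zi <- zi[, -const, drop = FALSE]
    colnames(zi) <- paste0(pid, "_", seq_len(ncol(zi)))
    cols[[pid]] <- zi
    grows[[pid]] <- data.frame(pair_id = pid, gene_r = ids[r], gene_s = ids[s],
                               ncols = ncol(zi),
                               nominal_size = ncol(xr) * ncol(xs))
  }
  if (length(dropped))
    warning(sprintf("%d degenerate pair(s) excluded: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(cols)) {
    z <- matrix(numeric(0), n, 0)
    groups <- data.frame(pair_id = character(0), gene_r = character(0),
                         gene_s = character(0), start = integer(0),
                         end = integer(0), nominal_size = integer(0))
  } else {
    z <- do.call(cbind, cols)
    groups <- do.call(rbind, grows)
    groups$end <- cumsum(groups$ncols)
    groups$start <- groups$end - groups$ncols + 1L
    groups <- groups[, c("pair_id", "gene_r", "gene_s", "start", "end",
                         "nominal_size")]
    rownames(groups) <- NULL
  }
  structure(list(z = z, groups = groups, method = method, q = q,
                 weights = weights, dropped = dropped),
            class = "ggee_interaction_set")
}

#' @export
print.ggee_interaction_set <- function(x, ...) {
  cat(sprintf("InteractionSet (%s): %d pairs, %d columns%s\n", x$method,
              nrow(x$groups), ncol(x$z),
              if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped)) else ""))
  invisible(x)
}

# PCA scores with loadings/standardization estimated on `idx` rows only.
pc_apply <- function(xg, q, idx) {
  xs <- standardize_cols(xg, train = idx)
  keep <- setdiff(seq_len(ncol(xs)), attr(xs, "zero_variance"))
  if (length(keep) < q) stop(errorCondition("degenerate", class = "ggee_degenerate_pair"))
  xs <- xs[, keep, drop = FALSE]
  sv <- svd(xs[idx, , drop = FALSE], nu = 0, nv = q)
  v <- sv$v[, seq_len(q), drop = FALSE]
  for (k in seq_len(q)) if (v[which.max(abs(v[, k])), k] < 0) v[, k] <- -v[, k]
  out <- xs %*% v
  attr(out, "loadings") <- v
  out
}

# PLS scores with all weights estimated on `idx` rows; scores for all rows.
pls_apply <- function(xr, xs, y, q, idx) {
  n <- nrow(xr)
  X <- standardize_cols(xr, train = idx)
  Tm <- standardize_cols(cbind(y = as.numeric(y), xs), train = idx)
  us <- matrix(NA_real_, ncol(X), q)
  Xi <- X[idx, , drop = FALSE]; Ti <- Tm[idx, , drop = FALSE]
  scores_tr <- matrix(NA_real_, length(idx), q)
  proj <- list()
  for (comp in seq_len(q)) {
    M <- crossprod(Xi, Ti) / (length(idx) - 1)
    if (max(abs(M)) <= 1e-12)
      stop(errorCondition("degenerate", class = "ggee_degenerate_pair"))
    sv <- svd(M, nu = 1, nv = 1)
    u <- sv$u[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    us[, comp] <- u
    t1 <- as.numeric(Xi %*% u)
    scores_tr[, comp] <- t1
    tt <- sum(t1^2)
    proj[[comp]] <- as.numeric(crossprod(t1, Xi)) / tt
    Xi <- Xi - t1 %*% crossprod(t1, Xi) / tt
    Ti <- Ti - t1 %*% crossprod(t1, Ti) / tt
  }
  # apply the same deflation sequence to all rows
  Xa <- X
  out <- matrix(NA_real_, n, q)
  for (comp in seq_len(q)) {
    t_all <- as.numeric(Xa %*% us[, comp])
    out[, comp] <- t_all
    Xa <- Xa - t_all %*% matrix(proj[[comp]], 1)
  }
  attr(out, "weights") <- us
  out
}
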