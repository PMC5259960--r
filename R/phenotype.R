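# Phenotype simulation: effect layouts, trait models, noise calibration,
# and the R^2 decomposition into main and interaction parts.

#' Predefined simulation settings
#'
#' Effect layouts of the simplified power study, identified by letter:
#' \describe{
#'   \item{A / B}{main effects on genes 1 and 2 plus an interaction between
#'     the same two genes; trait model `wang` (A) or `pca` (B).}
#'   \item{C / D}{main effects on genes 1 and 2, interaction between genes 3
#'     and 4; model `wang` (C) or `pca` (D).}
#'   \item{E / F}{interaction between genes 1 and 2 only; model `wang` (E)
#'     or `pca` (F).}
#'   \item{OME}{main effects on genes 1 and 2 only.}
#'   \item{NE}{no effects at all (global null).}
#' }
#' All causal effects share the same coefficient (default 2).
#'
#' @param id one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"F"`, `"OME"`, `"NE"`.
#' @param coefficient common effect size for every causal main effect and
#'   interaction.
#' @return An object of class `ggee_setting` with fields `id`,
#'   `phenotype_model` (`"wang"` or `"pca"`), `main_genes` (integer gene
#'   positions), `interaction_pairs` (list of length-2 integer vectors),
#'   and `coefficient`.
#' @export
sim_setting <- function(id = c("A", "B", "C", "D", "E", "F", "OME", "NE"),
                        coefficient = 2) {
  id <- match.arg(id)
  layout <- switch(id,
    A   = list(model = "wang", mains = c(1L, 2L), pairs = list(c(1L, 2L))),
    B   = list(model = "pca",  mains = c(1L, 2L), pairs = list(c(1L, 2L))),
    C   = list(model = "wang", mains = c(1L, 2L), pairs = list(c(3L, 4L))),
    D   = list(model = "pca",  mains = c(1L, 2L), pairs = list(c(3L, 4L))),
    E   = list(model = "wang", mains = integer(0), pairs = list(c(1L, 2L))),
    F   = list(model = "pca",  mains = integer(0), pairs = list(c(1L, 2L))),
    OME = list(model = "wang", mains = c(1L, 2L), pairs = list()),
    NE  = list(model = "wang", mains = integer(0), pairs = list()))
  structure(list(id = id, phenotype_model = layout$model,
                 main_genes = layout$mains,
                 interaction_pairs = layout$pairs,
                 coefficient = coefficient),
            class = "ggee_setting")
}

#' Supplementary many-gene setting (25 genes, 4 interactions)
#'
#' Config preset for the larger layout: 25 genes, causal interactions
#' between four gene pairs disjoint from the two main-effect genes.
#' @param coefficient common effect size.
#' @return A `ggee_setting` object with id `"S25"`.
#' @export
sim_setting_25 <- function(coefficient = 2) {
  structure(list(id = "S25", phenotype_model = "wang",
                 main_genes = c(1L, 2L),
                 interaction_pairs = list(c(3L, 4L), c(5L, 6L),
                                          c(7L, 8L), c(9L, 10L)),
                 coefficient = coefficient),
            class = "ggee_setting")
}

#' Standardized row sum
#'
#' Sums the columns row-wise, then centers and scales the sum to sample mean
#' 0 and sample variance 1. This is the building block of every simulated
#' effect component.
#'
#' @param columns numeric matrix (n x k) or vector.
#' @return numeric vector of length n with mean 0, variance 1.
#' @export
standardized_sum <- function(columns) {
  m <- as.matrix(columns)
  if (ncol(m) < 1) stop_invalid("need at least one column")
  s <- rowSums(m)
  sdv <- sd(s)
  if (!is.finite(sdv) || sdv <= 0)
    stop_degenerate("row sum has zero variance; cannot standardize")
  (s - mean(s)) / sdv
}

#' Residual variance for a target coefficient of determination
#'
#' Given the signal vector (the noiseless linear predictor) and a target
#' R^2, returns the Gaussian residual variance
#' \deqn{\sigma^2 = \frac{(R^2 - 1)\sum_i (Q_i - \bar Q)^2}{R^2 (2 - n)},}
#' where \eqn{\bar Q} is the mean of the signal. Positive for R^2 in (0,1);
#' tends to 0 as R^2 tends to 1.
#'
#' @param signal numeric vector of noiseless trait values (length n > 2).
#' @param r2 target coefficient of determination in (0, 1).
#' @return scalar residual variance.
#' @export
sigma2_from_r2 <- function(signal, r2) {
  n <- length(signal)
  if (n <= 2) stop_invalid("need n > 2")
  if (r2 <= 0 || r2 >= 1) stop_invalid("r2 must be in (0, 1)")
  ss <- sum((signal - mean(signal))^2)
  if (ss <= 0) stop_degenerate("constant signal: R^2 calibration undefined")
  (r2 - 1) * ss / (r2 * (2 - n))
}

#' Simulate a quantitative phenotype under a chosen effect layout
#'
#' Builds the noiseless signal \eqn{Q\phi} from standardized, unit-variance
#' effect components and adds Gaussian noise calibrated so the expected
#' coefficient of determination matches `r2`:
#' \itemize{
#'   \item Main effect of a causal gene: `coefficient` times the
#'     standardized sum of its two causal SNPs (by default the first two
#'     columns of the gene block).
#'   \item Interaction, `wang` model: `coefficient` times the standardized
#'     sum of all pairwise products of the causal SNPs of the two genes.
#'   \item Interaction, `pca` model: `coefficient` times the standardized
#'     elementwise product of the two genes' first principal-component
#'     scores.
#' }
#' The intercept is 0. For the null layout (`NE`) the trait is pure
#' standard-normal noise and `r2` is ignored.
#'
#' @param geno a [ggee_geno] object.
#' @param setting a [sim_setting] object.
#' @param r2 target R^2 in (0, 1).
#' @param q_pc number of principal components for the `pca` interaction
#'   model (the default 1 matches the standard construction).
#' @param seed optional seed for the residual draw.
#' @param n_causal_snps causal SNPs per causal gene (default 2, taken from
#'   the start of the gene block).
#' @return list with `y` (numeric length-n trait) and `truth`, an object of
#'   class `ggee_truth` holding causal genes/pairs, causal SNP indices,
#'   coefficients, the standardized component matrices, `sigma2` and
#'   `r2_target`.
#' @export
simulate_phenotype <- function(geno, setting, r2 = 0.5, q_pc = 1,
                               seed = NULL, n_causal_snps = 2) {
  stopifnot(inherits(geno, "ggee_geno"), inherits(setting, "ggee_setting"))
  G <- nrow(geno$gene_map)
  n <- nrow(geno$values)
  mains <- setting$main_genes
  pairs <- setting$interaction_pairs
  used <- unique(c(mains, unlist(pairs)))
  if (length(used) && max(used) > G)
    stop_invalid("setting references genes beyond the gene map")
  has_effects <- length(mains) > 0 || length(pairs) > 0
  if (has_effects && (r2 <= 0 || r2 >= 1))
    stop_invalid("r2 must be in (0, 1)")

  causal_snps <- list()
  for (g in used) {
    cols <- gene_cols(geno, g)
    k <- min(n_causal_snps, length(cols))
    if (setting$phenotype_model == "wang" && k < 2)
      stop_invalid(sprintf("gene %d has < 2 SNPs; wang model needs 2 causal SNPs", g))
    causal_snps[[as.character(g)]] <- cols[seq_len(k)]
  }

  main_comp <- matrix(numeric(0), n, 0)
  if (length(mains)) {
    main_comp <- sapply(mains, function(g)
      standardized_sum(geno$values[, causal_snps[[as.character(g)]], drop = FALSE]))
    main_comp <- matrix(main_comp, n, length(mains))
    colnames(main_comp) <- gene_ids(geno)[mains]
  }

  int_comp <- matrix(numeric(0), n, 0)
  if (length(pairs)) {
    int_comp <- sapply(pairs, function(pr) {
      r <- pr[1]; s <- pr[2]
      if (setting$phenotype_model == "wang") {
        xr <- geno$values[, causal_snps[[as.character(r)]], drop = FALSE]
        xs <- geno$values[, causal_snps[[as.character(s)]], drop = FALSE]
        standardized_sum(pairwise_products(xr, xs)$w)
      } else {
        cr <- pca_gene_components(geno$values[, gene_cols(geno, r), drop = FALSE], q_pc)
        cs <- pca_gene_components(geno$values[, gene_cols(geno, s), drop = FALSE], q_pc)
        standardized_sum(pairwise_products(cr, cs)$w)
      }
    })
    int_comp <- matrix(int_comp, n, length(pairs))
    colnames(int_comp) <- vapply(pairs, function(pr)
      paste(gene_ids(geno)[pr], collapse = ":"), "")
  }

  beta <- rep(setting$coefficient, length(mains))
  gamma <- rep(setting$coefficient, length(pairs))
  signal <- as.numeric(main_comp %*% beta) + as.numeric(int_comp %*% gamma)

  if (has_effects) {
    sigma2 <- sigma2_from_r2(signal, r2)
  } else {
    sigma2 <- 1
  }
  y <- with_seed(seed, signal + rnorm(n, 0, sqrt(sigma2)))

  truth <- structure(list(
    causal_main = gene_ids(geno)[mains],
    causal_pairs = lapply(pairs, function(pr) gene_ids(geno)[pr]),
    causal_snps = causal_snps,
    beta = beta, gamma = gamma,
    main_components = main_comp,
    interaction_components = int_comp,
    sigma2 = sigma2, r2_target = if (has_effects) r2 else NA_real_),
    class = "ggee_truth")
  list(y = y, truth = truth)
}

# R^2 of an intercept-included least-squares fit of y on X.
ols_r2 <- function(y, x) {
  if (is.null(x) || ncol(as.matrix(x)) == 0) return(0)
  f <- lm.fit(cbind(1, as.matrix(x)), y)
  tss <- sum((y - mean(y))^2)
  1 - sum(f$residuals^2) / tss
}

#' Share of R^2 attributable to interaction and main effects
#'
#' Fits three intercept-included OLS models of the trait on the true
#' simulated components — interaction components only, main components
#' only, and both — and returns
#' \eqn{p_I = 100 R^2_I / R^2_T} and \eqn{p_M = 100 R^2_M / R^2_T}.
#' The two shares need not sum to 100 when components are collinear.
#'
#' @param y numeric trait vector.
#' @param truth a `ggee_truth` object from [simulate_phenotype].
#' @return named numeric vector `c(p_I = , p_M = )`, in percent.
#' @export
variance_decomposition <- function(y, truth) {
  stopifnot(inherits(truth, "ggee_truth"))
  M <- truth$main_components
  I <- truth$interaction_components
  if ((ncol(M) && nrow(M) != length(y)) || (ncol(I) && nrow(I) != length(y)))
    stop_invalid("components not conformable with y")
  r2_t <- ols_r2(y, cbind(M, I))
  if (r2_t <= 0) stop_degenerate("total R^2 is zero; decomposition undefined")
  c(p_I = 100 * ols_r2(y, I) / r2_t,
    p_M = 100 * ols_r2(y, M) / r2_t)
}
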