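# Genotype container and block-LD Hardy-Weinberg genotype simulator.

#' Construct a genotype object
#'
#' Holds an additive-coded genotype matrix (entries in \{1, 2, 3\}: 1 = major
#' homozygote, 2 = heterozygote, 3 = minor homozygote) together with the SNP
#' identifiers and the gene grouping of the columns. Gene column ranges must
#' be contiguous, disjoint, and cover every column.
#'
#' @param values numeric matrix, n individuals x p SNPs, entries in \{1,2,3\}.
#' @param gene_map data.frame with columns `gene_id`, `start`, `end`
#'   (1-based inclusive column ranges, in column order).
#' @param snp_ids character vector of p SNP labels (defaults to colnames).
#' @param mafs optional numeric vector of p minor-allele frequencies.
#' @return An object of class `ggee_geno` with fields `values`, `snp_ids`,
#'   `gene_map`, `mafs`.
#' @export
ggee_geno <- function(values, gene_map, snp_ids = NULL, mafs = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(1, 2, 3)))
    stop_invalid("genotype entries must all be in {1, 2, 3}")
  p <- ncol(values)
  snp_ids <- snp_ids %||% colnames(values) %||% sprintf("snp%03d", seq_len(p))
  if (length(snp_ids) != p) stop_invalid("snp_ids length must equal ncol(values)")
  gene_map <- as.data.frame(gene_map)
  if (!all(c("gene_id", "start", "end") %in% names(gene_map)))
    stop_invalid("gene_map needs columns gene_id, start, end")
  gene_map <- gene_map[order(gene_map$start), , drop = FALSE]
  covered <- unlist(Map(seq, gene_map$start, gene_map$end))
  if (anyDuplicated(covered) || !identical(sort(covered), seq_len(p)))
    stop_invalid("gene column ranges must be disjoint and cover all columns")
  if (!is.null(mafs)) {
    if (length(mafs) != p || any(mafs <= 0 | mafs > 0.5))
      stop_invalid("mafs must have length p with values in (0, 0.5]")
  }
  colnames(values) <- snp_ids
  structure(list(values = values, snp_ids = snp_ids,
                 gene_map = gene_map, mafs = mafs),
            class = "ggee_geno")
}

#' @export
print.ggee_geno <- function(x, ...) {
  cat(sprintf("Genotypes: %d individuals x %d SNPs in %d genes\n",
              nrow(x$values), ncol(x$values), nrow(x$gene_map)))
  sizes <- x$gene_map$end - x$gene_map$start + 1L
  cat("  gene sizes:", paste(utils::head(sizes, 10), collapse = ", "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.ggee_geno <- function(x) dim(x$values)

# Column indices of one gene (by id or position in the map).
gene_cols <- function(geno, gene) {
  gm <- geno$gene_map
  i <- if (is.character(gene)) match(gene, gm$gene_id) else as.integer(gene)
  if (is.na(i) || i < 1 || i > nrow(gm)) stop_invalid(paste("unknown gene:", gene))
  seq.int(gm$start[i], gm$end[i])
}

gene_ids <- function(geno) as.character(geno$gene_map$gene_id)

# All unordered gene pairs (indices into the gene map), r < s, lexicographic.
gene_pair_index <- function(G) {
  if (G < 2) stop_invalid("need at least two genes")
  idx <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  cbind(r = idx[, "row"], s = idx[, "col"])
}

#' Simulate genotypes with block linkage disequilibrium under Hardy-Weinberg
#'
#' Rows are drawn i.i.d. from a p-variate normal whose correlation matrix is
#' block diagonal: within a gene every pair of latent variables is correlated
#' at `rho`, across genes correlations are zero. Each latent column is then
#' discretized at standard-normal quantiles so that the genotype classes
#' follow the Hardy-Weinberg proportions for that column's minor allele
#' frequency p: the minor homozygote (coded 3) has probability p^2, the
#' heterozygote (coded 2) probability 2p(1-p), and the major homozygote
#' (coded 1) probability (1-p)^2. Non-causal MAFs are drawn uniformly on
#' [0.05, 0.5]; columns listed in `causal_snps` are forced to `maf_causal`.
#'
#' @param n number of individuals (>= 2).
#' @param gene_sizes integer vector of SNP counts per gene (each >= 1).
#' @param rho within-gene latent correlation in [0, 1).
#' @param maf_causal MAF assigned to causal SNPs, in (0, 0.5].
#' @param causal_snps integer vector of (global) column indices of causal
#'   SNPs; may be empty.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return A [ggee_geno] object; gene ids are `gene1`, `gene2`, ...
#' @export
simulate_genotypes <- function(n, gene_sizes, rho = 0.8, maf_causal = 0.2,
                               causal_snps = integer(0), seed = NULL) {
  if (n < 2) stop_invalid("n must be >= 2")
  if (length(gene_sizes) == 0 || any(gene_sizes < 1))
    stop_invalid("gene_sizes must be nonempty with every size >= 1")
  if (rho < 0 || rho >= 1) stop_invalid("rho must be in [0, 1)")
  if (maf_causal <= 0 || maf_causal > 0.5)
    stop_invalid("maf_causal must be in (0, 0.5]")
  p <- sum(gene_sizes)
  if (length(causal_snps) && (any(causal_snps < 1) || any(causal_snps > p)))
    stop_invalid("causal_snps out of range")
  with_seed(seed, {
    mafs <- runif(p, 0.05, 0.5)
    mafs[causal_snps] <- maf_causal
    values <- matrix(NA_real_, n, p)
    col <- 1L
    for (m in gene_sizes) {
      shared <- rnorm(n)
      for (j in seq_len(m)) {
        latent <- sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
        pm <- mafs[col]
        q_minor <- qnorm(pm^2)
        q_het <- qnorm(pm^2 + 2 * pm * (1 - pm))
        values[, col] <- ifelse(latent < q_minor, 3,
                                ifelse(latent < q_het, 2, 1))
        col <- col + 1L
      }
    }
    ends <- cumsum(gene_sizes)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    gm <- data.frame(gene_id = paste0("gene", seq_along(gene_sizes)),
                     start = starts, end = ends)
    ids <- unlist(lapply(seq_along(gene_sizes), function(g)
      paste0("gene", g, "_snp", seq_len(gene_sizes[g]))))
    ggee_geno(values, gm, snp_ids = ids, mafs = mafs)
  })
}

#' Simulate genotypes with variable, realistic gene sizes (surrogate mode)
#'
#' A surrogate for power studies on real genotype panels, where gene sizes
#' are highly skewed (many one- or two-SNP genes, a few very large ones).
#' Sizes are drawn from a truncated geometric-like distribution calibrated
#' to a target median, then genotypes are generated by the same latent-block
#' model as [simulate_genotypes]. This is a synthetic stand-in, not a
#' reproduction of any real panel.
#'
#' @param n individuals.
#' @param n_genes number of genes.
#' @param size_median target median gene size.
#' @param size_max maximum gene size.
#' @inheritParams simulate_genotypes
#' @return A [ggee_geno] object.
#' @export
simulate_genotypes_surrogate <- function(n, n_genes = 6, size_median = 2,
                                         size_max = 1119, rho = 0.8,
                                         maf_causal = 0.2,
                                         causal_snps = integer(0),
                                         seed = NULL) {
  with_seed(seed, {
    # geometric with success prob giving the requested median, truncated
    pr <- 1 - 0.5^(1 / size_median)
    sizes <- pmin(stats::rgeom(n_genes, pr) + 1L, size_max)
    simulate_genotypes(n, sizes, rho = rho, maf_causal = maf_causal,
                       causal_snps = causal_snps, seed = NULL)
  })
}
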