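# Simulation study driver: replicate loop, power estimation, and the
# R^2-decomposition summaries.

#' Estimate power as a detection proportion
#'
#' @param flags logical vector, one entry per replicate: was the target
#'   (causal) interaction declared significant?
#' @return proportion of detections.
#' @export
estimate_power <- function(flags) {
  if (length(flags) == 0) stop_invalid("need at least one replicate")
  mean(as.logical(flags))
}

#' Average the per-replicate R^2 decomposition
#'
#' @param per_replicate matrix or data.frame with columns p_I, p_M (in
#'   percent), one row per replicate.
#' @return named vector `c(mean_p_I = , mean_p_M = )`.
#' @export
summarize_decomposition <- function(per_replicate) {
  m <- as.matrix(per_replicate)
  if (nrow(m) < 1) stop_invalid("need at least one replicate")
  c(mean_p_I = mean(m[, 1]), mean_p_M = mean(m[, 2]))
}

#' Run one simulation setting end to end
#'
#' For each replicate: simulate genotypes (block-LD, Hardy-Weinberg, causal
#' MAF override), simulate the phenotype under the setting's effect layout
#' at the requested R^2, build the interaction design by the requested
#' method, run the screen-and-clean pipeline, and record which variables
#' (gene main effects and gene-pair interactions) were declared significant
#' together with the replicate's (p_I, p_M). Per-replicate seeds are derived
#' deterministically from the master seed, so any replicate can be
#' regenerated in isolation and the whole result is reproducible.
#'
#' @param setting a [sim_setting].
#' @param method interaction construction (`"ggee"`, `"pca"`, `"pls"`).
#' @param r2 target coefficient of determination.
#' @param n individuals per replicate.
#' @param reps number of replicates.
#' @param master_seed master seed.
#' @param n_genes,gene_size,rho,maf_causal genotype-simulator settings
#'   (defaults: six genes of six SNPs, within-gene correlation 0.8, causal
#'   MAF 0.2).
#' @param alpha,B,cv_folds,q,strict pipeline settings (see
#'   [epistasis_scan]); B defaults to 199 for study-scale runs.
#' @param decomposition_only skip the detection pipeline and record only
#'   (p_I, p_M) — much faster when only the R^2 decomposition is needed.
#' @return An object of class `ggee_study`: `discovery` (named proportion
#'   vector over all G main + G(G-1)/2 interaction variables), `power`
#'   (named, one entry per causal pair), `replicate_discovery` (reps x
#'   variables logical matrix), `mean_p_I`, `mean_p_M`, `decomposition`
#'   (reps x 2 matrix), `n_failed`, `seeds`, and the configuration.
#' @export
run_setting <- function(setting, method = "ggee", r2 = 0.5, n = 600,
                        reps = 10, master_seed = 1, n_genes = 6,
                        gene_size = 6, rho = 0.8, maf_causal = 0.2,
                        alpha = 0.05, B = 199, cv_folds = 5, q = 1,
                        strict = TRUE, perm = "group",
                        decomposition_only = FALSE) {
  stopifnot(inherits(setting, "ggee_setting"))
  if (reps < 1) stop_invalid("reps must be >= 1")
  gene_sizes <- rep(gene_size, n_genes)
  causal_genes <- sort(unique(c(setting$main_genes,
                                unlist(setting$interaction_pairs))))
  ends <- cumsum(gene_sizes); starts <- c(1L, utils::head(ends, -1) + 1L)
  causal_snps <- unlist(lapply(causal_genes, function(g)
    starts[g] + seq_len(min(2, gene_sizes[g])) - 1L))

  seeds <- matrix(derive_seeds(master_seed, 3 * reps), reps, 3)
  glabels <- paste0("gene", seq_len(n_genes))
  pairs <- gene_pair_index(n_genes)
  plabels <- paste0(glabels[pairs[, "r"]], ":", glabels[pairs[, "s"]])
  var_labels <- c(glabels, plabels)

  disc <- matrix(NA, reps, length(var_labels),
                 dimnames = list(NULL, var_labels))
  n_nonconv <- 0L
  dec <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("p_I", "p_M")))
  failed <- 0L
  for (rep_i in seq_len(reps)) {
    ok <- tryCatch({
      geno <- simulate_genotypes(n, gene_sizes, rho = rho,
                                 maf_causal = maf_causal,
                                 causal_snps = causal_snps,
                                 seed = seeds[rep_i, 1])
      sim <- simulate_phenotype(geno, setting, r2 = r2,
                                seed = seeds[rep_i, 2])
      if (length(setting$main_genes) || length(setting$interaction_pairs))
        dec[rep_i, ] <- variance_decomposition(sim$y, sim$truth)
      if (!decomposition_only) {
        # collect (rather than print) per-replicate non-convergence flags
        rep_out <- withCallingHandlers(
          epistasis_scan(geno, sim$y, method = method, q = q,
                         alpha = alpha, B = B, cv_folds = cv_folds,
                         perm = perm, seed = seeds[rep_i, 3],
                         strict = strict),
          warning = function(w) {
            if (grepl("did not converge", conditionMessage(w))) {
              n_nonconv <<- n_nonconv + 1L
              invokeRestart("muffleWarning")
            }
          })
        tab <- rep_out$table
        disc[rep_i, ] <- tab$significant[match(var_labels, tab$group)]
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- failed + 1L
  }

  disc_prop <- colMeans(disc, na.rm = TRUE)
  if (decomposition_only) disc_prop[] <- NA_real_
  causal_pair_labels <- vapply(setting$interaction_pairs, function(pr)
    paste0(glabels[pr[1]], ":", glabels[pr[2]]), "")
  power <- if (length(causal_pair_labels) && !decomposition_only)
    setNames(disc_prop[causal_pair_labels], causal_pair_labels)
  else setNames(numeric(0), character(0))
  dec_ok <- dec[stats::complete.cases(dec), , drop = FALSE]
  structure(list(
    setting = setting$id, method = method, r2 = r2, n = n, reps = reps,
    power = power, discovery = disc_prop, replicate_discovery = disc,
    decomposition = dec,
    mean_p_I = if (nrow(dec_ok)) mean(dec_ok[, "p_I"]) else NA_real_,
    mean_p_M = if (nrow(dec_ok)) mean(dec_ok[, "p_M"]) else NA_real_,
    n_failed = failed, n_nonconverged = n_nonconv,
    seeds = seeds, alpha = alpha, B = B, q = q,
    strict = strict, master_seed = master_seed),
    class = "ggee_study")
}

#' @export
print.ggee_study <- function(x, ...) {
  cat(sprintf("Study: setting %s, method %s, R2 = %.2f, %d reps (%d failed)\n",
              x$setting, x$method, x$r2, x$reps, x$n_failed))
  if (length(x$power))
    cat("  power:", paste(sprintf("%s = %.3f", names(x$power), x$power),
                          collapse = ", "), "\n")
  if (is.finite(x$mean_p_I))
    cat(sprintf("  mean p_I = %.2f, mean p_M = %.2f\n",
                x$mean_p_I, x$mean_p_M))
  invisible(x)
}
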