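# Readers and writers for the plain-text interchange formats: genotype
# TSV / PLINK raw tables, SNP-to-gene maps, phenotype vectors, reports and
# run manifests.

#' Read a genotype matrix from TSV or PLINK raw text
#'
#' `format = "tsv"`: tab-separated, header row of SNP ids, one row per
#' individual. `format = "plink_raw"`: the output of `plink --recode A`
#' (six leading columns FID IID PAT MAT SEX PHENOTYPE, then one dosage
#' column per SNP named like `rs123_A`; the allele suffix is stripped).
#' Entries may use either the \{0,1,2\} dosage convention or the \{1,2,3\}
#' additive coding; \{0,1,2\} input is shifted up by one, and the applied
#' mapping is recorded in the `"coding"` attribute. Missing genotypes are
#' imputed to the column mode with a message, or rejected when
#' `strict_missing = TRUE`.
#'
#' @param path file path.
#' @param gene_map a data.frame as returned by [read_gene_map], used to
#'   group and order the columns; SNPs absent from the map are dropped
#'   (with a message), map entries absent from the file are ignored with a
#'   warning.
#' @param format `"tsv"` or `"plink_raw"`.
#' @param strict_missing error on missing genotypes instead of imputing.
#' @return a [ggee_geno] object.
#' @export
read_genotypes <- function(path, gene_map, format = c("tsv", "plink_raw"),
                           strict_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_invalid(paste("no such file:", path))
  raw <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("NA", "-9", ""))
  if (format == "plink_raw") {
    lead <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(raw))
    raw <- raw[, setdiff(names(raw), lead), drop = FALSE]
    names(raw) <- sub("_[ACGT]$", "", names(raw))
  }
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(raw, 2, as.numeric))) &
                   !is.na(as.matrix(raw)), arr.ind = TRUE)
    if (nrow(bad))
      stop_invalid(sprintf("unparseable genotype at line %d, column %s",
                           bad[1, 1] + 1L, names(raw)[bad[1, 2]]),
                   class = "ggee_parse_error")
    m <- apply(raw, 2, as.numeric)
  }
  # impute or reject missing values
  if (anyNA(m)) {
    if (strict_missing) stop_invalid("missing genotypes present (strict mode)")
    n_imp <- sum(is.na(m))
    for (j in which(colSums(is.na(m)) > 0)) {
      obs <- m[!is.na(m[, j]), j]
      if (!length(obs)) stop_invalid(sprintf("column %s entirely missing",
                                             colnames(m)[j]))
      mode_val <- as.numeric(names(which.max(table(obs))))
      m[is.na(m[, j]), j] <- mode_val
    }
    message(sprintf("imputed %d missing genotype(s) to column mode", n_imp))
  }
  vals <- sort(unique(as.numeric(m)))
  coding <- if (all(vals %in% 0:2)) "0/1/2 (+1 applied)" else "1/2/3"
  if (all(vals %in% 0:2)) m <- m + 1
  if (!all(m %in% c(1, 2, 3)))
    stop_invalid("genotype values outside {0,1,2}/{1,2,3}",
                 class = "ggee_parse_error")

  # order columns contiguously per gene, genes by first appearance
  gene_map <- gene_map[gene_map$snp_id %in% colnames(m), , drop = FALSE]
  if (!nrow(gene_map)) stop_invalid("no mapped SNPs present in genotype file")
  unmapped <- setdiff(colnames(m), gene_map$snp_id)
  if (length(unmapped))
    message(sprintf("dropping %d unmapped SNP(s)", length(unmapped)))
  genes <- unique(gene_map$gene_id)
  ord <- unlist(lapply(genes, function(g)
    gene_map$snp_id[gene_map$gene_id == g]))
  m <- m[, ord, drop = FALSE]
  sizes <- vapply(genes, function(g) sum(gene_map$gene_id == g), 0L)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  gm <- data.frame(gene_id = genes, start = starts, end = ends)
  out <- ggee_geno(m, gm, snp_ids = colnames(m))
  attr(out, "coding") <- coding
  out
}

#' Read a SNP-to-gene map
#'
#' Two-column TSV (`snp_id`, `gene_id`; a header is detected and honored,
#' otherwise the first two columns are used). Genes keep their order of
#' first appearance. A SNP listed under more than one gene is dropped with
#' a warning (gene groups must not overlap).
#'
#' @param path file path.
#' @return data.frame with columns `snp_id`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("no such file:", path))
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(first)) stop_invalid("empty gene map file")
  has_header <- grepl("snp", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  df <- read.table(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_invalid("gene map needs two columns")
  df <- df[, 1:2]
  names(df) <- c("snp_id", "gene_id")
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  multi <- dup[vapply(dup, function(s)
    length(unique(df$gene_id[df$snp_id == s])) > 1, TRUE)]
  if (length(multi)) {
    warning(sprintf("dropping %d SNP(s) mapped to multiple genes: %s",
                    length(multi), paste(utils::head(multi, 5), collapse = ", ")))
    df <- df[!df$snp_id %in% multi, , drop = FALSE]
  }
  df[!duplicated(df$snp_id), , drop = FALSE]
}

#' Read a phenotype vector
#'
#' One value per line, no header, order matching the genotype rows.
#' @param path file path.
#' @param family `"gaussian"` or `"binomial"` (binary must be 0/1).
#' @return numeric vector.
#' @export
read_phenotype <- function(path, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop_invalid(paste("no such file:", path))
  y <- scan(path, what = numeric(), quiet = TRUE)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop_invalid("binary phenotypes must be coded 0/1")
  y
}

#' Write genotypes, gene map and phenotype as text files
#'
#' Genotypes go to `<prefix>_genotypes.tsv` (header = SNP ids, one row per
#' individual), the map to `<prefix>_genes.tsv`, the phenotype to
#' `<prefix>_pheno.txt`, and the simulation truth (if given) to
#' `<prefix>_truth.json`.
#'
#' @param geno a [ggee_geno].
#' @param prefix output path prefix.
#' @param y optional phenotype vector.
#' @param truth optional `ggee_truth`.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(geno, prefix, y = NULL, truth = NULL) {
  paths <- character(0)
  gpath <- paste0(prefix, "_genotypes.tsv")
  write.table(geno$values, gpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, gpath)
  gm <- geno$gene_map
  map <- data.frame(
    snp_id = geno$snp_ids,
    gene_id = rep(as.character(gm$gene_id), gm$end - gm$start + 1L))
  mpath <- paste0(prefix, "_genes.tsv")
  write.table(map, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, mpath)
  if (!is.null(y)) {
    ppath <- paste0(prefix, "_pheno.txt")
    writeLines(format(y, digits = 10), ppath)
    paths <- c(paths, ppath)
  }
  if (!is.null(truth)) {
    tpath <- paste0(prefix, "_truth.json")
    tr <- truth
    tr$main_components <- NULL
    tr$interaction_components <- NULL
    jsonlite::write_json(unclass(tr), tpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}

#' Write a clean report or study result with its manifest
#'
#' Clean reports become a TSV with deterministic column order (group, type,
#' screened, statistic, p, p_adjusted, significant); study results become
#' JSON. A JSON run manifest with all settings is written alongside as
#' `<path>.manifest.json`.
#'
#' @param report a `ggee_clean_report` or `ggee_study`.
#' @param path output file path.
#' @param manifest named list of run settings to record.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, manifest = list()) {
  if (inherits(report, "ggee_clean_report")) {
    tab <- report$table
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(v) round(v, 6))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, list(lambda = report$lambda,
                                 ridge_lambda = report$ridge_lambda,
                                 B = report$B, alpha = report$alpha))
  } else if (inherits(report, "ggee_study")) {
    out <- unclass(report)
    out$seeds <- NULL
    out$replicate_discovery <- NULL
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else stop_invalid("unsupported report object")
  manifest$package_version <- as.character(utils::packageVersion("ggee"))
  manifest$written <- path
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}

#' Read back a study result written by [write_report]
#' @param path JSON path.
#' @return list mirroring the `ggee_study` fields.
#' @export
read_study_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
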