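#' Gene-by-sample count container for a triad experiment
#'
#' Bundles an integer count matrix (genes in rows, samples in columns) with
#' the sample design sheet mapping each sample to its genotype role in the
#' triad (`parent1`, `parent2`, `hybrid`) and a replicate index.
#'
#' @param counts Numeric matrix of non-negative integer counts with gene ids
#'   as rownames and sample ids as colnames.
#' @param design Data frame with columns `sample_id`, `genotype` (one of
#'   `"parent1"`, `"parent2"`, `"hybrid"`) and `replicate`. Rows must cover
#'   exactly the columns of `counts`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` and `design` (design reordered to match the columns).
#' @examples
#' cfg <- triad_sim_config(n_genes = 50, seed = 1)
#' sim <- simulate_triad(cfg)
#' em <- sim$em
#' dim(em$counts)
#' @export
expression_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  design <- as.data.frame(design)
  req <- c("sample_id", "genotype", "replicate")
  if (!all(req %in% names(design)))
    stop("design needs columns: ", paste(req, collapse = ", "))
  if (!setequal(design$sample_id, colnames(counts)))
    stop("design sample ids do not match count matrix columns")
  roles <- c("parent1", "parent2", "hybrid")
  if (!all(design$genotype %in% roles))
    stop("genotype must be one of: ", paste(roles, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$design$genotype))
  invisible(x)
}

role_samples <- function(em, role) {
  em$design$sample_id[em$design$genotype == role]
}

#' Read a count matrix and design sheet from TSV files
#'
#' @param counts_path TSV with first column `gene_id` and one column per
#'   sample (header row of sample ids).
#' @param design_path TSV with columns `sample_id`, `genotype`, `replicate`.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(counts_path, design_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           comment.char = "#")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  design <- utils::read.delim(design_path, comment.char = "#")
  expression_matrix(counts, design)
}

#' Write an expression matrix to counts + design TSV files
#'
#' @param em An [expression_matrix()].
#' @param counts_path,design_path Output file paths.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @return Invisibly, the two paths.
#' @export
write_expression_tsv <- function(em, counts_path, design_path,
                                 header = NULL) {
  write_tsv_commented(
    data.frame(gene_id = rownames(em$counts), em$counts,
               check.names = FALSE),
    counts_path, header)
  write_tsv_commented(em$design, design_path, header)
  invisible(c(counts_path, design_path))
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
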