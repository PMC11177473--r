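#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per gene x genotype; the reference
#' gene's mean Ct is subtracted within each genotype (dCt), the
#' calibrator genotype's dCt is subtracted (ddCt), and relative
#' expression is `2^-ddCt` (amplification efficiency fixed at 2). The
#' calibrator genotype therefore returns exactly 1.
#'
#' @param ct_table Data frame with columns `gene`, `genotype`, `replicate`,
#'   `ct` and either an `is_reference` logical column or the
#'   `reference_gene` argument.
#' @param calibrator Genotype used as the calibrator (fold = 1).
#' @param reference_gene Name of the reference (housekeeping) gene;
#'   inferred from `is_reference` when absent.
#' @return Data frame `gene`, `genotype`, `delta_ct`, `delta_delta_ct`,
#'   `fold` for every target gene x genotype.
#' @examples
#' ct <- data.frame(gene = rep(c("ref", "g1"), each = 2),
#'                  genotype = rep(c("hybrid", "parent"), 2),
#'                  replicate = 1, ct = c(18, 18, 22, 24))
#' ddct(ct, calibrator = "parent", reference_gene = "ref")
#' @export
ddct <- function(ct_table, calibrator, reference_gene = NULL) {
  tab <- as.data.frame(ct_table)
  req <- c("gene", "genotype", "ct")
  if (!all(req %in% names(tab)))
    stop("ct_table needs columns: ", paste(req, collapse = ", "))
  if (is.null(reference_gene)) {
    if (!"is_reference" %in% names(tab))
      stop("provide reference_gene or an is_reference column")
    refs <- unique(tab$gene[as.logical(tab$is_reference)])
    if (length(refs) != 1)
      stop("exactly one reference gene required, found: ", length(refs))
    reference_gene <- refs
  }
  if (!calibrator %in% tab$genotype)
    stop("calibrator genotype not present: ", calibrator)
  mean_ct <- stats::aggregate(ct ~ gene + genotype, tab, mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, ]
  targets <- mean_ct[mean_ct$gene != reference_gene, ]
  out <- list()
  for (g in unique(targets$gene)) {
    tg <- targets[targets$gene == g, ]
    miss <- setdiff(tg$genotype, ref$genotype)
    if (length(miss))
      stop("reference gene ", reference_gene,
           " not measured in sample(s): ", paste(miss, collapse = ", "))
    if (!calibrator %in% tg$genotype)
      stop("calibrator genotype missing for gene ", g)
    dct <- tg$ct - ref$ct[match(tg$genotype, ref$genotype)]
    ddct_v <- dct - dct[tg$genotype == calibrator]
    out[[g]] <- data.frame(gene = g, genotype = tg$genotype,
                           delta_ct = dct, delta_delta_ct = ddct_v,
                           fold = 2^(-ddct_v))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' @param qpcr_folds,rnaseq_folds Named numeric vectors (gene -> fold
#'   change relative to the same calibrator); at least 3 shared genes.
#' @return List `agreement` (fraction of shared genes whose up/down
#'   direction matches), `spearman` (rank correlation of the log2 folds)
#'   and `n` (shared genes).
#' @export
concordance <- function(qpcr_folds, rnaseq_folds) {
  shared <- intersect(names(qpcr_folds), names(rnaseq_folds))
  if (length(shared) < 3)
    stop("need >= 3 shared genes, found ", length(shared))
  lq <- log2(qpcr_folds[shared])
  lr <- log2(rnaseq_folds[shared])
  list(agreement = mean(sign(lq) == sign(lr)),
       spearman = stats::cor(lq, lr, method = "spearman"),
       n = length(shared))
}
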