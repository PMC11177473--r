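#' Classify triad significance calls into the 12 expression patterns
#'
#' Vectorized decision table over the three contrast calls of each gene.
#' With `sig_*` the DEG flags and `dir_*` the fold-change signs of the
#' hybrid-vs-parent1, hybrid-vs-parent2 and parent1-vs-parent2 contrasts
#' (positive = first-named genotype higher, i.e. hybrid resp. parent1):
#'
#' * up-regulated overdominant (P10-P12): hybrid significantly above both
#'   parents; sub-code by the parental contrast (parent1 lower: P10,
#'   parents indistinguishable: P11, parent1 higher: P12);
#' * down-regulated overdominant (P7-P9): hybrid significantly below both
#'   parents (parent1 lower: P7, indistinguishable: P8, higher: P9);
#' * dominant (P3-P6): parents significantly different and the hybrid
#'   indistinguishable from exactly one of them; sub-code by which parent
#'   is matched and whether it is the high or low parent (high parent1: P3,
#'   high parent2: P4, low parent1: P5, low parent2: P6);
#' * additive (P1-P2): parents significantly different, hybrid
#'   significantly different from both and its mean strictly between the
#'   parental means (parent1 higher: P1, parent2 higher: P2);
#' * anything else: `UNCLASSIFIED`.
#'
#' @param sig_fp1,sig_fp2,sig_pp Logical DEG flags for the three contrasts.
#' @param dir_fp1,dir_fp2,dir_pp Fold-change signs (any numeric; only the
#'   sign is used, and only where the corresponding flag is `TRUE`).
#' @param mean_p1,mean_f1,mean_p2 Genotype mean expression levels (used for
#'   the additive betweenness check).
#' @return Character vector of pattern codes.
#' @export
classify_calls <- function(sig_fp1, dir_fp1, sig_fp2, dir_fp2,
                           sig_pp, dir_pp, mean_p1, mean_f1, mean_p2) {
  n <- length(sig_fp1)
  code <- rep("UNCLASSIFIED", n)
  up1 <- sig_fp1 & dir_fp1 > 0; dn1 <- sig_fp1 & dir_fp1 < 0
  up2 <- sig_fp2 & dir_fp2 > 0; dn2 <- sig_fp2 & dir_fp2 < 0
  p1hi <- sig_pp & dir_pp > 0; p1lo <- sig_pp & dir_pp < 0

  od_up <- up1 & up2
  code[od_up & p1lo] <- "P10"
  code[od_up & !sig_pp] <- "P11"
  code[od_up & p1hi] <- "P12"

  od_dn <- dn1 & dn2
  code[od_dn & p1lo] <- "P7"
  code[od_dn & !sig_pp] <- "P8"
  code[od_dn & p1hi] <- "P9"

  dom <- sig_pp & xor(sig_fp1, sig_fp2)
  code[dom & !sig_fp1 & p1hi] <- "P3"  # hybrid matches the high parent1
  code[dom & !sig_fp2 & p1lo] <- "P4"  # hybrid matches the high parent2
  code[dom & !sig_fp1 & p1lo] <- "P5"  # hybrid matches the low parent1
  code[dom & !sig_fp2 & p1hi] <- "P6"  # hybrid matches the low parent2

  between <- (mean_f1 > pmin(mean_p1, mean_p2)) &
             (mean_f1 < pmax(mean_p1, mean_p2))
  # overdominance takes precedence when the calls contradict the means
  addv <- sig_pp & sig_fp1 & sig_fp2 & between & !od_up & !od_dn
  code[addv & p1hi] <- "P1"
  code[addv & p1lo] <- "P2"
  code
}

#' Classify the genes of a triad differential-expression result
#'
#' Applies [classify_calls()] to every tested gene, taking significance and
#' direction from the three contrast tables and genotype means from the
#' size-factor-normalized base means. Genes with no significant contrast
#' (non-DEGs) are `UNCLASSIFIED`.
#'
#' @param de A [triad_de()] result.
#' @param deg_union_only Keep only genes in the union of the three DEG sets
#'   (default `TRUE`; when `FALSE` every tested gene is returned, non-DEGs
#'   as `UNCLASSIFIED`).
#' @return Data frame `gene_id`, `pattern_code`, `category`.
#' @export
classify_patterns <- function(de, deg_union_only = TRUE) {
  stopifnot(inherits(de, "triad_de"))
  r <- de$results
  stopifnot(all(r$F1vsP1$gene_id == r$F1vsP2$gene_id),
            all(r$F1vsP1$gene_id == r$P1vsP2$gene_id))
  code <- classify_calls(
    sig_fp1 = r$F1vsP1$significant, dir_fp1 = r$F1vsP1$log2FC,
    sig_fp2 = r$F1vsP2$significant, dir_fp2 = r$F1vsP2$log2FC,
    sig_pp  = r$P1vsP2$significant, dir_pp  = r$P1vsP2$log2FC,
    mean_p1 = r$F1vsP1$baseMeanA, mean_f1 = r$F1vsP1$baseMeanB,
    mean_p2 = r$F1vsP2$baseMeanA)
  out <- data.frame(gene_id = r$F1vsP1$gene_id, pattern_code = code,
                    category = pattern_category(code))
  if (deg_union_only) {
    is_deg <- r$F1vsP1$significant | r$F1vsP2$significant |
      r$P1vsP2$significant
    out <- out[is_deg, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Counts and shares of the expression patterns
#'
#' Percentages are computed over classified genes (codes P1-P12), so the
#' category shares sum to 100; the `UNCLASSIFIED` count is reported
#' separately.
#'
#' @param codes Character vector of pattern codes, or the data frame
#'   returned by [classify_patterns()].
#' @return A `pattern_summary` list: `per_code` (data frame `pattern_code`,
#'   `n`, `pct`), `per_category`, `n_classified`, `n_unclassified`.
#' @export
summarize_patterns <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$pattern_code
  stopifnot(length(codes) > 0, all(codes %in% PATTERN_CODES))
  tab <- table(factor(codes, levels = PATTERN_CODES))
  n_un <- tab[["UNCLASSIFIED"]]
  n_cls <- length(codes) - n_un
  pc <- data.frame(pattern_code = paste0("P", 1:12),
                   n = as.integer(tab[paste0("P", 1:12)]))
  pc$pct <- if (n_cls > 0) 100 * pc$n / n_cls else NA_real_
  cat_of <- pattern_category(pc$pattern_code)
  agg <- tapply(pc$n, cat_of, sum)
  cats <- c("additive", "dominant", "overdominant_down", "overdominant_up")
  ct <- data.frame(category = cats, n = as.integer(agg[cats]))
  ct$pct <- if (n_cls > 0) 100 * ct$n / n_cls else NA_real_
  structure(list(per_code = pc, per_category = ct,
                 n_classified = n_cls, n_unclassified = n_un),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("%d classified DEGs (%d unclassified)\n",
              x$n_classified, x$n_unclassified))
  print(x$per_category, row.names = FALSE)
  invisible(x)
}
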