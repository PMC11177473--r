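#' Differential-expression screening configuration
#'
#' Defaults follow the screening rule used throughout: a gene is a DEG when
#' `p < p_threshold` (strict) and `|log2FC| >= lfc_threshold` (inclusive).
#'
#' @param p_threshold Significance threshold on the raw p-value (or on the
#'   BH-adjusted value when `use_adjusted = TRUE`), default 0.05.
#' @param lfc_threshold Minimum absolute log2 fold change, default 2.
#' @param use_adjusted Screen on the BH-adjusted p-value instead of the raw
#'   one (default `FALSE`, matching the raw-p screening rule).
#' @param pseudocount Added to both group means for the reported log2 fold
#'   change (default 1).
#' @return A `de_config` list.
#' @export
de_config <- function(p_threshold = 0.05, lfc_threshold = 2,
                      use_adjusted = FALSE, pseudocount = 1) {
  stopifnot(p_threshold > 0, lfc_threshold > 0, pseudocount >= 0)
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                 use_adjusted = use_adjusted, pseudocount = pseudocount),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference genes (genes with nonzero counts in
#' every sample) of the ratio of the gene's count to its geometric mean
#' across samples; factors are rescaled to geometric mean 1. When no gene is
#' nonzero in all samples, falls back to total-count (library-size) factors
#' with a warning.
#'
#' @param x An [expression_matrix()] or a count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "expression_matrix")) x$counts else as.matrix(x)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to library-size factors")
    f <- colSums(counts)
    if (any(f == 0)) stop("sample with all-zero counts")
  } else {
    lgm <- rowMeans(log(counts[ref, , drop = FALSE]))
    f <- apply(counts[ref, , drop = FALSE], 2,
               function(col) stats::median(exp(log(col) - lgm)))
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Method-of-moments negative-binomial dispersion per gene
#'
#' On size-factor-normalized counts, estimates phi in
#' `Var = mu + phi * mu^2` by pooling within-genotype moments:
#' `phi_hat = sum_g (s2_g - m_g) / sum_g m_g^2` over genotype groups, floored
#' at 1e-8 (genes with variance at or below the mean, or with zero means,
#' receive the floor).
#'
#' @param em An [expression_matrix()].
#' @param sf Optional precomputed size factors.
#' @return Named non-negative numeric vector, one phi per gene.
#' @export
estimate_dispersion <- function(em, sf = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(sf)) sf <- size_factors(em)
  y <- sweep(em$counts, 2, sf[colnames(em$counts)], "/")
  roles <- unique(em$design$genotype)
  num <- den <- 0
  for (r in roles) {
    cols <- role_samples(em, r)
    if (length(cols) < 2)
      stop("genotype ", r, " needs >= 2 replicates for dispersion estimation")
    yr <- y[, cols, drop = FALSE]
    m <- rowMeans(yr)
    s2 <- apply(yr, 1, stats::var)
    num <- num + (s2 - m)
    den <- den + m^2
  }
  phi <- ifelse(den > 0, num / den, 0)
  stats::setNames(pmax(phi, 1e-8), rownames(em$counts))
}

# Wald z statistic for equality of two NB group means on the log scale.
# Mean of normalized counts m_g estimates mu; Var(k_ij/sf_j) =
# mu/sf_j + phi*mu^2, so Var(m_g) = (1/n^2) sum_j (mu/sf_j + phi*mu^2),
# and by the delta method Var(log m_g) = Var(m_g)/m_g^2.
nb_wald <- function(mA, mB, sfA, sfB, phi) {
  a <- pmax(mA, 0.5 / length(sfA))  # half-count floor keeps logs finite
  b <- pmax(mB, 0.5 / length(sfB))
  relvar <- function(m, sf) {
    n <- length(sf)
    (sum(1 / sf) * m + phi * m^2 * n) / (n^2 * m^2)
  }
  (log(b) - log(a)) / sqrt(relvar(a, sfA) + relvar(b, sfB))
}

#' Negative-binomial Wald test of one triad contrast
#'
#' Tests equality of the two genotype means on size-factor-normalized
#' counts with a Wald statistic on the log scale, using the NB variance
#' `mu + phi * mu^2` with a plug-in per-gene dispersion. The reported
#' `log2FC` is `log2((meanB + pseudocount) / (meanA + pseudocount))`;
#' p-values are BH-adjusted within the contrast and the DEG flag applies
#' the [de_config()] screen. All-zero genes get `p = 1`, `log2FC = 0`.
#'
#' @param em An [expression_matrix()].
#' @param groupA,groupB Genotype roles to compare (`log2FC > 0` means
#'   higher expression in `groupB`).
#' @param config A [de_config()].
#' @param sf,dispersion Optional shared size factors / per-gene dispersions
#'   (computed from `em` when `NULL`).
#' @return Data frame `gene_id`, `baseMeanA`, `baseMeanB`, `log2FC`, `p`,
#'   `padj`, `significant`.
#' @export
test_contrast <- function(em, groupA, groupB, config = de_config(),
                          sf = NULL, dispersion = NULL) {
  stopifnot(inherits(em, "expression_matrix"), inherits(config, "de_config"))
  if (is.null(sf)) sf <- size_factors(em)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(em, sf)
  colsA <- role_samples(em, groupA)
  colsB <- role_samples(em, groupB)
  if (length(colsA) < 2 || length(colsB) < 2)
    stop("both groups need >= 2 replicates")
  y <- sweep(em$counts, 2, sf[colnames(em$counts)], "/")
  mA <- rowMeans(y[, colsA, drop = FALSE])
  mB <- rowMeans(y[, colsB, drop = FALSE])
  phi <- dispersion[rownames(em$counts)]
  z <- nb_wald(mA, mB, sf[colsA], sf[colsB], phi)
  # t reference: the plug-in moment estimates of mean and dispersion make a
  # normal reference anticonservative at small n. The dispersion pools the
  # within-group moments of every genotype, so the residual df is
  # samples minus genotype groups over the whole design.
  df <- nrow(em$design) - length(unique(em$design$genotype))
  p <- 2 * stats::pt(-abs(z), df = df)
  lfc <- log2((mB + config$pseudocount) / (mA + config$pseudocount))
  zero <- mA == 0 & mB == 0
  p[zero] <- 1
  lfc[zero] <- 0
  padj <- stats::p.adjust(p, method = "BH")
  screen_p <- if (config$use_adjusted) padj else p
  res <- data.frame(
    gene_id = rownames(em$counts), baseMeanA = mA, baseMeanB = mB,
    log2FC = lfc, p = p, padj = padj,
    significant = screen_p < config$p_threshold &
      abs(lfc) >= config$lfc_threshold)
  rownames(res) <- NULL
  res
}

#' Differential expression over the three triad contrasts
#'
#' Restricts to genes detected in all three genotypes (nonzero mean count in
#' each), then runs [test_contrast()] for `F1vsP1` (parent1 vs hybrid),
#' `F1vsP2` and `P1vsP2` (parent2 vs parent1) with shared size factors and
#' dispersions. Positive `log2FC` means higher in the hybrid
#' (resp. parent1 for `P1vsP2`).
#'
#' @param em An [expression_matrix()].
#' @param config A [de_config()].
#' @return A `triad_de` list: `results` (named list of the three contrast
#'   data frames), `genes_tested`, `sf`, `dispersion`, `config`.
#' @export
triad_de <- function(em, config = de_config()) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- rep(TRUE, nrow(em$counts))
  for (r in c("parent1", "parent2", "hybrid")) {
    cols <- role_samples(em, r)
    if (length(cols) < 2) stop("genotype ", r, " needs >= 2 replicates")
    keep <- keep & rowMeans(em$counts[, cols, drop = FALSE]) > 0
  }
  emf <- expression_matrix(em$counts[keep, , drop = FALSE], em$design)
  sf <- size_factors(emf)
  disp <- estimate_dispersion(emf, sf)
  contrasts <- list(F1vsP1 = c("parent1", "hybrid"),
                    F1vsP2 = c("parent2", "hybrid"),
                    P1vsP2 = c("parent2", "parent1"))
  results <- lapply(contrasts, function(gr)
    test_contrast(emf, gr[1], gr[2], config, sf, disp))
  structure(list(results = results, genes_tested = rownames(emf$counts),
                 sf = sf, dispersion = disp, config = config),
            class = "triad_de")
}

#' @export
print.triad_de <- function(x, ...) {
  cat(sprintf("triad_de: %d genes tested\n", length(x$genes_tested)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: %d up, %d down\n", nm,
                sum(r$significant & r$log2FC > 0),
                sum(r$significant & r$log2FC < 0)))
  }
  invisible(x)
}

#' DEG ids of one contrast
#'
#' @param de A [triad_de()] result.
#' @param contrast One of `"F1vsP1"`, `"F1vsP2"`, `"P1vsP2"`.
#' @return Character vector of significant gene ids.
#' @export
deg_set <- function(de, contrast) {
  r <- de$results[[contrast]]
  if (is.null(r)) stop("unknown contrast: ", contrast)
  r$gene_id[r$significant]
}

#' Seven-region Venn counts of three gene sets
#'
#' @param setA,setB,setC Character vectors (gene ids).
#' @return Named integer vector `A_only`, `B_only`, `C_only`, `AB_only`,
#'   `AC_only`, `BC_only`, `ABC`; the regions sum to the union size.
#' @export
venn_counts <- function(setA, setB, setC) {
  setA <- unique(setA); setB <- unique(setB); setC <- unique(setC)
  u <- union(union(setA, setB), setC)
  inA <- u %in% setA; inB <- u %in% setB; inC <- u %in% setC
  c(A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB_only = sum(inA & inB & !inC),
    AC_only = sum(inA & !inB & inC),
    BC_only = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC))
}
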