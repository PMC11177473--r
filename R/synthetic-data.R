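#' Pattern codes and their expression-mode categories
#'
#' The twelve triad expression patterns: P1-P2 additive (F1 at the
#' mid-parent level with the parents differing), P3-P6 expression-level
#' dominant (F1 indistinguishable from exactly one parent), P7-P9
#' down-regulated overdominant (F1 below both parents) and P10-P12
#' up-regulated overdominant (F1 above both parents).
#'
#' @format `PATTERN_CODES` is the character vector `P1`..`P12` plus
#'   `UNCLASSIFIED`.
#' @export
PATTERN_CODES <- c(paste0("P", 1:12), "UNCLASSIFIED")

#' Map a pattern code to its expression-mode category
#'
#' @param code Character vector of codes in `P1`..`P12` or `UNCLASSIFIED`.
#' @return Character vector in `additive`, `dominant`, `overdominant_down`,
#'   `overdominant_up`, `unclassified`.
#' @examples
#' pattern_category(c("P1", "P5", "P8", "P11"))
#' @export
pattern_category <- function(code) {
  stopifnot(all(code %in% PATTERN_CODES))
  num <- suppressWarnings(as.integer(sub("^P", "", code)))
  out <- rep("unclassified", length(code))
  out[!is.na(num) & num <= 2] <- "additive"
  out[!is.na(num) & num >= 3 & num <= 6] <- "dominant"
  out[!is.na(num) & num >= 7 & num <= 9] <- "overdominant_down"
  out[!is.na(num) & num >= 10] <- "overdominant_up"
  out
}

default_pattern_proportions <- function(unclassified = 0.5) {
  # classified half follows the study's category shares: 0.13% additive,
  # 23.18% dominant, 76.69% overdominant, equal sub-code split per category
  cls <- 1 - unclassified
  p <- c(rep(0.0013 / 2, 2),
         rep(0.2318 / 4, 4),
         rep(0.7669 / 6, 6)) * cls
  stats::setNames(c(p, unclassified), PATTERN_CODES)
}

#' Configuration for the synthetic triad count generator
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per genotype (>= 2; the downstream tests need
#'   replication).
#' @param pattern_proportions Named numeric over `P1`..`P12` and
#'   `UNCLASSIFIED`, summing to 1. Default: 50% unclassified background, the
#'   remainder split 0.13% / 23.18% / 76.69% across the additive, dominant
#'   and overdominant categories with equal sub-code shares.
#' @param base_mean_log2_range Range (log2 scale) of the baseline gene
#'   abundance drawn uniformly per gene.
#' @param effect_log2fc Designed log2 separation between "different"
#'   expression states (> 0).
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), > 0.
#' @param libsize_factors Per-sample positive multipliers on the expected
#'   counts, length `3 * n_reps` (order: parent1, parent2, hybrid
#'   replicates), or `NULL` for uniform 1.
#' @param seed Integer seed; identical configs give identical output.
#' @return A `triad_sim_config` list.
#' @export
triad_sim_config <- function(n_genes = 5000, n_reps = 3,
                             pattern_proportions = default_pattern_proportions(),
                             base_mean_log2_range = c(3, 9),
                             effect_log2fc = 3, dispersion = 0.05,
                             libsize_factors = NULL, seed = 1) {
  stopifnot(n_genes >= 1, length(base_mean_log2_range) == 2)
  if (n_reps < 2)
    stop("n_reps must be >= 2: the differential-expression test needs replication")
  if (effect_log2fc <= 0) stop("effect_log2fc must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (is.null(names(pattern_proportions)) ||
      !all(names(pattern_proportions) %in% PATTERN_CODES))
    stop("pattern_proportions must be named by pattern codes")
  if (any(pattern_proportions < 0) ||
      abs(sum(pattern_proportions) - 1) > 1e-9)
    stop("pattern_proportions must be non-negative and sum to 1")
  if (is.null(libsize_factors)) libsize_factors <- rep(1, 3 * n_reps)
  if (length(libsize_factors) != 3 * n_reps || any(libsize_factors <= 0))
    stop("libsize_factors must be ", 3 * n_reps, " positive values")
  structure(list(n_genes = n_genes, n_reps = n_reps,
                 pattern_proportions = pattern_proportions,
                 base_mean_log2_range = base_mean_log2_range,
                 effect_log2fc = effect_log2fc, dispersion = dispersion,
                 libsize_factors = libsize_factors, seed = seed),
            class = "triad_sim_config")
}

# designed genotype means (log2 scale) realizing each pattern:
# b = baseline, e = designed log2 separation. Additive patterns place the
# hybrid at the arithmetic mid-parent on the raw scale; dominant patterns
# place it exactly on one parental mean; overdominant patterns push it
# beyond both parents by >= e.
pattern_log2_means <- function(code, b, e) {
  raw <- function(x) 2^x
  switch(code,
    P1  = c(raw(b + e), (raw(b + e) + raw(b)) / 2, raw(b)),
    P2  = c(raw(b), (raw(b + e) + raw(b)) / 2, raw(b + e)),
    P3  = c(raw(b + e), raw(b + e), raw(b)),
    P4  = c(raw(b), raw(b + e), raw(b + e)),
    P5  = c(raw(b), raw(b), raw(b + e)),
    P6  = c(raw(b + e), raw(b), raw(b)),
    P7  = c(raw(b + e), raw(b), raw(b + 2 * e)),
    P8  = c(raw(b + e), raw(b), raw(b + e)),
    P9  = c(raw(b + 2 * e), raw(b), raw(b + e)),
    P10 = c(raw(b), raw(b + 2 * e), raw(b + e)),
    P11 = c(raw(b), raw(b + e), raw(b)),
    P12 = c(raw(b + e), raw(b + 2 * e), raw(b)),
    UNCLASSIFIED = c(raw(b), raw(b), raw(b)))
}

# deterministic integer allocation of n items to proportions: floor plus
# largest-remainder for the leftover
allocate_counts <- function(proportions, n) {
  raw <- proportions * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  k
}

#' Simulate a triad RNA-seq count matrix with known pattern labels
#'
#' For each gene a pattern code is assigned per the configured proportions;
#' the three genotype means (parent1, hybrid, parent2) are chosen to realize
#' that pattern (see [triad_sim_config()]), and replicate counts are drawn
#' from a negative binomial with the configured dispersion and library-size
#' factors.
#'
#' @param config A [triad_sim_config()].
#' @return A list of class `synthetic_triad` with elements `em` (an
#'   [expression_matrix()]), `truth` (data frame `gene_id`, `pattern_code`),
#'   `means` (designed genotype means, genes x 3) and `config`.
#' @examples
#' sim <- simulate_triad(triad_sim_config(n_genes = 100, seed = 7))
#' table(sim$truth$pattern_code)
#' @export
simulate_triad <- function(config) {
  stopifnot(inherits(config, "triad_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  props <- config$pattern_proportions[names(config$pattern_proportions)]
  k <- allocate_counts(props, n)
  codes <- sample(rep(names(k), k))
  b <- stats::runif(n, config$base_mean_log2_range[1],
                    config$base_mean_log2_range[2])
  e <- config$effect_log2fc
  mu <- t(vapply(seq_len(n),
                 function(i) pattern_log2_means(codes[i], b[i], e),
                 numeric(3)))
  colnames(mu) <- c("parent1", "hybrid", "parent2")
  gene_id <- sprintf("gene%05d", seq_len(n))
  rownames(mu) <- gene_id

  reps <- seq_len(config$n_reps)
  design <- data.frame(
    sample_id = c(paste0("parent1_r", reps), paste0("parent2_r", reps),
                  paste0("hybrid_r", reps)),
    genotype = rep(c("parent1", "parent2", "hybrid"),
                   each = config$n_reps),
    replicate = rep(reps, 3))
  sf <- config$libsize_factors
  size <- 1 / config$dispersion
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu_j <- mu[, design$genotype[j]] * sf[j]
    counts[, j] <- stats::rnbinom(n, mu = mu_j, size = size)
  }
  structure(list(em = expression_matrix(counts, design),
                 truth = data.frame(gene_id = gene_id,
                                    pattern_code = codes),
                 means = mu, config = config),
            class = "synthetic_triad")
}

#' Write a synthetic triad to counts/design/truth TSV files
#'
#' @param sim A [simulate_triad()] result.
#' @param dir Output directory (created if needed).
#' @param header Optional `#`-comment lines for every file.
#' @return Invisibly, the written paths.
#' @export
write_triad_tsv <- function(sim, dir, header = NULL) {
  stopifnot(inherits(sim, "synthetic_triad"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "design.tsv", "truth.tsv"))
  write_expression_tsv(sim$em, paths[1], paths[2], header)
  write_tsv_commented(sim$truth, paths[3], header)
  invisible(paths)
}

default_varieties <- function() {
  data.frame(
    variety = c("K326", "Va116", "GDH94", "JCP2", "GDH88",
                "K326xGDH94", "K326xJCP2", "K326xGDH88",
                "Va116xGDH94", "Va116xJCP2", "Va116xGDH88"),
    parent1 = c(rep(NA, 5), rep("K326", 3), rep("Va116", 3)),
    parent2 = c(rep(NA, 5), rep(c("GDH94", "JCP2", "GDH88"), 2)))
}

default_growth_params <- function() {
  data.frame(
    variety = c("K326", "Va116", "GDH94", "JCP2", "GDH88"),
    asymptote = c(75, 68, 55, 60, 50),   # g dry weight per plant
    rate = 0.15,                         # 1/day
    midpoint = 52)                       # days after transplanting
}

default_mph_schedule <- function() {
  days <- c(38, 45, 52, 59, 66)
  # common mean path whose consecutive differences are the observed trend
  # deltas (+14.99, -12.90, +5.68 points after day 45), plus a constant
  # per-hybrid offset summing to zero; Va116xGDH94 peaks at 22.50% on day 45
  mean_path <- c(10, 15, 29.99, 17.09, 22.77)
  offsets <- c(Va116xGDH94 = 7.5, K326xGDH94 = 3, K326xJCP2 = 1,
               Va116xJCP2 = -2, K326xGDH88 = -4, Va116xGDH88 = -5.5)
  do.call(rbind, lapply(names(offsets), function(h)
    data.frame(hybrid = h, day = days, mph_pct = mean_path + offsets[[h]])))
}

#' Configuration for the biomass time-course generator
#'
#' @param varieties Data frame `variety`, `parent1`, `parent2` (parents `NA`
#'   for inbred lines). Default: the 5-parent / 6-hybrid incomplete diallel.
#' @param timepoints_days Strictly increasing integer days after
#'   transplanting (default 38, 45, 52, 59, 66).
#' @param mph_schedule Data frame `hybrid`, `day`, `mph_pct` giving each
#'   hybrid's designed mid-parent heterosis in percent.
#' @param growth_params Data frame `variety`, `asymptote`, `rate`,
#'   `midpoint` of per-parent logistic growth (dry weight in grams).
#' @param noise_cv Coefficient of variation of the multiplicative replicate
#'   noise (>= 0).
#' @param n_reps Replicates per variety and day.
#' @param seed Integer seed.
#' @return A `biomass_sim_config` list.
#' @export
biomass_sim_config <- function(varieties = default_varieties(),
                               timepoints_days = c(38, 45, 52, 59, 66),
                               mph_schedule = default_mph_schedule(),
                               growth_params = default_growth_params(),
                               noise_cv = 0.05, n_reps = 3, seed = 1) {
  if (any(diff(timepoints_days) <= 0))
    stop("timepoints_days must be strictly increasing")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  hybrids <- varieties[!is.na(varieties$parent1), , drop = FALSE]
  parents <- varieties$variety[is.na(varieties$parent1)]
  bad <- setdiff(c(hybrids$parent1, hybrids$parent2), parents)
  if (length(bad))
    stop("unknown parent variety in hybrid pairing: ",
         paste(unique(bad), collapse = ", "))
  structure(list(varieties = varieties, timepoints_days = timepoints_days,
                 mph_schedule = mph_schedule, growth_params = growth_params,
                 noise_cv = noise_cv, n_reps = n_reps, seed = seed),
            class = "biomass_sim_config")
}

logistic_value <- function(t, asymptote, rate, midpoint) {
  asymptote / (1 + exp(-rate * (t - midpoint)))
}

#' Simulate a multi-variety biomass time course with designed heterosis
#'
#' Parent means follow their logistic growth curves; each hybrid mean at
#' each timepoint is the mid-parent value scaled by
#' `1 + mph_schedule / 100`; replicates receive multiplicative Gaussian
#' noise with the configured coefficient of variation.
#'
#' @param config A [biomass_sim_config()].
#' @param trait Trait name recorded in the output (default `"biomass"`).
#' @return A long-format trait table: data frame `variety`, `parent1`,
#'   `parent2`, `day`, `replicate`, `value`, `trait`.
#' @examples
#' tab <- simulate_biomass(biomass_sim_config(noise_cv = 0, seed = 2))
#' head(tab)
#' @export
simulate_biomass <- function(config, trait = "biomass") {
  stopifnot(inherits(config, "biomass_sim_config"))
  set.seed(config$seed)
  v <- config$varieties
  gp <- config$growth_params
  days <- config$timepoints_days
  parent_mean <- function(name, day) {
    p <- gp[gp$variety == name, ]
    if (nrow(p) != 1) stop("no growth parameters for parent ", name)
    logistic_value(day, p$asymptote, p$rate, p$midpoint)
  }
  rows <- list()
  for (i in seq_len(nrow(v))) {
    for (day in days) {
      if (is.na(v$parent1[i])) {
        m <- parent_mean(v$variety[i], day)
      } else {
        mp <- (parent_mean(v$parent1[i], day) +
               parent_mean(v$parent2[i], day)) / 2
        sched <- config$mph_schedule
        hit <- sched$hybrid == v$variety[i] & sched$day == day
        mph <- if (any(hit)) sched$mph_pct[hit][1] else 0
        m <- mp * (1 + mph / 100)
      }
      noise <- 1 + stats::rnorm(config$n_reps, 0, config$noise_cv)
      rows[[length(rows) + 1]] <- data.frame(
        variety = v$variety[i], parent1 = v$parent1[i],
        parent2 = v$parent2[i], day = day,
        replicate = seq_len(config$n_reps),
        value = pmax(m * noise, 0), trait = trait)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
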