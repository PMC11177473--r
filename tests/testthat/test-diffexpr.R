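test_that("identical columns give unit size factors; doubling one column doubles its factor", {
  counts <- matrix(rep(c(5, 10, 200, 0), 4), ncol = 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  counts[4, ] <- 7  # keep one all-nonzero row
  f <- size_factors(counts)
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)

  doubled <- counts
  doubled[, 2] <- counts[, 2] * 2
  f2 <- size_factors(doubled)
  expect_equal(unname(f2[2] / f2[1]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  set.seed(17)
  sim <- simulate_triad(triad_sim_config(
    n_genes = 500, seed = 17,
    libsize_factors = exp(rnorm(9, 0, 0.1))))
  ours <- size_factors(sim$em)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$em$counts)
  # both fix only relative factors, and the reference takes its median in
  # log space (even-count medians differ geometrically vs arithmetically),
  # so compare rescaled factors loosely
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-4)
})

test_that("genes containing zeros are excluded from the reference set", {
  # one clean gene with ratio 1 everywhere; one zero-containing gene that
  # would drag the median if (wrongly) included
  counts <- rbind(c(10, 10, 10), c(0, 1000, 1000), c(20, 20, 20))
  dimnames(counts) <- list(paste0("g", 1:3), paste0("s", 1:3))
  f <- size_factors(counts)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
})

test_that("all-zero reference falls back to library-size factors with a warning", {
  counts <- rbind(c(0, 4, 8), c(2, 0, 4), c(4, 8, 0))
  dimnames(counts) <- list(paste0("g", 1:3), paste0("s", 1:3))
  expect_warning(f <- size_factors(counts), "library-size")
  expect_equal(unname(f / f[1]), colSums(counts) / colSums(counts)[1],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dispersion of exactly repeated counts is floored", {
  em <- two_group_em(c(10, 50), c(10, 50), n_reps = 3, phi = 0.05, seed = 1)
  em$counts[] <- rep(c(10, 50), ncol(em$counts))
  phi <- estimate_dispersion(em)
  expect_true(all(phi == 1e-8))
})

test_that("moment dispersion recovers the simulation phi at high replication", {
  em <- two_group_em(rep(200, 2000), rep(200, 2000), n_reps = 50,
                     phi = 0.05, seed = 42)
  phi <- estimate_dispersion(em)
  expect_gt(stats::median(phi), 0.04)
  expect_lt(stats::median(phi), 0.06)

  set.seed(9)
  pois <- matrix(rpois(2000 * 100, 200), ncol = 100,
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 sprintf("s%03d", 1:100)))
  des <- data.frame(sample_id = colnames(pois),
                    genotype = rep(c("parent1", "hybrid"), each = 50),
                    replicate = rep(1:50, 2))
  phi0 <- estimate_dispersion(expression_matrix(pois, des))
  expect_lte(stats::median(phi0), 0.01)
})

test_that("all-zero genes get p = 1, log2FC = 0, not significant", {
  em <- two_group_em(c(100, 100), c(100, 800), n_reps = 3, seed = 3)
  em$counts[1, ] <- 0
  r <- test_contrast(em, "parent1", "hybrid")
  expect_equal(r$p[1], 1)
  expect_equal(r$log2FC[1], 0)
  expect_false(r$significant[1])
})

test_that("swapping the groups negates log2FC and keeps p", {
  em <- two_group_em(runif(100, 20, 500), runif(100, 20, 500), seed = 5)
  a <- test_contrast(em, "parent1", "hybrid")
  b <- test_contrast(em, "hybrid", "parent1")
  expect_equal(a$p, b$p, tolerance = 1e-12)
  # pseudocount makes the display fold asymmetric; compare the raw ratio
  expect_equal(log2(a$baseMeanB / a$baseMeanA),
               -log2(b$baseMeanB / b$baseMeanA), tolerance = 1e-12)
})

test_that("padj is BH-monotone and bounds p from above", {
  em <- two_group_em(runif(300, 10, 1000), runif(300, 10, 1000), seed = 6)
  r <- test_contrast(em, "parent1", "hybrid")
  expect_true(all(r$padj >= r$p - 1e-15))
  ord <- order(r$p)
  expect_true(all(diff(r$padj[ord]) >= -1e-12))
  expect_equal(r$padj, oracle_bh(r$p), tolerance = 1e-12)
})

test_that("a designed 8-fold change at low dispersion is detected with the right sign", {
  # one designed gene on a null background (normalization must not absorb it)
  set.seed(99)
  bg <- runif(40, 50, 500)
  hits <- 0
  for (seed in 1:50) {
    em <- two_group_em(c(100, bg), c(800, bg), n_reps = 3, phi = 0.01,
                       seed = seed)
    r <- test_contrast(em, "parent1", "hybrid")
    hits <- hits + (r$significant[1] && r$log2FC[1] > 0)
  }
  expect_gte(hits / 50, 0.95)
})

test_that("a hybrid identical to parent1 yields no F1vsP1 DEGs", {
  sim <- simulate_triad(triad_sim_config(n_genes = 300, seed = 10))
  em <- sim$em
  p1 <- em$counts[, em$design$genotype == "parent1"]
  em$counts[, em$design$genotype == "hybrid"] <- p1
  de <- triad_de(em)
  expect_equal(length(deg_set(de, "F1vsP1")), 0)
})

test_that("triad DE recovers the designed overdominant set", {
  props <- c(UNCLASSIFIED = 0.8, P10 = 0.1, P11 = 0.05, P12 = 0.05)
  sim <- simulate_triad(triad_sim_config(n_genes = 1500,
                                         pattern_proportions = props,
                                         dispersion = 0.05, seed = 14))
  de <- triad_de(sim$em)
  both <- intersect(deg_set(de, "F1vsP1"), deg_set(de, "F1vsP2"))
  truth_od <- sim$truth$gene_id[sim$truth$pattern_code %in%
                                  c("P10", "P11", "P12")]
  jac <- length(intersect(both, truth_od)) / length(union(both, truth_od))
  expect_gte(jac, 0.8)
})

test_that("reported up/down counts equal threshold filtering of the tables", {
  sim <- simulate_triad(triad_sim_config(n_genes = 500, seed = 15))
  rep_ <- run_pipeline(pipeline_config(
    triad_sim = triad_sim_config(n_genes = 500, seed = 15), seed = 15))
  for (i in seq_len(nrow(rep_$deg_counts))) {
    r <- rep_$de$results[[rep_$deg_counts$contrast[i]]]
    keep <- r$p < 0.05 & abs(r$log2FC) >= 2
    expect_equal(rep_$deg_counts$up[i], sum(keep & r$log2FC > 0))
    expect_equal(rep_$deg_counts$down[i], sum(keep & r$log2FC < 0))
  }
})

test_that("venn regions enumerate correctly and sum to the union", {
  v <- venn_counts(c("a", "b"), c("b", "c"), c("b"))
  expect_equal(unname(v), c(1, 1, 0, 0, 0, 0, 1))

  same <- venn_counts(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(unname(same["ABC"]), 5)
  expect_equal(sum(same), 5)

  set.seed(20)
  for (i in 1:10) {
    u <- sprintf("g%04d", 1:5000)
    A <- sample(u, 1000); B <- sample(u, 1000); C <- sample(u, 1000)
    v <- venn_counts(A, B, C)
    expect_equal(sum(v), length(union(union(A, B), C)))
    expect_equal(unname(v["ABC"]), length(intersect(intersect(A, B), C)))
  }
})
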