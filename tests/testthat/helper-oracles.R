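# Independent scalar oracles used to cross-check the vectorized
# implementations.

# Rule-table classifier written as literal scalar logic over one gene's
# calls: each call is "up", "down" or "ns" (direction of the first-named
# genotype: hybrid for fp1/fp2, parent1 for pp).
oracle_classify_one <- function(fp1, fp2, pp, mean_p1, mean_f1, mean_p2) {
  if (fp1 == "up" && fp2 == "up") {
    if (pp == "down") return("P10")
    if (pp == "ns") return("P11")
    return("P12")
  }
  if (fp1 == "down" && fp2 == "down") {
    if (pp == "down") return("P7")
    if (pp == "ns") return("P8")
    return("P9")
  }
  if (pp != "ns") {
    if (fp1 == "ns" && fp2 != "ns")
      return(if (pp == "up") "P3" else "P5")   # hybrid sits on parent1
    if (fp2 == "ns" && fp1 != "ns")
      return(if (pp == "down") "P4" else "P6") # hybrid sits on parent2
    if (fp1 != "ns" && fp2 != "ns" &&
        mean_f1 > min(mean_p1, mean_p2) && mean_f1 < max(mean_p1, mean_p2))
      return(if (pp == "up") "P1" else "P2")
  }
  "UNCLASSIFIED"
}

# every combination of the three calls with every mean triple over {1,2,3}
oracle_call_grid <- function() {
  lv <- c("ns", "up", "down")
  expand.grid(fp1 = lv, fp2 = lv, pp = lv,
              mean_p1 = 1:3, mean_f1 = 1:3, mean_p2 = 1:3,
              stringsAsFactors = FALSE)
}

run_classifier_on_grid <- function(grid) {
  dir_of <- function(call) ifelse(call == "up", 1, ifelse(call == "down", -1, 0))
  classify_calls(
    sig_fp1 = grid$fp1 != "ns", dir_fp1 = dir_of(grid$fp1),
    sig_fp2 = grid$fp2 != "ns", dir_fp2 = dir_of(grid$fp2),
    sig_pp = grid$pp != "ns", dir_pp = dir_of(grid$pp),
    mean_p1 = grid$mean_p1, mean_f1 = grid$mean_f1, mean_p2 = grid$mean_p2)
}

run_oracle_on_grid <- function(grid) {
  vapply(seq_len(nrow(grid)), function(i)
    oracle_classify_one(grid$fp1[i], grid$fp2[i], grid$pp[i],
                        grid$mean_p1[i], grid$mean_f1[i], grid$mean_p2[i]),
    character(1))
}

# brute-force hypergeometric upper tail by direct summation of the
# combinatorial point probabilities
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# truth-vs-recovered pattern comparison for a synthetic triad
recovery_rates <- function(sim, patterns) {
  truth <- sim$truth[sim$truth$pattern_code != "UNCLASSIFIED", ]
  got <- patterns$pattern_code[match(truth$gene_id, patterns$gene_id)]
  got[is.na(got)] <- "UNCLASSIFIED"
  list(code = mean(got == truth$pattern_code),
       category = mean(pattern_category(got) ==
                         pattern_category(truth$pattern_code)))
}

# tiny two-group expression matrix from designed means
two_group_em <- function(muA, muB, n_reps = 3, phi = 0.05, seed = 1) {
  set.seed(seed)
  ng <- length(muA)
  counts <- cbind(
    matrix(stats::rnbinom(ng * n_reps, mu = rep(muA, n_reps), size = 1 / phi),
           nrow = ng),
    matrix(stats::rnbinom(ng * n_reps, mu = rep(muB, n_reps), size = 1 / phi),
           nrow = ng))
  rownames(counts) <- sprintf("g%04d", seq_len(ng))
  colnames(counts) <- sprintf("s%02d", seq_len(2 * n_reps))
  design <- data.frame(sample_id = colnames(counts),
                       genotype = rep(c("parent1", "hybrid"), each = n_reps),
                       replicate = rep(seq_len(n_reps), 2))
  expression_matrix(counts, design)
}
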