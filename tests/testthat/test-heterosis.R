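test_that("mph computes (F1 - MP)/MP * 100 and rejects MP <= 0", {
  expect_equal(mph(120, 120), 0)
  expect_equal(mph(61.25, 50), 22.5)
  expect_equal(mph(40, 50), -20)
  expect_error(mph(10, 0), "MP")
  expect_error(mph(10, -5), "MP")
})

test_that("mph is invariant to rescaling both arguments", {
  set.seed(1)
  for (i in 1:50) {
    f1 <- runif(1, 1, 100); mp <- runif(1, 1, 100); c0 <- runif(1, 0.01, 50)
    expect_equal(mph(c0 * f1, c0 * mp), mph(f1, mp), tolerance = 1e-12)
  }
})

test_that("mph_series handles parent-only tables and missing parents", {
  tab <- simulate_biomass(biomass_sim_config(noise_cv = 0, seed = 1))
  parents_only <- tab[is.na(tab$parent1), ]
  expect_equal(nrow(mph_series(parents_only)), 0)

  drop_parent <- tab[!(tab$variety == "GDH94" & tab$day == 52), ]
  # GDH94 fathers two hybrids, so two skip warnings are emitted
  warns <- testthat::capture_warnings(s <- mph_series(drop_parent))
  expect_true(all(grepl("parent measurement missing", warns)))
  expect_length(warns, 2)
  expect_false(any(s$hybrid == "Va116xGDH94" & s$day == 52))
  expect_true(any(s$hybrid == "Va116xGDH94" & s$day == 45))
})

test_that("trend deltas subtract consecutive MPH values and flag the key period", {
  series <- data.frame(hybrid = "h", day = c(38, 45, 52),
                       F1 = 1, MP = 1, MPH_pct = c(5, 10, 25))
  d <- trend_deltas(series)
  expect_equal(d$delta_points, c(5, 15))
  expect_equal(d$key_period, c(FALSE, TRUE))
  expect_equal(unlist(d[d$key_period, c("day_from", "day_to")],
                      use.names = FALSE), c(45, 52))

  flat <- series; flat$MPH_pct <- 7
  expect_false(any(trend_deltas(flat)$key_period))

  single <- series[1, ]
  expect_equal(nrow(trend_deltas(single)), 0)
})

test_that("designed maximum rise yields the expected key period for every hybrid", {
  tab <- simulate_biomass(biomass_sim_config(noise_cv = 0, seed = 8))
  d <- trend_deltas(mph_series(tab))
  key <- d[d$key_period, ]
  expect_true(all(key$day_from == 45) && all(key$day_to == 52))
  mean_d <- d[d$hybrid == "(mean)", ]
  expect_equal(mean_d$delta_points[mean_d$day_from == 45], 14.99,
               tolerance = 1e-9)
  expect_equal(mean_d$delta_points[mean_d$day_from == 52], -12.90,
               tolerance = 1e-9)
  expect_equal(mean_d$delta_points[mean_d$day_from == 59], 5.68,
               tolerance = 1e-9)
})

make_trait <- function(means, sd = 1, n = 3, day = 45, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(means), function(v)
    data.frame(variety = v, parent1 = NA, parent2 = NA, day = day,
               replicate = seq_len(n),
               value = means[[v]] + rnorm(n, 0, sd))))
}

test_that("duncan letters separate and merge the textbook fixtures", {
  sep <- make_trait(c(a1 = 100, a2 = 50, a3 = 10), sd = 1, seed = 2)
  g <- duncan_letters(sep, 45)$groups
  expect_equal(g$letters, c("a", "b", "c"))
  expect_equal(g$variety, c("a1", "a2", "a3"))

  mrg <- make_trait(c(a1 = 100, a2 = 100, a3 = 10), sd = 1, seed = 3)
  g2 <- duncan_letters(mrg, 45)$groups
  expect_equal(sort(g2$letters[g2$variety %in% c("a1", "a2")]), c("a", "a"))
  expect_equal(g2$letters[g2$variety == "a3"], "b")
})

test_that("identical replicate values across two varieties share a letter", {
  tab <- data.frame(variety = rep(c("x", "y"), each = 3), parent1 = NA,
                    parent2 = NA, day = 45, replicate = 1:3,
                    value = rep(c(5, 6, 7), 2))
  g <- duncan_letters(tab, 45)$groups
  expect_equal(g$letters, c("a", "a"))
})

test_that("zero within-group variance with distinct means gives distinct letters", {
  tab <- data.frame(variety = rep(c("x", "y", "z"), each = 3), parent1 = NA,
                    parent2 = NA, day = 45, replicate = 1:3,
                    value = rep(c(3, 2, 1), each = 3))
  g <- duncan_letters(tab, 45)$groups
  expect_equal(g$letters, c("a", "b", "c"))
})

test_that("two-group Duncan letters agree with the pooled-variance t-test", {
  for (seed in 1:40) {
    set.seed(seed)
    mu2 <- runif(1, 0, 3)
    x <- rnorm(4, 0, 1)
    y <- rnorm(4, mu2, 1)
    tab <- data.frame(variety = rep(c("x", "y"), each = 4), parent1 = NA,
                      parent2 = NA, day = 1, replicate = 1:4,
                      value = c(x, y))
    g <- duncan_letters(tab, 1)$groups
    p_t <- stats::t.test(x, y, var.equal = TRUE)$p.value
    expect_equal(g$letters[1] != g$letters[2], p_t < 0.05,
                 info = paste("seed", seed))
  }
})

test_that("the variety with the largest mean always holds letter a", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:6, 1)
    tab <- do.call(rbind, lapply(seq_len(k), function(i)
      data.frame(variety = paste0("v", i), parent1 = NA, parent2 = NA,
                 day = 1, replicate = 1:3,
                 value = rnorm(3, runif(1, 0, 20), 2))))
    g <- duncan_letters(tab, 1)$groups
    expect_true(grepl("a", g$letters[1]))
    expect_equal(g$mean, sort(g$mean, decreasing = TRUE))
  }
})

test_that("unbalanced groups and undersized inputs are handled", {
  tab <- data.frame(variety = c(rep("x", 5), rep("y", 3)), parent1 = NA,
                    parent2 = NA, day = 1, replicate = c(1:5, 1:3),
                    value = c(rnorm(5, 10), rnorm(3, 0)))
  expect_s3_class(duncan_letters(tab, 1), "duncan_letters")
  expect_error(duncan_letters(tab[tab$variety == "x", ], 1), ">= 2 varieties")
  one_rep <- rbind(tab, data.frame(variety = "z", parent1 = NA, parent2 = NA,
                                   day = 1, replicate = 1, value = 5))
  expect_error(duncan_letters(one_rep, 1), "replicates")
})
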