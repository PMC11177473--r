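#' Mid-parent heterosis
#'
#' `MPH(%) = (F1 - MP) / MP * 100`, where `F1` is the hybrid trait value and
#' `MP` the mean of the two parental values.
#'
#' @param F1 Hybrid trait value(s).
#' @param MP Mid-parent trait value(s), > 0.
#' @return MPH in percent (vectorized).
#' @examples
#' mph(61.25, 50)   # 22.5
#' mph(40, 50)      # -20
#' @export
mph <- function(F1, MP) {
  if (any(MP <= 0)) stop("MP must be > 0")
  (F1 - MP) / MP * 100
}

#' Mid-parent heterosis time series from a trait table
#'
#' For every hybrid and day at which both of its parents were measured,
#' computes the replicate-mean hybrid value `F1`, the mid-parent value `MP`
#' (mean of the two parental replicate means) and `MPH_pct`. Hybrid/day
#' combinations with a missing parent are skipped with a warning.
#'
#' @param table Long-format trait table as produced by [simulate_biomass()]
#'   (columns `variety`, `parent1`, `parent2`, `day`, `value`; optional
#'   `trait`).
#' @param trait Optional trait name to subset on when the table carries a
#'   `trait` column.
#' @return Data frame `hybrid`, `day`, `F1`, `MP`, `MPH_pct`, one row per
#'   hybrid x day; empty if the table holds no hybrids.
#' @export
mph_series <- function(table, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(table))
    table <- table[table$trait == trait, , drop = FALSE]
  hyb <- unique(table[!is.na(table$parent1),
                      c("variety", "parent1", "parent2")])
  out <- list()
  group_mean <- function(variety, day) {
    v <- table$value[table$variety == variety & table$day == day]
    if (!length(v)) NA_real_ else mean(v)
  }
  for (i in seq_len(nrow(hyb))) {
    days <- sort(unique(table$day[table$variety == hyb$variety[i]]))
    for (day in days) {
      f1 <- group_mean(hyb$variety[i], day)
      p1 <- group_mean(hyb$parent1[i], day)
      p2 <- group_mean(hyb$parent2[i], day)
      if (is.na(p1) || is.na(p2)) {
        warning(sprintf("skipping %s at day %d: parent measurement missing",
                        hyb$variety[i], day))
        next
      }
      mp <- (p1 + p2) / 2
      out[[length(out) + 1]] <- data.frame(
        hybrid = hyb$variety[i], day = day, F1 = f1, MP = mp,
        MPH_pct = mph(f1, mp))
    }
  }
  if (!length(out))
    return(data.frame(hybrid = character(), day = integer(),
                      F1 = numeric(), MP = numeric(), MPH_pct = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

delta_rows <- function(label, days, vals) {
  if (length(days) < 2) return(NULL)
  d <- diff(vals)
  key <- rep(FALSE, length(d))
  if (max(d) > 0) key[which.max(d)] <- TRUE  # earliest interval on ties
  data.frame(hybrid = label, day_from = days[-length(days)],
             day_to = days[-1], delta_points = d, key_period = key)
}

#' Consecutive-timepoint changes of the heterosis trend
#'
#' For each hybrid (and for the across-hybrid mean series, reported as
#' hybrid `"(mean)"`), computes `MPH_pct(t+1) - MPH_pct(t)` in percentage
#' points over consecutive timepoints and flags the interval of maximum
#' increase as the key period of heterosis formation. No interval is
#' flagged when the trend never rises; exact ties resolve to the earliest
#' interval.
#'
#' @param series Output of [mph_series()].
#' @return Data frame `hybrid`, `day_from`, `day_to`, `delta_points`,
#'   `key_period`.
#' @export
trend_deltas <- function(series) {
  out <- list()
  for (h in unique(series$hybrid)) {
    s <- series[series$hybrid == h, ]
    s <- s[order(s$day), ]
    out[[length(out) + 1]] <- delta_rows(h, s$day, s$MPH_pct)
  }
  if (length(unique(series$hybrid)) > 1) {
    m <- stats::aggregate(MPH_pct ~ day, series, mean)
    m <- m[order(m$day), ]
    out[[length(out) + 1]] <- delta_rows("(mean)", m$day, m$MPH_pct)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(hybrid = character(), day_from = integer(),
                      day_to = integer(), delta_points = numeric(),
                      key_period = logical())
  rownames(out) <- NULL
  out
}

# Duncan least-significant range for a stretch of p ordered means:
# studentized range quantile at protection level 1 - (1-alpha)^(p-1)
duncan_lsr <- function(p, df, alpha, mse, n) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, p, df) * sqrt(mse / n)
}

#' Duncan multiple-range-test letter grouping at one timepoint
#'
#' One-way ANOVA pooled error across varieties at the given day, then
#' Duncan's stepwise range procedure: two means whose ordered stretch spans
#' `p` ranks differ significantly when their difference exceeds
#' `LSR_p = q'(p, df, alpha) * sqrt(MSE / n)` with the studentized-range
#' quantile taken at Duncan's protection level `1 - (1 - alpha)^(p - 1)`.
#' Compact letters are assigned so two varieties share a letter iff they
#' fall in a common non-significant stretch; the largest mean always holds
#' letter "a". Unbalanced group sizes use the harmonic mean; zero pooled
#' variance with distinct means yields all-distinct letters.
#'
#' @param table Long-format trait table (columns `variety`, `day`, `value`,
#'   optional `trait`).
#' @param day Day to analyse.
#' @param alpha Significance level (default 0.05).
#' @param trait Optional trait subset.
#' @return A `duncan_letters` list: `groups` (data frame `variety`, `mean`,
#'   `n`, `letters`, sorted by descending mean), `alpha`, `mse`, `df`.
#' @export
duncan_letters <- function(table, day, alpha = 0.05, trait = NULL) {
  if (!is.null(trait) && "trait" %in% names(table))
    table <- table[table$trait == trait, , drop = FALSE]
  sub <- table[table$day == day, , drop = FALSE]
  groups <- split(sub$value, sub$variety)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2)
    stop("need >= 2 varieties measured at day ", day)
  if (any(lengths(groups) < 2))
    stop("need >= 2 replicates per variety at day ", day)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  df <- sum(ns) - length(groups)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df
  n_h <- length(ns) / sum(1 / ns)  # harmonic mean for unbalanced groups

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  sig <- matrix(FALSE, k, k)
  if (mse == 0) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- m[i] != m[j]
  } else {
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- (m[i] - m[j]) > duncan_lsr(j - i + 1, df, alpha, mse, n_h)
  }
  # maximal stretches of ordered means with no significant pair inside
  stretches <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:j, j + 1])) j <- j + 1
    if (!length(stretches) || stretches[[length(stretches)]][2] < j)
      stretches[[length(stretches) + 1]] <- c(i, j)
  }
  letters_vec <- rep("", k)
  for (s in seq_along(stretches)) {
    idx <- stretches[[s]][1]:stretches[[s]][2]
    letters_vec[idx] <- paste0(letters_vec[idx], letters[s])
  }
  structure(list(
    groups = data.frame(variety = names(m), mean = unname(m),
                        n = unname(ns[ord]), letters = letters_vec),
    alpha = alpha, mse = mse, df = df), class = "duncan_letters")
}

#' @export
print.duncan_letters <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$mse, x$df))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
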