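# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package code paths they check.

# daily MME as a plain sum of products (non-tiered drugs only)
oracle_mme <- function(strength, doses, factor) {
  sum(strength * doses * factor)
}

# brute-force K-means for k = 2: enumerate every bipartition and minimize
# total within-cluster sum of squares
oracle_kmeans2 <- function(x) {
  n <- length(x)
  best <- NULL
  best_ss <- Inf
  for (m in 1:(n - 1)) {
    idx <- combn(n, m)
    for (j in seq_len(ncol(idx))) {
      a <- x[idx[, j]]; b <- x[-idx[, j]]
      ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      if (ss < best_ss - 1e-12) {
        best_ss <- ss
        best <- sort(c(mean(a), mean(b)))
      }
    }
  }
  best
}

# Kruskal-Wallis H computed from first principles (tie-corrected)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Spearman's rho from the rank-difference formula (no ties)
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# a minimal three-drug prescription builder
rx_tbl <- function(drug, strength, doses, otc = FALSE) {
  tibble::tibble(drug = drug, strength_mg = strength,
                 doses_per_day = doses, usage = NA_character_,
                 is_otc = otc)
}
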