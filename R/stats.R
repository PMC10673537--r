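new_test_result <- function(test_name, statistic, p_value, groups = NULL,
                            n_per_group = NULL, extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    c(list(test_name = test_name, statistic = unname(statistic),
           p_value = unname(p_value), groups = groups,
           n_per_group = n_per_group), extra),
    class = "dipa_test"
  )
}

#' @export
print.dipa_test <- function(x, ...) {
  cat(x$test_name, "\n")
  cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$groups)) {
    cat("  groups:", paste0(x$groups, " (n=", x$n_per_group, ")",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.dipa_test <- function(x, ...) {
  data.frame(test_name = x$test_name, statistic = x$statistic,
             p_value = x$p_value,
             groups = paste(x$groups, collapse = "/"),
             n = sum(x$n_per_group))
}

#' Shapiro-Wilk normality test
#'
#' Used to check the ANOVA normality assumption on the per-class MME
#' distributions; non-normality motivates the nonparametric battery
#' (Kruskal-Wallis, Mann-Whitney).
#'
#' @param sample numeric vector, 3 <= n <= 5000.
#' @return a `dipa_test` result with the W statistic and p-value.
#' @export
shapiro_wilk <- function(sample) {
  x <- sample[!is.na(sample)]
  if (length(x) < 3) abort("Shapiro-Wilk requires at least 3 observations")
  if (length(x) > 5000) abort("Shapiro-Wilk supports at most 5000 observations")
  if (sd(x) == 0) abort("Shapiro-Wilk is undefined for a constant sample")
  st <- shapiro.test(x)
  new_test_result("Shapiro-Wilk normality", st$statistic, st$p.value,
                  n_per_group = length(x))
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric comparison of two or more groups, used to test that the
#' narcotic classes C, D and E differ in daily MME. The H statistic is
#' tie-corrected and referred to a chi-square approximation.
#'
#' @param groups a named or unnamed list of numeric vectors (>= 2 groups,
#'   each non-empty).
#' @return a `dipa_test` result.
#' @export
#' @examples
#' kruskal_wallis(list(C = c(10, 20), D = c(40, 50), E = c(90, 100)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("kruskal_wallis needs a list of at least 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    abort("All groups must be non-empty")
  }
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, integer(1))),
              levels = labels)
  st <- kruskal.test(x, g)
  new_test_result("Kruskal-Wallis", st$statistic, st$p.value,
                  groups = labels,
                  n_per_group = vapply(groups, length, integer(1)),
                  extra = list(df = unname(st$parameter)))
}

# internal: U statistic of a vs b counting a > b, ties as 1/2
mw_u_statistic <- function(a, b) {
  sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
}

# internal: exact two-sided p by enumeration of all C(n1+n2, n1)
# assignments of the pooled (tied) ranks to group a; a permutation test on
# U, so ties are handled exactly
mw_exact_p <- function(a, b) {
  u_obs <- mw_u_statistic(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) {
    mw_u_statistic(pooled[i], pooled[-i])
  })
  eps <- 1e-9
  # standard two-sided p: twice the smaller tail, capped at 1
  p_low <- mean(u_all <= u_obs + eps)
  p_high <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_low, p_high))
}

# internal: normal approximation with tie correction and continuity
# correction
mw_normal_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- mw_u_statistic(a, b)
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * pnorm(-abs(z))))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-based comparison of two independent samples, used for the
#' decline in the narcotic share between two post-operative periods and
#' for the gender vs pain-tolerability comparison. Small samples
#' (both groups <= 8 by default) are handled exactly, by enumerating all
#' assignments of the pooled observations to the two groups (a
#' permutation test on U, so ties are exact too); larger samples use the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact
#'   enumeration; `NULL` (default) chooses by sample size.
#' @return a `dipa_test` result with the U statistic (count of pairs
#'   where `a` exceeds `b`, ties counted 1/2) and the two-sided p-value;
#'   the `method` field records which branch was used.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty")
  }
  if (anyNA(a) || anyNA(b)) abort("Samples must not contain NA")
  use_exact <- exact %||% (length(a) <= 8 && length(b) <= 8)
  if (use_exact) {
    u <- mw_u_statistic(a, b)
    p <- mw_exact_p(a, b)
    method <- "exact enumeration"
  } else {
    res <- mw_normal_p(a, b)
    u <- res$u; p <- res$p
    method <- "normal approximation"
  }
  new_test_result("Mann-Whitney U", u, p, groups = c("a", "b"),
                  n_per_group = c(length(a), length(b)),
                  extra = list(method = method))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, used for the
#' class-vs-MME and dosing-frequency-vs-MME associations. Medication
#' class letters are accepted directly and mapped to ordinal ranks
#' A=0 .. E=4. With `verbose = TRUE` Kendall's tau is reported alongside,
#' since an ordinal association can be summarized by either coefficient.
#'
#' @param x,y equal-length vectors (numeric, or class letters for `x`/`y`).
#' @param verbose also compute Kendall's tau.
#' @return a `dipa_test` result with `statistic` = rho in [-1, 1]; the
#'   p-value uses the t approximation (AS 89 is unreliable with ties).
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
spearman_rho <- function(x, y, verbose = FALSE) {
  to_num <- function(v) {
    if (is.character(v) || is.factor(v)) {
      as.numeric(class_factor(v)) - 1  # A=0 .. E=4
    } else {
      as.numeric(v)
    }
  }
  xn <- to_num(x); yn <- to_num(y)
  if (length(xn) != length(yn)) abort("x and y must have equal length")
  keep <- complete.cases(xn, yn)
  xn <- xn[keep]; yn <- yn[keep]
  if (length(xn) < 3) abort("Need at least 3 complete pairs")
  st <- suppressWarnings(cor.test(xn, yn, method = "spearman", exact = FALSE))
  extra <- list(rho = unname(st$estimate))
  if (verbose) {
    kt <- suppressWarnings(cor.test(xn, yn, method = "kendall", exact = FALSE))
    extra$tau <- unname(kt$estimate)
    extra$tau_p_value <- kt$p.value
  }
  new_test_result("Spearman rank correlation", st$estimate, st$p.value,
                  n_per_group = length(xn), extra = extra)
}

#' Run the full statistical validation battery on a cohort
#'
#' Mirrors the scale's validation analyses: Shapiro-Wilk normality of the
#' per-class MME samples, Kruskal-Wallis separation of narcotic classes
#' C/D/E, Mann-Whitney on the narcotic indicator between the first and
#' last periods, Spearman correlations of class vs MME and dosing
#' frequency vs MME, and the gender vs pain-tolerability comparison
#' (Mann-Whitney on IPA by gender; `gender_test = "chisq"` switches to a
#' 2x3 chi-square alternative).
#'
#' @param visits an augmented cohort (see [augment_cohort()]).
#' @param periods two period labels to compare for the narcotic decline
#'   (default first and last canonical periods present).
#' @param gender_test `"mann_whitney"` (default) or `"chisq"`.
#' @param verbose pass-through to [spearman_rho()].
#' @return a tibble with one row per test: `test_name`, `statistic`,
#'   `p_value`, `groups`, `n`.
#' @export
validate_cohort <- function(visits, periods = NULL,
                            gender_test = c("mann_whitney", "chisq"),
                            verbose = FALSE) {
  gender_test <- match.arg(gender_test)
  if (!all(c("daily_mme", "med_class") %in% names(visits))) {
    abort("Run augment_cohort() before validate_cohort()")
  }
  cl <- as.character(visits$med_class)
  narc <- cl %in% c("C", "D", "E")
  results <- list()

  mme_by_class <- split(visits$daily_mme[narc], cl[narc])
  mme_by_class <- mme_by_class[vapply(mme_by_class, length, integer(1)) > 0]
  for (letter in names(mme_by_class)) {
    x <- mme_by_class[[letter]]
    if (length(x) >= 3 && sd(x) > 0) {
      r <- shapiro_wilk(x)
      r$test_name <- paste0("Shapiro-Wilk normality (class ", letter, " MME)")
      results <- c(results, list(r))
    }
  }
  if (length(mme_by_class) >= 2) {
    r <- kruskal_wallis(mme_by_class)
    r$test_name <- "Kruskal-Wallis: MME across narcotic classes"
    results <- c(results, list(r))
  }

  pf <- period_factor(visits$period)
  present <- levels(droplevels(pf))
  if (is.null(periods)) periods <- c(present[1], present[length(present)])
  if (length(present) >= 2 && periods[1] != periods[2]) {
    ind1 <- as.numeric(narc[pf == periods[1]])
    ind2 <- as.numeric(narc[pf == periods[2]])
    r <- mann_whitney(ind1, ind2)
    r$test_name <- paste0("Mann-Whitney: narcotic use, ", periods[1],
                          " vs ", periods[2])
    r$groups <- periods
    results <- c(results, list(r))
  }

  if (any(narc)) {
    r <- spearman_rho(cl, visits$daily_mme, verbose = verbose)
    r$test_name <- "Spearman: medication class vs MME"
    results <- c(results, list(r))
    freq <- vapply(visits$prescriptions, function(p) {
      if (is.null(p) || nrow(p) == 0) return(0)
      otc <- if ("is_otc" %in% names(p)) p$is_otc %in% TRUE else rep(FALSE, nrow(p))
      sum(p$doses_per_day[!otc])
    }, numeric(1))
    r <- spearman_rho(freq, visits$daily_mme, verbose = verbose)
    r$test_name <- "Spearman: dosing frequency vs MME"
    results <- c(results, list(r))
  }

  if ("gender" %in% names(visits) && !anyNA(visits$gender) &&
        length(unique(visits$gender)) == 2) {
    gsplit <- split(visits$ipa, visits$gender)
    gsplit <- lapply(gsplit, function(v) v[!is.na(v)])
    if (all(vapply(gsplit, length, integer(1)) > 0)) {
      if (gender_test == "mann_whitney") {
        r <- mann_whitney(gsplit[[1]], gsplit[[2]])
        r$groups <- names(gsplit)
      } else {
        tabg <- table(unlist(lapply(names(gsplit), function(nm) {
          rep(nm, length(gsplit[[nm]]))
        })), unlist(gsplit))
        st <- suppressWarnings(stats::chisq.test(tabg))
        r <- new_test_result("chi-square", st$statistic, st$p.value,
                             groups = names(gsplit),
                             n_per_group = vapply(gsplit, length, integer(1)))
      }
      r$test_name <- paste0(r$test_name %||% "", "")
      r$test_name <- paste0(sub(":.*$", "", r$test_name),
                            ": pain tolerability by gender")
      results <- c(results, list(r))
    }
  }

  dplyr::bind_rows(lapply(results, as.data.frame)) |> tibble::as_tibble()
}
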