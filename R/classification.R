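#' Operational medication-class boundaries
#'
#' The DIPA medication classes are A (no pain medication), B
#' (over-the-counter only), and three narcotic classes defined on daily
#' MME: C occasional short-acting narcotics, D consistent short-acting
#' narcotics, E long-acting or stronger narcotics. The operational scheme
#' uses contiguous half-open intervals C = (0, 30], D = (30, 80),
#' E = [80, Inf), which agree with the integer cutoffs 1-30 / 31-79 / 80+
#' while covering every positive real dose.
#'
#' @param c_high upper bound of class C (inclusive), MME/day.
#' @param e_min lower bound of class E (inclusive), MME/day.
#' @return a `dipa_boundaries` object.
#' @export
#' @examples
#' operational_boundaries()
operational_boundaries <- function(c_high = 30, e_min = 80) {
  new_boundaries(c_low = 0, c_high = c_high, d_low = c_high,
                 d_high = e_min, e_min = e_min,
                 source = "operational_default")
}

new_boundaries <- function(c_low, c_high, d_low, d_high, e_min, source,
                           seed = NULL, table_version = NULL) {
  if (!(c_low >= 0 && c_low < c_high && c_high <= d_low &&
          d_low < d_high && d_high <= e_min)) {
    abort("Class boundaries must be ordered and disjoint: C < D < E")
  }
  structure(
    list(c_low = c_low, c_high = c_high, d_low = d_low, d_high = d_high,
         e_min = e_min, source = source, seed = seed,
         table_version = table_version),
    class = "dipa_boundaries"
  )
}

#' @export
print.dipa_boundaries <- function(x, ...) {
  cat("DIPA medication-class boundaries (", x$source, ")\n", sep = "")
  cat(sprintf("  C: (%g, %g]   D: (%g, %g)   E: [%g, Inf)\n",
              x$c_low, x$c_high, x$d_low, x$d_high, x$e_min))
  invisible(x)
}

#' Write / read class boundaries as JSON
#'
#' @param boundaries a `dipa_boundaries` object.
#' @param path file path for the JSON document.
#' @return `boundaries_to_json` returns `path` invisibly;
#'   `boundaries_from_json` returns a `dipa_boundaries` object.
#' @export
boundaries_to_json <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "dipa_boundaries"))
  jsonlite::write_json(unclass(boundaries), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname boundaries_to_json
#' @export
boundaries_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_boundaries(x$c_low, x$c_high, x$d_low, x$d_high, x$e_min,
                 source = x$source, seed = x$seed,
                 table_version = x$table_version)
}

#' Assign the A-E medication class for a visit
#'
#' Class A and B are distinguished by medication presence (both are
#' 0 MME); the narcotic classes are assigned from daily MME alone:
#' `0 < MME <= c_high` is C, `c_high < MME < e_min` is D, `MME >= e_min`
#' is E. Usage pattern (occasional vs consistent) is descriptive in this
#' scheme and does not override the MME-based class; see
#' [flag_usage_mismatch()].
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param daily_mme non-negative daily MME value(s).
#' @param has_any_medication logical: any medication at all (OTC counts)?
#' @param has_opioid logical: any opioid prescription?
#' @param boundaries a `dipa_boundaries` object.
#' @return an ordered factor of class letters (A < B < C < D < E).
#' @export
#' @examples
#' classify_visit(c(0, 0, 20, 45, 94), c(FALSE, TRUE, TRUE, TRUE, TRUE),
#'                c(FALSE, FALSE, TRUE, TRUE, TRUE))
classify_visit <- function(daily_mme, has_any_medication, has_opioid,
                           boundaries = operational_boundaries()) {
  stopifnot(inherits(boundaries, "dipa_boundaries"))
  n <- max(length(daily_mme), length(has_any_medication), length(has_opioid))
  daily_mme <- rep_len(daily_mme, n)
  has_any_medication <- rep_len(as.logical(has_any_medication), n)
  has_opioid <- rep_len(as.logical(has_opioid), n)

  if (anyNA(daily_mme) || any(daily_mme < 0)) {
    abort("daily_mme must be non-negative and non-missing")
  }
  if (any(has_opioid & !has_any_medication)) {
    abort("has_opioid implies has_any_medication")
  }
  if (any(has_opioid & daily_mme == 0)) {
    abort("Inconsistent visit: an opioid prescription is present but daily MME is 0")
  }
  if (any(daily_mme > 0 & !has_opioid)) {
    abort("Inconsistent visit: daily MME > 0 without an opioid prescription")
  }

  letter <- ifelse(daily_mme == 0,
                   ifelse(has_any_medication, "B", "A"),
                   ifelse(daily_mme <= boundaries$c_high, "C",
                          ifelse(daily_mme < boundaries$e_min, "D", "E")))
  class_factor(letter)
}

#' Combine medication class and IPA score into a DIPA rating
#'
#' A DIPA rating concatenates the medication class letter with the IPA
#' pain digit (0 no pain, 1 tolerable pain, 2 intolerable pain): a patient
#' on occasional short-acting narcotics reporting tolerable pain is a
#' "C1". Vectorized.
#'
#' @param med_class class letter(s) A-E (character or factor).
#' @param ipa integer IPA score(s) in {0, 1, 2}.
#' @return a character vector of rating codes, e.g. `"C1"`.
#' @export
#' @examples
#' make_dipa_rating("C", 1)
make_dipa_rating <- function(med_class, ipa) {
  med_class <- as.character(class_factor(med_class))
  if (anyNA(ipa) || !all(ipa %in% 0:2)) {
    abort("ipa must be 0 (no pain), 1 (tolerable pain) or 2 (intolerable pain)")
  }
  paste0(med_class, as.integer(ipa))
}

#' Split a DIPA rating code back into its components
#'
#' @param code character rating code(s) such as `"C1"`.
#' @return a tibble with columns `med_class` (ordered factor) and `ipa`.
#' @export
parse_dipa_rating <- function(code) {
  ok <- grepl("^[ABCDE][012]$", code)
  if (!all(ok)) {
    abort(paste0("Not a DIPA rating code: ",
                 paste(unique(code[!ok]), collapse = ", ")))
  }
  tibble::tibble(med_class = class_factor(substr(code, 1, 1)),
                 ipa = as.integer(substr(code, 2, 2)))
}

#' Derive narcotic class boundaries by cluster analysis
#'
#' Reproduces the two-stage derivation of the narcotic class cutoffs from
#' observed daily MME values: a hierarchical cluster analysis (Ward
#' linkage on Euclidean distances) proposes the number of narcotic
#' classes -- by maximum average silhouette width when `k = "auto"` --
#' and K-means (with restarts) then fixes the cluster centers. The
#' highest and lowest observed value within each cluster become the
#' cutoff points of the derived class intervals.
#'
#' @param narcotic_mmes positive daily MME values of narcotic users.
#' @param k number of clusters, or `"auto"` to search k in 2..6.
#' @param seed RNG seed for the K-means restarts (results are
#'   deterministic given the seed; the caller's RNG state is preserved).
#' @param nstart number of K-means restarts.
#' @return a list with elements `clustering` (fields `k`, `centers`
#'   sorted ascending, `extremes` per-cluster min/max tibble,
#'   `assignments`, `silhouette`) and, when `k >= 3`, `boundaries`
#'   (a `dipa_boundaries` with `source = "cluster_derived"` whose C/D
#'   intervals are the two lowest clusters' observed ranges and `e_min`
#'   is the top cluster's minimum).
#' @export
#' @examples
#' x <- c(rnorm(50, 16, 5), rnorm(50, 45, 5), rnorm(50, 94, 6))
#' derive_boundaries(abs(x), k = 3)$clustering$centers
derive_boundaries <- function(narcotic_mmes, k = "auto", seed = 1976,
                              nstart = 10) {
  x <- as.numeric(narcotic_mmes)
  if (length(x) == 0) abort("narcotic_mmes must be non-empty")
  if (anyNA(x) || any(x <= 0)) {
    abort("narcotic_mmes must be positive daily MME values")
  }
  n_distinct <- length(unique(x))

  auto <- identical(k, "auto")
  if (!auto) {
    k <- as.integer(k)
    if (k < 1) abort("k must be a positive integer or \"auto\"")
    if (n_distinct < k) {
      abort(paste0("Degenerate input: ", n_distinct,
                   " distinct value(s) but k = ", k))
    }
  }

  if (!auto && k == 1) {
    clustering <- list(
      k = 1L, centers = mean(x),
      extremes = tibble::tibble(cluster = 1L, min = min(x), max = max(x)),
      assignments = rep(1L, length(x)), silhouette = NA_real_
    )
    return(list(clustering = clustering, boundaries = NULL))
  }

  hc <- hclust(dist(x), method = "ward.D2")
  d2 <- dist(x)
  if (auto) {
    ks <- 2:min(6, n_distinct)
    sil <- vapply(ks, function(kk) {
      cl <- cutree(hc, k = kk)
      mean(cluster::silhouette(cl, d2)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
    sil_k <- max(sil)
  } else {
    cl <- cutree(hc, k = k)
    sil_k <- mean(cluster::silhouette(cl, d2)[, "sil_width"])
  }

  # hierarchical solution proposes k; K-means (seeded restarts) finalizes
  km <- with_preserved_seed(seed, kmeans(x, centers = k, nstart = nstart,
                                         iter.max = 100))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[km$cluster]
  centers <- unname(sort(km$centers[, 1]))

  extremes <- tibble::tibble(
    cluster = seq_len(k),
    min = vapply(seq_len(k), function(i) min(x[assignments == i]), numeric(1)),
    max = vapply(seq_len(k), function(i) max(x[assignments == i]), numeric(1))
  )

  boundaries <- NULL
  if (k >= 3) {
    boundaries <- new_boundaries(
      c_low = extremes$min[1], c_high = extremes$max[1],
      d_low = extremes$min[2], d_high = extremes$max[2],
      e_min = extremes$min[k],
      source = "cluster_derived", seed = seed
    )
  }

  list(
    clustering = list(k = as.integer(k), centers = centers,
                      extremes = extremes, assignments = assignments,
                      silhouette = sil_k),
    boundaries = boundaries
  )
}

#' Flag visits whose usage pattern disagrees with their MME class
#'
#' Class C is described as occasional and class D as consistent narcotic
#' use, but classification is MME-driven: a patient at 25 MME/day taken
#' consistently is still class C. This helper annotates such visits
#' rather than reclassifying them.
#'
#' @param med_class class letters (character or factor).
#' @param usage usage pattern, `"occasional"` or `"consistent"` (NA allowed).
#' @return logical vector: `TRUE` where usage conflicts with the class
#'   description (C taken consistently, or D taken occasionally).
#' @export
flag_usage_mismatch <- function(med_class, usage) {
  med_class <- as.character(med_class)
  (med_class == "C" & !is.na(usage) & usage == "consistent") |
    (med_class == "D" & !is.na(usage) & usage == "occasional")
}
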