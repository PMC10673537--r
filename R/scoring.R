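#' Provider efficiency (pain-management) score
#'
#' The efficiency score is the percentage of surveyed patients who report
#' no pain (IPA 0) or tolerable pain (IPA 1): each such patient counts 1,
#' intolerable-pain patients (IPA 2) count 0, and the sum is divided by
#' the number surveyed and multiplied by 100. It is the complement of the
#' intolerable-pain percentage.
#'
#' @param ipa_values integer IPA responses in {0, 1, 2}.
#' @return a percentage in [0, 100].
#' @export
#' @examples
#' efficiency_score(c(0, 1, 2, 1))  # 75
efficiency_score <- function(ipa_values) {
  if (length(ipa_values) == 0) {
    abort("Efficiency score is undefined for an empty cohort")
  }
  if (anyNA(ipa_values) || !all(ipa_values %in% 0:2)) {
    abort("IPA values must be 0, 1 or 2")
  }
  100 * sum(ipa_values <= 1) / length(ipa_values)
}

#' Percentage of patients on narcotics
#'
#' The share of visits in the narcotic medication classes C, D or E.
#'
#' @param classes class letters A-E (character or factor).
#' @return a percentage in [0, 100].
#' @export
#' @examples
#' percent_on_narcotics(c("A", "B", "C", "D", "E"))  # 60
percent_on_narcotics <- function(classes) {
  if (length(classes) == 0) {
    abort("percent_on_narcotics is undefined for an empty cohort")
  }
  cl <- class_factor(classes)
  if (anyNA(cl)) abort("Medication classes must be letters A-E")
  100 * sum(cl %in% c("C", "D", "E")) / length(cl)
}

#' Summarize one post-operative period
#'
#' Computes the per-period quantities displayed on a DIPA graph: visit
#' count, efficiency score, percent on narcotics, mean daily MME (over
#' all visits, class A/B zeros included, plus a narcotics-only mean),
#' the class distribution, and a per-class IPA breakdown.
#'
#' Visits missing an IPA response are excluded from the efficiency-score
#' denominator (but still counted in the class distribution).
#'
#' @param visits a data frame of visits from a single period with columns
#'   `period`, `ipa`, `daily_mme`, `med_class` (see [augment_cohort()]).
#' @return a one-row tibble: `period`, `n`, `efficiency_score`,
#'   `pct_on_narcotics`, `mean_mme`, `mean_mme_narcotic`, class
#'   proportions `p_A` .. `p_E`, and a list-column `ipa_by_class`.
#' @export
summarize_period <- function(visits) {
  req <- c("period", "ipa", "daily_mme", "med_class")
  missing_cols <- setdiff(req, names(visits))
  if (length(missing_cols) > 0) {
    abort(paste0("Visits are missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Run augment_cohort() first."))
  }
  if (nrow(visits) == 0) abort("Cannot summarize an empty period")
  per <- unique(as.character(visits$period))
  if (length(per) != 1) {
    abort(paste0("summarize_period expects a single period, got: ",
                 paste(per, collapse = ", ")))
  }

  cl <- class_factor(visits$med_class)
  ipa <- visits$ipa[!is.na(visits$ipa)]
  narc <- cl %in% c("C", "D", "E")
  p_class <- as.numeric(table(cl)) / length(cl)

  ipa_by_class <- visits |>
    dplyr::filter(!is.na(.data$ipa)) |>
    dplyr::count(med_class = class_factor(.data$med_class), .data$ipa,
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "ipa", values_from = "n",
                       names_prefix = "ipa_", values_fill = 0L)

  tibble::tibble(
    period = per,
    n = nrow(visits),
    efficiency_score = efficiency_score(ipa),
    pct_on_narcotics = percent_on_narcotics(cl),
    mean_mme = mean(visits$daily_mme),
    mean_mme_narcotic = if (any(narc)) mean(visits$daily_mme[narc]) else NA_real_,
    p_A = p_class[1], p_B = p_class[2], p_C = p_class[3],
    p_D = p_class[4], p_E = p_class[5],
    ipa_by_class = list(ipa_by_class)
  )
}

#' Summarize a cohort across all post-operative periods
#'
#' @param visits an augmented cohort (see [augment_cohort()]).
#' @return a tibble with one [summarize_period()] row per period, ordered
#'   2wk < 6wk < 3mo < 6mo.
#' @export
summarize_cohort <- function(visits) {
  if (nrow(visits) == 0) abort("Cannot summarize an empty cohort")
  periods <- levels(droplevels(period_factor(visits$period)))
  dplyr::bind_rows(lapply(periods, function(p) {
    summarize_period(visits[as.character(visits$period) == p, , drop = FALSE])
  }))
}

#' Derive per-visit MME, class and rating for a cohort
#'
#' Computes each visit's daily MME from its prescription list, assigns
#' the medication class and DIPA rating, and flags usage/class
#' mismatches. This populates the derived columns that
#' [summarize_period()], [validate_cohort()] and [dipa_report()] consume.
#'
#' @param visits a cohort tibble with one row per visit: `patient_id`,
#'   `period`, `ipa`, and a `prescriptions` list-column of prescription
#'   tibbles (as produced by [generate_cohort()] or [read_cohort()]).
#' @param table conversion table from [load_conversion_table()].
#' @param boundaries a `dipa_boundaries` object.
#' @return the input with columns `daily_mme`, `med_class`, `rating`,
#'   `usage_mismatch` added/overwritten.
#' @export
augment_cohort <- function(visits, table = load_conversion_table(),
                           boundaries = operational_boundaries()) {
  if (!"prescriptions" %in% names(visits)) {
    abort("Cohort must carry a 'prescriptions' list-column")
  }
  rx <- visits$prescriptions
  visits$daily_mme <- vapply(rx, compute_daily_mme, numeric(1), table = table)
  has_med <- vapply(rx, function(p) !is.null(p) && nrow(p) > 0, logical(1))
  has_opioid <- vapply(rx, function(p) {
    if (is.null(p) || nrow(p) == 0) return(FALSE)
    otc <- if ("is_otc" %in% names(p)) p$is_otc %in% TRUE else rep(FALSE, nrow(p))
    p <- p[!otc, , drop = FALSE]
    if (nrow(p) == 0) return(FALSE)
    any(table$is_opioid[resolve_drug(p$drug, table)], na.rm = TRUE)
  }, logical(1))
  visits$med_class <- classify_visit(visits$daily_mme, has_med, has_opioid,
                                     boundaries)
  ok_ipa <- !is.na(visits$ipa)
  visits$rating <- NA_character_
  visits$rating[ok_ipa] <- make_dipa_rating(visits$med_class[ok_ipa],
                                            visits$ipa[ok_ipa])
  usage <- vapply(rx, function(p) {
    if (is.null(p) || nrow(p) == 0 || !"usage" %in% names(p)) return(NA_character_)
    u <- p$usage[!is.na(p$usage)]
    if (length(u) == 0) NA_character_ else u[1]
  }, character(1))
  visits$usage_mismatch <- flag_usage_mismatch(visits$med_class, usage)
  visits
}
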