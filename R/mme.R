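#' Load an opioid-to-MME conversion-factor table
#'
#' Reads a delimited conversion table mapping drug names (and brand-name
#' synonyms) to oral morphine-milligram-equivalent factors. The packaged
#' default transcribes the CDC oral MME factor set, the same reference
#' applied by prescription registries such as MAPS: e.g. morphine 1 (by
#' definition), hydrocodone 1, oxycodone 1.5, tramadol 0.1, and tiered
#' factors for methadone keyed on total daily mg. Over-the-counter
#' analgesics are listed with factor 0 so that brand-name entry of, say,
#' "tylenol" resolves cleanly instead of erroring.
#'
#' The expected columns are `drug`, `factor`, `is_opioid`, and optionally
#' `synonyms` (pipe-separated), `schedule`, and `tier_max_mg`/`tier_factor`
#' in long format (one row per tier, sorted ascending; `Inf` for the open
#' top tier). Unknown columns are ignored. The table version is taken from
#' a `_v<N>` suffix in the file name and propagated into all downstream
#' reports.
#'
#' @param path path to a conversion CSV; `NULL` (default) loads the
#'   packaged table.
#' @return a tibble with one row per drug (`drug`, `factor`, `is_opioid`,
#'   `schedule`, list-columns `synonyms` and `tiers`), with attributes
#'   `version` and `source_path`. Class `"mme_table"`.
#' @export
#' @examples
#' tab <- load_conversion_table()
#' tab[tab$drug == "morphine", "factor"]
load_conversion_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mme_conversion_v1.csv", package = "dipa")
  }
  if (!file.exists(path)) {
    abort(paste0("Conversion table not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("drug", "factor", "is_opioid")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Conversion table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  n <- nrow(raw)
  col_or <- function(nm, default) if (nm %in% names(raw)) raw[[nm]] else default
  drug <- tolower(trimws(raw$drug))
  tier_raw <- col_or("tier_max_mg", rep(NA_character_, n))
  has_tier <- !is.na(tier_raw) & nzchar(tier_raw)

  parse_num <- function(col, what, allow_na) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & nzchar(col) & is.na(out) &
                   toupper(col) != "INF")
    out[toupper(col) == "INF"] <- Inf
    if (length(bad) > 0) {
      abort(paste0("Malformed ", what, " on line ", bad[1] + 1L,
                   " of ", path, ": '", col[bad[1]], "'"))
    }
    empty <- which(is.na(col) | !nzchar(col))
    if (!allow_na && length(empty) > 0) {
      abort(paste0("Missing ", what, " on line ", empty[1] + 1L, " of ", path))
    }
    out
  }

  factor_num <- parse_num(raw$factor, "factor", allow_na = TRUE)
  is_opioid <- toupper(trimws(raw$is_opioid)) %in% c("TRUE", "T", "1", "YES")
  bad_flag <- which(!(toupper(trimws(raw$is_opioid)) %in%
                        c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO")))
  if (length(bad_flag) > 0) {
    abort(paste0("Malformed is_opioid on line ", bad_flag[1] + 1L,
                 " of ", path))
  }
  no_factor <- which(!has_tier & (is.na(raw$factor) | !nzchar(raw$factor)))
  if (length(no_factor) > 0) {
    abort(paste0("Missing factor on line ", no_factor[1] + 1L, " of ", path))
  }
  bad_factor <- which(!has_tier & is_opioid & factor_num <= 0)
  if (length(bad_factor) > 0) {
    abort(paste0("Non-positive MME factor for opioid '", drug[bad_factor[1]],
                 "' on line ", bad_factor[1] + 1L, " of ", path))
  }
  bad_nonop <- which(!is_opioid & !is.na(factor_num) & factor_num != 0)
  if (length(bad_nonop) > 0) {
    abort(paste0("Non-opioid '", drug[bad_nonop[1]],
                 "' must have factor 0 (line ", bad_nonop[1] + 1L, ")"))
  }

  tier_max <- if (any(has_tier)) parse_num(tier_raw, "tier_max_mg", TRUE) else rep(NA_real_, n)
  tier_fac <- if (any(has_tier)) parse_num(col_or("tier_factor", rep(NA_character_, n)), "tier_factor", TRUE) else rep(NA_real_, n)
  if (any(has_tier & (is.na(tier_fac) | tier_fac <= 0))) {
    i <- which(has_tier & (is.na(tier_fac) | tier_fac <= 0))[1]
    abort(paste0("Tier row for '", drug[i], "' needs a positive tier_factor (line ",
                 i + 1L, ")"))
  }

  # duplicate plain (non-tier) drug rows are rejected; tier rows for the
  # same drug are the long-format encoding and must be contiguous+ascending
  plain <- drug[!has_tier]
  if (anyDuplicated(plain) > 0) {
    abort(paste0("Duplicate drug entries in conversion table: ",
                 paste(unique(plain[duplicated(plain)]), collapse = ", ")))
  }
  if (any(drug[has_tier] %in% plain)) {
    abort("A drug cannot have both a plain factor row and tier rows")
  }

  split_syn <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    tolower(trimws(strsplit(s, "|", fixed = TRUE)[[1]]))
  }
  synonyms_all <- lapply(col_or("synonyms", rep(NA_character_, n)), split_syn)
  schedule_all <- as.character(col_or("schedule", rep(NA_character_, n)))

  keys <- unique(drug)
  rows <- lapply(keys, function(d) {
    idx <- which(drug == d)
    tiers <- NULL
    if (any(has_tier[idx])) {
      ti <- idx[has_tier[idx]]
      tiers <- tibble::tibble(max_mg = tier_max[ti], factor = tier_fac[ti])
      if (is.unsorted(tiers$max_mg, strictly = TRUE)) {
        abort(paste0("Tiers for '", d, "' must be sorted strictly ascending by max_mg"))
      }
      if (!is.infinite(tiers$max_mg[nrow(tiers)])) {
        abort(paste0("Tiers for '", d, "' must end with an open (Inf) tier"))
      }
    }
    tibble::tibble(
      drug = d,
      factor = if (is.null(tiers)) factor_num[idx[1]] else NA_real_,
      is_opioid = is_opioid[idx[1]],
      schedule = schedule_all[idx[1]],
      synonyms = list(unique(unlist(synonyms_all[idx]))),
      tiers = list(tiers)
    )
  })
  tab <- dplyr::bind_rows(rows)

  dup_syn <- unlist(tab$synonyms)
  if (anyDuplicated(dup_syn) > 0 || any(dup_syn %in% tab$drug)) {
    abort("Conversion table synonyms must be unique and distinct from drug names")
  }
  if ("morphine" %in% tab$drug && !isTRUE(tab$factor[tab$drug == "morphine"] == 1)) {
    abort("morphine must have conversion factor exactly 1 (MME is defined in morphine units)")
  }

  version <- sub("^.*_v([0-9]+)\\.[A-Za-z]+$", "v\\1", basename(path))
  if (identical(version, basename(path))) version <- "unversioned"
  structure(tab, class = c("mme_table", class(tab)),
            version = version, source_path = path)
}

#' Version string of a conversion table
#' @param table an `mme_table` from [load_conversion_table()].
#' @return the version label, e.g. `"v1"`.
#' @export
table_version <- function(table) attr(table, "version") %||% "unversioned"

# internal: map free-text drug names to canonical table rows.
# Returns integer indices into `table` (NA for unresolved).
resolve_drug <- function(drug, table) {
  key <- tolower(trimws(drug))
  idx <- match(key, table$drug)
  syn_map <- rep(seq_len(nrow(table)), lengths(table$synonyms))
  syn_idx <- match(key, unlist(table$synonyms))
  ifelse(is.na(idx), syn_map[syn_idx], idx)
}

# internal: factor for a tiered drug given its total daily mg
tiered_factor <- function(tiers, daily_mg) {
  tiers$factor[which(daily_mg <= tiers$max_mg)[1]]
}

#' Compute total daily MME for one visit's prescriptions
#'
#' Sums `strength_mg * doses_per_day * factor` over all opioid records.
#' Over-the-counter records (`is_otc = TRUE`) and non-opioid drugs
#' contribute 0. For tiered drugs (methadone) the factor is selected by the
#' drug's total daily mg across all of its records, following CDC practice.
#' For combination products (e.g. Norco = hydrocodone-acetaminophen) enter
#' only the opioid component's mg in `strength_mg`.
#'
#' @param prescriptions a data frame with columns `drug`, `strength_mg`,
#'   `doses_per_day`, and optionally `is_otc` (default `FALSE`) and `usage`.
#'   An empty or `NULL` prescription list yields 0.
#' @param table conversion table from [load_conversion_table()].
#' @return a single non-negative number: the visit's daily MME.
#' @export
#' @examples
#' tab <- load_conversion_table()
#' rx <- tibble::tibble(drug = "Norco", strength_mg = 5, doses_per_day = 4)
#' compute_daily_mme(rx, tab)   # 20: hydrocodone factor is 1
compute_daily_mme <- function(prescriptions, table = load_conversion_table()) {
  if (is.null(prescriptions) || nrow(prescriptions) == 0) {
    return(0)
  }
  req <- c("drug", "strength_mg", "doses_per_day")
  missing_cols <- setdiff(req, names(prescriptions))
  if (length(missing_cols) > 0) {
    abort(paste0("Prescription records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rx <- tibble::as_tibble(prescriptions)
  if (!"is_otc" %in% names(rx)) rx$is_otc <- FALSE
  rx$is_otc[is.na(rx$is_otc)] <- FALSE

  if (any(is.na(rx$doses_per_day)) || any(rx$doses_per_day < 0)) {
    abort("doses_per_day must be non-negative")
  }

  rx <- rx[!rx$is_otc, , drop = FALSE]
  if (nrow(rx) == 0) return(0)

  idx <- resolve_drug(rx$drug, table)
  if (anyNA(idx)) {
    abort(paste0("Unresolvable drug name(s) in prescription list: ",
                 paste(unique(rx$drug[is.na(idx)]), collapse = ", "),
                 ". Add them to the conversion table or flag them is_otc."))
  }
  opioid <- table$is_opioid[idx]
  if (any(opioid & (is.na(rx$strength_mg) | rx$strength_mg <= 0))) {
    abort("strength_mg must be positive for opioid prescriptions")
  }
  if (!any(opioid)) return(0)

  rx <- rx[opioid, , drop = FALSE]
  idx <- idx[opioid]
  daily_mg <- rx$strength_mg * rx$doses_per_day

  total <- 0
  for (i in unique(idx)) {
    mg <- sum(daily_mg[idx == i])
    tiers <- table$tiers[[i]]
    f <- if (is.null(tiers)) table$factor[i] else tiered_factor(tiers, mg)
    total <- total + mg * f
  }
  total
}
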