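COHORT_COLUMNS <- c("patient_id", "period", "ipa", "gender", "age",
                    "procedure", "drug", "strength_mg", "doses_per_day",
                    "usage", "is_otc")

#' Write a cohort to CSV
#'
#' Flattens the prescriptions list-column into one row per prescription
#' (visit-level keys repeat; visits without medication get a single row
#' with empty drug fields). The schema is the registry-export emulation
#' used throughout the package:
#' `patient_id,period,ipa,gender,age,procedure,drug,strength_mg,doses_per_day,usage,is_otc`.
#'
#' @param visits a cohort tibble with a `prescriptions` list-column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(visits, path) {
  field <- function(v, nm, default) {
    if (nm %in% names(v)) v[[nm]] else default
  }
  rows <- lapply(seq_len(nrow(visits)), function(i) {
    v <- visits[i, ]
    rx <- v$prescriptions[[1]]
    base <- tibble::tibble(
      patient_id = v$patient_id, period = v$period, ipa = v$ipa,
      gender = field(v, "gender", NA_character_),
      age = field(v, "age", NA_integer_),
      procedure = field(v, "procedure", NA_character_)
    )
    if (is.null(rx) || nrow(rx) == 0) {
      dplyr::bind_cols(base, tibble::tibble(
        drug = NA_character_, strength_mg = NA_real_,
        doses_per_day = NA_real_, usage = NA_character_, is_otc = NA
      ))
    } else {
      dplyr::bind_cols(base[rep(1, nrow(rx)), ], rx)
    }
  })
  flat <- dplyr::bind_rows(rows)
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema and field domains and regroups prescription rows
#' into one visit row per patient-period with a `prescriptions`
#' list-column. Error messages name the offending column or CSV line.
#'
#' @param path cohort CSV path (schema as written by [write_cohort()]).
#' @return a cohort tibble suitable for [augment_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  flat <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  required <- c("patient_id", "period", "ipa", "drug", "strength_mg",
                "doses_per_day", "is_otc")
  missing_cols <- setdiff(required, names(flat))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  line <- seq_len(nrow(flat)) + 1L  # header is line 1

  num_or_stop <- function(col, what, allow_na = TRUE) {
    out <- suppressWarnings(as.numeric(flat[[col]]))
    bad <- which(!is.na(flat[[col]]) & nzchar(flat[[col]]) & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("Unparseable ", what, " '", flat[[col]][bad[1]],
                   "' on line ", line[bad[1]], " of ", path))
    }
    out
  }
  ipa <- num_or_stop("ipa", "IPA value")
  bad_ipa <- which(!is.na(ipa) & !(ipa %in% 0:2))
  if (length(bad_ipa) > 0) {
    abort(paste0("IPA value out of range (must be 0, 1 or 2) on line ",
                 line[bad_ipa[1]], " of ", path))
  }
  bad_per <- which(!(flat$period %in% DIPA_PERIODS))
  if (length(bad_per) > 0) {
    abort(paste0("Unknown period '", flat$period[bad_per[1]], "' on line ",
                 line[bad_per[1]], " of ", path, " (expected ",
                 paste(DIPA_PERIODS, collapse = "/"), ")"))
  }
  strength <- num_or_stop("strength_mg", "strength_mg")
  doses <- num_or_stop("doses_per_day", "doses_per_day")
  bad_dose <- which(!is.na(doses) & doses < 0)
  if (length(bad_dose) > 0) {
    abort(paste0("Negative doses_per_day on line ", line[bad_dose[1]],
                 " of ", path))
  }
  age <- if ("age" %in% names(flat)) num_or_stop("age", "age") else NA_real_

  flat$.ipa <- as.integer(ipa)
  flat$.strength <- strength
  flat$.doses <- doses
  flat$.age <- age
  flat$.otc <- toupper(trimws(flat$is_otc)) %in% c("TRUE", "T", "1", "YES")
  flat$.key <- paste(flat$patient_id, flat$period, sep = "\r")

  keys <- unique(flat$.key)
  rows <- lapply(keys, function(k) {
    g <- flat[flat$.key == k, , drop = FALSE]
    has_rx <- !is.na(g$drug) & nzchar(g$drug)
    rx <- if (any(has_rx)) {
      tibble::tibble(
        drug = g$drug[has_rx], strength_mg = g$.strength[has_rx],
        doses_per_day = g$.doses[has_rx],
        usage = if ("usage" %in% names(g)) g$usage[has_rx] else NA_character_,
        is_otc = g$.otc[has_rx]
      )
    } else {
      empty_prescriptions()
    }
    tibble::tibble(
      patient_id = g$patient_id[1], period = g$period[1], ipa = g$.ipa[1],
      gender = if ("gender" %in% names(g)) g$gender[1] else NA_character_,
      age = g$.age[1],
      procedure = if ("procedure" %in% names(g)) g$procedure[1] else NA_character_,
      prescriptions = list(rx)
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a longitudinal DIPA report
#'
#' Derives per-visit MME, class and rating, summarizes every period, and
#' attaches provenance metadata (conversion-table version, boundaries,
#' seed if the cohort carries one, an input content hash, timestamp).
#'
#' @param visits a cohort tibble (raw or already augmented).
#' @param table conversion table.
#' @param boundaries class boundaries.
#' @return a `dipa_report` object: list with `summaries` (tibble, one
#'   row per period), `visits` (augmented), `boundaries`, `metadata`.
#' @export
#' @examples
#' rep <- dipa_report(generate_cohort(seed = 1))
#' rep$summaries[, c("period", "efficiency_score", "pct_on_narcotics")]
dipa_report <- function(visits, table = load_conversion_table(),
                        boundaries = operational_boundaries()) {
  aug <- augment_cohort(visits, table = table, boundaries = boundaries)
  summaries <- summarize_cohort(aug)
  metadata <- list(
    table_version = table_version(table),
    boundaries_source = boundaries$source,
    seed = attr(visits, "seed"),
    input_hash = hash(list(visits$patient_id, visits$period, visits$ipa,
                           visits$prescriptions)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("dipa")),
    schema_version = "1"
  )
  structure(list(summaries = summaries, visits = aug,
                 boundaries = boundaries, metadata = metadata),
            class = "dipa_report")
}

#' @export
print.dipa_report <- function(x, ...) {
  cat("DIPA longitudinal report (", nrow(x$visits), " visits, table ",
      x$metadata$table_version, ")\n\n", sep = "")
  s <- x$summaries
  out <- data.frame(
    period = s$period, n = s$n,
    efficiency = sprintf("%.2f%%", s$efficiency_score),
    on_narcotics = sprintf("%.2f%%", s$pct_on_narcotics),
    mean_MME = sprintf("%.2f", s$mean_mme)
  )
  print(out, row.names = FALSE)
  invisible(x)
}

#' Serialize a DIPA report to JSON
#'
#' @param report a `dipa_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "dipa_report"))
  s <- report$summaries
  body <- list(
    schema = "dipa-report/1",
    metadata = report$metadata,
    boundaries = unclass(report$boundaries),
    periods = lapply(seq_len(nrow(s)), function(i) {
      list(period = s$period[i], n = s$n[i],
           efficiency_score = s$efficiency_score[i],
           pct_on_narcotics = s$pct_on_narcotics[i],
           mean_mme = s$mean_mme[i],
           mean_mme_narcotic = s$mean_mme_narcotic[i],
           class_distribution = list(A = s$p_A[i], B = s$p_B[i],
                                     C = s$p_C[i], D = s$p_D[i],
                                     E = s$p_E[i]),
           ipa_by_class = s$ipa_by_class[[i]])
    })
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# internal: open the right graphics device for a file extension
open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = if (capabilities("cairo")) {
           grDevices::png(path, width = width, height = height,
                          units = "in", res = 150, type = "cairo")
         } else {
           grDevices::png(path, width = width, height = height,
                          units = "in", res = 150)
         },
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         abort(paste0("Unsupported figure format: .", ext,
                      " (use png, svg or pdf)")))
}

#' Render the longitudinal DIPA graph
#'
#' One panel per the scale's graphical summary: stacked per-period
#' medication-class shares (A-E), the provider efficiency score as a
#' labeled line, and mean daily MME as a second line rescaled onto a
#' secondary axis.
#'
#' @param report a `dipa_report` with at least one period.
#' @param out output file (`.png`, `.svg` or `.pdf`).
#' @param width,height figure size in inches.
#' @return `out`, invisibly.
#' @export
render_dipa_graph <- function(report, out, width = 8, height = 5) {
  stopifnot(inherits(report, "dipa_report"))
  s <- report$summaries
  if (nrow(s) == 0) abort("Report has no periods to plot")

  shares <- s |>
    dplyr::select("period", dplyr::all_of(paste0("p_", DIPA_CLASSES))) |>
    tidyr::pivot_longer(-"period", names_to = "class",
                        names_prefix = "p_", values_to = "share")
  shares$period <- period_factor(shares$period)
  shares$class <- factor(shares$class, levels = rev(DIPA_CLASSES))

  mme_max <- max(s$mean_mme, 1)
  lines <- tibble::tibble(
    period = period_factor(s$period),
    efficiency = s$efficiency_score,
    mme_scaled = 100 * s$mean_mme / mme_max
  )

  p <- ggplot2::ggplot(shares,
                       ggplot2::aes(x = .data$period, y = 100 * .data$share,
                                    fill = .data$class)) +
    ggplot2::geom_col(width = 0.6, alpha = 0.85) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               name = "Class") +
    ggplot2::geom_line(data = lines, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$period, y = .data$efficiency,
                                    group = 1, colour = "Efficiency score"),
                       linewidth = 1) +
    ggplot2::geom_point(data = lines, inherit.aes = FALSE,
                        ggplot2::aes(x = .data$period, y = .data$efficiency,
                                     colour = "Efficiency score")) +
    ggplot2::geom_text(data = lines, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$period, y = .data$efficiency,
                                    label = sprintf("%.1f%%", .data$efficiency)),
                       vjust = -1, size = 3) +
    ggplot2::geom_line(data = lines, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$period, y = .data$mme_scaled,
                                    group = 1, colour = "Mean MME"),
                       linetype = "dashed", linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("Efficiency score" = "#D55E00",
                                            "Mean MME" = "#009E73"),
                                 name = NULL) +
    ggplot2::scale_y_continuous(
      name = "Class share / efficiency score (%)",
      limits = c(0, 110),
      sec.axis = ggplot2::sec_axis(~ . * mme_max / 100,
                                   name = "Mean daily MME")
    ) +
    ggplot2::labs(x = "Post-operative period",
                  title = "DIPA longitudinal summary") +
    ggplot2::theme_minimal()

  open_device(out, width, height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out)
}

#' Render the medication-class MME boxplot
#'
#' Box-and-whisker plot of daily MME per narcotic class with an 'X' mean
#' marker and 1.5*IQR outliers drawn as open circles, mirroring the
#' scale's class-range figure.
#'
#' @param mmes_by_class named list mapping class letters to MME vectors
#'   (at least one narcotic class non-empty).
#' @param out output file (`.png`, `.svg` or `.pdf`).
#' @param width,height figure size in inches.
#' @return `out`, invisibly.
#' @export
render_class_boxplot <- function(mmes_by_class, out, width = 6, height = 5) {
  mmes_by_class <- mmes_by_class[vapply(mmes_by_class, length, integer(1)) > 0]
  if (length(mmes_by_class) == 0) {
    abort("At least one class must have MME observations")
  }
  df <- tibble::tibble(
    class = class_factor(rep(names(mmes_by_class),
                             lengths(mmes_by_class))),
    mme = unlist(mmes_by_class, use.names = FALSE)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$mme)) +
    ggplot2::geom_boxplot(outlier.shape = 1, outlier.size = 2,
                          fill = "#9ECAE1", coef = 1.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3,
                          stroke = 1.2) +
    ggplot2::labs(x = "Medication class", y = "Daily MME",
                  title = "Daily MME by medication class",
                  subtitle = "X = class mean; o = 1.5×IQR outliers") +
    ggplot2::theme_minimal()

  open_device(out, width, height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out)
}
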