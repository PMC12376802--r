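#' Default cohort CSV schema
#'
#' Maps the canonical participant fields to the column names expected in a
#' cohort CSV. Override individual entries to read files with different
#' headers, e.g. `cohort_schema(asthma = "diagnosis")`.
#'
#' Required fields: `id`, `asthma` (reference-standard diagnosis), `feno`
#' (ppb), `ige` (IU/mL), `bec` (cells/uL), `prick` (skin prick positivity).
#' Optional covariates: `sex`, `weight` (kg), `fev1_pct` (% predicted).
#'
#' @param ... named overrides of the default column names.
#' @return named character vector mapping field -> column name.
#' @export
#' @examples
#' cohort_schema()
#' cohort_schema(asthma = "dx", prick = "spt_pos")
cohort_schema <- function(...) {
  schema <- c(
    id = "id", asthma = "asthma", feno = "feno", ige = "ige",
    bec = "bec", prick = "prick", sex = "sex", weight = "weight",
    fev1_pct = "fev1_pct"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) {
      th2_stop(sprintf("unknown schema field(s): %s",
                       paste(bad, collapse = ", ")), "th2_schema_error")
    }
    schema[names(dots)] <- dots
  }
  schema
}

# fields that must be present and complete in every analysed row
.required_fields <- c("id", "asthma", "feno", "ige", "bec", "prick")
.optional_fields <- c("sex", "weight", "fev1_pct")

# internal: liberal boolean parser (0/1, true/false, yes/no, T/F)
parse_boolean <- function(x, what = "value") {
  if (is.logical(x)) return(x)
  raw <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(raw))
  out[raw %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[raw %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- which(!is.na(raw) & raw != "" & is.na(out))
  if (length(bad)) {
    th2_stop(sprintf("cannot parse %s as boolean at row(s) %s: %s",
                     what, paste(utils::head(bad, 5), collapse = ", "),
                     paste(utils::head(raw[bad], 5), collapse = ", ")),
             "th2_parse_error")
  }
  out[raw == ""] <- NA
  out
}

#' Construct a validated cohort
#'
#' A cohort is a data frame of participants with columns
#' `id, asthma, feno, ige, bec, prick` (+ optional `sex, weight, fev1_pct`),
#' carrying class `th2_cohort` and a free-text `provenance` attribute.
#'
#' Validation enforces: unique ids; non-negative biomarkers; booleans for
#' `asthma` and `prick`; positive `weight`/`fev1_pct` where present.
#'
#' @param df data frame with canonical column names.
#' @param provenance free-text label recorded on the object.
#' @param strict if TRUE (default) rows with missing required values are an
#'   error; if FALSE they are dropped with a warning giving the count.
#' @return a `th2_cohort` data frame.
#' @export
as_cohort <- function(df, provenance = "unspecified", strict = TRUE) {
  if (!is.data.frame(df)) th2_stop("cohort input must be a data frame", "th2_type_error")
  if (nrow(df) == 0L) th2_stop("cohort is empty", "th2_empty_input")
  missing_cols <- setdiff(.required_fields, names(df))
  if (length(missing_cols)) {
    th2_stop(sprintf("missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")), "th2_schema_error")
  }

  df$id <- as.character(df$id)
  df$asthma <- parse_boolean(df$asthma, "asthma")
  df$prick <- parse_boolean(df$prick, "prick")
  for (v in c("feno", "ige", "bec")) df[[v]] <- as.numeric(df[[v]])

  incomplete <- !stats::complete.cases(df[.required_fields])
  if (any(incomplete)) {
    if (strict) {
      th2_stop(sprintf("%d row(s) have missing required values (first at row %d)",
                       sum(incomplete), which(incomplete)[1]), "th2_row_error")
    }
    warning(sprintf("dropping %d row(s) with missing required values", sum(incomplete)),
            call. = FALSE)
    df <- df[!incomplete, , drop = FALSE]
    if (nrow(df) == 0L) th2_stop("all rows dropped during validation", "th2_empty_input")
  }

  if (anyDuplicated(df$id)) {
    th2_stop("participant ids are not unique", "th2_row_error")
  }
  neg <- vapply(c("feno", "ige", "bec"), function(v) any(df[[v]] < 0), logical(1))
  if (any(neg)) {
    th2_stop(sprintf("negative biomarker value(s) in: %s",
                     paste(names(neg)[neg], collapse = ", ")), "th2_row_error")
  }
  for (v in c("weight", "fev1_pct")) {
    if (v %in% names(df)) {
      df[[v]] <- as.numeric(df[[v]])
      if (any(!is.na(df[[v]]) & df[[v]] <= 0)) {
        th2_stop(sprintf("non-positive %s", v), "th2_row_error")
      }
    }
  }
  if ("sex" %in% names(df) && !all(is.na(df$sex))) {
    sx <- tolower(trimws(as.character(df$sex)))
    sx[sx %in% c("m", "male")] <- "male"
    sx[sx %in% c("f", "female")] <- "female"
    if (any(!is.na(sx) & !sx %in% c("male", "female"))) {
      th2_stop("sex must be male/female (m/f accepted)", "th2_parse_error")
    }
    df$sex <- sx
  }

  rownames(df) <- NULL
  structure(df, class = c("th2_cohort", "data.frame"), provenance = provenance)
}

#' Read a cohort CSV
#'
#' Reads an RFC 4180 CSV with a header row, renames columns according to
#' `schema`, and validates the result (see [as_cohort()]).
#'
#' @param path path to a CSV file.
#' @param schema column-name mapping from [cohort_schema()].
#' @param strict if FALSE, rows with missing required biomarker values are
#'   dropped with a warning rather than rejected.
#' @return a `th2_cohort`.
#' @export
read_cohort <- function(path, schema = cohort_schema(), strict = TRUE) {
  if (!file.exists(path)) th2_stop(sprintf("file not found: %s", path), "th2_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) th2_stop(sprintf("no data rows in %s", path), "th2_empty_input")
  required_cols <- schema[.required_fields]
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    th2_stop(sprintf("missing column(s) in %s: %s", path,
                     paste(missing_cols, collapse = ", ")), "th2_schema_error")
  }
  present <- schema[schema %in% names(df)]
  out <- df[, present, drop = FALSE]
  names(out) <- names(present)
  as_cohort(out, provenance = path, strict = strict)
}

#' Write a cohort CSV
#'
#' Emits the canonical schema (plus any extra columns such as appended
#' scores) so that `read_cohort(write_cohort(x))` round-trips.
#'
#' @param cohort a `th2_cohort` (or scored cohort).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.th2_cohort <- function(x, ...) {
  cc <- cohort_counts(x)
  cat(sprintf("<th2_cohort> %d participants (%d asthma, %d no asthma; prevalence %s)\n",
              cc$n_total, cc$n_pos, cc$n_neg, render_percent(cc$prevalence, 0)))
  cat(sprintf("provenance: %s\n", attr(x, "provenance")))
  NextMethod()
}

#' Descriptive summary of one group of values
#'
#' Mean, sample SD (n-1 denominator), median and quartiles, matching the
#' "mean +/- SD or median (IQR)" presentation of clinical characteristics
#' tables. Quartiles use linear interpolation between order statistics
#' (quantile type 7, the common software default) unless overridden.
#'
#' @param values numeric vector, n >= 1, no NAs.
#' @param quartile_type passed to [stats::quantile()] `type` (default 7).
#' @return object of class `group_summary`: list with `n, mean, sd, median,
#'   q1, q3`. For n = 1 the SD is 0 by convention.
#' @export
#' @examples
#' summarize_group(c(1, 2, 3, 4, 5))
summarize_group <- function(values, quartile_type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0L) th2_stop("empty input", "th2_empty_input")
  if (anyNA(values)) th2_stop("missing values in group", "th2_row_error")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = quartile_type))
  structure(list(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) == 1L) 0 else stats::sd(values),
    median = q[2], q1 = q[1], q3 = q[3]
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat(sprintf("n = %d | mean %s +/- %s | median %s (IQR %s-%s)\n",
              x$n, signif(x$mean, digits), signif(x$sd, digits),
              signif(x$median, digits), signif(x$q1, digits), signif(x$q3, digits)))
  invisible(x)
}

#' Cohort composition counts
#'
#' @param cohort a `th2_cohort`.
#' @return list with `n_total`, `n_pos`, `n_neg`, `prevalence` (a fraction)
#'   and `prevalence_pct` (integer-percent rendering, half-up).
#' @export
#' @examples
#' \dontrun{cohort_counts(cohort)  # 22/48 -> prevalence 0.458, "46%"}
cohort_counts <- function(cohort) {
  if (!inherits(cohort, "th2_cohort")) cohort <- as_cohort(cohort)
  n <- nrow(cohort)
  if (n == 0L) th2_stop("empty cohort", "th2_empty_input")
  n_pos <- sum(cohort$asthma)
  list(
    n_total = n, n_pos = n_pos, n_neg = n - n_pos,
    prevalence = n_pos / n,
    prevalence_pct = render_percent(n_pos / n, digits = 0)
  )
}
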