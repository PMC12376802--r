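#' Dichotomization cutoffs for the Th2 biomarker panel
#'
#' The composite score dichotomizes each continuous marker at a predefined
#' clinical cutoff, scoring 1 when the value is at or above it (inclusive
#' ">="): BEC >= 150 cells/uL, total IgE >= 100 IU/mL, FENO >= 25 ppb.
#' Skin prick positivity contributes its own 0/1 indicator directly.
#'
#' @param bec_cutoff cells/uL (default 150).
#' @param ige_cutoff IU/mL (default 100).
#' @param feno_cutoff ppb (default 25).
#' @return object of class `cutoff_config`.
#' @export
cutoff_config <- function(bec_cutoff = 150, ige_cutoff = 100, feno_cutoff = 25) {
  for (v in c(bec_cutoff, ige_cutoff, feno_cutoff)) {
    if (!is_scalar_number(v) || v <= 0) {
      th2_stop("all cutoffs must be positive scalars", "th2_argument_error")
    }
  }
  structure(list(bec_cutoff = bec_cutoff, ige_cutoff = ige_cutoff,
                 feno_cutoff = feno_cutoff, comparison = ">="),
            class = "cutoff_config")
}

#' @export
print.cutoff_config <- function(x, ...) {
  cat(sprintf("<cutoff_config> BEC >= %g cells/uL | IgE >= %g IU/mL | FENO >= %g ppb | prick positive\n",
              x$bec_cutoff, x$ige_cutoff, x$feno_cutoff))
  invisible(x)
}

#' Dichotomize the four-biomarker panel
#'
#' Vectorized over participants. Each continuous indicator is 1 iff the
#' value is >= its cutoff; the prick indicator copies the prick result.
#'
#' @param feno,ige,bec numeric biomarker vectors (no NAs allowed).
#' @param prick logical prick-positivity vector.
#' @param cfg a [cutoff_config()].
#' @return data frame of 0/1 integer columns
#'   `feno_high, ige_high, bec_high, prick_high`.
#' @export
#' @examples
#' dichotomize(feno = 25, ige = 100, bec = 150, prick = TRUE)  # all 1
dichotomize <- function(feno, ige, bec, prick, cfg = cutoff_config()) {
  args <- list(feno = feno, ige = ige, bec = bec, prick = prick)
  for (nm in names(args)) {
    if (anyNA(args[[nm]])) {
      th2_stop(sprintf("missing biomarker value(s): %s", nm), "th2_missing_data")
    }
  }
  n <- length(feno)
  if (any(lengths(args) != n)) th2_stop("biomarker vectors must have equal length", "th2_argument_error")
  data.frame(
    feno_high = as.integer(feno >= cfg$feno_cutoff),
    ige_high = as.integer(ige >= cfg$ige_cutoff),
    bec_high = as.integer(bec >= cfg$bec_cutoff),
    prick_high = as.integer(as.logical(prick))
  )
}

#' Sum an indicator set into the composite 0-4 score
#'
#' @param indicators a data frame from [dichotomize()] (or any 4-column 0/1
#'   structure with one row per participant).
#' @return integer vector of scores in 0..4.
#' @export
composite_score <- function(indicators) {
  m <- as.matrix(indicators)
  if (ncol(m) != 4L) th2_stop("indicator set must have exactly 4 components", "th2_argument_error")
  if (!all(m %in% c(0L, 1L))) th2_stop("indicators must be 0/1", "th2_argument_error")
  as.integer(rowSums(m))
}

#' Classify a composite score at a threshold
#'
#' Test-positive iff `score >= threshold`. Under this single convention the
#' two usual operating points are `threshold = 2` ("2 points") and
#' `threshold = 3` (">2 points").
#'
#' @param score integer vector of composite scores (0..4).
#' @param threshold integer in 1..4.
#' @return logical vector, TRUE = test positive.
#' @export
#' @examples
#' classify(3, threshold = 3)  # TRUE
#' classify(2, threshold = 3)  # FALSE
classify <- function(score, threshold) {
  if (!is_scalar_number(threshold) || !threshold %in% 1:4) {
    th2_stop("threshold must be an integer in 1..4", "th2_argument_error")
  }
  score <- as.integer(score)
  if (any(score < 0 | score > 4, na.rm = TRUE)) {
    th2_stop("scores must lie in 0..4", "th2_argument_error")
  }
  score >= threshold
}

#' Score every participant in a cohort
#'
#' Appends the four 0/1 indicator columns and `composite_score` to the
#' cohort. Participants with a missing panel component are excluded with a
#' warning (never imputed); partial scores are not produced.
#'
#' @param cohort a `th2_cohort`.
#' @param cfg a [cutoff_config()].
#' @return the cohort with columns
#'   `feno_high, ige_high, bec_high, prick_high, composite_score` appended.
#' @export
score_cohort <- function(cohort, cfg = cutoff_config()) {
  if (!inherits(cohort, "th2_cohort")) cohort <- as_cohort(cohort)
  complete <- stats::complete.cases(cohort[, c("feno", "ige", "bec", "prick")])
  if (!all(complete)) {
    warning(sprintf("excluding %d participant(s) with an incomplete biomarker panel",
                    sum(!complete)), call. = FALSE)
    cohort <- cohort[complete, , drop = FALSE]
  }
  iv <- dichotomize(cohort$feno, cohort$ige, cohort$bec, cohort$prick, cfg)
  out <- cbind(as.data.frame(cohort), iv)
  out$composite_score <- composite_score(iv)
  structure(out, class = c("th2_cohort", "data.frame"),
            provenance = attr(cohort, "provenance"))
}
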