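#' WHO follicular-lymphoma grade from a centroblast count
#'
#' WHO bands: grade I for 0-5 CBs per high-power field, grade II for 6-15,
#' grade III above 15. Real-valued mean counts are compared directly to the
#' interval edges (a mean of 5.4 exceeds 5 and is therefore grade II); the
#' bands partition `[0, Inf)` as I: `[0, 5]`, II: `(5, 15]`, III: `(15, Inf)`.
#'
#' @param count non-negative CB count (vectorized; may be fractional when it
#'   is a mean over fields).
#' @return Factor with levels `I`, `II`, `III`.
#' @examples
#' who_grade(c(3, 10, 16)) # I, II, III
#' @export
who_grade <- function(count) {
  if (any(count < 0)) stop("count must be non-negative")
  cut(count, breaks = c(-Inf, 5, 15, Inf), labels = c("I", "II", "III"))
}

#' Grade a slide from per-HPF centroblast counts
#'
#' Averages CB counts over the provided high-power fields (conventionally 10)
#' and applies the WHO bands to the mean. A number of fields different from
#' `expected_n` triggers a warning, not a failure.
#'
#' @param hpf_counts non-negative CB counts, one per high-power field.
#' @param expected_n conventional number of fields (default 10).
#' @return An object of class `cb_grade_report`: `hpf_counts`, `mean_count`,
#'   `grade`.
#' @examples
#' grade_slide(c(0, 0, 0, 0, 0, 20, 20, 20, 20, 20)) # mean 10 -> grade II
#' @export
grade_slide <- function(hpf_counts, expected_n = 10L) {
  if (!length(hpf_counts)) stop("no HPF counts supplied")
  if (any(hpf_counts < 0)) stop("counts must be non-negative")
  if (length(hpf_counts) != expected_n)
    warning("grading from ", length(hpf_counts), " HPFs (conventional: ",
            expected_n, ")", call. = FALSE)
  m <- mean(hpf_counts)
  structure(list(hpf_counts = hpf_counts, mean_count = m,
                 grade = who_grade(m)),
            class = "cb_grade_report")
}

#' @export
print.cb_grade_report <- function(x, ...) {
  cat(sprintf("<cb_grade_report n_hpf=%d mean=%.2f grade=%s>\n",
              length(x$hpf_counts), x$mean_count, as.character(x$grade)))
  invisible(x)
}

#' Tabulate a cohort's grade distribution
#'
#' Counts and one-decimal percentages per grade label (labels `1`, `2`, `3`,
#' `3a`, `3b` are accepted) plus the conventional low-grade grouping
#' `{1, 2}` and the grade-3 grouping `{3, 3a, 3b}`.
#'
#' @param case_grades character vector, one grade label per case.
#' @return A list: `by_label` and `groups`, each a data.frame with `n` and
#'   `pct` columns.
#' @examples
#' tabulate_grades(rep(c("1", "2", "3", "3a", "3b"), c(49, 21, 2, 12, 3)))
#' @export
tabulate_grades <- function(case_grades) {
  allowed <- c("1", "2", "3", "3a", "3b")
  case_grades <- as.character(case_grades)
  bad <- setdiff(unique(case_grades), allowed)
  if (length(bad)) stop("unknown grade label(s): ", paste(bad, collapse = ", "))
  n <- length(case_grades)
  tab <- table(factor(case_grades, levels = allowed))
  pct <- round(100 * as.numeric(tab) / n, 1)
  by_label <- data.frame(grade = allowed, n = as.integer(tab), pct = pct)
  g12 <- sum(tab[c("1", "2")])
  g3 <- sum(tab[c("3", "3a", "3b")])
  groups <- data.frame(group = c("grades 1-2", "grade 3 (any)"),
                       n = c(g12, g3),
                       pct = round(100 * c(g12, g3) / n, 1))
  list(by_label = by_label, groups = groups, n_cases = n)
}

#' Centroblast count of a patch from detections
#'
#' Number of class-0 detections at or above a confidence cut (default 0.25,
#' the customary reporting threshold of the detection tooling this package
#' interoperates with). Note that one 512-px patch at 0.12 um/px is a 61.4 um
#' square — much smaller than a conventional microscope high-power field — so
#' mapping patch counts to HPF counts requires an explicit aggregation factor
#' chosen by the user (see the package vignette).
#'
#' @param dets detection box `data.frame`.
#' @param conf_threshold minimum confidence (default 0.25).
#' @return Integer count.
#' @export
count_cb <- function(dets, conf_threshold = 0.25) {
  sum(dets$class_id == CB_CLASS &
        (is.na(dets$confidence) | dets$confidence >= conf_threshold))
}
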