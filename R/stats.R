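#' @include AllClasses.R
NULL

#' Two-sample t test (closed form)
#'
#' Independent two-sample, two-sided t test implemented from the closed
#' form: pooled-variance (Student) by default, matching the default
#' behavior of the standard independent-samples t routine, or Welch when
#' \code{equalVariance = FALSE}. The p value comes from the t
#' distribution's survival function.
#'
#' The degenerate case of zero variance in both groups with equal means is
#' reported as t = 0, p = 1 with a \code{degenerate} flag rather than NaN.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param equalVariance Pooled-variance test if TRUE (default), Welch
#'   otherwise.
#' @return List with \code{t}, \code{p}, \code{df}, \code{mean_a},
#'   \code{mean_b}, \code{n_a}, \code{n_b}, \code{degenerate}.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(a, b, equalVariance = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means: p = 1 by convention")
      return(list(t = 0, p = 1, df = na + nb - 2, mean_a = mean(a),
                  mean_b = mean(b), n_a = na, n_b = nb, degenerate = TRUE))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  if (equalVariance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, df = df, mean_a = mean(a), mean_b = mean(b),
       n_a = na, n_b = nb, degenerate = degenerate)
}

#' Significance label for a p value
#'
#' The conventional star mapping: "n.s." for p > 0.05, "*" for p < 0.05,
#' "**" for p < 0.01, "***" for p < 0.001. The boundary p = 0.05 maps to
#' "n.s." (labels are strict inequalities). The threshold vector is
#' configurable; some figure conventions use 0.005 instead of 0.001 for
#' the third star.
#'
#' @param p p value(s) in [0, 1].
#' @param thresholds Decreasing significance thresholds for *, **, ***
#'   (default c(0.05, 0.01, 0.001)).
#' @return Character vector over \{"n.s.", "*", "**", "***"\}.
#' @examples
#' significanceLabel(c(0.2, 0.04, 0.0005))
#' @export
significanceLabel <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  if (length(thresholds) != 3 || any(diff(thresholds) >= 0))
    stop("thresholds must be 3 decreasing values")
  out <- ifelse(p < thresholds[3], "***",
         ifelse(p < thresholds[2], "**",
         ifelse(p < thresholds[1], "*", "n.s.")))
  out[is.na(p)] <- NA_character_
  out
}

#' Group summary and comparisons against a control group
#'
#' Per-group n, mean and standard deviation for each value column, plus a
#' two-sample t-test comparison of every non-control group against the
#' named control, with significance labels. Comparison rows are ordered
#' deterministically (group, then column, both in input order).
#'
#' @param records data.frame in long-per-cell layout: one row per cell.
#' @param groupColumn Name of the grouping column.
#' @param valueColumns Character vector of measurement columns.
#' @param control Name of the control group (must exist in the data);
#'   NULL suppresses comparisons (summary only).
#' @param equalVariance Passed to \code{\link{twoSampleT}}.
#' @param thresholds Passed to \code{\link{significanceLabel}}.
#' @return List with \code{summary} (group, variable, n, mean, sd) and
#'   \code{comparisons} (group_a = control, group_b, variable, n_a, n_b,
#'   mean_a, mean_b, t, p, label); \code{comparisons} is empty when
#'   \code{control} is NULL or only one group is present.
#' @export
groupSummary <- function(records, groupColumn, valueColumns, control = NULL,
                         equalVariance = TRUE,
                         thresholds = c(0.05, 0.01, 0.001)) {
  if (!groupColumn %in% names(records))
    stop("unknown group column: ", groupColumn)
  if (!all(valueColumns %in% names(records)))
    stop("unknown value column(s): ",
         paste(setdiff(valueColumns, names(records)), collapse = ", "))
  groups <- unique(as.character(records[[groupColumn]]))
  if (!is.null(control) && !control %in% groups)
    stop("unknown control group: ", control)
  summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- records[records[[groupColumn]] == g, , drop = FALSE]
    do.call(rbind, lapply(valueColumns, function(v) {
      x <- sub[[v]][is.finite(sub[[v]])]
      data.frame(group = g, variable = v, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  comparisons <- data.frame(group_a = character(0), group_b = character(0),
                            variable = character(0), n_a = integer(0),
                            n_b = integer(0), mean_a = numeric(0),
                            mean_b = numeric(0), t = numeric(0),
                            p = numeric(0), label = character(0),
                            stringsAsFactors = FALSE)
  if (!is.null(control) && length(groups) >= 2) {
    ctl <- records[records[[groupColumn]] == control, , drop = FALSE]
    for (g in setdiff(groups, control)) {
      sub <- records[records[[groupColumn]] == g, , drop = FALSE]
      for (v in valueColumns) {
        x <- ctl[[v]][is.finite(ctl[[v]])]
        y <- sub[[v]][is.finite(sub[[v]])]
        tt <- suppressWarnings(
          twoSampleT(x, y, equalVariance = equalVariance))
        comparisons <- rbind(comparisons, data.frame(
          group_a = control, group_b = g, variable = v,
          n_a = tt$n_a, n_b = tt$n_b, mean_a = tt$mean_a,
          mean_b = tt$mean_b, t = tt$t, p = tt$p,
          label = significanceLabel(tt$p, thresholds),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(summary = summary, comparisons = comparisons)
}
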