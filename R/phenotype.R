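#' Summary statistic triple (mean, SEM, n)
#'
#' The unit of every reconstructed two-group test: a group mean, its
#' standard error, and the group size, as printed in results sections
#' ("8.0 +/- 0.3, n = 17"). Fields may be equal-length vectors.
#'
#' @param mean Group mean(s), in trait units (e.g. mM glucose, percent
#'   methylation).
#' @param sem Standard error(s) of the mean; strictly positive.
#' @param n Group size(s); integer >= 2.
#' @return A `summary_stat` object (list of the three validated vectors).
#' @examples
#' summary_stat(8.0, 0.3, 17)
#' @export
summary_stat <- function(mean, sem, n) {
  mean <- as.numeric(mean); sem <- as.numeric(sem); n <- as.numeric(n)
  len <- length(mean)
  if (length(sem) != len || length(n) != len)
    stop("mean, sem and n must have equal length", call. = FALSE)
  if (any(!is.finite(mean)) || any(!is.finite(sem)) || any(!is.finite(n)))
    stop("summary statistics must be finite", call. = FALSE)
  if (any(n < 2) || any(n != floor(n)))
    stop("group size n must be an integer >= 2", call. = FALSE)
  if (any(sem <= 0)) stop("sem must be > 0", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = n), class = "summary_stat")
}

as_summary_stat <- function(x) {
  if (inherits(x, "summary_stat")) return(x)
  if (is.list(x) && all(c("mean", "sem", "n") %in% names(x)))
    return(summary_stat(x$mean, x$sem, x$n))
  stop("expected a summary_stat or a list with mean, sem, n", call. = FALSE)
}

#' Summarize raw values into a (mean, SEM, n) triple
#'
#' @param x Numeric vector of per-individual measurements (NA dropped).
#' @return A [summary_stat()].
#' @export
summarize_values <- function(x) {
  x <- x[!is.na(x)]
  summary_stat(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Two-group t test reconstructed from summary statistics
#'
#' Reconstructs the unpaired two-sample t test from printed (mean, SEM, n)
#' triples. The implied group SD is `sem * sqrt(n)`. `student_pooled` uses
#' the pooled-variance statistic with `n1 + n2 - 2` degrees of freedom;
#' `welch` uses the Welch statistic with Satterthwaite degrees of freedom.
#' Applied to summaries computed from raw data, both reproduce
#' `t.test(var.equal = TRUE)` / `t.test()` exactly.
#'
#' @param case,control [summary_stat()] objects (vectorized over elements).
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return A list with `statistic` (t, positive when case mean exceeds
#'   control mean), `df`, and two-sided `p_value`.
#' @examples
#' two_group_test_from_summary(summary_stat(10.9, 0.9, 14),
#'                             summary_stat(8.0, 0.3, 17))
#' @export
two_group_test_from_summary <- function(case, control,
                                        variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  case <- as_summary_stat(case); control <- as_summary_stat(control)
  m1 <- case$mean; sem1 <- case$sem; n1 <- case$n
  m2 <- control$mean; sem2 <- control$sem; n2 <- control$n
  if (variant == "student_pooled") {
    v1 <- sem1^2 * n1                      # implied group variance
    v2 <- sem2^2 * n2
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- sem1^2 + sem2^2
    se <- sqrt(se2)
    df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Phenotype call for a case group against its control
#'
#' @param label `"hyperglycaemic"`, `"normoglycaemic"` or
#'   `"hypoglycaemic"`.
#' @param p_value Two-sided p of the case-vs-control test.
#' @param direction Sign of (case mean - control mean).
#' @param statistic,df Optional test statistic and degrees of freedom.
#' @return A `phenotype_call` object.
#' @export
phenotype_call <- function(label, p_value, direction, statistic = NA_real_,
                           df = NA_real_) {
  label <- match.arg(label, c("hyperglycaemic", "normoglycaemic", "hypoglycaemic"))
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(label = label, p_value = p_value, direction = direction,
                 statistic = statistic, df = df),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s (t = %.3f, df = %.1f, p = %.4g, direction %+d)\n",
              x$label, x$statistic, x$df, x$p_value, x$direction))
  invisible(x)
}

#' Classify glycaemic phenotype from summary statistics
#'
#' A model is called hyperglycaemic when its fasting-glucose mean is
#' significantly above control, hypoglycaemic when significantly below, and
#' normoglycaemic otherwise, using [two_group_test_from_summary()].
#'
#' @inheritParams two_group_test_from_summary
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return A [phenotype_call()].
#' @examples
#' classify_glycaemia(summary_stat(9.4, 0.5, 23), summary_stat(13.6, 0.6, 23))
#' @export
classify_glycaemia <- function(case, control, alpha = 0.05,
                               variant = c("student_pooled", "welch")) {
  stopifnot(alpha > 0, alpha < 1)
  variant <- match.arg(variant)
  case <- as_summary_stat(case); control <- as_summary_stat(control)
  stopifnot(length(case$mean) == 1L, length(control$mean) == 1L)
  ts <- two_group_test_from_summary(case, control, variant)
  dir <- sign(case$mean - control$mean)
  label <- if (ts$p_value < alpha && dir > 0) "hyperglycaemic"
  else if (ts$p_value < alpha && dir < 0) "hypoglycaemic"
  else "normoglycaemic"
  phenotype_call(label, ts$p_value, dir, ts$statistic, ts$df)
}

#' Two-group test on raw per-individual values
#'
#' For per-animal input tables: Student/Welch t or the Mann-Whitney
#' (Wilcoxon rank-sum) test, which cannot be reconstructed from summary
#' statistics and therefore requires raw values.
#'
#' @param case,control Numeric vectors (NA dropped); each needs >= 2 values.
#' @param method `"student_pooled"`, `"welch"` or `"ranksum"`.
#' @return A list with `statistic`, `df` (NA for ranksum) and two-sided
#'   `p_value`.
#' @export
two_group_test_raw <- function(case, control,
                               method = c("student_pooled", "welch", "ranksum")) {
  method <- match.arg(method)
  case <- case[!is.na(case)]; control <- control[!is.na(control)]
  if (length(case) < 2 || length(control) < 2)
    stop("need >= 2 observations per group", call. = FALSE)
  if (method == "ranksum") {
    w <- suppressWarnings(stats::wilcox.test(case, control))
    return(list(statistic = unname(w$statistic), df = NA_real_,
                p_value = w$p.value))
  }
  tt <- stats::t.test(case, control, var.equal = method == "student_pooled")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Trapezoidal area under a response curve
#'
#' Summary statistic for tolerance-test time courses (e.g. blood glucose
#' after an intraperitoneal glucose bolus), in trait units times minutes.
#'
#' @param times Strictly increasing sampling times (minutes); >= 2 points.
#' @param values Measurements at those times.
#' @param baseline `"none"` (default, total area) or `"subtract_t0"`
#'   (subtracts the t = 0 value first; the incremental area may be
#'   negative).
#' @return Numeric area.
#' @examples
#' auc_trapezoid(c(0, 15, 30, 60, 120), c(5, 15, 12, 10, 7))
#' @export
auc_trapezoid <- function(times, values, baseline = c("none", "subtract_t0")) {
  baseline <- match.arg(baseline)
  if (length(times) < 2 || length(times) != length(values))
    stop("need >= 2 (time, value) pairs of equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (baseline == "subtract_t0") values <- values - values[1]
  pracma::trapz(times, values)
}

#' Percent-of-control effect summary
#'
#' `100 * case_mean / control_mean`, the scale on which disease-vs-control
#' expression changes are reported (e.g. "153% of control").
#'
#' @param case_mean,control_mean Group means; `control_mean` must be > 0.
#' @return Percentage.
#' @export
percent_of_control <- function(case_mean, control_mean) {
  if (any(control_mean <= 0))
    stop("control mean must be positive", call. = FALSE)
  100 * case_mean / control_mean
}
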