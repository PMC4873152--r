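#' Beta-value to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, the standard logit2 transform for
#' Infinium methylation fractions; strictly increasing, maps 0.5 to 0.
#' Values outside (0, 1) are rejected -- readers clamp boundary values
#' first ([read_matrix_tsv()]); the transform itself never clamps silently.
#'
#' @param beta Numeric vector/matrix strictly inside (0, 1).
#' @return M-values, same shape.
#' @examples
#' beta_to_m(c(0.5, 0.8))
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1))
    stop("beta values must lie strictly inside (0, 1); clamp at the reader boundary",
         call. = FALSE)
  log2(beta / (1 - beta))
}

#' Inverse of [beta_to_m()]
#'
#' @param m Numeric vector/matrix of M-values.
#' @return Beta values in (0, 1); `m_to_beta(beta_to_m(b))` recovers `b`
#'   up to floating error.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Methylation matrix bundle
#'
#' @param beta Probe x sample matrix of beta values strictly in (0, 1)
#'   (readers clamp exact 0/1 to `[1e-6, 1 - 1e-6]`).
#' @param detection_p Probe x sample matrix of detection P-values in
#'   `[0, 1]`, same dimnames as `beta`.
#' @param probes data.frame with at least `probe_id` and `gene_id`
#'   (probe-to-gene assignment); optional `chrom`, `position`.
#' @param group `"ND"` / `"T2D"` per sample column.
#' @return A `methylation_matrix` object.
#' @export
methylation_matrix <- function(beta, detection_p, probes, group) {
  stopifnot(is.matrix(beta), is.matrix(detection_p),
            identical(dim(beta), dim(detection_p)),
            identical(dimnames(beta), dimnames(detection_p)),
            !is.null(rownames(beta)), !is.null(colnames(beta)))
  if (any(beta <= 0 | beta >= 1))
    stop("beta values must lie strictly inside (0, 1)", call. = FALSE)
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection P-values must lie in [0, 1]", call. = FALSE)
  stopifnot(is.data.frame(probes), all(c("probe_id", "gene_id") %in% names(probes)))
  if (!setequal(probes$probe_id, rownames(beta)))
    stop("probe manifest does not match matrix rows", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(beta) || !all(group %in% c("ND", "T2D")))
    stop("group labels must be 'ND'/'T2D', one per sample", call. = FALSE)
  structure(list(beta = beta, detection_p = detection_p,
                 probes = probes[match(rownames(beta), probes$probe_id), ,
                                 drop = FALSE],
                 group = group),
            class = "methylation_matrix")
}

#' Detection P-value probe filter
#'
#' Removes probes whose mean detection P-value across samples exceeds the
#' threshold (strict inequality: a mean of exactly the threshold is
#' retained). Idempotent.
#'
#' @param mat A [methylation_matrix()].
#' @param threshold Cutoff in (0, 1); default 0.01.
#' @return The filtered `methylation_matrix`, with attribute `removed`
#'   (character vector of excluded probe ids).
#' @export
detection_filter <- function(mat, threshold = 0.01) {
  stopifnot(inherits(mat, "methylation_matrix"), threshold > 0, threshold < 1)
  mean_p <- rowMeans(mat$detection_p)
  drop <- mean_p > threshold
  if (all(drop))
    warning("all probes removed by detection filter", call. = FALSE)
  out <- mat
  out$beta <- mat$beta[!drop, , drop = FALSE]
  out$detection_p <- mat$detection_p[!drop, , drop = FALSE]
  out$probes <- mat$probes[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(mat$beta)[drop]
  out
}

## build and rank-check the covariate design (categoricals to indicator
## contrasts); returns the model matrix without intercept column name clashes
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  for (j in names(covariates))
    if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]                       # intercept added by the fit
}

#' Per-probe methylation-expression association
#'
#' For each probe, ordinary-least-squares fit of the probe's M-values on
#' the focal gene's expression plus covariates (batch, gender, BMI, age,
#' islet purity, days of culture, ...; categoricals expanded to indicator
#' contrasts). Reports the slope and two-sided p of the expression
#' coefficient; a negative slope means methylation falls as expression
#' rises. With no covariates this equals simple linear regression.
#'
#' @param mat A [methylation_matrix()].
#' @param expression Numeric per-sample expression of the probes' gene, in
#'   matrix column order.
#' @param covariates Optional data.frame, one row per sample.
#' @return A data.frame: `probe_id`, `slope`, `se`, `p_value`,
#'   `direction`.
#' @export
site_expression_association <- function(mat, expression, covariates = NULL) {
  stopifnot(inherits(mat, "methylation_matrix"),
            length(expression) == ncol(mat$beta))
  n <- ncol(mat$beta)
  X <- cbind(`(Intercept)` = 1, expression = expression,
             covariate_design(covariates, n))
  if (n <= ncol(X) + 1)
    stop("need n > number of regression parameters + 1", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  M <- beta_to_m(mat$beta)
  fit <- stats::lm.fit(X, t(M))
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))                     # single-probe input
    coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
  res <- as.matrix(fit$residuals)
  df <- n - ncol(X)
  rss <- colSums(res^2)
  xtxinv <- solve(crossprod(X))
  se <- sqrt(rss / df * xtxinv["expression", "expression"])
  slope <- coefs["expression", ]
  tval <- slope / se
  data.frame(probe_id = rownames(mat$beta),
             slope = unname(slope),
             se = unname(se),
             p_value = unname(2 * stats::pt(-abs(tval), df)),
             direction = unname(sign(slope)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag probes with significant negative methylation-expression association
#'
#' @param assocs Output of [site_expression_association()].
#' @param alpha Family alpha in (0, 1).
#' @param procedure Multiple-testing handling within the probe panel:
#'   `"bonferroni"` (default; with 16 probes this is p < alpha/16),
#'   `"none"` or `"BH"`.
#' @return Sorted character vector of flagged probe ids (negative slope and
#'   adjusted p below alpha).
#' @export
flag_negative_sites <- function(assocs, alpha = 0.05,
                                procedure = c("bonferroni", "none", "BH")) {
  procedure <- match.arg(procedure)
  stopifnot(alpha > 0, alpha < 1)
  p_adj <- stats::p.adjust(assocs$p_value, method = procedure)
  sort(assocs$probe_id[assocs$slope < 0 & p_adj < alpha])
}

#' Group methylation difference per probe
#'
#' Difference in methylation between control (ND) and disease (T2D)
#' groups, through the same summary-statistic test engine as the phenotype
#' layer. `delta` is group1 minus group2 (so a positive delta with
#' (ND, T2D) ordering is a reduction in disease). `beta_percent` works on
#' mean beta x 100 (percentage points); `m_value` on the M scale.
#'
#' @param x Either a [methylation_matrix()] (groups taken from it,
#'   group1 = ND, group2 = T2D), or a data.frame of summary pairs with
#'   columns `probe_id`, `mean_1`, `sem_1`, `n_1`, `mean_2`, `sem_2`,
#'   `n_2` already on the reporting scale.
#' @param scale `"beta_percent"` (default) or `"m_value"`; matrix input
#'   only.
#' @param variant Test variant, see [two_group_test_from_summary()].
#' @return data.frame: `probe_id`, `delta`, `p_value`, `mean_1`, `mean_2`.
#' @examples
#' group_methylation_difference(data.frame(
#'   probe_id = "cg05056497", mean_1 = 42.3, sem_1 = 1.5, n_1 = 34,
#'   mean_2 = 29.5, sem_2 = 1.9, n_2 = 15))
#' @export
group_methylation_difference <- function(x,
                                         scale = c("beta_percent", "m_value"),
                                         variant = c("student_pooled", "welch")) {
  scale <- match.arg(scale); variant <- match.arg(variant)
  if (inherits(x, "methylation_matrix")) {
    vals <- if (scale == "beta_percent") x$beta * 100 else beta_to_m(x$beta)
    i1 <- which(x$group == "ND"); i2 <- which(x$group == "T2D")
    if (!length(i1) || !length(i2))
      stop("both groups must be present", call. = FALSE)
    s1 <- summary_stat(rowMeans(vals[, i1, drop = FALSE]),
                       apply(vals[, i1, drop = FALSE], 1, stats::sd) / sqrt(length(i1)),
                       rep(length(i1), nrow(vals)))
    s2 <- summary_stat(rowMeans(vals[, i2, drop = FALSE]),
                       apply(vals[, i2, drop = FALSE], 1, stats::sd) / sqrt(length(i2)),
                       rep(length(i2), nrow(vals)))
    probe_id <- rownames(x$beta)
  } else {
    stopifnot(is.data.frame(x),
              all(c("probe_id", "mean_1", "sem_1", "n_1",
                    "mean_2", "sem_2", "n_2") %in% names(x)))
    s1 <- summary_stat(x$mean_1, x$sem_1, x$n_1)
    s2 <- summary_stat(x$mean_2, x$sem_2, x$n_2)
    probe_id <- as.character(x$probe_id)
  }
  ts <- two_group_test_from_summary(s1, s2, variant)
  data.frame(probe_id = probe_id,
             delta = s1$mean - s2$mean,
             p_value = ts$p_value,
             mean_1 = s1$mean, mean_2 = s2$mean,
             stringsAsFactors = FALSE, row.names = NULL)
}
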