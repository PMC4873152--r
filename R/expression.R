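#' Two-group expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative, no NA.
#' @param group Character/factor of `"ND"` / `"T2D"` per column (control
#'   and disease respectively).
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, group) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or drop upstream",
         call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("group labels must match the number of samples", call. = FALSE)
  if (!all(group %in% c("ND", "T2D")))
    stop("group labels must be 'ND' or 'T2D'", call. = FALSE)
  structure(list(values = values, group = group), class = "expression_matrix")
}

## vectorized two-sample t over matrix rows (log2 scale)
row_two_group_t <- function(x, case_idx, ctrl_idx, variant) {
  n1 <- length(case_idx); n2 <- length(ctrl_idx)
  m1 <- rowMeans(x[, case_idx, drop = FALSE])
  m2 <- rowMeans(x[, ctrl_idx, drop = FALSE])
  v1 <- rowSums((x[, case_idx, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, ctrl_idx, drop = FALSE] - m2)^2) / (n2 - 1)
  if (variant == "student_pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(df, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(diff = m1 - m2, t = t, df = df, degenerate = v1 == 0 & v2 == 0)
}

#' Per-gene differential-expression test (T2D vs ND)
#'
#' Surrogate two-group DE engine for normalized expression matrices.
#' `t_log2` applies the two-sample t test to `log2(x + 1)`-transformed
#' values; `ranksum` applies the Wilcoxon rank-sum test to raw values. The
#' fold change is always `mean(T2D) - mean(ND)` on the log2 scale, so
#' positive = higher in disease (fixed project-wide). Genes with zero
#' variance in both groups get `p = 1` by convention and are flagged
#' `degenerate`.
#'
#' @param x An [expression_matrix()].
#' @param method `"t_log2"` (default) or `"ranksum"`.
#' @param variant t variant for `t_log2` (see
#'   [two_group_test_from_summary()]).
#' @return A data.frame of per-gene results: `gene_id`, `log2fc`,
#'   `p_value`, `degenerate`, `source = "computed"`.
#' @export
de_test <- function(x, method = c("t_log2", "ranksum"),
                    variant = c("student_pooled", "welch")) {
  method <- match.arg(method); variant <- match.arg(variant)
  stopifnot(inherits(x, "expression_matrix"))
  case_idx <- which(x$group == "T2D"); ctrl_idx <- which(x$group == "ND")
  if (length(case_idx) < 2 || length(ctrl_idx) < 2)
    stop("need >= 2 samples in both groups", call. = FALSE)
  lx <- log2(x$values + 1)
  tt <- row_two_group_t(lx, case_idx, ctrl_idx, variant)
  if (method == "t_log2") {
    p <- 2 * stats::pt(-abs(tt$t), tt$df)
  } else {
    p <- vapply(seq_len(nrow(x$values)), function(i) {
      suppressWarnings(stats::wilcox.test(x$values[i, case_idx],
                                          x$values[i, ctrl_idx])$p.value)
    }, numeric(1))
  }
  p[tt$degenerate] <- 1
  res <- data.frame(gene_id = rownames(x$values),
                    log2fc = unname(tt$diff),
                    p_value = unname(p),
                    degenerate = unname(tt$degenerate),
                    source = "computed",
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Wrap precomputed per-gene DE statistics
#'
#' For pipelines that consume an upstream engine's per-gene results instead
#' of an expression matrix.
#'
#' @param gene_id,log2fc,p_value Equal-length vectors; `log2fc` positive =
#'   higher in disease.
#' @return A DE results data.frame with `source = "precomputed"`.
#' @export
de_results <- function(gene_id, log2fc, p_value) {
  stopifnot(length(gene_id) == length(log2fc),
            length(gene_id) == length(p_value),
            all(p_value >= 0 & p_value <= 1))
  if (anyDuplicated(gene_id)) stop("duplicate gene ids", call. = FALSE)
  data.frame(gene_id = as.character(gene_id), log2fc = as.numeric(log2fc),
             p_value = as.numeric(p_value), degenerate = FALSE,
             source = "precomputed", stringsAsFactors = FALSE)
}

#' Upregulation filter over a candidate gene set
#'
#' Retains candidate genes with positive fold change (higher in disease)
#' and (adjusted) p below `alpha`. Multiple-testing adjustment, when
#' requested, is applied within the candidate set actually tested.
#'
#' @param results DE results data.frame ([de_test()] or [de_results()]).
#' @param candidates Character vector of candidate gene ids.
#' @param alpha Level in (0, 1).
#' @param procedure `"none"` (default; reproduces a nominal-p funnel),
#'   `"BH"` or `"bonferroni"`.
#' @return A list: `retained` (sorted gene ids passing), `missing`
#'   (candidates absent from `results`, reported rather than silently
#'   dropped), and `table` (the candidate rows with `p_adj`).
#' @examples
#' res <- de_results(c("EVA1C", "OLIG2"), c(0.3, 0.4), c(0.038, 0.009))
#' filter_upregulated(res, c("EVA1C", "OLIG2"), alpha = 0.01)
#' @export
filter_upregulated <- function(results, candidates, alpha = 0.05,
                               procedure = c("none", "BH", "bonferroni")) {
  procedure <- match.arg(procedure)
  stopifnot(alpha > 0, alpha < 1)
  candidates <- unique(as.character(candidates))
  tab <- results[results$gene_id %in% candidates, , drop = FALSE]
  missing <- sort(setdiff(candidates, tab$gene_id))
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  tab$p_adj <- stats::p.adjust(tab$p_value, method = procedure)
  retained <- sort(tab$gene_id[tab$log2fc > 0 & tab$p_adj < alpha])
  rownames(tab) <- NULL
  list(retained = retained, missing = missing, table = tab)
}

#' Expression-covariate correlation
#'
#' Correlation between one gene's per-sample expression and a continuous
#' clinical covariate (e.g. HbA1c, BMI). Pairs with a missing covariate are
#' removed and counted.
#'
#' @param expr Numeric vector of per-sample expression.
#' @param covariate Numeric vector, same length.
#' @param method `"spearman"` (default; robust) or `"pearson"`.
#' @return A list: `estimate`, two-sided `p_value`, `n_used`, `n_removed`.
#' @export
covariate_correlation <- function(expr, covariate,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(expr) == length(covariate))
  keep <- !is.na(expr) & !is.na(covariate)
  n_removed <- sum(!keep)
  expr <- expr[keep]; covariate <- covariate[keep]
  if (length(expr) < 4)
    stop("need >= 4 complete (expression, covariate) pairs", call. = FALSE)
  if (stats::sd(expr) == 0 || stats::sd(covariate) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(expr, covariate, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_used = length(expr), n_removed = n_removed)
}
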