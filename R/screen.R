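#' Screen configuration
#'
#' All tunable choices of the funnel in one validated object. Unknown
#' arguments are rejected.
#'
#' @param alpha_phenotype,alpha_de,alpha_methylation Per-layer significance
#'   levels in (0, 1).
#' @param test_variant `"student_pooled"` or `"welch"` for every
#'   summary-statistic test.
#' @param containment Gene-in-segment rule, see [genes_in_segments()].
#' @param ortholog_policy See [synteny_map()].
#' @param de_procedure,methylation_procedure Multiple-testing procedures
#'   for the DE and methylation layers (`"none"`, `"BH"`,
#'   `"bonferroni"`). DE defaults to `"none"` (a nominal-p funnel);
#'   methylation defaults to `"bonferroni"` within the probe panel.
#' @param affected_label Phenotype defining "affected" models.
#' @param required_layers Layers a gene must pass to reach `final_pass`;
#'   must contain `"region"`. Default `c("region", "de")`: methylation is
#'   corroborative unless required.
#' @param methylation_covariate_adjust Adjust the methylation-expression
#'   association for the sample covariates. Default FALSE: the association
#'   is reported as the marginal relationship across all samples (the
#'   covariate-adjusted linear model is the convention for the group
#'   methylation difference, not for this correlation); set TRUE to
#'   adjust.
#' @param detection_threshold Detection P-value cutoff (default 0.01).
#' @param seed Optional integer recorded in the report.
#' @return A `screen_config` list.
#' @export
screen_config <- function(alpha_phenotype = 0.05, alpha_de = 0.05,
                          alpha_methylation = 0.05,
                          test_variant = c("student_pooled", "welch"),
                          containment = c("full", "any_overlap"),
                          ortholog_policy = c("one_to_one_only", "keep_all"),
                          de_procedure = c("none", "BH", "bonferroni"),
                          methylation_procedure = c("bonferroni", "none", "BH"),
                          affected_label = "hyperglycaemic",
                          required_layers = c("region", "de"),
                          methylation_covariate_adjust = FALSE,
                          detection_threshold = 0.01,
                          seed = NULL) {
  for (a in c(alpha_phenotype, alpha_de, alpha_methylation))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("all alphas must lie in (0, 1)", call. = FALSE)
  required_layers <- match.arg(required_layers,
                               c("region", "de", "methylation", "annotation"),
                               several.ok = TRUE)
  if (!"region" %in% required_layers)
    stop("required_layers must contain 'region'", call. = FALSE)
  structure(list(alpha_phenotype = alpha_phenotype, alpha_de = alpha_de,
                 alpha_methylation = alpha_methylation,
                 test_variant = match.arg(test_variant),
                 containment = match.arg(containment),
                 ortholog_policy = match.arg(ortholog_policy),
                 de_procedure = match.arg(de_procedure),
                 methylation_procedure = match.arg(methylation_procedure),
                 affected_label = affected_label,
                 required_layers = required_layers,
                 methylation_covariate_adjust = isTRUE(methylation_covariate_adjust),
                 detection_threshold = detection_threshold,
                 seed = seed),
            class = "screen_config")
}

## summary_stat pair (case, control) per model from a phenotype input table
phenotype_summaries <- function(phenotypes, model) {
  rows <- phenotypes[phenotypes$model == model, , drop = FALSE]
  if (!nrow(rows)) stop("no phenotype rows for model ", model, call. = FALSE)
  if ("value" %in% names(rows)) {          # per-animal table
    lapply(c(case = "case", control = "control"), function(role) {
      v <- rows$value[rows$role == role]
      if (length(v) < 2)
        stop(sprintf("model %s: need >= 2 %s animals", model, role),
             call. = FALSE)
      summarize_values(v)
    })
  } else {                                  # summary rows
    lapply(c(case = "case", control = "control"), function(role) {
      r <- rows[rows$role == role, , drop = FALSE]
      if (nrow(r) != 1)
        stop(sprintf("model %s: need exactly one %s summary row", model, role),
             call. = FALSE)
      summary_stat(r$mean, r$sem, r$n)
    })
  }
}

#' Run the full screening funnel
#'
#' Orchestrates phenotype classification, candidate-region mapping with
#' ortholog projection, the differential-expression filter, the
#' methylation corroboration layer and the optional per-gene annotation
#' flag, and returns a ranked evidence report. Deterministic given its
#' inputs.
#'
#' @param config A [screen_config()].
#' @param models List of [aneuploidy_model()]s (phenotype calls are
#'   attached by this function).
#' @param annotations List with `mouse` and `human` gene annotation
#'   data.frames.
#' @param synteny A [synteny_map()].
#' @param phenotypes Phenotype input table: per-animal
#'   (`model`, `role`, `animal_id`, `value`) or summary rows
#'   (`model`, `role`, `mean`, `sem`, `n`).
#' @param expression Optional [expression_matrix()]; ignored when `de` is
#'   given.
#' @param de Optional precomputed DE results ([de_results()]).
#' @param methylation Optional list with `matrix`
#'   ([methylation_matrix()]), `expression` (gene x sample matrix of the
#'   probed genes' expression in the methylation cohort) and optional
#'   `covariates` data.frame (a `sample_id` column, if present, is not
#'   used as a covariate).
#' @param annotation_flags Optional named logical vector per human gene
#'   (e.g. a user-supplied "known mitochondrial/secretion role" flag; this
#'   layer is never inferred automatically).
#' @param study Alternatively, a [generate_study()] bundle supplying all
#'   of the above.
#' @return A `screen_report`: `evidence` (one row per in-region gene, in
#'   [rank_candidates()] order), `counts` per layer, `phenotype_calls`,
#'   `config`, `provenance`.
#' @export
run_screen <- function(config = screen_config(), models = NULL,
                       annotations = NULL, synteny = NULL, phenotypes = NULL,
                       expression = NULL, de = NULL, methylation = NULL,
                       annotation_flags = NULL, study = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(study)) {
    stopifnot(inherits(study, "synthetic_study"))
    if (is.null(models)) models <- study$models
    if (is.null(annotations)) annotations <- study$annotations
    if (is.null(synteny)) synteny <- study$synteny
    if (is.null(phenotypes)) phenotypes <- study$phenotypes
    if (is.null(expression)) expression <- study$expression$matrix
    if (is.null(methylation)) methylation <- study$methylation
  }

  ## 1. phenotype layer
  models <- lapply(models, function(m) {
    s <- phenotype_summaries(phenotypes, m$name)
    m$phenotype <- classify_glycaemia(s$case, s$control,
                                      alpha = config$alpha_phenotype,
                                      variant = config$test_variant)
    m
  })
  calls <- lapply(models, `[[`, "phenotype")
  names(calls) <- vapply(models, `[[`, character(1), "name")

  ## 2. region layer
  region <- candidate_gene_set(models, annotations, synteny,
                               affected_label = config$affected_label,
                               containment = config$containment)
  candidates <- region$candidates

  ## 3. differential-expression layer
  if (is.null(de)) {
    if (is.null(expression))
      stop("need either an expression matrix or precomputed DE results",
           call. = FALSE)
    de <- de_test(expression, variant = config$test_variant)
  }
  de_filter <- filter_upregulated(de, candidates, alpha = config$alpha_de,
                                  procedure = config$de_procedure)
  de_tab <- de_filter$table

  ## 4. methylation layer (genes with probes only)
  meth_count <- setNames(rep(NA_integer_, length(candidates)), candidates)
  meth_flagged <- list()
  if (!is.null(methylation)) {
    mm <- detection_filter(methylation$matrix, config$detection_threshold)
    covs <- methylation$covariates
    if (!config$methylation_covariate_adjust) covs <- NULL
    if (!is.null(covs)) covs <- covs[, setdiff(names(covs), "sample_id"),
                                     drop = FALSE]
    for (gid in intersect(candidates, unique(mm$probes$gene_id))) {
      keep <- mm$probes$gene_id == gid
      sub <- mm
      sub$beta <- mm$beta[keep, , drop = FALSE]
      sub$detection_p <- mm$detection_p[keep, , drop = FALSE]
      sub$probes <- mm$probes[keep, , drop = FALSE]
      if (!nrow(sub$beta)) next
      if (!gid %in% rownames(methylation$expression))
        stop("no methylation-cohort expression for probed gene ", gid,
             call. = FALSE)
      assoc <- site_expression_association(sub,
                                           methylation$expression[gid, ],
                                           covs)
      fl <- flag_negative_sites(assoc, alpha = config$alpha_methylation,
                                procedure = config$methylation_procedure)
      meth_count[gid] <- length(fl)
      meth_flagged[[gid]] <- fl
    }
  }

  ## 5. evidence table
  ev <- data.frame(gene_id = candidates,
                   in_region = TRUE,
                   stringsAsFactors = FALSE)
  idx <- match(candidates, de_tab$gene_id)
  ev$de_log2fc <- de_tab$log2fc[idx]
  ev$de_p <- de_tab$p_value[idx]
  ev$de_p_adj <- de_tab$p_adj[idx]
  ev$de_pass <- ev$gene_id %in% de_filter$retained
  ev$meth_n_flagged <- unname(meth_count[candidates])
  ev$meth_pass <- ifelse(is.na(ev$meth_n_flagged), NA, ev$meth_n_flagged >= 1L)
  ev$annotation_flag <- if (is.null(annotation_flags)) NA else
    unname(annotation_flags[ev$gene_id])

  layer_pass <- function(layer) {
    switch(layer,
           region = ev$in_region,
           de = ev$de_pass,
           methylation = !is.na(ev$meth_pass) & ev$meth_pass,  # no data = fail when required
           annotation = !is.na(ev$annotation_flag) & ev$annotation_flag)
  }
  ev$final_pass <- Reduce(`&`, lapply(config$required_layers, layer_pass),
                          rep(TRUE, nrow(ev)))
  ev$n_layers_passed <- rowSums(cbind(ev$in_region,
                                      ev$de_pass,
                                      !is.na(ev$meth_pass) & ev$meth_pass,
                                      !is.na(ev$annotation_flag) & ev$annotation_flag))
  ev <- rank_candidates(ev)

  counts <- c(region = nrow(ev),
              de = sum(ev$de_pass),
              de_and_methylation = sum(ev$de_pass & !is.na(ev$meth_pass) & ev$meth_pass),
              final = sum(ev$final_pass))

  structure(list(evidence = ev,
                 counts = counts,
                 phenotype_calls = calls,
                 de_missing = de_filter$missing,
                 meth_flagged = meth_flagged,
                 region = region,
                 config = config,
                 provenance = list(seed = config$seed,
                                   package_version = as.character(utils::packageVersion("aneuscreen")),
                                   input_digests = list())),
            class = "screen_report")
}

#' Rank an evidence table
#'
#' Orders genes by number of passing layers (descending), then DE p-value
#' (ascending), then count of flagged methylation probes (descending),
#' with gene id as the final lexicographic tiebreak. The order is total
#' and stable.
#'
#' @param evidence An evidence data.frame from [run_screen()].
#' @return The same data.frame, reordered.
#' @export
rank_candidates <- function(evidence) {
  stopifnot(is.data.frame(evidence), "gene_id" %in% names(evidence))
  nl <- if ("n_layers_passed" %in% names(evidence)) evidence$n_layers_passed
  else rep(0L, nrow(evidence))
  dep <- if ("de_p" %in% names(evidence)) evidence$de_p else rep(NA_real_, nrow(evidence))
  mc <- if ("meth_n_flagged" %in% names(evidence)) evidence$meth_n_flagged
  else rep(NA_integer_, nrow(evidence))
  ord <- order(-nl,
               ifelse(is.na(dep), Inf, dep),
               -ifelse(is.na(mc), -Inf, mc),
               evidence$gene_id,
               method = "radix")
  out <- evidence[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat("  phenotype calls:",
      paste(sprintf("%s=%s", names(x$phenotype_calls),
                    vapply(x$phenotype_calls, `[[`, character(1), "label")),
            collapse = ", "), "\n")
  cat(sprintf("  funnel: %d in region -> %d DE-pass -> %d DE+methylation -> %d final\n",
              x$counts["region"], x$counts["de"],
              x$counts["de_and_methylation"], x$counts["final"]))
  if (any(x$evidence$final_pass))
    cat("  final_pass:",
        paste(x$evidence$gene_id[x$evidence$final_pass], collapse = ", "), "\n")
  invisible(x)
}
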