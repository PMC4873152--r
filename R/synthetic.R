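#' Slope that yields a target methylation-expression correlation
#'
#' For `M = intercept + slope * x + e`, `e ~ N(0, noise_sd^2)`, the
#' marginal correlation is `slope * sd(x) / sqrt(slope^2 sd(x)^2 +
#' noise_sd^2)`; inverting gives the slope magnitude that plants a chosen
#' `|r|`.
#'
#' @param target_r Target correlation magnitude in (0, 1).
#' @param expr_sd Standard deviation of the expression predictor.
#' @param noise_sd Residual SD on the M scale.
#' @return Positive slope magnitude.
#' @export
slope_for_target_r <- function(target_r, expr_sd, noise_sd) {
  stopifnot(target_r > 0, target_r < 1, expr_sd > 0, noise_sd > 0)
  target_r / sqrt(1 - target_r^2) * noise_sd / expr_sd
}

#' Simulate two-group expression for one gene
#'
#' Log2-scale Normal noise around a baseline, with the case group's mean
#' shifted by `log2(fold)`, exponentiated to abundance. Because both groups
#' share the log-scale SD, the ratio of expected abundances equals `fold`
#' exactly.
#'
#' @param n_control,n_case Group sizes.
#' @param fold Planted case/control ratio of group mean abundance (> 0).
#' @param log2_baseline Control-group mean on the log2 scale.
#' @param log2_sd Log2-scale noise SD.
#' @return List with numeric abundance vectors `control` and `case`.
#' @export
simulate_two_group_expression <- function(n_control = 77, n_case = 12,
                                          fold = 1.53, log2_baseline = 5,
                                          log2_sd = 0.5) {
  stopifnot(n_control >= 2, n_case >= 2, fold > 0)
  list(control = 2^stats::rnorm(n_control, log2_baseline, log2_sd),
       case = 2^stats::rnorm(n_case, log2_baseline + log2(fold), log2_sd))
}

#' Simulate group-parameterised beta values (percent scale)
#'
#' Draws per-sample methylation percentages Normal around the printed group
#' means with per-sample SD reconstructed as `SEM * sqrt(n)`, clamped into
#' (0, 100). Used to emulate sites whose group summaries are known.
#'
#' @param n_1,n_2 Group sizes.
#' @param mean_1,sem_1,mean_2,sem_2 Printed group means and SEMs, in
#'   percent.
#' @return List with percent vectors `group1` and `group2`.
#' @export
simulate_group_betas <- function(n_1 = 34, n_2 = 15, mean_1 = 42.3,
                                 sem_1 = 1.5, mean_2 = 29.5, sem_2 = 1.9) {
  stopifnot(n_1 >= 2, n_2 >= 2)
  clamp <- function(x) pmin(pmax(x, 1e-4), 100 - 1e-4)
  list(group1 = clamp(stats::rnorm(n_1, mean_1, sem_1 * sqrt(n_1))),
       group2 = clamp(stats::rnorm(n_2, mean_2, sem_2 * sqrt(n_2))))
}

#' Simulate a CpG probe panel with planted negative associations
#'
#' Builds a 16-probe-style methylation panel for one gene: expression is
#' drawn on the log2 scale, the first `n_planted` probes get M-values
#' linear in expression with a negative slope calibrated (against the
#' realized expression spread) to the target correlation magnitude, and
#' the remaining probes are null. Betas are the inverse-logit2 of the
#' M-values, so they stay strictly in (0, 1).
#'
#' @param n_samples Number of samples (default 89).
#' @param n_probes Panel size (default 16).
#' @param n_planted Probes with a planted negative association (default 3).
#' @param target_r Planted correlation magnitude (default 0.5).
#' @param m_noise_sd Residual SD on the M scale (default 1).
#' @param expr_log2_mean,expr_log2_sd Expression distribution (log2 scale).
#' @param gene_id Gene the probes are assigned to.
#' @return List: `mat` (a [methylation_matrix()]), `expression`
#'   (per-sample abundance-scale-free log2 expression), `planted`
#'   (planted probe ids), `slopes` (the planted slopes).
#' @export
simulate_association_panel <- function(n_samples = 89, n_probes = 16,
                                       n_planted = 3, target_r = 0.5,
                                       m_noise_sd = 1, expr_log2_mean = 5,
                                       expr_log2_sd = 0.5,
                                       gene_id = "gene") {
  stopifnot(n_planted <= n_probes, n_samples >= 8)
  x <- stats::rnorm(n_samples, expr_log2_mean, expr_log2_sd)
  slope <- -slope_for_target_r(target_r, stats::sd(x), m_noise_sd)
  probe_id <- c(sprintf("cg_planted_%02d", seq_len(n_planted)),
                sprintf("cg_null_%02d", seq_len(n_probes - n_planted)))
  base_beta <- rep(c(0.3, 0.45, 0.6, 0.75), length.out = n_probes)
  m0 <- beta_to_m(base_beta)
  M <- matrix(stats::rnorm(n_probes * n_samples, 0, m_noise_sd),
              nrow = n_probes,
              dimnames = list(probe_id, sprintf("s%03d", seq_len(n_samples))))
  M <- M + m0
  if (n_planted > 0)
    M[seq_len(n_planted), ] <- M[seq_len(n_planted), , drop = FALSE] +
      rep(slope * (x - mean(x)), each = n_planted)
  beta <- m_to_beta(M)
  det <- matrix(stats::runif(length(beta), 0, 0.005), nrow = n_probes,
                dimnames = dimnames(beta))
  mat <- methylation_matrix(beta, det,
                            data.frame(probe_id = probe_id, gene_id = gene_id,
                                       stringsAsFactors = FALSE),
                            group = rep("ND", n_samples))
  list(mat = mat, expression = x,
       planted = sort(probe_id[seq_len(n_planted)]),
       slopes = rep(slope, n_planted))
}

#' Frozen study configuration mirroring the printed summaries
#'
#' The defaults are the study conditions: four trisomy models at the
#' printed fasting-glucose (mean, SEM, n) pairs; an expression cohort of
#' 77 non-diabetic and 12 T2D samples with a 1.53-fold increase planted on
#' the focal gene; a methylation cohort of 34 vs 15 samples with 16 probes
#' on the focal gene, three of them carrying a planted negative
#' methylation-expression association (|r| about 0.5) and group means
#' anchored to the printed percentages. The genome is an illustrative
#' synthetic layout (60 mouse chr16 genes, syntenic to 60 human chr21
#' genes) whose model spans make the affected-minus-unaffected algebra
#' yield a 38-gene candidate region containing the focal gene.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A `synthetic_config` list; see [generate_study()].
#' @export
default_study_config <- function(seed = 1) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_genes = 60L, gene_length = 10000L, gene_spacing = 20000L,
                  mouse_chrom = "chr16", human_chrom = "chr21",
                  focal_index = 42L, focal_symbol_mouse = "Rcan1",
                  focal_symbol_human = "RCAN1",
                  one_to_one_through = 56L),   # genes beyond: ambiguous/unmapped
    models = list(
      Ts65Dn = list(species = "mouse", gene_spans = list(c(5L, 55L)),
                    control = c(mean = 8.0, sem = 0.3, n = 17),
                    case = c(mean = 10.9, sem = 0.9, n = 14)),
      Dp16 = list(species = "mouse", gene_spans = list(c(1L, 50L)),
                  control = c(mean = 9.7, sem = 0.5, n = 10),
                  case = c(mean = 12.1, sem = 0.9, n = 11)),
      Ts1Rhr = list(species = "mouse", gene_spans = list(c(20L, 25L)),
                    control = c(mean = 11.1, sem = 0.6, n = 18),
                    case = c(mean = 11.5, sem = 0.4, n = 12)),
      Tc1 = list(species = "human", gene_spans = list(c(49L, 54L), c(57L, 60L)),
                 control = c(mean = 13.6, sem = 0.6, n = 23),
                 case = c(mean = 9.4, sem = 0.5, n = 23))),
    expression = list(n_nd = 77L, n_t2d = 12L, log2_baseline = 5,
                      log2_sd = 0.5, focal_fold = 1.53, hba1c_r = 0.3),
    methylation = list(
      n_nd = 34L, n_t2d = 15L, n_probes = 16L,
      target_r = 0.5, m_noise_sd = 1, contamination_rate = 0,
      planted = data.frame(
        probe_id = c("cg05156137_like", "cg21301258_like", "cg05056497_like"),
        mean_nd = c(51.1, 57.9, 42.3), sem_nd = c(1.8, 1.9, 1.5),
        mean_t2d = c(40.2, 48.0, 29.5), sem_t2d = c(3.1, 3.2, 1.9),
        stringsAsFactors = FALSE)),
    covariates = list(n_batches = 2L))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Build a study configuration
#'
#' Starts from [default_study_config()] and overrides named components;
#' unknown names are rejected.
#'
#' @param seed Seed.
#' @param ... Named components to replace (`genome`, `models`,
#'   `expression`, `methylation`, `covariates`), each merged field-wise.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- default_study_config(seed)
  over <- list(...)
  bad <- setdiff(names(over), setdiff(names(cfg), "seed"))
  if (length(bad))
    stop("unknown configuration component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      for (f in names(over[[nm]])) cfg[[nm]][[f]] <- over[[nm]][[f]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  e <- cfg$expression; m <- cfg$methylation
  stopifnot(e$n_nd >= 2, e$n_t2d >= 2, e$focal_fold > 0,
            m$n_nd >= 2, m$n_t2d >= 2,
            nrow(m$planted) <= m$n_probes,
            m$contamination_rate >= 0, m$contamination_rate <= 1)
  if (!is.null(e$hba1c_r) && abs(e$hba1c_r) >= 1)
    stop("infeasible target correlation (|r| must be < 1)", call. = FALSE)
  for (md in cfg$models)
    stopifnot(md$control[["n"]] >= 2, md$case[["n"]] >= 2,
              md$control[["sem"]] > 0, md$case[["sem"]] > 0)
  invisible(cfg)
}

## gene index span -> bp interval on the synthetic layout
span_to_interval <- function(chrom, span, g) {
  genomic_intervals(chrom,
                    (span[1] - 1L) * g$gene_spacing,
                    (span[2] - 1L) * g$gene_spacing + g$gene_length)
}

synthetic_annotation <- function(g, species) {
  idx <- seq_len(g$n_genes)
  chrom <- if (species == "mouse") g$mouse_chrom else g$human_chrom
  prefix <- if (species == "mouse") "mmu_g" else "hsa_g"
  sym <- if (species == "mouse") sprintf("Gm%02d", idx) else sprintf("HG%02d", idx)
  sym[g$focal_index] <- if (species == "mouse") g$focal_symbol_mouse else g$focal_symbol_human
  data.frame(gene_id = sprintf("%s%02d", prefix, idx),
             symbol = sym,
             species = species,
             chrom = chrom,
             start = (idx - 1L) * g$gene_spacing,
             end = (idx - 1L) * g$gene_spacing + g$gene_length,
             strand = rep(c("+", "-"), length.out = g$n_genes),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic screen study with planted truth
#'
#' Emulates the statistical structure the screen assumes: per-animal
#' fasting glucose Normal around the configured arm means (SD =
#' SEM * sqrt(n)); log2-Normal two-group expression with the focal fold
#' planted; HbA1c linearly linked to focal-gene expression at the target
#' correlation; a methylation probe panel where planted probes are linear
#' in focal-gene expression on the M scale (negative slope calibrated to
#' the target |r|, intercepts anchored to the printed control-group
#' percentages) and the remaining probes are null; detection P-values
#' Uniform(0, 0.005) for clean probes and Uniform(0.011, 0.2) for
#' contaminated ones. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()] / [default_study_config()].
#' @return A `synthetic_study` list with everything [run_screen()]
#'   consumes (`models`, `annotations`, `synteny`, `phenotypes`,
#'   `expression`, `methylation`) plus `truth` (causal gene, planted
#'   effects, true model labels).
#' @export
generate_study <- function(config = default_study_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  g <- config$genome

  annotations <- list(mouse = synthetic_annotation(g, "mouse"),
                      human = synthetic_annotation(g, "human"))

  k <- g$one_to_one_through
  pairs <- data.frame(mouse = sprintf("mmu_g%02d", seq_len(k)),
                      human = sprintf("hsa_g%02d", seq_len(k)),
                      stringsAsFactors = FALSE)
  if (g$n_genes > k + 1)  # one ambiguous mouse gene with two human links
    pairs <- rbind(pairs,
                   data.frame(mouse = sprintf("mmu_g%02d", c(k + 1L, k + 1L)),
                              human = sprintf("hsa_g%02d", c(k + 1L, k + 2L)),
                              stringsAsFactors = FALSE))
  synteny <- suppressWarnings(synteny_map(pairs, "one_to_one_only"))

  models <- lapply(names(config$models), function(nm) {
    md <- config$models[[nm]]
    chrom <- if (md$species == "mouse") g$mouse_chrom else g$human_chrom
    segs <- do.call(rbind, lapply(md$gene_spans, span_to_interval,
                                  chrom = chrom, g = g))
    aneuploidy_model(nm, md$species, segs)
  })
  names(models) <- names(config$models)

  phenotypes <- do.call(rbind, lapply(names(config$models), function(nm) {
    md <- config$models[[nm]]
    draw <- function(arm, role) {
      n <- as.integer(arm[["n"]])
      data.frame(model = nm, role = role,
                 animal_id = sprintf("%s_%s_%02d", nm, role, seq_len(n)),
                 value = stats::rnorm(n, arm[["mean"]],
                                      arm[["sem"]] * sqrt(n)),
                 stringsAsFactors = FALSE)
    }
    rbind(draw(md$case, "case"), draw(md$control, "control"))
  }))

  ## --- expression cohort (human islet emulation) ---
  e <- config$expression
  n_samp <- e$n_nd + e$n_t2d
  group <- c(rep("ND", e$n_nd), rep("T2D", e$n_t2d))
  sample_id <- sprintf("islet_%03d", seq_len(n_samp))
  focal_hsa <- sprintf("hsa_g%02d", g$focal_index)
  baseline <- e$log2_baseline + 0.5 * (seq_len(g$n_genes) %% 7)  # fixed per gene
  lmat <- matrix(stats::rnorm(g$n_genes * n_samp, baseline, e$log2_sd),
                 nrow = g$n_genes,
                 dimnames = list(annotations$human$gene_id, sample_id))
  lmat[focal_hsa, group == "T2D"] <-
    lmat[focal_hsa, group == "T2D"] + log2(e$focal_fold)
  values <- 2^lmat
  expr <- expression_matrix(values, group)

  z <- as.numeric(scale(lmat[focal_hsa, ]))
  r <- e$hba1c_r
  hba1c <- 5.6 + 1.2 * (group == "T2D") +
    0.5 * (r * z + sqrt(1 - r^2) * stats::rnorm(n_samp))
  samples <- data.frame(sample_id = sample_id, group = group,
                        HbA1c = hba1c,
                        BMI = stats::rnorm(n_samp, 28, 4),
                        stringsAsFactors = FALSE)

  ## --- methylation cohort ---
  m <- config$methylation
  n_meth <- m$n_nd + m$n_t2d
  mgroup <- c(rep("ND", m$n_nd), rep("T2D", m$n_t2d))
  msample <- sprintf("meth_%03d", seq_len(n_meth))
  mx <- stats::rnorm(n_meth, e$log2_baseline, e$log2_sd) +
    log2(e$focal_fold) * (mgroup == "T2D")
  n_planted <- nrow(m$planted)
  slope <- -slope_for_target_r(m$target_r, stats::sd(mx), m$m_noise_sd)
  probe_id <- c(m$planted$probe_id,
                sprintf("cg_null_%02d", seq_len(m$n_probes - n_planted)))
  M <- matrix(stats::rnorm(m$n_probes * n_meth, 0, m$m_noise_sd),
              nrow = m$n_probes, dimnames = list(probe_id, msample))
  ## planted probes: anchored at the printed control-group percent,
  ## negative slope in expression
  for (i in seq_len(n_planted)) {
    m0 <- beta_to_m(m$planted$mean_nd[i] / 100)
    M[i, ] <- M[i, ] + m0 + slope * (mx - mean(mx[mgroup == "ND"]))
  }
  if (m$n_probes > n_planted) {
    null_base <- beta_to_m(rep(c(0.3, 0.45, 0.6, 0.75),
                               length.out = m$n_probes - n_planted))
    M[seq(n_planted + 1, m$n_probes), ] <-
      M[seq(n_planted + 1, m$n_probes), , drop = FALSE] + null_base
  }
  beta <- m_to_beta(M)
  contaminated <- stats::runif(m$n_probes) < m$contamination_rate
  det <- matrix(stats::runif(m$n_probes * n_meth, 0, 0.005),
                nrow = m$n_probes, dimnames = dimnames(beta))
  det[contaminated, ] <- stats::runif(sum(contaminated) * n_meth, 0.011, 0.2)
  probes <- data.frame(probe_id = probe_id, gene_id = focal_hsa,
                       chrom = g$human_chrom,
                       position = annotations$human$start[g$focal_index] +
                         seq_len(m$n_probes) * 50L,
                       stringsAsFactors = FALSE)
  meth_mat <- methylation_matrix(beta, det, probes, mgroup)
  covariates <- data.frame(
    sample_id = msample,
    batch = sample(sprintf("batch%d", seq_len(config$covariates$n_batches)),
                   n_meth, replace = TRUE),
    gender = sample(c("F", "M"), n_meth, replace = TRUE),
    BMI = stats::rnorm(n_meth, 28, 4),
    age = round(stats::runif(n_meth, 35, 75)),
    purity = stats::runif(n_meth, 0.6, 0.95),
    days_culture = round(stats::runif(n_meth, 1, 9)),
    stringsAsFactors = FALSE)
  meth_expr <- matrix(mx, nrow = 1,
                      dimnames = list(focal_hsa, msample))

  structure(list(
    config = config,
    models = models,
    annotations = annotations,
    synteny = synteny,
    phenotypes = phenotypes,
    expression = list(matrix = expr, samples = samples),
    methylation = list(matrix = meth_mat, expression = meth_expr,
                       covariates = covariates),
    truth = list(causal_gene = focal_hsa,
                 causal_symbol = g$focal_symbol_human,
                 planted_fold = e$focal_fold,
                 planted_probes = sort(m$planted$probe_id),
                 planted_slope = slope,
                 contaminated_probes = probe_id[contaminated],
                 ## label implied by the configured arm parameters themselves
                 model_labels = vapply(config$models, function(md) {
                   classify_glycaemia(
                     summary_stat(md$case[["mean"]], md$case[["sem"]], md$case[["n"]]),
                     summary_stat(md$control[["mean"]], md$control[["sem"]],
                                  md$control[["n"]]))$label
                 }, character(1)))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> seed %d: %d models, %d+%d expression samples, %d probes x %d methylation samples; causal gene %s\n",
              x$config$seed, length(x$models),
              sum(x$expression$matrix$group == "ND"),
              sum(x$expression$matrix$group == "T2D"),
              nrow(x$methylation$matrix$beta), ncol(x$methylation$matrix$beta),
              x$truth$causal_gene))
  invisible(x)
}
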