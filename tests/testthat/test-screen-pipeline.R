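## deterministic phenotype layer: summary rows at the configured arm values
summary_phenotypes <- function(cfg) {
  do.call(rbind, lapply(names(cfg$models), function(nm) {
    md <- cfg$models[[nm]]
    data.frame(model = nm, role = c("case", "control"),
               mean = c(md$case[["mean"]], md$control[["mean"]]),
               sem = c(md$case[["sem"]], md$control[["sem"]]),
               n = c(md$case[["n"]], md$control[["n"]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("the full funnel recovers the planted causal gene", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  scfg <- screen_config(required_layers = c("region", "de", "methylation"))
  ## phenotype layer anchored at the printed summaries (deterministic);
  ## expression and methylation layers run on the generated data
  rep <- run_screen(scfg, models = st$models, annotations = st$annotations,
                    synteny = st$synteny, phenotypes = summary_phenotypes(cfg),
                    expression = st$expression$matrix,
                    methylation = st$methylation)
  labels <- vapply(rep$phenotype_calls, `[[`, character(1), "label")
  expect_equal(unname(labels[c("Ts65Dn", "Dp16", "Ts1Rhr", "Tc1")]),
               c("hyperglycaemic", "hyperglycaemic", "normoglycaemic",
                 "hypoglycaemic"))
  expect_equal(rep$counts[["region"]], 38)
  expect_equal(rep$evidence$gene_id[rep$evidence$final_pass],
               st$truth$causal_gene)
  ## funnel counts never increase along the layers
  expect_true(rep$counts[["region"]] >= rep$counts[["de"]])
  expect_true(rep$counts[["de"]] >= rep$counts[["de_and_methylation"]])
})

test_that("precomputed DE statistics drive the five-gene layer", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  region <- candidate_gene_set(
    lapply(st$models, function(m) {
      s <- summary_phenotypes(cfg)
      m$phenotype <- classify_glycaemia(
        summary_stat(s$mean[s$model == m$name & s$role == "case"],
                     s$sem[s$model == m$name & s$role == "case"],
                     s$n[s$model == m$name & s$role == "case"]),
        summary_stat(s$mean[s$model == m$name & s$role == "control"],
                     s$sem[s$model == m$name & s$role == "control"],
                     s$n[s$model == m$name & s$role == "control"]))
      m
    }), st$annotations, st$synteny)
  cand <- region$candidates
  expect_length(cand, 38)
  ## plant the printed p-values on five candidates, nulls elsewhere
  five <- c(st$truth$causal_gene, setdiff(cand, st$truth$causal_gene)[1:4])
  de <- de_results(cand,
                   log2fc = ifelse(cand %in% five, 0.4, 0.01),
                   p_value = ifelse(cand %in% five,
                                    c(0.009, 0.038, 0.009, 0.021, 0.0003)[
                                      match(cand, five)], 0.8))
  scfg <- screen_config(required_layers = c("region", "de"))
  rep <- run_screen(scfg, models = st$models, annotations = st$annotations,
                    synteny = st$synteny, phenotypes = summary_phenotypes(cfg),
                    de = de)
  expect_equal(rep$counts[["final"]], 5)
  expect_setequal(rep$evidence$gene_id[rep$evidence$final_pass], five)
})

test_that("a panel with no affected model aborts with a clear error", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  ph <- summary_phenotypes(cfg)
  ph$mean[ph$role == "case"] <- ph$mean[ph$role == "control"]
  scfg <- screen_config()
  expect_error(run_screen(scfg, models = st$models,
                          annotations = st$annotations, synteny = st$synteny,
                          phenotypes = ph, de = de_results("x", 1, 0.5)),
               "no affected model")
})

test_that("ranking orders by layers, DE p, methylation count, then id", {
  ev <- data.frame(gene_id = c("gB", "gA", "gC", "gD"),
                   de_p = c(0.038, 0.009, 0.009, NA),
                   meth_n_flagged = c(1L, 1L, 1L, NA),
                   n_layers_passed = c(3L, 3L, 3L, 1L),
                   stringsAsFactors = FALSE)
  r <- rank_candidates(ev)
  expect_equal(r$gene_id, c("gA", "gC", "gB", "gD"))  # p ties break on id
  tie <- data.frame(gene_id = c("z", "a"), de_p = c(NA, NA),
                    meth_n_flagged = c(NA, NA), n_layers_passed = c(0L, 0L))
  expect_equal(rank_candidates(tie)$gene_id, c("a", "z"))
})

test_that("requiring more layers never enlarges the final set", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  args <- list(models = st$models, annotations = st$annotations,
               synteny = st$synteny, phenotypes = summary_phenotypes(cfg),
               expression = st$expression$matrix, methylation = st$methylation)
  layer_sets <- list(c("region"), c("region", "de"),
                     c("region", "de", "methylation"),
                     c("region", "de", "methylation", "annotation"))
  sizes <- vapply(layer_sets, function(ls) {
    r <- do.call(run_screen, c(list(screen_config(required_layers = ls)), args))
    sum(r$evidence$final_pass)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("genes without probes fail methylation only when it is required", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  args <- list(models = st$models, annotations = st$annotations,
               synteny = st$synteny, phenotypes = summary_phenotypes(cfg),
               expression = st$expression$matrix, methylation = st$methylation)
  corro <- do.call(run_screen, c(list(screen_config()), args))
  ## no-probe genes carry NA in the corroborative layer, not FALSE
  noprobe <- corro$evidence[corro$evidence$gene_id != st$truth$causal_gene, ]
  expect_true(all(is.na(noprobe$meth_pass)))
  strict <- do.call(run_screen,
                    c(list(screen_config(required_layers = c("region", "de",
                                                             "methylation"))),
                      args))
  fp <- strict$evidence[strict$evidence$final_pass, "gene_id"]
  expect_true(all(fp %in% st$truth$causal_gene))
})

test_that("input row order does not change the evidence table", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  ph <- summary_phenotypes(cfg)
  scfg <- screen_config(required_layers = c("region", "de", "methylation"))
  r1 <- run_screen(scfg, models = st$models, annotations = st$annotations,
                   synteny = st$synteny, phenotypes = ph,
                   expression = st$expression$matrix,
                   methylation = st$methylation)
  set.seed(61)
  ann2 <- st$annotations
  ann2$mouse <- ann2$mouse[sample(nrow(ann2$mouse)), ]
  ann2$human <- ann2$human[sample(nrow(ann2$human)), ]
  r2 <- run_screen(scfg, models = rev(st$models), annotations = ann2,
                   synteny = st$synteny, phenotypes = ph[sample(nrow(ph)), ],
                   expression = st$expression$matrix,
                   methylation = st$methylation)
  expect_equal(r2$evidence, r1$evidence, ignore_attr = TRUE)
})

test_that("written reports are byte-identical across reruns", {
  cfg <- default_study_config(seed = 11)
  st <- generate_study(cfg)
  scfg <- screen_config(required_layers = c("region", "de", "methylation"))
  rep <- run_screen(scfg, study = st,
                    phenotypes = summary_phenotypes(cfg))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  for (f in c("evidence.tsv", "summary.json", "screen.log"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  ## evidence rows come out in ranked order
  ev <- read.delim(file.path(d1, "evidence.tsv"))
  expect_identical(ev$gene_id, rep$evidence$gene_id)
})
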