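#' Read dosage-altered segments from a BED3+ file
#'
#' Columns: chrom, start, end, optional model name in column 4. Coordinates
#' are 0-based half-open, as written. Malformed lines are rejected with
#' their line numbers.
#'
#' @param path File path.
#' @param default_name Model name used when column 4 is absent.
#' @return data.frame: `model`, `chrom`, `start`, `end`.
#' @export
read_bed_segments <- function(path, default_name = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("%s line %d: need >= 3 tab-separated columns", path, i),
           call. = FALSE)
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end))
      stop(sprintf("%s line %d: non-integer coordinates", path, i), call. = FALSE)
    if (start < 0 || start >= end)
      stop(sprintf("%s line %d: need 0 <= start < end, got %s-%s", path, i,
                   f[2], f[3]), call. = FALSE)
    data.frame(model = if (length(f) >= 4) f[4] else default_name,
               chrom = f[1], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(data.frame(model = character(),
                                               chrom = character(),
                                               start = numeric(),
                                               end = numeric()))))
  rownames(res) <- NULL
  res
}

#' Write segments as BED3+ (chrom, start, end, model)
#'
#' @param segments data.frame with `chrom`, `start`, `end` and optionally
#'   `model`.
#' @param path Output path.
#' @export
write_bed_segments <- function(segments, path) {
  validate_intervals(segments, "segment")
  model <- if ("model" %in% names(segments)) segments$model else NULL
  df <- data.frame(segments$chrom, format_int(segments$start),
                   format_int(segments$end))
  if (!is.null(model)) df[[4]] <- model
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `symbol`, `species`, `chrom`, `start`,
#' `end`, `strand` (coordinates already 0-based half-open), or a GFF3 file
#' from which gene-type features are taken (1-based inclusive coordinates
#' converted to the internal convention on read; `gene_id`/`ID` and
#' `Name` attributes used for id and symbol).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @param species Species tag to assign for GFF3 input (the TSV carries
#'   its own column).
#' @return Annotation data.frame in internal coordinates.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gff3"),
                                 species = "mouse") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "symbol", "species", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(ann))
    if (length(miss))
      stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    id <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    sym <- if (!is.null(gr$Name)) gr$Name else id
    ann <- data.frame(gene_id = as.character(id),
                      symbol = as.character(sym),
                      species = species,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,  # 1-based -> 0-based
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
    ann$strand[!ann$strand %in% c("+", "-")] <- "unknown"
  }
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1], call. = FALSE)
  validate_intervals(ann, "gene annotation")
  ann
}

#' Read a two-column ortholog map TSV
#'
#' Columns: mouse gene id, human gene id; `#` comment lines allowed.
#'
#' @param path File path.
#' @param policy Passed to [synteny_map()].
#' @return A [synteny_map()].
#' @export
read_ortholog_map <- function(path, policy = "one_to_one_only") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("mouse", "human"))
  synteny_map(df, policy)
}

#' Read a feature x sample matrix TSV
#'
#' Rectangular TSV: header row of sample ids, first column the feature id.
#' `"NA"` is the only missing-value token. Beta matrices are validated to
#' `[0, 1]` and boundary values clamped into `[1e-6, 1 - 1e-6]` with a
#' logged count (attribute `n_clamped`); detection-P matrices are
#' validated to `[0, 1]`.
#'
#' @param path File path.
#' @param kind `"expression"`, `"beta"` or `"detection_p"`.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, kind = c("expression", "beta", "detection_p")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", colClasses = NA)
  if (ncol(df) < 2) stop(path, ": need a feature id column plus samples", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature id: ", ids[duplicated(ids)][1], call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    stop(sprintf("%s: non-numeric cell at row %s, column %s", path,
                 ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- ids
  n_clamped <- 0L
  if (kind %in% c("beta", "detection_p")) {
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop(path, ": values outside [0, 1]", call. = FALSE)
    if (kind == "beta") {
      eps <- 1e-6
      at_bound <- m <= 0 | m >= 1
      n_clamped <- sum(at_bound, na.rm = TRUE)
      if (n_clamped) {
        message(sprintf("%s: clamped %d boundary beta value(s) into [%g, %g]",
                        path, n_clamped, eps, 1 - eps))
        m[m <= 0] <- eps
        m[m >= 1] <- 1 - eps
      }
    }
  }
  attr(m, "n_clamped") <- n_clamped
  attr(m, "digest") <- unname(tools::md5sum(path))
  m
}

#' Write a feature x sample matrix TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the feature id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype input TSV
#'
#' Either per-animal rows (`model`, `role`, `animal_id`, `value`) or
#' summary rows (`model`, `role`, `mean`, `sem`, `n`), with
#' `role` in case/control.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("model", "role") %in% names(df)))
    stop(path, ": need 'model' and 'role' columns", call. = FALSE)
  if (!all(df$role %in% c("case", "control")))
    stop(path, ": role must be 'case' or 'control'", call. = FALSE)
  if (!("value" %in% names(df)) && !all(c("mean", "sem", "n") %in% names(df)))
    stop(path, ": need either a 'value' column or mean/sem/n columns",
         call. = FALSE)
  df
}

#' Write a screen report to disk
#'
#' Emits `evidence.tsv` (one row per candidate gene, fixed column order,
#' p-values in scientific notation with 6 significant digits),
#' `summary.json` (layer counts, phenotype calls, configuration echo,
#' provenance) and `screen.log`. Output is byte-stable across reruns with
#' equal inputs (no timestamps).
#'
#' @param report A `screen_report` from [run_screen()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "screen_report"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  if (file.access(outdir, 2) != 0)
    stop("output directory not writable: ", outdir, call. = FALSE)
  ev <- report$evidence
  fmt <- function(p) ifelse(is.na(p), "NA", sprintf("%.6e", p))
  tab <- data.frame(gene_id = ev$gene_id,
                    in_region = ev$in_region,
                    de_log2fc = ifelse(is.na(ev$de_log2fc), "NA",
                                       sprintf("%.6f", ev$de_log2fc)),
                    de_p = fmt(ev$de_p),
                    de_p_adj = fmt(ev$de_p_adj),
                    de_pass = ev$de_pass,
                    meth_n_flagged = ifelse(is.na(ev$meth_n_flagged), "NA",
                                            as.character(ev$meth_n_flagged)),
                    meth_pass = ifelse(is.na(ev$meth_pass), "NA",
                                       as.character(ev$meth_pass)),
                    annotation_flag = ifelse(is.na(ev$annotation_flag), "NA",
                                             as.character(ev$annotation_flag)),
                    n_layers_passed = ev$n_layers_passed,
                    final_pass = ev$final_pass,
                    stringsAsFactors = FALSE)
  paths <- file.path(outdir, c("evidence.tsv", "summary.json", "screen.log"))
  utils::write.table(tab, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- lapply(report$phenotype_calls, function(p)
    list(label = p$label, p_value = p$p_value, direction = p$direction))
  jsonlite::write_json(list(counts = as.list(report$counts),
                            phenotype_calls = calls,
                            final_pass = ev$gene_id[ev$final_pass],
                            de_missing = report$de_missing,
                            config = unclass(report$config),
                            provenance = report$provenance),
                       paths[2], auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_lines <- c(sprintf("aneuscreen %s", report$provenance$package_version),
                 sprintf("phenotype: %s", paste(sprintf("%s=%s",
                   names(report$phenotype_calls),
                   vapply(report$phenotype_calls, `[[`, character(1), "label")),
                   collapse = " ")),
                 sprintf("funnel: region=%d de=%d de+meth=%d final=%d",
                         report$counts["region"], report$counts["de"],
                         report$counts["de_and_methylation"],
                         report$counts["final"]))
  writeLines(log_lines, paths[3])
  invisible(paths)
}

#' Write a synthetic study as a pipeline input bundle
#'
#' Serializes every input a screen run needs (model segments BED,
#' annotation and ortholog TSVs, phenotype TSV, expression and methylation
#' matrices, sample sheets, covariates) plus `truth.json`, all as plain
#' text. [read_study()] restores the bundle losslessly up to numeric
#' formatting precision (15 significant digits).
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  old <- options(digits = 15); on.exit(options(old))
  segs <- do.call(rbind, lapply(study$models, function(m)
    data.frame(model = m$name, m$segments, species = m$species,
               stringsAsFactors = FALSE)))
  write_bed_segments(segs[, c("chrom", "start", "end", "model")], p("models.bed"))
  utils::write.table(unique(segs[, c("model", "species")]), p("model_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotations$mouse, p("annotation_mouse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotations$human, p("annotation_human.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$synteny$pairs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(study$phenotypes, p("phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$expression$matrix$values, p("expression.tsv"), "gene_id")
  utils::write.table(study$expression$samples, p("expression_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$methylation$matrix$beta, p("methylation_beta.tsv"),
                   "probe_id")
  write_matrix_tsv(study$methylation$matrix$detection_p,
                   p("methylation_detection_p.tsv"), "probe_id")
  utils::write.table(study$methylation$matrix$probes, p("probe_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = colnames(study$methylation$matrix$beta),
                                group = study$methylation$matrix$group,
                                stringsAsFactors = FALSE),
                     p("methylation_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$methylation$expression, p("methylation_expression.tsv"),
                   "gene_id")
  utils::write.table(study$methylation$covariates, p("covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Bundle directory.
#' @return A list with the same input components as a
#'   [generate_study()] result (`models`, `annotations`, `synteny`,
#'   `phenotypes`, `expression`, `methylation`), plus `truth` when
#'   `truth.json` is present. The object is accepted by [run_screen()]'s
#'   individual arguments.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  segs <- read_bed_segments(p("models.bed"))
  spec <- utils::read.delim(p("model_species.tsv"), stringsAsFactors = FALSE)
  models <- lapply(spec$model, function(nm)
    aneuploidy_model(nm, spec$species[spec$model == nm],
                     segs[segs$model == nm, c("chrom", "start", "end")]))
  names(models) <- spec$model
  annotations <- list(
    mouse = read_gene_annotation(p("annotation_mouse.tsv")),
    human = read_gene_annotation(p("annotation_human.tsv")))
  synteny <- read_ortholog_map(p("orthologs.tsv"))
  phenotypes <- read_phenotypes(p("phenotypes.tsv"))
  esamp <- utils::read.delim(p("expression_samples.tsv"), stringsAsFactors = FALSE)
  evals <- read_matrix_tsv(p("expression.tsv"), "expression")
  expr <- expression_matrix(evals[, esamp$sample_id, drop = FALSE], esamp$group)
  beta <- read_matrix_tsv(p("methylation_beta.tsv"), "beta")
  det <- read_matrix_tsv(p("methylation_detection_p.tsv"), "detection_p")
  probes <- utils::read.delim(p("probe_manifest.tsv"), stringsAsFactors = FALSE)
  msamp <- utils::read.delim(p("methylation_samples.tsv"), stringsAsFactors = FALSE)
  meth <- methylation_matrix(beta[, msamp$sample_id, drop = FALSE],
                             det[, msamp$sample_id, drop = FALSE],
                             probes, msamp$group)
  mexpr <- read_matrix_tsv(p("methylation_expression.tsv"), "expression")
  covs <- utils::read.delim(p("covariates.tsv"), stringsAsFactors = FALSE)
  out <- list(models = models, annotations = annotations, synteny = synteny,
              phenotypes = phenotypes,
              expression = list(matrix = expr, samples = esamp),
              methylation = list(matrix = meth, expression = mexpr,
                                 covariates = covs))
  if (file.exists(p("truth.json")))
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  out
}
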