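#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention): `start` is the first
#' base covered, `end` is one past the last. Empty intervals
#' (`start >= end`) are rejected rather than represented.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-valued vector of 0-based inclusive starts (>= 0).
#' @param end Integer-valued vector of 0-based exclusive ends.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and class
#'   `genomic_intervals`.
#' @examples
#' genomic_intervals("chr16", 10, 20)
#' @export
genomic_intervals <- function(chrom = character(), start = numeric(),
                              end = numeric()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(is.na(df$chrom) | is.na(df$start) | is.na(df$end) |
                 df$start < 0 | df$start >= df$end |
                 df$start != floor(df$start) | df$end != floor(df$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row(s) %s: need 0 <= start < end (integers); got e.g. %s:%s-%s",
                 what, paste(utils::head(bad, 5), collapse = ","),
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  }
  invisible(df)
}

## half-open data.frame <-> GRanges (1-based closed) conversion
as_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

from_granges <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Normalize a set of genomic intervals
#'
#' Sorts by (chrom, start) and merges overlapping or bookended
#' (`end == start`) same-chromosome intervals. Total covered base pairs are
#' unchanged and the result is idempotent under re-normalization.
#'
#' @param segments A `genomic_intervals` data.frame (or coercible
#'   data.frame with `chrom`, `start`, `end`).
#' @return A normalized `genomic_intervals` data.frame.
#' @examples
#' normalize_segments(genomic_intervals(c("chr16", "chr16"), c(10, 15), c(20, 30)))
#' @export
normalize_segments <- function(segments) {
  validate_intervals(segments, "segment")
  from_granges(GenomicRanges::reduce(as_granges(segments)))
}

#' Set algebra over interval sets
#'
#' Computes the per-base-pair union, intersection or difference of two
#' normalized interval sets.
#'
#' @param a,b Normalized `genomic_intervals` data.frames.
#' @param mode One of `"union"`, `"intersect"`, `"subtract"` (`a` minus `b`).
#' @return A normalized `genomic_intervals` data.frame whose covered
#'   positions equal the corresponding set operation on the inputs.
#' @examples
#' a <- genomic_intervals("chr16", 0, 100)
#' b <- genomic_intervals("chr16", 40, 60)
#' segment_set_op(a, b, "subtract")
#' @export
segment_set_op <- function(a, b, mode = c("union", "intersect", "subtract")) {
  mode <- match.arg(mode)
  validate_intervals(a, "segment (a)")
  validate_intervals(b, "segment (b)")
  ga <- as_granges(a); gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  gr <- switch(mode,
               union = GenomicRanges::reduce(c(ga, gb)),
               intersect = GenomicRanges::intersect(ga, gb, ignore.strand = TRUE),
               subtract = GenomicRanges::setdiff(ga, gb, ignore.strand = TRUE))
  from_granges(GenomicRanges::reduce(gr))
}

#' Genes covered by dosage-altered segments
#'
#' @param genes A gene annotation data.frame with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open; see
#'   [read_gene_annotation()]).
#' @param segments Normalized `genomic_intervals`.
#' @param containment `"full"` (default): a gene counts only if its interval
#'   lies entirely within one segment -- partial triplication does not
#'   guarantee a functional extra copy. `"any_overlap"`: one shared base pair
#'   suffices.
#' @return Sorted character vector of `gene_id`s.
#' @examples
#' ann <- data.frame(gene_id = "g1", chrom = "chr16", start = 50, end = 60)
#' genes_in_segments(ann, genomic_intervals("chr16", 0, 100))
#' @export
genes_in_segments <- function(genes, segments,
                              containment = c("full", "any_overlap")) {
  containment <- match.arg(containment)
  if (nrow(genes) == 0L || nrow(segments) == 0L) return(character())
  validate_intervals(genes, "gene location")
  gg <- as_granges(genes)
  gs <- as_granges(segments)
  lv <- union(GenomeInfoDb::seqlevels(gg), GenomeInfoDb::seqlevels(gs))
  GenomeInfoDb::seqlevels(gg) <- lv
  GenomeInfoDb::seqlevels(gs) <- lv
  type <- if (containment == "full") "within" else "any"
  hits <- GenomicRanges::findOverlaps(gg, gs, type = type,
                                      ignore.strand = TRUE)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Construct an ortholog (synteny) map
#'
#' @param pairs A data.frame with columns `mouse` and `human` holding gene
#'   identifiers; duplicate rows are collapsed.
#' @param policy `"one_to_one_only"` (default) drops every gene involved in
#'   an ambiguous (one-to-many or many-to-one) link -- dosage reasoning is
#'   ill-defined for ambiguous orthology. `"keep_all"` retains the full
#'   relation.
#' @return A `synteny_map` object; ambiguous pairs removed under
#'   `one_to_one_only` are kept in `$ambiguous`.
#' @export
synteny_map <- function(pairs, policy = c("one_to_one_only", "keep_all")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(pairs), all(c("mouse", "human") %in% names(pairs)))
  pairs <- unique(pairs[, c("mouse", "human")])
  pairs$mouse <- as.character(pairs$mouse)
  pairs$human <- as.character(pairs$human)
  if (anyNA(pairs)) stop("ortholog pairs contain missing identifiers", call. = FALSE)
  ambiguous <- pairs[0, ]
  if (policy == "one_to_one_only") {
    multi <- pairs$mouse %in% pairs$mouse[duplicated(pairs$mouse)] |
      pairs$human %in% pairs$human[duplicated(pairs$human)]
    ambiguous <- pairs[multi, , drop = FALSE]
    if (nrow(ambiguous))
      warning(sprintf("dropped %d ambiguous ortholog pair(s) under one_to_one_only",
                      nrow(ambiguous)), call. = FALSE)
    pairs <- pairs[!multi, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, policy = policy, ambiguous = ambiguous),
            class = "synteny_map")
}

#' Project a gene set across species through an ortholog map
#'
#' @param gene_ids Character vector (treated as a set).
#' @param map A [synteny_map()].
#' @param direction `"mouse_to_human"` or `"human_to_mouse"`.
#' @return A list with `genes` (sorted image of the set) and `dropped`
#'   (input genes with no retained ortholog link).
#' @examples
#' m <- synteny_map(data.frame(mouse = "Rcan1_m", human = "RCAN1_h"))
#' project_orthologs("Rcan1_m", m, "mouse_to_human")
#' @export
project_orthologs <- function(gene_ids, map,
                              direction = c("mouse_to_human", "human_to_mouse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "synteny_map"))
  gene_ids <- unique(as.character(gene_ids))
  from <- if (direction == "mouse_to_human") map$pairs$mouse else map$pairs$human
  to <- if (direction == "mouse_to_human") map$pairs$human else map$pairs$mouse
  keep <- from %in% gene_ids
  list(genes = sort(unique(to[keep])),
       dropped = sort(setdiff(gene_ids, from)))
}

#' Aneuploidy model: named dosage-altered segments plus a phenotype call
#'
#' @param name Model label (e.g. `"Ts65Dn"`); non-empty.
#' @param species `"mouse"`, `"human"` (e.g. a transchromosomic line
#'   carrying a human chromosome) or `"mixed"`.
#' @param segments Dosage-altered (3-copy) intervals; normalized on
#'   construction.
#' @param phenotype Optional [phenotype_call()] (usually attached by the
#'   screen after classification).
#' @return An `aneuploidy_model` object.
#' @export
aneuploidy_model <- function(name, species = c("mouse", "human", "mixed"),
                             segments, phenotype = NULL) {
  species <- match.arg(species)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("model name must be a non-empty string", call. = FALSE)
  segments <- normalize_segments(segments)
  if (!is.null(phenotype) && !inherits(phenotype, "phenotype_call"))
    stop("phenotype must be a phenotype_call or NULL", call. = FALSE)
  structure(list(name = name, species = species, segments = segments,
                 phenotype = phenotype),
            class = "aneuploidy_model")
}

#' @export
print.aneuploidy_model <- function(x, ...) {
  lab <- if (is.null(x$phenotype)) "unclassified" else x$phenotype$label
  cat(sprintf("<aneuploidy_model> %s (%s): %d segment(s), %s bp at 3 copies; phenotype: %s\n",
              x$name, x$species, nrow(x$segments),
              format(sum(x$segments$end - x$segments$start), big.mark = ","),
              lab))
  invisible(x)
}

## core of the screen: genes triplicated in every affected model and in no
## unaffected model (set-level; used on projected human gene sets)
screen_gene_sets <- function(affected_sets, unaffected_sets = list()) {
  stopifnot(length(affected_sets) >= 1L)
  core <- Reduce(intersect, affected_sets)
  excl <- if (length(unaffected_sets)) Reduce(union, unaffected_sets) else character()
  sort(setdiff(core, excl))
}

## dosage gene set of one model, projected to human ids
model_human_gene_set <- function(model, annotations, map, containment) {
  mouse_part <- character(); human_part <- character(); dropped <- character()
  if (model$species %in% c("mouse", "mixed")) {
    g <- genes_in_segments(annotations$mouse, model$segments, containment)
    pr <- project_orthologs(g, map, "mouse_to_human")
    mouse_part <- pr$genes
    dropped <- pr$dropped
  }
  if (model$species %in% c("human", "mixed")) {
    human_part <- genes_in_segments(annotations$human, model$segments, containment)
  }
  list(genes = sort(union(mouse_part, human_part)), dropped = dropped)
}

#' Candidate gene set from a classified model panel
#'
#' Implements the screen's region logic: genes whose dosage is increased in
#' every phenotype-affected model and in no non-affected model. Mouse gene
#' sets are projected to human orthologs; human-species models contribute
#' human genes directly. "Non-affected" is any phenotype different from
#' `affected_label` (so both normal and opposite-direction models exclude
#' their regions).
#'
#' @param models List of [aneuploidy_model()]s, each with a phenotype call.
#' @param annotations List with elements `mouse` and `human`, each a gene
#'   annotation data.frame (`gene_id`, `chrom`, `start`, `end`, ...).
#' @param map A [synteny_map()].
#' @param affected_label Phenotype label defining "affected"
#'   (default `"hyperglycaemic"`).
#' @param containment Passed to [genes_in_segments()].
#' @return A list: `candidates` (sorted human gene ids), `per_model`
#'   (named list of each model's projected gene set), `affected` /
#'   `unaffected` (model names), `dropped` (mouse genes without ortholog
#'   links, by model).
#' @export
candidate_gene_set <- function(models, annotations, map,
                               affected_label = "hyperglycaemic",
                               containment = c("full", "any_overlap")) {
  containment <- match.arg(containment)
  stopifnot(length(models) >= 1L)
  nm <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate model names in panel", call. = FALSE)
  no_ph <- nm[vapply(models, function(m) is.null(m$phenotype), logical(1))]
  if (length(no_ph))
    stop("model(s) without a phenotype call: ", paste(no_ph, collapse = ", "),
         call. = FALSE)
  labels <- vapply(models, function(m) m$phenotype$label, character(1))
  affected <- nm[labels == affected_label]
  if (!length(affected))
    stop(sprintf("no affected model: no model in the panel is '%s'", affected_label),
         call. = FALSE)
  sets <- lapply(models, model_human_gene_set,
                 annotations = annotations, map = map, containment = containment)
  names(sets) <- nm
  gene_sets <- lapply(sets, `[[`, "genes")
  candidates <- screen_gene_sets(gene_sets[affected],
                                 gene_sets[setdiff(nm, affected)])
  list(candidates = candidates,
       per_model = gene_sets,
       affected = affected,
       unaffected = setdiff(nm, affected),
       dropped = lapply(sets, `[[`, "dropped"))
}
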