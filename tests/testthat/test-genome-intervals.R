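test_that("interval construction rejects empty and negative intervals", {
  expect_error(genomic_intervals("chr16", 200, 100), "row\\(s\\) 1")
  expect_error(genomic_intervals("chr16", 10, 10), "start < end")
  expect_error(genomic_intervals("chr16", -5, 10), "start < end|0 <=")
  expect_silent(genomic_intervals("chr16", 0, 1))
})

test_that("normalize_segments merges overlaps and bookends, preserves coverage", {
  out <- normalize_segments(genomic_intervals(c("chr16", "chr16"),
                                              c(10, 15), c(20, 30)))
  expect_equal(out$start, 10)
  expect_equal(out$end, 30)

  one <- genomic_intervals("chr16", 10, 20)
  expect_equal(normalize_segments(one)$end, 20)

  book <- genomic_intervals(c("chr16", "chr16", "chr17"),
                            c(0, 5, 2), c(5, 9, 4))
  out <- normalize_segments(book)
  expect_equal(nrow(out), 2)
  expect_setequal(bp_coverage(out), bp_coverage(book))
})

test_that("normalize_segments is idempotent on random inputs", {
  set.seed(101)
  for (i in 1:25) {
    x <- random_intervals()
    n1 <- normalize_segments(x)
    expect_identical(normalize_segments(n1), n1)
    expect_true(is_normalized(n1))
    expect_setequal(bp_coverage(n1), bp_coverage(x))
  }
})

test_that("segment_set_op matches the per-base-pair oracle in all modes", {
  a <- genomic_intervals("chr16", 0, 100)
  b <- genomic_intervals("chr16", 40, 60)
  expect_equal(segment_set_op(a, b, "intersect"),
               genomic_intervals("chr16", 40, 60), ignore_attr = TRUE)
  expect_equal(segment_set_op(a, b, "subtract")$start, c(0, 60))
  expect_equal(segment_set_op(a, b, "subtract")$end, c(40, 100))
  u <- segment_set_op(genomic_intervals("chr16", 0, 10),
                      genomic_intervals("chr17", 0, 10), "union")
  expect_equal(nrow(u), 2)
  expect_error(segment_set_op(a, b, "xor"), "arg")

  set.seed(202)
  for (i in 1:20) {
    x <- normalize_segments(random_intervals())
    y <- normalize_segments(random_intervals())
    for (mode in c("union", "intersect", "subtract")) {
      got <- segment_set_op(x, y, mode)
      expect_true(is_normalized(got))
      expect_setequal(bp_coverage(got), bp_set_op(x, y, mode))
    }
  }
})

test_that("genes_in_segments honours containment mode and chromosome", {
  seg <- genomic_intervals("chr16", 0, 100)
  inside <- data.frame(gene_id = "g", chrom = "chr16", start = 50, end = 60)
  straddle <- data.frame(gene_id = "g", chrom = "chr16", start = 90, end = 110)
  offchrom <- data.frame(gene_id = "g", chrom = "chr17", start = 50, end = 60)
  expect_equal(genes_in_segments(inside, seg, "full"), "g")
  expect_equal(genes_in_segments(straddle, seg, "full"), character())
  expect_equal(genes_in_segments(straddle, seg, "any_overlap"), "g")
  expect_equal(genes_in_segments(offchrom, seg, "full"), character())
  expect_equal(genes_in_segments(offchrom, seg, "any_overlap"), character())
  expect_equal(genes_in_segments(inside[0, ], seg), character())
})

test_that("ortholog projection maps, drops, and round-trips", {
  m <- synteny_map(data.frame(mouse = "Rcan1_m", human = "RCAN1_h"))
  expect_equal(project_orthologs("Rcan1_m", m, "mouse_to_human")$genes,
               "RCAN1_h")
  expect_equal(project_orthologs(character(), m, "mouse_to_human")$genes,
               character())
  pr <- project_orthologs(c("g1_m", "g2_m"),
                          synteny_map(data.frame(mouse = "g1_m", human = "G1_h")),
                          "mouse_to_human")
  expect_equal(pr$genes, "G1_h")
  expect_equal(pr$dropped, "g2_m")
  expect_error(project_orthologs("x", m, "sideways"), "arg")

  ## one_to_one_only drops ambiguous links with a warning
  expect_warning(
    amb <- synteny_map(data.frame(mouse = c("a", "a", "b"),
                                  human = c("A", "B", "C"))),
    "ambiguous")
  expect_equal(amb$pairs$mouse, "b")

  ## m->h then h->m lands inside the original set
  set.seed(3)
  pairs <- data.frame(mouse = sprintf("m%d", 1:30),
                      human = sprintf("h%d", sample(1:40, 30)))
  map <- suppressWarnings(synteny_map(pairs))
  s <- sprintf("m%d", sample(1:35, 12))
  fwd <- project_orthologs(s, map, "mouse_to_human")$genes
  back <- project_orthologs(fwd, map, "human_to_mouse")$genes
  expect_true(all(back %in% s))
})

make_panel_gene <- function(ids) {
  ## genes "gN" at disjoint 10bp slots on one chromosome, mouse + human twin
  data.frame(gene_id = ids, symbol = ids, species = "x",
             chrom = "c1", start = (as.integer(sub("g", "", ids)) - 1) * 10,
             end = (as.integer(sub("g", "", ids)) - 1) * 10 + 8,
             strand = "+", stringsAsFactors = FALSE)
}

panel_model <- function(name, idx, label, species = "mouse",
                        chrom = if (species == "mouse") "c1" else "h1") {
  segs <- genomic_intervals(rep(chrom, length(idx)),
                            (idx - 1) * 10, (idx - 1) * 10 + 10)
  aneuploidy_model(name, species, segs,
                   phenotype_call(label, if (label == "normoglycaemic") 0.5 else 1e-4,
                                  if (label == "hypoglycaemic") -1 else 1))
}

panel_fixture <- function() {
  mouse <- make_panel_gene(sprintf("g%d", 1:20))
  human <- mouse
  human$gene_id <- sub("g", "h", human$gene_id)
  human$chrom <- "h1"
  list(ann = list(mouse = mouse, human = human),
       map = synteny_map(data.frame(mouse = sprintf("g%d", 1:20),
                                    human = sprintf("h%d", 1:20))))
}

test_that("candidate_gene_set intersects affected and excludes unaffected", {
  fx <- panel_fixture()
  A <- panel_model("A", 1:10, "hyperglycaemic")
  B <- panel_model("B", 5:15, "hyperglycaemic")
  C <- panel_model("C", 7:8, "normoglycaemic")
  res <- candidate_gene_set(list(A, B, C), fx$ann, fx$map)
  expect_equal(res$candidates, sort(sprintf("h%d", c(5, 6, 9, 10))))

  ## single affected model, nothing to exclude -> its full projected set
  solo <- candidate_gene_set(list(A), fx$ann, fx$map)
  expect_equal(solo$candidates, sort(sprintf("h%d", 1:10)))

  ## disjoint affected models -> empty
  D <- panel_model("D", 15:20, "hyperglycaemic")
  expect_equal(candidate_gene_set(list(A, D), fx$ann, fx$map)$candidates,
               character())

  ## human-species model contributes human genes directly (no projection)
  Tc <- panel_model("Tc", 9:10, "hypoglycaemic", species = "human")
  res2 <- candidate_gene_set(list(A, B, Tc), fx$ann, fx$map)
  expect_equal(res2$candidates, sort(sprintf("h%d", 5:8)))

  ## error paths
  expect_error(candidate_gene_set(list(C), fx$ann, fx$map), "no affected")
  noph <- aneuploidy_model("E", "mouse", genomic_intervals("c1", 0, 10))
  expect_error(candidate_gene_set(list(A, noph), fx$ann, fx$map),
               "without a phenotype")
})

test_that("candidate set is anti-monotone in added models", {
  fx <- panel_fixture()
  set.seed(404)
  for (i in 1:10) {
    aff <- lapply(1:2, function(k)
      panel_model(paste0("A", k), sort(sample(1:20, sample(5:15, 1))),
                  "hyperglycaemic"))
    base <- candidate_gene_set(aff, fx$ann, fx$map)$candidates
    extra_un <- panel_model("U", sort(sample(1:20, 5)), "normoglycaemic")
    extra_af <- panel_model("A3", sort(sample(1:20, 8)), "hyperglycaemic")
    with_un <- candidate_gene_set(c(aff, list(extra_un)), fx$ann, fx$map)$candidates
    with_af <- candidate_gene_set(c(aff, list(extra_af)), fx$ann, fx$map)$candidates
    expect_true(all(with_un %in% base))
    expect_true(all(with_af %in% base))
  }
})
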