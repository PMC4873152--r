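## Independent brute-force oracles used across the suite.

## every covered base pair as "chrom:pos" tokens (0-based positions)
bp_coverage <- function(df) {
  if (nrow(df) == 0L) return(character())
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1))))
}

## per-bp set operation oracle
bp_set_op <- function(a, b, mode) {
  ca <- bp_coverage(a); cb <- bp_coverage(b)
  switch(mode,
         union = union(ca, cb),
         intersect = intersect(ca, cb),
         subtract = setdiff(ca, cb))
}

## random interval set on a tiny genome
random_intervals <- function(n_max = 20, genome = 1000,
                             chroms = c("chrA", "chrB")) {
  n <- sample.int(n_max, 1)
  start <- sample.int(genome - 1, n, replace = TRUE) - 1
  len <- sample.int(60, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE),
                    start, pmin(start + len, genome))
}

## raw vector with EXACT sample mean m and sample sd s (affine-rescaled noise)
raw_with_moments <- function(m, s, n) {
  z <- rnorm(n)
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

## is an interval table normalized? (sorted, strictly separated per chrom)
is_normalized <- function(df) {
  if (nrow(df) < 2) return(TRUE)
  ord <- order(df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df)))) return(FALSE)
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  all(!same | df$start[-1] > df$end[-nrow(df)])
}
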