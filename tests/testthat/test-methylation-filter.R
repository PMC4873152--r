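toy_meth <- function(beta, det = NULL, group = NULL) {
  if (is.null(det)) det <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (is.null(group)) group <- rep("ND", ncol(beta))
  methylation_matrix(beta, det,
                     data.frame(probe_id = rownames(beta), gene_id = "g"),
                     group)
}

test_that("the logit2 transform hits its anchor points and inverts exactly", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.25), -1.584962500721156)  # log2(1/3)
  expect_error(beta_to_m(0), "strictly inside")
  expect_error(beta_to_m(1.2), "strictly inside")
  grid <- seq(1e-6, 1 - 1e-6, length.out = 10000)
  expect_equal(m_to_beta(beta_to_m(grid)), grid, tolerance = 1e-12)
  expect_true(all(diff(beta_to_m(grid)) > 0))
})

test_that("detection filter removes by MEAN detection P, strictly", {
  beta <- matrix(0.5, 3, 4, dimnames = list(c("p1", "p2", "p3"),
                                            sprintf("s%d", 1:4)))
  det <- rbind(p1 = rep(0.02, 4),      # mean 0.02 > 0.01 -> removed
               p2 = rep(0, 4),         # clean -> retained
               p3 = rep(0.01, 4))      # exactly the threshold -> retained
  colnames(det) <- sprintf("s%d", 1:4)
  mm <- toy_meth(beta, det)
  f <- detection_filter(mm, 0.01)
  expect_setequal(rownames(f$beta), c("p2", "p3"))
  expect_equal(attr(f, "removed"), "p1")
  ## idempotent, and order of probes does not matter
  expect_equal(rownames(detection_filter(f, 0.01)$beta), rownames(f$beta))
  perm <- toy_meth(beta[c(3, 1, 2), ], det[c(3, 1, 2), ])
  expect_setequal(attr(detection_filter(perm, 0.01), "removed"), "p1")
  expect_warning(detection_filter(toy_meth(beta, det * 0 + 0.5)), "all probes")
})

test_that("association recovers a noise-free linear signal exactly", {
  set.seed(41)
  n <- 30
  x <- rnorm(n, 5, 0.5)
  cov1 <- rnorm(n)
  M <- rbind(site1 = -2 * x + 0.5 * cov1 + 3)
  beta <- m_to_beta(M)
  colnames(beta) <- sprintf("s%d", 1:n)
  mm <- toy_meth(beta)
  a <- site_expression_association(mm, x, data.frame(cov1 = cov1))
  expect_equal(a$slope, -2, tolerance = 1e-10)
  expect_lt(a$p_value, 1e-20)
  expect_equal(a$direction, -1)
})

test_that("with no covariates the fit equals closed-form simple regression", {
  set.seed(42)
  n <- 49
  x <- rnorm(n, 5, 0.5)
  M <- rbind(s1 = -0.8 * x + rnorm(n), s2 = 0.3 * x + rnorm(n))
  beta <- m_to_beta(M / 4)  # keep betas inside (0,1) comfortably
  colnames(beta) <- sprintf("s%d", 1:n)
  mm <- toy_meth(beta)
  a <- site_expression_association(mm, x, NULL)
  for (i in 1:2) {
    y <- beta_to_m(beta[i, ])
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    p <- 2 * pt(-abs(slope / se), n - 2)
    expect_equal(a$slope[i], slope, tolerance = 1e-11)
    expect_equal(a$se[i], se, tolerance = 1e-11)
    expect_equal(a$p_value[i], p, tolerance = 1e-11)
  }
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  set.seed(43)
  n <- 20
  x <- rnorm(n)
  beta <- m_to_beta(rbind(s1 = rnorm(n) / 4))
  colnames(beta) <- sprintf("s%d", 1:n)
  expect_error(site_expression_association(toy_meth(beta), x,
                                           data.frame(dup = x)),
               "collinear.*dup|rank-deficient")
})

test_that("negative-site flagging gates on direction and adjusted p", {
  a <- data.frame(probe_id = c("neg_sig", "pos_sig", "neg_ns"),
                  slope = c(-0.5, 0.5, -0.5),
                  p_value = c(1e-6, 1e-9, 0.2),
                  direction = c(-1, 1, -1))
  expect_equal(flag_negative_sites(a, 0.05, "bonferroni"), "neg_sig")
  expect_equal(flag_negative_sites(a, 0.05, "none"), "neg_sig")
})

test_that("family-wise false-flag rate under the 16-probe null is controlled", {
  set.seed(44)
  reps <- 400
  hits <- replicate(reps, {
    n <- 49
    x <- rnorm(n, 5, 0.5)
    M <- matrix(rnorm(16 * n), 16,
                dimnames = list(sprintf("p%02d", 1:16), sprintf("s%d", 1:n)))
    mm <- toy_meth(m_to_beta(M / 4))
    length(flag_negative_sites(site_expression_association(mm, x, NULL),
                               0.05, "bonferroni")) > 0
  })
  rate <- mean(hits)
  ## one-sided family alpha for negative flags is 0.05/2 at most
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("group methylation differences reproduce the printed site summaries", {
  printed <- data.frame(
    probe_id = c("cg05156137", "cg21301258", "cg05056497"),
    mean_1 = c(51.1, 57.9, 42.3), sem_1 = c(1.8, 1.9, 1.5), n_1 = 34,
    mean_2 = c(40.2, 48.0, 29.5), sem_2 = c(3.1, 3.2, 1.9), n_2 = 15)
  d <- group_methylation_difference(printed)
  expect_equal(d$delta, c(10.9, 9.9, 12.8))
  expect_lt(d$p_value[d$probe_id == "cg05056497"], 0.001)
  expect_lt(d$p_value[d$probe_id == "cg21301258"], 0.01)
  expect_lt(d$p_value[d$probe_id == "cg05156137"], 0.01)

  same <- data.frame(probe_id = "x", mean_1 = 50, sem_1 = 2, n_1 = 10,
                     mean_2 = 50, sem_2 = 2, n_2 = 10)
  ds <- group_methylation_difference(same)
  expect_equal(ds$delta, 0)
  expect_equal(ds$p_value, 1)
})

test_that("matrix-input group differences agree with a direct t test", {
  set.seed(45)
  n1 <- 20; n2 <- 12
  beta <- rbind(pr1 = c(rbeta(n1, 8, 8), rbeta(n2, 5, 8)))
  colnames(beta) <- sprintf("s%d", seq_len(n1 + n2))
  mm <- toy_meth(beta, group = c(rep("ND", n1), rep("T2D", n2)))
  d <- group_methylation_difference(mm, scale = "beta_percent")
  ref <- t.test(100 * beta[1, 1:n1], 100 * beta[1, n1 + 1:n2], var.equal = TRUE)
  expect_equal(d$p_value, ref$p.value, tolerance = 1e-11)
  expect_equal(d$delta, unname(diff(rev(ref$estimate))), tolerance = 1e-11)
})
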