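test_that("pooled scatter matches hand arithmetic and scales homogeneously", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  groups <- rep(c("patient", "control"), each = 3)
  expect_equal(pooled_scatter(mat, groups), sqrt(2 / 3), tolerance = 1e-12)
  # zero within-group variance
  flat <- matrix(c(1, 1, 1, 5, 5, 5), nrow = 1)
  expect_equal(pooled_scatter(flat, groups), 0)
  # homogeneity: scaling values by c scales s by c
  set.seed(1)
  m <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(pooled_scatter(3.7 * m, groups),
               3.7 * pooled_scatter(m, groups), tolerance = 1e-12)
})

test_that("d-scores follow the (mean diff)/(s + s0) definition", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  groups <- rep(c("patient", "control"), each = 3)
  expect_equal(d_scores(mat, groups, s0 = 0), -3 / sqrt(2 / 3),
               tolerance = 1e-12)
  # mean diff 1, s = 0, s0 = 0.5 -> d = 2
  flat <- matrix(c(2, 2, 2, 1, 1, 1), nrow = 1)
  expect_equal(d_scores(flat, groups, s0 = 0.5), 2)
  # swapping labels negates d
  set.seed(2)
  m <- matrix(rnorm(8 * 8), 8, 8)
  g <- rep(c("patient", "control"), each = 4)
  expect_equal(d_scores(m, g, 0.1), -d_scores(m, rev(g), 0.1),
               tolerance = 1e-12)
})

test_that("with s0 = 0 and equal groups d matches the classical t up to a constant", {
  set.seed(3)
  m <- matrix(rnorm(50 * 8), 50, 8)
  g <- rep(c("patient", "control"), each = 4)
  d <- d_scores(m, g, s0 = 0)
  tstat <- apply(m, 1, function(x) {
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic
  })
  expect_equal(d, unname(tstat), tolerance = 1e-9)
})

test_that("s0 estimation: fixed passthrough, degenerate tie, CV improvement", {
  p <- sam_params(s0_method = "fixed", s0_fixed = 0.5)
  expect_equal(estimate_s0(rnorm(10), runif(10), p), 0.5)
  # all scatters equal: every candidate ties, smallest returned
  num <- rnorm(200)
  s <- rep(2, 200)
  expect_equal(estimate_s0(num, s), 2)
  # heteroscedastic data: chosen s0 reduces the CV relative to s0 = 0
  set.seed(4)
  s <- sort(runif(2000, 0.05, 2))
  num <- rnorm(2000, 0, s + 0.5)
  s0 <- estimate_s0(num, s)
  cv_of <- function(a) {
    bins <- cut(s, breaks = quantile(s, seq(0, 1, length.out = 101)),
                include.lowest = TRUE)
    med <- tapply(abs(num / (s + a)), bins, median)
    sd(med) / mean(med)
  }
  expect_lte(cv_of(s0), cv_of(0))
})

test_that("permutation null enumerates exhaustively and includes the identity", {
  m <- toy_matrix(p = 6)
  g <- toy_groups()
  null <- permutation_null(m, g, s0 = 0.2, sam_params(seed = 1))
  expect_true(null$exhaustive)
  expect_equal(null$n_assignments, choose(8, 4))
  expect_equal(ncol(null$d_null), 70)
  # 3 patients vs 4 controls
  m2 <- toy_matrix(p = 6, n1 = 3, n2 = 4)
  null2 <- permutation_null(m2, toy_groups(3, 4), s0 = 0.2,
                            sam_params(seed = 1))
  expect_equal(null2$n_assignments, choose(7, 3))
  expect_equal(ncol(null2$d_null), 35)
  # identity assignment reproduces the observed d exactly
  d_obs <- d_scores(m, g, 0.2)
  found <- any(apply(null$d_null, 2, function(col) {
    isTRUE(all.equal(col, sort(d_obs), tolerance = 1e-12))
  }))
  expect_true(found)
})

test_that("fdr table limits: huge delta calls nothing, zero delta calls everything", {
  m <- toy_matrix()
  g <- toy_groups()
  null <- permutation_null(m, g, 0.2, sam_params(seed = 1))
  d <- d_scores(m, g, 0.2)
  ft <- fdr_table(d, null, deltas = c(0, 1e6))
  expect_equal(ft$n_called[ft$delta == 1e6], 0L)
  expect_equal(ft$fdr[ft$delta == 1e6], 0)
  expect_equal(ft$n_called[ft$delta == 0], nrow(m))
})

test_that("q-values: most extreme probe hits the floor, d = 0 gives q = 1", {
  m <- toy_matrix(p = 12, n_de = 2, effect = 6)
  m[3, ] <- c(rep(2, 4), rep(2, 4))  # exactly equal group means -> d = 0
  g <- toy_groups()
  res <- run_sam(m, g, sam_params(seed = 1, s0_method = "fixed",
                                  s0_fixed = 0.3))
  tb <- res$table
  expect_equal(tb$q_value[3], 1)
  expect_equal(sprintf("%.3f", min(tb$q_value)), "0.000")
  expect_equal(tb$q_value[which.max(abs(tb$d))], min(tb$q_value))
})

test_that("fold changes follow the signed reciprocal convention", {
  g <- rep(c("patient", "control"), each = 2)
  same <- matrix(c(3, 3, 3, 3), nrow = 1)
  expect_equal(fold_changes(same, g), 1)
  down2 <- matrix(c(5, 5, 7, 7), nrow = 1)  # patient 2 log2 units below
  expect_equal(fold_changes(down2, g), -4)
  set.seed(5)
  m <- matrix(rnorm(100 * 4), 100, 4)
  expect_true(all(abs(fold_changes(m, g)) >= 1))
})

test_that("full SAM equals the independent brute-force recount on a tiny instance", {
  m <- toy_matrix(p = 12, n_de = 3, effect = 2.5, seed = 11)
  g <- toy_groups()
  s0 <- 0.25
  res <- run_sam(m, g, sam_params(seed = 1, s0_method = "fixed",
                                  s0_fixed = s0))
  orc <- oracle_sam(m, g, s0)
  expect_true(res$exhaustive)
  expect_equal(res$table$d, orc$d, tolerance = 1e-12)
  expect_equal(res$dbar, orc$dbar, tolerance = 1e-12)
  expect_equal(res$fdr_table$delta, orc$deltas, tolerance = 1e-12)
  expect_equal(res$fdr_table$n_called, orc$n_called)
  expect_equal(res$fdr_table$fdr, orc$fdr, tolerance = 1e-12)
  expect_equal(res$table$q_value, orc$q, tolerance = 1e-12)
})

test_that("q-values are invariant to probe order and identical across reruns", {
  m <- toy_matrix(p = 15, n_de = 3, seed = 21)
  g <- toy_groups()
  p <- sam_params(seed = 9, s0_method = "fixed", s0_fixed = 0.2)
  r1 <- run_sam(m, g, p)
  r2 <- run_sam(m, g, p)
  expect_identical(r1$table, r2$table)  # determinism contract
  perm <- sample(nrow(m))
  r3 <- run_sam(m[perm, ], g, p)
  expect_equal(r3$table$q_value[match(r1$table$probe_id, r3$table$probe_id)],
               r1$table$q_value, tolerance = 1e-12)
})

test_that("null data yields an empty low-q tail and spike-ins take the lowest ranks", {
  set.seed(31)
  frac <- replicate(5, {
    m <- matrix(rnorm(300 * 8), 300, 8)
    res <- run_sam(m, toy_groups(), sam_params(seed = 1))
    mean(res$table$q_value <= 0.05)
  })
  expect_lte(median(frac), 0.02)

  m <- toy_matrix(p = 300, n_de = 6, effect = 3, seed = 32)
  res <- run_sam(m, toy_groups(), sam_params(seed = 1))
  top6 <- res$table$probe_id[order(res$table$q_value,
                                   -abs(res$table$d))][1:6]
  expect_setequal(top6, sprintf("g%02d", 1:6))
})
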