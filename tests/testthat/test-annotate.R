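test_that("probe classification covers intronic sense/antisense, coding and intergenic", {
  gm <- toy_gene_models()
  probes <- tibble::tibble(
    probe_id = c("in_sense", "in_anti", "exonic", "between"),
    chrom = "chr1",
    start = c(225L, 225L, 245L, 380L),
    end = c(234L, 234L, 254L, 389L),
    strand = c("+", "-", "+", "+"))
  # probe 1/2 sit between exon1 (200-219) and exon2 (240-259) of GENEA (+)
  cl <- classify_probes(probes, gm)
  expect_equal(cl$probe_class,
               c("intronic", "intronic", "coding", "intergenic"))
  expect_equal(cl$orientation[1:2], c("sense", "antisense"))
  expect_true(is.na(cl$orientation[3]))
  expect_equal(cl$locus_name, c("GENEA", "GENEA", "GENEA", "GENEA"))
  # every probe got exactly one class
  expect_false(anyNA(cl$probe_class))
})

test_that("intergenic probes take the nearest gene; boundary overlap is coding", {
  gm <- toy_gene_models()
  # nearer GENEB (gap 500-450=50... probe 440-449: gap to GENEA(end 300)=140, to GENEB(start 500)=51)
  p <- tibble::tibble(probe_id = "x", chrom = "chr1", start = 440L,
                      end = 449L, strand = "-")
  cl <- classify_probes(p, gm)
  expect_equal(cl$probe_class, "intergenic")
  expect_equal(cl$locus_name, "GENEB")
  expect_equal(cl$orientation, "sense")  # GENEB is on "-"
  # a probe straddling an exon boundary on the same strand is coding
  straddle <- tibble::tibble(probe_id = "y", chrom = "chr1", start = 215L,
                             end = 225L, strand = "+")
  expect_equal(classify_probes(straddle, gm)$probe_class, "coding")
  # unknown chromosome -> intergenic-unnamed with a warning
  off <- tibble::tibble(probe_id = "z", chrom = "chr9", start = 10L,
                        end = 20L, strand = "+")
  expect_warning(clz <- classify_probes(off, gm), "absent")
  expect_equal(clz$probe_class, "intergenic")
  expect_true(is.na(clz$locus_name))
})

test_that("nearest gene uses minimal gaps with a deterministic tie rule", {
  gm <- tibble::tibble(
    locus_name = c("G1", "G2"), locus_id = 1:2, chrom = "chr1",
    strand = "+", start = c(200L, 500L), end = c(300L, 600L),
    exons = list(list(start = 200L, end = 300L),
                 list(start = 500L, end = 600L)))
  expect_equal(nearest_gene("chr1", 100, 159, gm), "G1")  # gap 41 vs 341
  expect_equal(nearest_gene("chr1", 250, 260, gm), "G1")  # inside, distance 0
  # equidistant: gaps both 99 -> lower start coordinate wins
  expect_message(g <- nearest_gene("chr1", 400, 400, gm), "tie")
  expect_equal(g, "G1")
  expect_error(nearest_gene("chr5", 1, 2, gm), "no gene models")
})

test_that("coding/ncRNA partition counts are exhaustive and sum correctly", {
  ann <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6),
    probe_class = c("coding", "coding", "intronic", "intronic",
                    "intergenic", "coding"))
  cons <- tibble::tibble(
    probe_id = sprintf("p%d", 1:5),
    direction = c("up", "down", "up", "down", "down"),
    q_value = 0.001, fold_change = c(2, -2, 3, -3, -2))
  part <- partition_coding_noncoding(cons, ann)
  expect_equal(sum(part$n), nrow(cons))
  get <- function(cl, dir) part$n[part$class == cl & part$direction == dir]
  expect_equal(get("coding", "up"), 1L)
  expect_equal(get("coding", "down"), 1L)
  expect_equal(get("ncrna", "up"), 1L)
  expect_equal(get("ncrna", "down"), 2L)
  # empty consensus -> all-zero grid
  empty <- partition_coding_noncoding(cons[0, ], ann)
  expect_equal(sum(empty$n), 0L)
  expect_equal(nrow(empty), 4)
  # unannotated probe is an error naming it
  expect_error(
    partition_coding_noncoding(
      tibble::tibble(probe_id = "ghost", direction = "up",
                     q_value = 0, fold_change = 2), ann),
    "ghost")
})

test_that("locus concordance pairs significant ncRNA and coding probes per locus", {
  ann <- tibble::tibble(
    probe_id = c("c1", "n1", "c2", "n2", "c3", "n3a", "n3b"),
    locus_name = c("L1", "L1", "L2", "L2", "L3", "L3", "L3"),
    probe_class = c("coding", "intronic", "coding", "intergenic",
                    "coding", "intronic", "intronic"))
  cons <- tibble::tibble(
    probe_id = c("c1", "n1", "c2", "n2", "c3", "n3a", "n3b"),
    direction = c("up", "up", "down", "up", "down", "down", "down"),
    q_value = c(0.001, 0.002, 0.001, 0.004, 0.0, 0.001, 0.003),
    fold_change = c(2, 2, -2, 2, -3, -2, -2))
  lc <- locus_concordance(cons, ann)
  # one pair per significant ncRNA probe: n1, n2, n3a, n3b
  expect_equal(nrow(lc$pairs), 4)
  expect_equal(lc$summary$n_both_up, 1L)     # L1
  expect_equal(lc$summary$n_both_down, 2L)   # L3 twice
  expect_equal(lc$summary$n_discordant, 1L)  # L2
  expect_equal(sum(lc$pairs$concordant) + sum(!lc$pairs$concordant),
               nrow(lc$pairs))
})

test_that("z-score rows are standardized with the population SD", {
  expect_equal(unname(zscore_matrix(rbind(c(1, 1, 1, 1), c(0, 0, 2, 2)))),
               rbind(c(0, 0, 0, 0), c(-1, -1, 1, 1)),
               ignore_attr = TRUE) |> suppressWarnings()
  set.seed(61)
  m <- matrix(rnorm(40), 8, 5)
  z <- zscore_matrix(m)
  expect_equal(rowMeans(z), rep(0, 8), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 8), tolerance = 1e-12)
  expect_warning(zscore_matrix(rbind(c(1, 1, 1), c(1, 2, 3))), "zero-variance")
})

test_that("UPGMA clustering on correlation distance behaves deterministically", {
  set.seed(62)
  base <- rnorm(50)
  m <- cbind(s1 = base + rnorm(50, 0, 0.01),
             s2 = base + rnorm(50, 0, 0.01),
             s3 = rnorm(50))
  res <- upgma_order(m)
  merge1 <- res$hclust$merge[1, ]
  expect_setequal(res$hclust$labels[-merge1], c("s1", "s2"))
  expect_lt(res$hclust$height[1], 0.01)
  # hand-computed 3-leaf average linkage heights
  d <- as.matrix(res$dist)
  h2_expected <- mean(c(d["s3", "s1"], d["s3", "s2"]))
  expect_equal(res$hclust$height[2], h2_expected, tolerance = 1e-12)
  # constant column is an error naming the sample
  bad <- cbind(m, s4 = rep(1, 50))
  expect_error(upgma_order(bad), "s4")
})

test_that("two well-separated groups cluster apart and order is permutation-stable", {
  set.seed(63)
  sig <- rnorm(100)
  grp_a <- sapply(1:4, function(i) sig + rnorm(100, 0, 0.2))
  grp_b <- sapply(1:4, function(i) -sig + rnorm(100, 0, 0.2))
  m <- cbind(grp_a, grp_b)
  colnames(m) <- c(paste0("PT", 1:4), paste0("CT", 1:4))
  ord <- upgma_order(m)$order
  pa <- which(ord %in% paste0("PT", 1:4))
  expect_true(all(diff(sort(pa)) == 1))  # patients contiguous in leaf order
  perm <- sample(8)
  ord2 <- upgma_order(m[, perm])$order
  expect_equal(ord2, ord)
})

test_that("cross-group correlation summarizes homogeneity and detects contrasts", {
  set.seed(64)
  base <- rnorm(200)
  ident <- sapply(1:6, function(i) base)
  colnames(ident) <- c(paste0("PT", 1:3), paste0("CT", 1:3))
  g <- rep(c("patient", "control"), each = 3)
  expect_equal(cross_group_correlation(ident, g)$mean_cor, 1)
  noise <- matrix(rnorm(4000 * 6), 4000, 6,
                  dimnames = list(NULL, colnames(ident)))
  expect_lt(abs(cross_group_correlation(noise, g)$mean_cor), 0.05)
  # planted: compartment 1 more homogeneous than compartment 2
  hom <- sapply(1:6, function(i) base + rnorm(200, 0, 0.2))
  het <- sapply(1:6, function(i) base + rnorm(200, 0, 1.0))
  colnames(hom) <- colnames(het) <- colnames(ident)
  cmp <- compare_group_correlation(hom, g, het, g)
  expect_gt(cmp$mean_cor_1, cmp$mean_cor_2)
  expect_lt(cmp$p_value, 0.01)
})
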