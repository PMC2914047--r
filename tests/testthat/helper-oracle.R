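# Independent brute-force SAM recount used as the oracle on tiny
# instances: plain loops, no shared code with the package internals.
oracle_sam <- function(mat, groups, s0, n_deltas = 200,
                       summary_fun = stats::median) {
  n <- ncol(mat)
  p <- nrow(mat)
  pat <- which(groups == "patient")
  n1 <- length(pat)

  d_for <- function(cols_pat) {
    cols_ctl <- setdiff(seq_len(n), cols_pat)
    out <- numeric(p)
    for (i in seq_len(p)) {
      x <- mat[i, cols_pat]
      y <- mat[i, cols_ctl]
      ss <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
      si <- sqrt((1 / length(x) + 1 / length(y)) * ss /
                   (length(x) + length(y) - 2))
      out[i] <- (mean(x) - mean(y)) / (si + s0)
    }
    out
  }

  d_obs <- d_for(pat)
  combos <- utils::combn(n, n1)
  null_sorted <- matrix(0, p, ncol(combos))
  for (j in seq_len(ncol(combos))) {
    null_sorted[, j] <- sort(d_for(combos[, j]))
  }
  dbar <- rowMeans(null_sorted)
  d_sorted <- sort(d_obs)
  deltas <- seq(0, max(abs(d_sorted - dbar)), length.out = n_deltas)

  cut_up <- cut_low <- fdr <- numeric(n_deltas)
  n_called <- integer(n_deltas)
  for (k in seq_along(deltas)) {
    if (deltas[k] == 0) {
      cu <- -Inf
      cl <- Inf
    } else {
      ups <- d_sorted[(d_sorted - dbar) >= deltas[k] & d_sorted >= 0]
      los <- d_sorted[(dbar - d_sorted) >= deltas[k] & d_sorted <= 0]
      cu <- if (length(ups)) min(ups) else Inf
      cl <- if (length(los)) max(los) else -Inf
    }
    called <- if (cl >= cu) rep(TRUE, p) else (d_obs >= cu) | (d_obs <= cl)
    nc <- sum(called)
    if (nc == 0) {
      f <- 0
    } else {
      counts <- numeric(ncol(null_sorted))
      for (j in seq_len(ncol(null_sorted))) {
        dn <- null_sorted[, j]
        counts[j] <- if (cl >= cu) p else sum(dn >= cu) + sum(dn <= cl)
      }
      f <- min(1, summary_fun(counts) / nc)
    }
    cut_up[k] <- cu; cut_low[k] <- cl; n_called[k] <- nc; fdr[k] <- f
  }

  q <- vapply(d_obs, function(dv) {
    ok <- (cut_low >= cut_up) |
      (((dv >= cut_up) | (dv <= cut_low)) & dv != 0)
    if (any(ok)) min(fdr[ok]) else 1
  }, numeric(1))

  list(d = d_obs, dbar = dbar, deltas = deltas, cut_up = cut_up,
       cut_low = cut_low, n_called = n_called, fdr = fdr, q = q)
}

# Small deterministic two-group matrix with a few separated probes.
toy_matrix <- function(p = 10, n1 = 4, n2 = 4, n_de = 3, effect = 3,
                       seed = 42) {
  set.seed(seed)
  mat <- matrix(rnorm(p * (n1 + n2)), p, n1 + n2)
  if (n_de > 0) {
    mat[seq_len(n_de), seq_len(n1)] <- mat[seq_len(n_de), seq_len(n1)] + effect
  }
  rownames(mat) <- sprintf("g%02d", seq_len(p))
  colnames(mat) <- c(sprintf("PT%d", seq_len(n1)), sprintf("CT%d", seq_len(n2)))
  mat
}

toy_groups <- function(n1 = 4, n2 = 4) {
  rep(c("patient", "control"), c(n1, n2))
}

toy_metadata <- function(n1 = 4, n2 = 4) {
  tibble::tibble(
    sample_id = c(sprintf("PT%d", seq_len(n1)), sprintf("CT%d", seq_len(n2))),
    group = rep(c("patient", "control"), c(n1, n2)),
    cell_type = "toy", dye = "Cy5")
}

# Tiny gene-model table: two genes per chromosome given, three exons each.
toy_gene_models <- function() {
  tibble::tibble(
    locus_name = c("GENEA", "GENEB"),
    locus_id = c(1L, 2L),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(200L, 500L),
    end = c(300L, 600L),
    exons = list(
      list(start = c(200L, 240L, 281L), end = c(219L, 259L, 300L)),
      list(start = c(500L, 540L, 581L), end = c(519L, 559L, 600L)))
  )
}
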