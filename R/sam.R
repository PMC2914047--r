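#' SAM parameters
#'
#' @param n_permutations Number of label permutations for the null
#'   (default 500). When `exhaustive_if_possible` and the number of
#'   distinct label assignments is at most `n_permutations` (e.g.
#'   choose(8,4) = 70 for a 4 vs 4 design), all assignments are
#'   enumerated instead.
#' @param seed Integer seed for sampled permutations (mandatory for
#'   reproducibility).
#' @param s0_method `"tusher_quantile"` picks the exchangeability factor
#'   s0 among the percentiles of the per-probe scatter s by minimizing the
#'   coefficient of variation of median |d| across s-quantile bins;
#'   `"fixed"` uses `s0_fixed` as given.
#' @param s0_fixed Value of s0 when `s0_method = "fixed"`.
#' @param exhaustive_if_possible Enumerate all assignments when feasible.
#' @param false_count_summary `"median"` (canonical) or `"q90"`: summary
#'   of the per-permutation false-call counts entering the FDR.
#' @param n_deltas Size of the delta grid used for the FDR table and
#'   q-values (default 200, spanning 0 to max |d(i) - dbar(i)|).
#' @return A list of class `sam_params`.
#' @export
sam_params <- function(n_permutations = 500, seed = 1L,
                       s0_method = c("tusher_quantile", "fixed"),
                       s0_fixed = NULL,
                       exhaustive_if_possible = TRUE,
                       false_count_summary = c("median", "q90"),
                       n_deltas = 200) {
  s0_method <- match.arg(s0_method)
  false_count_summary <- match.arg(false_count_summary)
  stopifnot(n_permutations >= 1, n_deltas >= 2)
  if (s0_method == "fixed" && is.null(s0_fixed)) {
    abort("s0_fixed must be given when s0_method = 'fixed'")
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), s0_method = s0_method,
                 s0_fixed = s0_fixed,
                 exhaustive_if_possible = isTRUE(exhaustive_if_possible),
                 false_count_summary = false_count_summary,
                 n_deltas = as.integer(n_deltas)),
            class = "sam_params")
}

as_group_indicator <- function(groups, n) {
  if (length(groups) != n) abort("groups length must match sample count")
  g <- match_values(groups, c("patient", "control"), "group")
  ind <- g == "patient"
  if (sum(ind) < 2 || sum(!ind) < 2) {
    abort("each group needs at least 2 samples")
  }
  ind
}

#' Pooled scatter of the SAM statistic
#'
#' s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2)), the gene-specific
#' scatter of the two-class unpaired SAM score, per probe.
#'
#' @param mat Probes x samples matrix of log2 values.
#' @param groups Character vector (`patient`/`control`) aligned to the
#'   columns of `mat`.
#' @return Numeric vector of per-probe scatters.
#' @export
pooled_scatter <- function(mat, groups) {
  mat <- as.matrix(mat)
  ind <- as_group_indicator(groups, ncol(mat))
  n1 <- sum(ind); n2 <- sum(!ind)
  m1 <- rowMeans(mat[, ind, drop = FALSE])
  m2 <- rowMeans(mat[, !ind, drop = FALSE])
  ss1 <- rowSums((mat[, ind, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, !ind, drop = FALSE] - m2)^2)
  unname(sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2)))
}

#' Estimate the exchangeability factor s0
#'
#' Candidates are the percentiles (0, 5, ..., 100) of the scatter s. For
#' each candidate, probes are binned into s-quantile bins and the
#' coefficient of variation of the median |numerator / (s + s0)| across
#' bins is computed; the candidate minimizing the CV wins, ties broken to
#' the smallest candidate. With fewer than 100 probes the method falls
#' back to median(s) with a message.
#'
#' @param numerator Per-probe group mean differences (patient - control).
#' @param s Per-probe scatter from [pooled_scatter()].
#' @param params A [sam_params()]; `s0_method = "fixed"` returns
#'   `s0_fixed` untouched.
#' @return Scalar s0 >= 0.
#' @export
estimate_s0 <- function(numerator, s, params = sam_params()) {
  if (params$s0_method == "fixed") return(params$s0_fixed)
  p <- length(s)
  if (p < 100) {
    inform("fewer than 100 probes: s0 set to median scatter")
    return(median(s))
  }
  candidates <- unname(quantile(s, probs = seq(0, 1, by = 0.05), type = 7))
  if (length(unique(candidates)) == 1) {
    return(candidates[1])  # all scatters equal: every candidate ties
  }
  n_bins <- min(100L, max(2L, floor(p / 20)))
  bin_breaks <- unique(quantile(s, probs = seq(0, 1, length.out = n_bins + 1),
                                type = 7))
  if (length(bin_breaks) < 3) {
    inform("degenerate scatter distribution: s0 set to median scatter")
    return(median(s))
  }
  bins <- cut(s, breaks = bin_breaks, include.lowest = TRUE)
  cv <- vapply(candidates, function(a) {
    med <- tapply(abs(numerator / (s + a)), bins, median)
    med <- med[!is.na(med)]
    m <- mean(med)
    if (m == 0) 0 else sd(med) / m
  }, numeric(1))
  cv[!is.finite(cv)] <- Inf
  candidates[which.min(cv)]  # which.min takes the first = smallest candidate
}

#' SAM d-scores
#'
#' d = (mean_patient - mean_control) / (s + s0), per probe.
#'
#' @inheritParams pooled_scatter
#' @param s0 Exchangeability factor (scalar >= 0).
#' @return Numeric vector of d-scores.
#' @export
d_scores <- function(mat, groups, s0) {
  mat <- as.matrix(mat)
  ind <- as_group_indicator(groups, ncol(mat))
  s <- pooled_scatter(mat, groups)
  if (any(s + s0 == 0)) {
    abort("s + s0 is zero for some probe; use s0 > 0")
  }
  num <- rowMeans(mat[, ind, drop = FALSE]) -
    rowMeans(mat[, !ind, drop = FALSE])
  unname(num / (s + s0))
}

# All d-scores for a set of label assignments, sharing one s0.
# assignment matrix: B x n logical, TRUE = "patient" label.
d_for_assignments <- function(mat, assign, s0) {
  n <- ncol(mat)
  apply(assign, 1, function(ind) {
    n1 <- sum(ind); n2 <- n - n1
    m1 <- rowMeans(mat[, ind, drop = FALSE])
    m2 <- rowMeans(mat[, !ind, drop = FALSE])
    ss1 <- rowSums((mat[, ind, drop = FALSE] - m1)^2)
    ss2 <- rowSums((mat[, !ind, drop = FALSE] - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    (m1 - m2) / (s + s0)
  })
}

#' Permutation null for the SAM statistic
#'
#' Permutes the group labels and recomputes d with the same s0 as the
#' observed data. When `exhaustive_if_possible` and the number of distinct
#' label assignments (choose(n, n1)) does not exceed `n_permutations`, all
#' assignments are enumerated; otherwise assignments are sampled with the
#' stated seed — without replacement while the distinct count is at most
#' five times the request, with replacement beyond that. The expected
#' order statistics dbar(i) are the means, across permutations, of the
#' i-th smallest null d.
#'
#' @inheritParams d_scores
#' @param params A [sam_params()].
#' @return List with `d_null` (probes x permutations, each column
#'   sorted ascending), `dbar` (expected order statistics), `n_assignments`
#'   (distinct label assignments available), and `exhaustive` (logical).
#' @export
permutation_null <- function(mat, groups, s0, params = sam_params()) {
  mat <- as.matrix(mat)
  ind <- as_group_indicator(groups, ncol(mat))
  n <- ncol(mat)
  n1 <- sum(ind)
  n_distinct <- choose(n, n1)
  exhaustive <- params$exhaustive_if_possible &&
    n_distinct <= params$n_permutations
  if (exhaustive) {
    combos <- combn(n, n1)
    assign <- t(apply(combos, 2, function(ix) seq_len(n) %in% ix))
  } else {
    set.seed(params$seed)
    B <- params$n_permutations
    if (n_distinct <= 5 * B) {
      combos <- combn(n, n1)
      pick <- sample(ncol(combos), min(B, ncol(combos)))
      assign <- t(apply(combos[, pick, drop = FALSE], 2,
                        function(ix) seq_len(n) %in% ix))
    } else {
      assign <- t(replicate(B, seq_len(n) %in% sample(n, n1)))
    }
  }
  d_null <- d_for_assignments(mat, assign, s0)
  d_null <- apply(d_null, 2, sort)
  if (is.null(dim(d_null))) d_null <- matrix(d_null, nrow = 1)
  dimnames(d_null) <- NULL
  list(d_null = d_null, dbar = rowMeans(d_null),
       n_assignments = n_distinct, exhaustive = exhaustive)
}

#' Per-delta FDR table
#'
#' For each delta, the upper cutoff is the smallest non-negative observed
#' order statistic d(i) with d(i) - dbar(i) >= delta and the lower cutoff
#' the largest non-positive one with dbar(i) - d(i) >= delta (cutoffs sit
#' on their respective sides of zero, as in the original procedure). Called probes lie at or beyond a
#' cutoff; false calls are the per-permutation counts of null d beyond the
#' same cutoffs, summarized by the median (or the 90th percentile when
#' configured); FDR = min(1, summary / max(n_called, 1)) with the null
#' proportion fixed at 1.
#'
#' @param d_obs Observed d-scores.
#' @param null Output of [permutation_null()].
#' @param deltas Increasing vector of non-negative thresholds; by default
#'   a grid of `params$n_deltas` points from 0 to max |d(i) - dbar(i)|.
#' @param params A [sam_params()].
#' @return Tibble: delta, cut_low, cut_up, n_called, n_false, fdr.
#' @export
fdr_table <- function(d_obs, null, deltas = NULL, params = sam_params()) {
  d_sorted <- sort(d_obs)
  dbar <- null$dbar
  stopifnot(length(d_sorted) == length(dbar))
  diffs <- d_sorted - dbar
  if (is.null(deltas)) {
    deltas <- seq(0, max(abs(diffs)), length.out = params$n_deltas)
  }
  summary_fun <- if (params$false_count_summary == "median") {
    function(x) median(x)
  } else {
    function(x) unname(quantile(x, 0.9, type = 7))
  }
  # cutoffs are searched on their respective sides of zero, as in the
  # original procedure: an upper cutoff is a non-negative order statistic
  cut_up <- vapply(deltas, function(delta) {
    if (delta == 0) return(-Inf)  # zero threshold calls everything
    i <- which(diffs >= delta & d_sorted >= 0)
    if (length(i)) d_sorted[min(i)] else Inf
  }, numeric(1))
  cut_low <- vapply(deltas, function(delta) {
    if (delta == 0) return(Inf)
    i <- which(-diffs >= delta & d_sorted <= 0)
    if (length(i)) d_sorted[max(i)] else -Inf
  }, numeric(1))
  count_vec <- function(sorted_x) {
    # per-delta count of values at or beyond the cutoffs in a sorted vector
    n <- length(sorted_x)
    nlow <- findInterval(cut_low, sorted_x)
    nup <- n - findInterval(cut_up, sorted_x, left.open = TRUE)
    ifelse(cut_low >= cut_up, n, nlow + nup)
  }
  n_called <- count_vec(d_sorted)
  false_mat <- vapply(seq_len(ncol(null$d_null)),
                      function(b) count_vec(null$d_null[, b]),
                      numeric(length(deltas)))
  if (is.null(dim(false_mat))) false_mat <- matrix(false_mat, nrow = 1)
  n_false <- apply(false_mat, 1, summary_fun)
  n_false[n_called == 0] <- 0
  tibble(delta = deltas, cut_low = cut_low, cut_up = cut_up,
         n_called = as.integer(n_called), n_false = n_false,
         fdr = ifelse(n_called == 0, 0, pmin(1, n_false / pmax(n_called, 1))))
}

#' Per-probe q-values
#'
#' q(probe) = the minimum FDR over all deltas at which the probe is
#' called (i.e. its d lies at or beyond that delta's cutoffs); probes
#' never called get q = 1. A probe with d = 0 has no direction and is
#' never called at a positive delta.
#'
#' @param d_obs Observed d-scores.
#' @param fdr_tbl Output of [fdr_table()] on a dense delta grid.
#' @return Numeric vector of q-values in `[0, 1]`.
#' @export
q_values <- function(d_obs, fdr_tbl) {
  q <- rep(1, length(d_obs))
  for (r in seq_len(nrow(fdr_tbl))) {
    if (fdr_tbl$cut_low[r] >= fdr_tbl$cut_up[r]) {
      called <- rep(TRUE, length(d_obs))
    } else {
      # a zero score has no direction: never called at a positive delta
      called <- ((d_obs >= fdr_tbl$cut_up[r]) |
                   (d_obs <= fdr_tbl$cut_low[r])) & d_obs != 0
    }
    q[called] <- pmin(q[called], fdr_tbl$fdr[r])
  }
  q
}

#' Signed linear fold changes
#'
#' r = 2^(mean_patient - mean_control); FC = r when r >= 1, else -1/r, so
#' down-regulation prints as the negative reciprocal (magnitude >= 1).
#'
#' @inheritParams pooled_scatter
#' @return Numeric vector of signed fold changes.
#' @export
fold_changes <- function(mat, groups) {
  mat <- as.matrix(mat)
  ind <- as_group_indicator(groups, ncol(mat))
  r <- 2^(rowMeans(mat[, ind, drop = FALSE]) -
            rowMeans(mat[, !ind, drop = FALSE]))
  unname(ifelse(r >= 1, r, -1 / r))
}

#' Run the full SAM analysis
#'
#' Wires together [pooled_scatter()], [estimate_s0()], [d_scores()],
#' [permutation_null()], [fdr_table()], [q_values()] and
#' [fold_changes()] into one call on a filtered log2 matrix.
#'
#' @param mat Probes x samples matrix of log2 values (probe ids as
#'   rownames) or an [expr_matrix()].
#' @param groups Character vector (`patient`/`control`) aligned to
#'   columns.
#' @param params A [sam_params()].
#' @return An object of class `sam_result`: list with `table` (tibble:
#'   probe_id, numerator, s, d, fold_change, q_value), `s0`, `fdr_table`,
#'   `dbar`, `d_sorted`, `n_assignments`, `exhaustive`, `params`, `groups`.
#' @export
run_sam <- function(mat, groups, params = sam_params()) {
  if (inherits(mat, "expr_matrix")) mat <- mat$values
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("probe%05d", seq_len(nrow(mat)))
  }
  ind <- as_group_indicator(groups, ncol(mat))
  s <- pooled_scatter(mat, groups)
  num <- unname(rowMeans(mat[, ind, drop = FALSE]) -
                  rowMeans(mat[, !ind, drop = FALSE]))
  s0 <- estimate_s0(num, s, params)
  d <- num / (s + s0)
  null <- permutation_null(mat, groups, s0, params)
  ft <- fdr_table(d, null, params = params)
  q <- q_values(d, ft)
  fc <- fold_changes(mat, groups)
  structure(list(
    table = tibble(probe_id = rownames(mat), numerator = num, s = s,
                   d = d, fold_change = fc, q_value = q),
    s0 = s0, fdr_table = ft, dbar = null$dbar, d_sorted = sort(d),
    n_assignments = null$n_assignments, exhaustive = null$exhaustive,
    params = params, groups = groups
  ), class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "<sam_result> %d probes, s0 = %.4g, %s permutations (%d assignments)\n",
    nrow(x$table), x$s0,
    if (x$exhaustive) "exhaustive" else as.character(x$params$n_permutations),
    x$n_assignments))
  cat(sprintf("  q <= 0.05: %d probes; q <= 0.01: %d probes\n",
              sum(x$table$q_value <= 0.05), sum(x$table$q_value <= 0.01)))
  invisible(x)
}
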