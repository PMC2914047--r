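#' Normalized expression matrix container
#'
#' Probes-by-samples grid of log2 intensities plus a same-shaped logical
#' mask of expressed calls. The filtered matrix used for statistics has no
#' missing values; the mask records which probe/sample pairs passed the
#' above-background call.
#'
#' @param values Numeric matrix (probes x samples) of log2 intensities,
#'   with probe ids as rownames and sample ids as colnames.
#' @param expressed Logical matrix of the same shape (default: all TRUE).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, expressed = NULL) {
  values <- as.matrix(values)
  if (is.null(expressed)) {
    expressed <- matrix(TRUE, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  expressed <- as.matrix(expressed)
  if (!identical(dim(values), dim(expressed))) {
    abort("expressed mask shape must equal value shape")
  }
  structure(list(values = values, expressed = expressed),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples (%.1f%% expressed)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$expressed)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Preprocessing parameters
#'
#' @param background_k Multiplier for the background spread in the
#'   expressed call: a probe is expressed when fg > bg + k * spread. The
#'   default 2.6 approximates a one-sided normal call at p < 0.005,
#'   matching typical feature-extraction "well above background" flags.
#' @param lowess_span Fraction of points in each local fit of the dye
#'   correction (0-1).
#' @param floor Minimal post-subtraction intensity, keeping log2 defined.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(background_k = 2.6, lowess_span = 0.3,
                              floor = 1.0) {
  stopifnot(background_k >= 0, lowess_span > 0, lowess_span <= 1, floor > 0)
  structure(list(background_k = background_k, lowess_span = lowess_span,
                 floor = floor),
            class = "preprocess_params")
}

#' Local background subtraction
#'
#' @param fg,bg Foreground and background intensities (same length).
#' @param floor Minimal net intensity; net = max(fg - bg, floor), so the
#'   output is strictly positive and log2-safe.
#' @return Numeric vector of net intensities.
#' @export
subtract_background <- function(fg, bg, floor = 1.0) {
  stopifnot(length(fg) == length(bg), floor > 0)
  pmax(fg - bg, floor)
}

#' Above-background expressed call
#'
#' A probe is called expressed in a channel when its foreground exceeds
#' the local background by more than `background_k` background spreads.
#' With `background_k = 0` the call reduces to fg > bg.
#'
#' @param fg,bg,spread Per-probe foreground, background and background
#'   spread for one channel.
#' @param background_k Spread multiplier (default 2.6).
#' @return Logical vector.
#' @export
call_expressed <- function(fg, bg, spread, background_k = 2.6) {
  stopifnot(length(fg) == length(bg))
  if (length(spread) == 1) spread <- rep(spread, length(fg))
  fg > bg + background_k * spread
}

#' LOWESS dye-bias correction for one two-color array
#'
#' Computes M = log2(Cy5/Cy3) and A = 0.5 * log2(Cy5 * Cy3), fits the
#' smooth trend M-hat(A) by locally weighted linear regression (span
#' `lowess_span`, one robustifying iteration), and returns the corrected
#' ratios M - M-hat along with A and the fitted trend. Per-channel log2
#' intensities are reconstructed as A +/- (M - M-hat)/2.
#'
#' @param net_cy3,net_cy5 Strictly positive net intensities per probe.
#' @param lowess_span Local fit span (default 0.3).
#' @return Tibble with columns A, M_raw, trend, M (corrected),
#'   log2_cy5, log2_cy3 (reconstructed).
#' @export
lowess_dye_correct <- function(net_cy3, net_cy5, lowess_span = 0.3) {
  stopifnot(length(net_cy3) == length(net_cy5),
            all(net_cy3 > 0), all(net_cy5 > 0))
  M <- log2(net_cy5 / net_cy3)
  A <- 0.5 * log2(net_cy5 * net_cy3)
  if (length(M) < 10) {
    warn("fewer than 10 probes: dye-bias fit refused, ratios passed through")
    trend <- rep(0, length(M))
  } else {
    fit <- lowess(A, M, f = lowess_span, iter = 1)
    trend <- approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  }
  Mc <- M - trend
  tibble(A = A, M_raw = M, trend = trend, M = Mc,
         log2_cy5 = A + Mc / 2, log2_cy3 = A - Mc / 2)
}

#' Quantile normalization across samples
#'
#' Forces every column to the common distribution given by the row-wise
#' mean of the sorted columns, preserving within-column ranks; tied values
#' receive the mean of their target quantile values. Idempotent and
#' equivariant under column permutation.
#'
#' @param mat Numeric matrix (probes x samples), no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("quantile_normalize requires a complete matrix")
  if (ncol(mat) == 1) {
    warn("single sample: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Assemble the normalized, filtered expression matrix
#'
#' Runs the full preprocessing chain on a set of two-color scans:
#' background subtraction, per-channel expressed calls, LOWESS dye
#' correction, reconstruction of the sample-channel log2 intensity,
#' quantile normalization across samples, and finally restriction to the
#' probes called expressed in every sample (in the channel carrying that
#' sample).
#'
#' @param scans Named list of [array_scan()] objects, one per sample.
#' @param metadata Sample metadata tibble (sample_id, group, dye).
#' @param params A [preprocess_params()].
#' @return An [expr_matrix()] restricted to probes expressed in all
#'   samples; the full pre-filter matrix and mask are attached as
#'   attributes `unfiltered` for audit.
#' @export
assemble_expression_matrix <- function(scans, metadata,
                                       params = preprocess_params()) {
  stopifnot(length(scans) >= 2)
  if (is.null(names(scans))) {
    names(scans) <- vapply(scans, function(s) s$sample_id, character(1))
  }
  metadata <- metadata[metadata$sample_id %in% names(scans), , drop = FALSE]
  if (any(table(metadata$group) < 2)) {
    abort("need at least 2 samples per group")
  }
  common <- Reduce(intersect, lapply(scans, function(s) s$data$probe_id))
  ns <- vapply(scans, function(s) nrow(s$data), integer(1))
  if (any(ns != length(common))) {
    inform(sprintf("probe sets differ across scans; using %d shared probes",
                   length(common)))
  }
  sample_ids <- metadata$sample_id
  p <- length(common)
  values <- matrix(NA_real_, p, length(sample_ids),
                   dimnames = list(common, sample_ids))
  expressed <- matrix(NA, p, length(sample_ids),
                      dimnames = list(common, sample_ids))
  for (sid in sample_ids) {
    scan <- scans[[sid]]
    d <- scan$data[match(common, scan$data$probe_id), , drop = FALSE]
    net3 <- subtract_background(d$fg_cy3, d$bg_cy3, params$floor)
    net5 <- subtract_background(d$fg_cy5, d$bg_cy5, params$floor)
    corr <- lowess_dye_correct(net3, net5, params$lowess_span)
    if (scan$sample_channel == "Cy5") {
      values[, sid] <- corr$log2_cy5
      expressed[, sid] <- call_expressed(d$fg_cy5, d$bg_cy5, d$spread_cy5,
                                         params$background_k)
    } else {
      values[, sid] <- corr$log2_cy3
      expressed[, sid] <- call_expressed(d$fg_cy3, d$bg_cy3, d$spread_cy3,
                                         params$background_k)
    }
  }
  values <- quantile_normalize(values)
  keep <- rowSums(expressed) == ncol(expressed)
  if (!any(keep)) {
    abort("no probe is expressed in all samples; consider lowering background_k")
  }
  out <- expr_matrix(values[keep, , drop = FALSE],
                     expressed[keep, , drop = FALSE])
  attr(out, "unfiltered") <- list(values = values, expressed = expressed)
  out
}
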