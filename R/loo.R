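#' Consensus thresholds for the leave-one-out wrapper
#'
#' @param fc_min Minimal absolute linear fold change (default 1.7).
#' @param fdr_max Maximal q-value: 0.01 for a CD34-like analysis, 0.05 for
#'   a stromal-like one; relaxed lists use 0.05 / 0.15.
#' @param include_full_dataset Also require passing on the full sample set
#'   (default TRUE), so the reported per-probe FC and q come from all
#'   samples.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(fc_min = 1.7, fdr_max = 0.01,
                             include_full_dataset = TRUE) {
  stopifnot(fc_min >= 1, fdr_max > 0, fdr_max < 1)
  structure(list(fc_min = fc_min, fdr_max = fdr_max,
                 include_full_dataset = isTRUE(include_full_dataset)),
            class = "consensus_params")
}

#' Enumerate leave-one-out sample subsets
#'
#' One subset per sample (patients and controls alike), each of size
#' n - 1, plus the full set when `include_full_dataset`. Removing a sample
#' from a group of size 2 is refused: the SAM statistic needs at least two
#' samples per class in every run.
#'
#' @param metadata Sample metadata tibble (sample_id, group).
#' @param include_full_dataset Include the full sample set as a run.
#' @return Tibble: run_id, left_out (NA for the full run), samples
#'   (list-column of sample id vectors).
#' @export
enumerate_loo <- function(metadata, include_full_dataset = TRUE) {
  counts <- table(metadata$group)
  if (any(counts < 2)) {
    abort("each group needs at least 2 samples")
  }
  if (any(counts < 3)) {
    abort(sprintf(
      "group(s) of size 2 (%s): removing a sample would leave a single-sample class",
      paste(names(counts)[counts < 3], collapse = ", ")))
  }
  runs <- lapply(metadata$sample_id, function(sid) {
    tibble(run_id = paste0("loo_", sid), left_out = sid,
           samples = list(setdiff(metadata$sample_id, sid)))
  })
  out <- bind_rows(runs)
  if (include_full_dataset) {
    out <- bind_rows(
      tibble(run_id = "full", left_out = NA_character_,
             samples = list(metadata$sample_id)),
      out)
  }
  out
}

#' Leave-one-out consensus differential expression
#'
#' Reruns the SAM analysis on every dataset formed by removing one sample
#' (and on the full set when configured) and keeps the probes that pass
#' the fold-change and FDR thresholds with a consistent direction in
#' every run. Each run's permutation seed derives deterministically from
#' the master seed in `sam_params` and the left-out sample id, so the
#' whole consensus is reproducible from one integer.
#'
#' @param mat Probes x samples log2 matrix or [expr_matrix()] (already
#'   filtered to probes expressed in all samples of the full set).
#' @param metadata Sample metadata tibble covering the columns of `mat`.
#' @param sam_params A [sam_params()].
#' @param params A [consensus_params()].
#' @return An object of class `consensus_result`: `table` (tibble per
#'   surviving probe: probe_id, direction, fold_change and q_value from
#'   the full-data run — or the worst run when the full set is not
#'   included — plus worst_q and min_abs_fold_change across runs),
#'   `trace` (per run x probe: q, fold change, pass), `runs`, `params`,
#'   `sam_results` (named list).
#' @export
run_consensus <- function(mat, metadata, sam_params = sam_params(),
                          params = consensus_params()) {
  if (inherits(mat, "expr_matrix")) mat <- mat$values
  mat <- as.matrix(mat)
  metadata <- metadata[match(colnames(mat), metadata$sample_id), ,
                       drop = FALSE]
  if (anyNA(metadata$sample_id)) {
    abort("metadata does not cover all matrix columns")
  }
  runs <- enumerate_loo(metadata, params$include_full_dataset)
  sams <- vector("list", nrow(runs))
  names(sams) <- runs$run_id
  traces <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    ids <- runs$samples[[i]]
    sp <- sam_params
    sp$seed <- as.integer(derive_seed(sam_params$seed,
                                      runs$run_id[i]) %% 2147483647)
    res <- run_sam(mat[, ids, drop = FALSE],
                   metadata$group[match(ids, metadata$sample_id)], sp)
    sams[[i]] <- res
    traces[[i]] <- res$table %>%
      mutate(run_id = runs$run_id[i],
             pass = .data$q_value <= params$fdr_max &
               abs(.data$fold_change) >= params$fc_min) %>%
      select("run_id", "probe_id", "fold_change", "q_value", "pass")
  }
  trace <- bind_rows(traces)
  verdict <- trace %>%
    group_by(.data$probe_id) %>%
    summarise(
      n_runs = dplyr::n(),
      n_pass = sum(.data$pass),
      sign_consistent = length(unique(sign(.data$fold_change))) == 1,
      worst_q = max(.data$q_value),
      min_abs_fold_change = min(abs(.data$fold_change)),
      .groups = "drop")
  survivors <- verdict %>%
    filter(.data$n_pass == .data$n_runs, .data$sign_consistent)
  report_run <- if (params$include_full_dataset) "full" else NULL
  if (!is.null(report_run)) {
    rep_tbl <- sams[[report_run]]$table %>%
      select("probe_id", "fold_change", "q_value")
  } else {
    rep_tbl <- trace %>%
      group_by(.data$probe_id) %>%
      dplyr::slice_max(.data$q_value, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      select("probe_id", "fold_change", "q_value")
  }
  table <- survivors %>%
    left_join(rep_tbl, by = "probe_id") %>%
    mutate(direction = ifelse(.data$fold_change >= 0, "up", "down")) %>%
    arrange(dplyr::desc(abs(.data$fold_change))) %>%
    select("probe_id", "direction", "fold_change", "q_value", "worst_q",
           "min_abs_fold_change")
  structure(list(table = table, trace = trace, runs = runs,
                 params = params, sam_params = sam_params,
                 sam_results = sams),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d probes pass |FC| >= %.2f and q <= %g in all %d runs (%d up, %d down)\n",
    nrow(x$table), x$params$fc_min, x$params$fdr_max, nrow(x$runs),
    sum(x$table$direction == "up"), sum(x$table$direction == "down")))
  invisible(x)
}

#' Write the per-run consensus audit trace
#'
#' @param consensus A `consensus_result`.
#' @param path Output TSV path.
#' @param stamp Optional provenance string written as a leading `#`
#'   comment line.
#' @return Invisibly, the trace tibble.
#' @export
write_trace <- function(consensus, path, stamp = NULL) {
  write_tsv_stamped(consensus$trace, path, stamp)
  invisible(consensus$trace)
}
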