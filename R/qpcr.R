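#' Per-sample delta-CT
#'
#' ΔCT = mean(target CT replicates) - mean(reference CT replicates), per
#' sample and gene. Replicate spreads (max - min) above one cycle trigger
#' a warning naming the sample.
#'
#' @param data Long tibble with columns sample_id, group, gene,
#'   replicate, ct_target, ct_reference (CT in cycles, within (0, 45)).
#' @return Tibble: sample_id, group, gene, delta_ct.
#' @export
delta_ct <- function(data) {
  check_columns(data, c("sample_id", "group", "gene", "ct_target",
                        "ct_reference"), "qPCR table")
  cts <- c(data$ct_target, data$ct_reference)
  if (any(cts <= 0 | cts >= 45)) {
    abort("CT values must lie in (0, 45) cycles", class = "samloo_data_error")
  }
  out <- data %>%
    group_by(.data$sample_id, .data$group, .data$gene) %>%
    summarise(
      delta_ct = mean(.data$ct_target) - mean(.data$ct_reference),
      spread = max(max(.data$ct_target) - min(.data$ct_target),
                   max(.data$ct_reference) - min(.data$ct_reference)),
      .groups = "drop")
  wide_spread <- out$sample_id[out$spread > 1]
  if (length(wide_spread) > 0) {
    warn(sprintf("replicate spread exceeds 1 cycle for sample(s): %s",
                 paste(unique(wide_spread), collapse = ", ")))
  }
  out %>% select("sample_id", "group", "gene", "delta_ct")
}

#' 2^-ΔΔCT relative quantification
#'
#' ΔΔCT = ΔCT of a sample minus the arithmetic mean ΔCT of the control
#' group for that gene; RQ = 2^-ΔΔCT (amplification efficiency fixed at
#' 2). Controls are evaluated against their own mean, so the control
#' group's geometric-mean RQ is 1 per gene.
#'
#' @param dct Output of [delta_ct()].
#' @return `dct` with added columns ddct and rq.
#' @export
relative_quantity <- function(dct) {
  check_columns(dct, c("sample_id", "group", "gene", "delta_ct"),
                "delta-CT table")
  if (!any(dct$group == "control")) {
    abort("need at least 1 control sample", class = "samloo_data_error")
  }
  dct %>%
    group_by(.data$gene) %>%
    mutate(ddct = .data$delta_ct -
             mean(.data$delta_ct[.data$group == "control"]),
           rq = 2^(-.data$ddct)) %>%
    ungroup()
}

#' Sign agreement between qPCR and array fold changes
#'
#' Summarizes RQ per gene (mean over patient samples), converts it to the
#' signed fold-change convention (-1/RQ when RQ < 1) and compares its
#' direction with the array's signed fold change. Genes absent from
#' either side are listed and excluded from the agreement fraction.
#'
#' @param rq Output of [relative_quantity()].
#' @param array_fc Tibble with columns gene (or probe_id) and
#'   fold_change (signed array fold changes).
#' @return List with `table` (gene, mean_rq, qpcr_signed_fc,
#'   qpcr_direction, array_fold_change, array_direction, agree),
#'   `fraction_agree`, and `unmatched` (genes missing on either side).
#' @export
compare_with_array <- function(rq, array_fc) {
  if ("probe_id" %in% names(array_fc) && !"gene" %in% names(array_fc)) {
    array_fc <- rename(array_fc, gene = "probe_id")
  }
  check_columns(array_fc, c("gene", "fold_change"), "array fold-change table")
  qsum <- rq %>%
    filter(.data$group == "patient") %>%
    group_by(.data$gene) %>%
    summarise(mean_rq = mean(.data$rq), .groups = "drop")
  unmatched <- union(setdiff(qsum$gene, array_fc$gene),
                     setdiff(array_fc$gene, qsum$gene))
  tbl <- qsum %>%
    inner_join(array_fc %>% select("gene", array_fold_change = "fold_change"),
               by = "gene") %>%
    mutate(
      qpcr_signed_fc = ifelse(.data$mean_rq >= 1, .data$mean_rq,
                              -1 / .data$mean_rq),
      qpcr_direction = ifelse(.data$mean_rq >= 1, "up", "down"),
      array_direction = ifelse(.data$array_fold_change >= 0, "up", "down"),
      agree = .data$qpcr_direction == .data$array_direction)
  list(table = tbl,
       fraction_agree = if (nrow(tbl) > 0) mean(tbl$agree) else NA_real_,
       unmatched = unmatched)
}

#' Read a qPCR CT table
#'
#' @param path TSV with columns sample_id, group, gene, replicate,
#'   ct_target, ct_reference.
#' @return Tibble in the layout [delta_ct()] expects.
#' @export
read_qpcr_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = "c", group = "c", gene = "c",
                          replicate = "i", ct_target = "d",
                          ct_reference = "d"))
  check_columns(df, c("sample_id", "group", "gene", "ct_target",
                      "ct_reference"), "qPCR table")
  df$group <- match_values(df$group, c("patient", "control"), "group")
  df
}
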