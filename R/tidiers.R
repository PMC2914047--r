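#' Tidy a SAM result
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return Tibble with one row per probe: probe_id, numerator, s, d,
#'   fold_change, q_value.
#' @export
tidy.sam_result <- function(x, ...) {
  x$table
}

#' One-row summary of a SAM result
#'
#' @param x A `sam_result`.
#' @param ... Unused.
#' @return Tibble: n_probes, s0, n_assignments, exhaustive,
#'   n_q_le_0.05, n_q_le_0.01.
#' @export
glance.sam_result <- function(x, ...) {
  tibble(
    n_probes = nrow(x$table),
    s0 = x$s0,
    n_assignments = x$n_assignments,
    exhaustive = x$exhaustive,
    n_q_le_0.05 = sum(x$table$q_value <= 0.05),
    n_q_le_0.01 = sum(x$table$q_value <= 0.01)
  )
}

#' Tidy a consensus result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return The surviving-probe tibble (probe_id, direction, fold_change,
#'   q_value, worst_q, min_abs_fold_change).
#' @export
tidy.consensus_result <- function(x, ...) {
  x$table
}

#' One-row summary of a consensus result
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return Tibble: n_runs, n_probes_tested, n_consensus, n_up, n_down,
#'   fc_min, fdr_max.
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    n_runs = nrow(x$runs),
    n_probes_tested = length(unique(x$trace$probe_id)),
    n_consensus = nrow(x$table),
    n_up = sum(x$table$direction == "up"),
    n_down = sum(x$table$direction == "down"),
    fc_min = x$params$fc_min,
    fdr_max = x$params$fdr_max
  )
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Long tibble: probe_id, sample_id, log2_intensity, expressed.
#' @export
tidy.expr_matrix <- function(x, ...) {
  vals <- as_tibble(x$values, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "log2_intensity")
  mask <- as_tibble(x$expressed, rownames = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id",
                        values_to = "expressed")
  left_join(vals, mask, by = c("probe_id", "sample_id"))
}
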