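#' Construct a two-channel array scan
#'
#' Holds raw feature-extraction style intensities for one hybridization:
#' foreground, background and background spread per probe for each of the
#' Cy3 and Cy5 channels, plus which channel carries the biological sample
#' (the other carries the common reference).
#'
#' @param sample_id Biological sample hybridized on this array.
#' @param data Tibble with columns `probe_id`, `fg_cy3`, `bg_cy3`,
#'   `spread_cy3`, `fg_cy5`, `bg_cy5`, `spread_cy5` (intensities >= 0).
#' @param sample_channel `"Cy5"` or `"Cy3"`.
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(sample_id, data, sample_channel = c("Cy5", "Cy3")) {
  sample_channel <- match.arg(sample_channel)
  data <- as_tibble(data)
  check_columns(data, c("probe_id", "fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5"),
                "scan table")
  if (!"spread_cy3" %in% names(data)) {
    data$spread_cy3 <- mad(data$bg_cy3)
    inform("background spread missing for Cy3; using global MAD of background")
  }
  if (!"spread_cy5" %in% names(data)) {
    data$spread_cy5 <- mad(data$bg_cy5)
    inform("background spread missing for Cy5; using global MAD of background")
  }
  ints <- c("fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5")
  neg <- vapply(data[ints], function(x) any(x < 0), logical(1))
  if (any(neg)) {
    abort(sprintf("negative intensities in column(s): %s",
                  paste(ints[neg], collapse = ", ")),
          class = "samloo_data_error")
  }
  if (anyDuplicated(data$probe_id)) {
    abort("duplicate probe_id in scan table", class = "samloo_data_error")
  }
  structure(list(sample_id = sample_id, data = data,
                 sample_channel = sample_channel),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("<array_scan> sample %s on %s, %d probes\n",
              x$sample_id, x$sample_channel, nrow(x$data)))
  invisible(x)
}

parse_coordinates <- function(coord) {
  m <- regmatches(coord, regexec("^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$",
                                 trimws(coord)))
  t(vapply(m, function(g) {
    if (length(g) != 4) c(NA_real_, NA_real_) else as.numeric(g[3:4])
  }, numeric(2)))
}

#' Read a probe annotation table
#'
#' Reads a TSV with one row per array feature. Coordinates may come either
#' as `start`/`end` columns with a `chrom` column, or as a single
#' `coordinates` column in `chr:start-end` form (the layout of the
#' platform's published probe tables). Rows with malformed coordinates or
#' `end < start` are rejected and enumerated in a warning; duplicate probe
#' ids are an error.
#'
#' @param path TSV file with a single header line.
#' @param col_map Optional named character vector mapping the canonical
#'   column names (`probe_id`, `locus_name`, `locus_id`, `chrom`, `start`,
#'   `end`, `coordinates`, `strand`, `probe_class`, `orientation`) to the
#'   file's actual header names, to absorb feature-extraction dialects.
#' @return Tibble with columns probe_id, locus_name, locus_id, chrom,
#'   start, end, strand, probe_class (`coding`/`intronic`/`intergenic`)
#'   and orientation (`sense`/`antisense`, `NA` for coding probes).
#' @export
read_probe_annotation <- function(path, col_map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  df <- apply_col_map(df, col_map)
  check_columns(df, c("probe_id", "locus_name", "locus_id", "strand",
                      "probe_class"), "annotation")
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    check_columns(df, "coordinates", "annotation")
    parsed <- parse_coordinates(df$coordinates)
    df$chrom <- sub(":.*$", "", trimws(df$coordinates))
    df$chrom[is.na(parsed[, 1])] <- NA_character_
    df$start <- parsed[, 1]
    df$end <- parsed[, 2]
  } else {
    df$start <- suppressWarnings(as.numeric(df$start))
    df$end <- suppressWarnings(as.numeric(df$end))
  }
  if (nrow(df) == 0) {
    return(tibble(probe_id = character(), locus_name = character(),
                  locus_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  probe_class = character(), orientation = character()))
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  if (length(bad) > 0) {
    warn(sprintf("rejected %d annotation row(s) with malformed coordinates (row index: %s)",
                 length(bad), paste(bad, collapse = ", ")),
         class = "samloo_rejected_rows")
    df <- df[-bad, , drop = FALSE]
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("duplicate probe_id: %s",
                  paste(unique(df$probe_id[duplicated(df$probe_id)]),
                        collapse = ", ")),
          class = "samloo_format_error")
  }
  out <- tibble(
    probe_id = df$probe_id,
    locus_name = df$locus_name,
    locus_id = suppressWarnings(as.integer(df$locus_id)),
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    strand = match_values(df$strand, c("+", "-"), "strand"),
    probe_class = match_values(df$probe_class,
                               c("coding", "intronic", "intergenic"),
                               "probe_class"),
    orientation = if ("orientation" %in% names(df)) {
      match_values(df$orientation, c("sense", "antisense"), "orientation")
    } else NA_character_
  )
  out$orientation[out$probe_class == "coding"] <- NA_character_
  no_orient <- out$probe_class != "coding" & is.na(out$orientation)
  if (any(no_orient)) {
    abort(sprintf("ncRNA probe(s) without orientation: %s",
                  paste(out$probe_id[no_orient], collapse = ", ")),
          class = "samloo_format_error")
  }
  out
}

apply_col_map <- function(df, col_map) {
  names(df) <- tolower(names(df))
  if (!is.null(col_map)) {
    idx <- match(tolower(col_map), names(df))
    names(df)[idx[!is.na(idx)]] <- names(col_map)[!is.na(idx)]
  }
  df
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, group (`patient`/`control`),
#'   cell_type, dye (`Cy3`/`Cy5` — channel carrying the sample).
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(df) <- tolower(names(df))
  check_columns(df, c("sample_id", "group"), "metadata")
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id in metadata", class = "samloo_format_error")
  }
  tibble(
    sample_id = df$sample_id,
    group = match_values(df$group, c("patient", "control"), "group"),
    cell_type = if ("cell_type" %in% names(df)) df$cell_type else NA_character_,
    dye = if ("dye" %in% names(df)) {
      ifelse(tolower(df$dye) == "cy5", "Cy5", "Cy3")
    } else "Cy5"
  )
}

#' Read a raw two-channel scan table
#'
#' @param path TSV with columns probe_id, fg_cy3, bg_cy3, fg_cy5, bg_cy5
#'   and optionally spread_cy3/spread_cy5 (or dialect names via `col_map`).
#' @param sample_id Biological sample on this array.
#' @param sample_channel Channel carrying the sample (default Cy5).
#' @param annotation Optional annotation tibble; when given, the scan is
#'   restricted to probes shared with the annotation and the mismatch
#'   count is logged (never a hard failure, so re-runs tolerate control
#'   probes).
#' @param col_map Optional canonical-to-file column name map.
#' @return An [array_scan()].
#' @export
read_scan_table <- function(path, sample_id, sample_channel = "Cy5",
                            annotation = NULL, col_map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  df <- apply_col_map(df, col_map)
  check_columns(df, c("probe_id", "fg_cy3", "bg_cy3", "fg_cy5", "bg_cy5"),
                "scan table")
  num_cols <- setdiff(names(df), "probe_id")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  if (!is.null(annotation)) {
    shared <- intersect(df$probe_id, annotation$probe_id)
    n_drop <- nrow(df) - length(shared) +
      (nrow(annotation) - length(shared))
    if (length(shared) < nrow(df) || length(shared) < nrow(annotation)) {
      inform(sprintf(
        "scan/annotation probe mismatch for %s: using %d shared probes (%d unmatched)",
        sample_id, length(shared), n_drop))
    }
    df <- df[df$probe_id %in% shared, , drop = FALSE]
  }
  array_scan(sample_id, df, sample_channel)
}

#' Read a GEO series-matrix file into an expression matrix
#'
#' Parses the text series-matrix format (table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`). `"null"`
#' or empty entries become missing values and are excluded from the
#' expressed mask, so downstream filtering keeps only probes measured in
#' every sample. Used to bypass preprocessing when validating against a
#' deposited processed matrix.
#'
#' @param path Series-matrix text file.
#' @return An [expr_matrix()] whose expressed mask is `!is.na(values)`.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("series-matrix file not found: %s", path),
          class = "samloo_io_error")
  }
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(fin) != 1 || fin <= beg + 1) {
    abort("no !series_matrix_table_begin/!series_matrix_table_end delimited table found",
          class = "samloo_format_error")
  }
  tbl <- readr::read_tsv(I(lines[(beg + 1):(fin - 1)]),
                         show_col_types = FALSE, na = c("", "null", "NA"),
                         col_types = readr::cols(.default = "c"))
  probe_id <- dplyr::pull(tbl, 1)
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  vals <- gsub('^"|"$', "", vals)
  storage.mode(vals) <- "double"
  rownames(vals) <- gsub('^"|"$', "", probe_id)
  expr_matrix(vals, expressed = !is.na(vals))
}

#' Write a consensus results table
#'
#' Columns mirror the published supplementary layout: locus name and id,
#' probe coordinates, strand, probe class, orientation, then the
#' statistics. Fold changes carry the signed convention (down-regulation
#' as the negative reciprocal, e.g. -4.45). A `q_printed` column shows q
#' at 3 decimals alongside the full-precision `q_value`.
#'
#' @param consensus A `consensus_result` (see [run_consensus()]).
#' @param annotation Annotation tibble covering the consensus probes.
#' @param path Output TSV path.
#' @param stamp Optional provenance string written as a leading `#`
#'   comment line (skipped by [read_results()]).
#' @return Invisibly, the written tibble.
#' @export
write_results <- function(consensus, annotation, path, stamp = NULL) {
  tbl <- consensus$table
  out <- tbl %>%
    left_join(annotation, by = "probe_id") %>%
    mutate(
      coordinates = ifelse(is.na(.data$chrom), NA_character_,
                           sprintf("%s:%d-%d", .data$chrom,
                                   as.integer(.data$start),
                                   as.integer(.data$end))),
      q_printed = sprintf("%.3f", .data$q_value)
    ) %>%
    select("probe_id", "locus_name", "locus_id", "coordinates", "strand",
           "probe_class", "orientation", "direction", "fold_change",
           "q_value", "q_printed", "worst_q", "min_abs_fold_change")
  write_tsv_stamped(out, path, stamp)
  invisible(out)
}

write_tsv_stamped <- function(df, path, stamp = NULL) {
  if (!is.null(stamp)) {
    writeLines(paste0("# ", stamp), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(df)
}

#' Read back a consensus results table written by [write_results()]
#'
#' @param path TSV produced by [write_results()].
#' @return Tibble with the same columns.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                  col_types = readr::cols(
                    probe_id = "c", locus_name = "c", locus_id = "i",
                    coordinates = "c", strand = "c", probe_class = "c",
                    orientation = "c", direction = "c", fold_change = "d",
                    q_value = "d", q_printed = "c", worst_q = "d",
                    min_abs_fold_change = "d"))
}
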