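write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path)
  path
}

test_that("probe annotation reader parses coordinate strings and rejects bad rows", {
  df <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    locus_name = c("NEIL1", "GENEX", "GENEY"),
    locus_id = c(79661L, 2L, 3L),
    coordinates = c("chr15:73434282-73434341", "chr1:100-50", "chr2:oops"),
    strand = c("+", "+", "-"),
    probe_class = c("Intronic", "Coding", "Coding"),
    orientation = c("Sense", NA, NA))
  path <- write_tsv_tmp(df)
  expect_warning(ann <- read_probe_annotation(path), "row index: 2, 3")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$locus_name, "NEIL1")
  expect_equal(ann$chrom, "chr15")
  expect_equal(ann$start, 73434282)
  expect_equal(ann$end, 73434341)
  expect_equal(ann$probe_class, "intronic")
  expect_equal(ann$orientation, "sense")
})

test_that("probe annotation reader handles empty files, duplicates and missing columns", {
  hdr_only <- tibble::tibble(
    probe_id = character(), locus_name = character(),
    locus_id = integer(), chrom = character(), start = integer(),
    end = integer(), strand = character(), probe_class = character(),
    orientation = character())
  expect_equal(nrow(read_probe_annotation(write_tsv_tmp(hdr_only))), 0)

  dup <- tibble::tibble(
    probe_id = c("p1", "p1"), locus_name = "G", locus_id = 1L,
    chrom = "chr1", start = c(10L, 20L), end = c(19L, 29L),
    strand = "+", probe_class = "coding", orientation = NA_character_)
  expect_error(read_probe_annotation(write_tsv_tmp(dup)), "duplicate probe_id")

  nostrand <- dplyr::select(dup[1, ], -"strand")
  expect_error(read_probe_annotation(write_tsv_tmp(nostrand)), "strand")
})

test_that("scan reader populates both channels and validates input", {
  df <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    fg_cy3 = c(100, 200, 300), bg_cy3 = c(10, 20, 30),
    fg_cy5 = c(150, 250, 350), bg_cy5 = c(15, 25, 35),
    spread_cy3 = 5, spread_cy5 = 5)
  scan <- read_scan_table(write_tsv_tmp(df), "S1")
  expect_s3_class(scan, "array_scan")
  expect_equal(nrow(scan$data), 3)
  expect_equal(scan$data$fg_cy5, c(150, 250, 350))

  expect_error(read_scan_table(write_tsv_tmp(df[, -5]), "S1"), "bg_cy5")

  neg <- df; neg$fg_cy3[2] <- -1
  expect_error(read_scan_table(write_tsv_tmp(neg), "S1"), "negative")
})

test_that("scan/annotation mismatch restricts to shared probes with a log message", {
  df <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    fg_cy3 = 100, bg_cy3 = 10, fg_cy5 = 100, bg_cy5 = 10,
    spread_cy3 = 5, spread_cy5 = 5)
  ann <- tibble::tibble(probe_id = c("p1", "p2"))
  expect_message(scan <- read_scan_table(write_tsv_tmp(df), "S1",
                                         annotation = ann),
                 "2 shared probes")
  expect_setequal(scan$data$probe_id, intersect(df$probe_id, ann$probe_id))
})

test_that("series-matrix reader parses fixtures and flags missing values", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"synthetic fixture\"",
    "!series_matrix_table_begin",
    "ID_REF\tS1\tS2",
    "p1\t1.5\t2.5",
    "p2\tnull\t4.0",
    "!series_matrix_table_end"), path)
  em <- read_series_matrix(path)
  expect_equal(dim(em$values), c(2, 2))
  expect_equal(em$values["p1", "S2"], 2.5)
  expect_true(is.na(em$values["p2", "S1"]))
  expect_false(em$expressed["p2", "S1"])
  expect_true(em$expressed["p1", "S1"])

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ID_REF\tS1", "p1\t1.0"), bad)
  expect_error(read_series_matrix(bad), "series_matrix_table_begin")
})

test_that("results writer emits signed fold changes and roundtrips", {
  ann <- tibble::tibble(
    probe_id = c("p1", "p2"), locus_name = c("GENEA", "GENEB"),
    locus_id = c(1L, 2L), chrom = "chr1", start = c(100, 400),
    end = c(159, 459), strand = c("+", "-"),
    probe_class = c("coding", "intronic"),
    orientation = c(NA, "antisense"))
  cons <- structure(list(table = tibble::tibble(
    probe_id = c("p1", "p2"), direction = c("up", "down"),
    fold_change = c(2.0, -4.45), q_value = c(0.004, 0),
    worst_q = c(0.008, 0.001), min_abs_fold_change = c(1.9, 4.1))),
    class = "consensus_result")
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_results(cons, ann, path)
  expect_equal(out$q_printed, c("0.004", "0.000"))
  expect_true(all(out$fold_change[out$direction == "down"] < 0))
  back <- read_results(path)
  expect_equal(back$fold_change, cons$table$fold_change)
  expect_equal(back$q_value, cons$table$q_value)
  expect_equal(back$worst_q, cons$table$worst_q)
  expect_equal(back$coordinates, c("chr1:100-159", "chr1:400-459"))

  empty <- structure(list(table = cons$table[0, ]), class = "consensus_result")
  write_results(empty, ann, path)
  expect_equal(nrow(read_results(path)), 0)
})

test_that("sample metadata reader validates groups and duplicates", {
  df <- tibble::tibble(sample_id = c("PT1", "CT1"),
                       group = c("Patient", "Control"),
                       cell_type = "CD34", dye = c("Cy5", "Cy5"))
  md <- read_sample_metadata(write_tsv_tmp(df))
  expect_equal(md$group, c("patient", "control"))
  dup <- df; dup$sample_id <- "PT1"
  expect_error(read_sample_metadata(write_tsv_tmp(dup)), "duplicate")
})
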