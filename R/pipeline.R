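#' Pipeline configuration
#'
#' Bundles the stage parameters, analysis preset and master seed for an
#' end-to-end run. Presets fix the consensus thresholds: `cd34`
#' (FDR 1%), `stromal` (5%), and the relaxed network-export lists
#' `networks-cd34` (5%) and `networks-stromal` (15%); all use the 1.7
#' minimal fold change.
#'
#' @param preset One of `"cd34"`, `"stromal"`, `"networks-cd34"`,
#'   `"networks-stromal"`.
#' @param seed Master seed for every source of randomness.
#' @param preprocess A [preprocess_params()].
#' @param sam A [sam_params()] (its seed is overridden by `seed`).
#' @param consensus Optional [consensus_params()] overriding the preset
#'   thresholds.
#' @param simulate Optional [synth_config()]: when given, inputs are
#'   simulated rather than read from files.
#' @param paths Optional named list with `annotation`, `scans` (named
#'   vector of scan TSVs), `metadata` for file-based runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("cd34", "stromal", "networks-cd34",
                                       "networks-stromal"),
                            seed = 1L,
                            preprocess = preprocess_params(),
                            sam = sam_params(seed = seed),
                            consensus = NULL,
                            simulate = NULL,
                            paths = NULL) {
  preset <- match.arg(preset)
  fdr <- c(`cd34` = 0.01, `stromal` = 0.05,
           `networks-cd34` = 0.05, `networks-stromal` = 0.15)[[preset]]
  if (is.null(consensus)) consensus <- consensus_params(fdr_max = fdr)
  sam$seed <- as.integer(seed)
  structure(list(preset = preset, seed = as.integer(seed),
                 preprocess = preprocess, sam = sam, consensus = consensus,
                 simulate = simulate, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `preset`, `seed`, `preprocess`, `sam`,
#' `consensus` (each a mapping of the corresponding parameter-builder
#' arguments), and `paths`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    preset = y$preset %||% "cd34",
    seed = y$seed %||% 1L,
    preprocess = do.call(preprocess_params, y$preprocess %||% list()),
    sam = do.call(sam_params, y$sam %||% list()),
    paths = y$paths
  )
  if (!is.null(y$consensus)) {
    args$consensus <- do.call(consensus_params, y$consensus)
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — preprocessing, SAM with the
#' leave-one-out consensus, probe classification and reporting — and
#' writes the result bundle: consensus TSV, coding/ncRNA partition
#' counts (JSON), locus concordance TSV, z-score heatmap matrix TSV,
#' sample dendrogram (Newick), audit trace TSV, and a log of every
#' parameter used, each stamped with the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if absent); `NULL` skips
#'   writing and just returns the bundle.
#' @return Invisibly, a list with elements `expr`, `consensus`,
#'   `annotation`, `partition`, `concordance`, `zscores`, `clustering`,
#'   `truth` (synthetic runs only), `config_hash`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      annot <- synth_annotation(config$simulate)
      expt <- synth_experiment(config$simulate, annot)
      annotation <- annot$annotation
      scans <- expt$scans
      metadata <- expt$metadata
      truth <- expt$truth
      gene_models <- annot$gene_models
    } else {
      if (is.null(config$paths)) {
        abort("config needs either a simulate block or input paths")
      }
      annotation <- read_probe_annotation(config$paths$annotation)
      metadata <- read_sample_metadata(config$paths$metadata)
      scans <- lapply(names(config$paths$scans), function(sid) {
        read_scan_table(config$paths$scans[[sid]], sid,
                        sample_channel = metadata$dye[metadata$sample_id == sid],
                        annotation = annotation)
      })
      names(scans) <- names(config$paths$scans)
      truth <- NULL
      gene_models <- NULL
    }

    stage <- "preprocess"
    expr <- assemble_expression_matrix(scans, metadata, config$preprocess)

    stage <- "sam/consensus"
    consensus <- run_consensus(expr, metadata, config$sam, config$consensus)

    stage <- "annotation_report"
    partition <- partition_coding_noncoding(consensus, annotation)
    concordance <- locus_concordance(consensus, annotation)
    sig <- consensus$table$probe_id
    zs <- NULL; clustering <- NULL
    if (length(sig) >= 1) {
      zs <- zscore_matrix(expr$values[sig, , drop = FALSE])
      clustering <- upgma_order(expr$values[sig, , drop = FALSE])
    }
    list(expr = expr, consensus = consensus, annotation = annotation,
         gene_models = gene_models, partition = partition,
         concordance = concordance, zscores = zs, clustering = clustering,
         truth = truth, metadata = metadata)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })

  cfg_hash <- hash(config)
  result$config_hash <- cfg_hash
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("config_hash: %s seed: %d", cfg_hash, config$seed)
    write_results(result$consensus, result$annotation,
                  file.path(outdir, "consensus.tsv"), stamp = stamp)
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = config$seed,
           preset = config$preset,
           partition = result$partition,
           concordance = result$concordance$summary),
      file.path(outdir, "partition_counts.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv_stamped(result$concordance$pairs,
                      file.path(outdir, "concordance.tsv"), stamp)
    if (!is.null(result$zscores)) {
      write_tsv_stamped(as_tibble(result$zscores, rownames = "probe_id"),
                        file.path(outdir, "zscores.tsv"), stamp)
    }
    if (!is.null(result$clustering$newick)) {
      writeLines(result$clustering$newick,
                 file.path(outdir, "dendrogram.nwk"))
    }
    write_trace(result$consensus, file.path(outdir, "trace.tsv"), stamp)
    writeLines(c(paste0("# ", stamp),
                 yaml::as.yaml(list(
                   preset = config$preset, seed = config$seed,
                   preprocess = unclass(config$preprocess),
                   sam = unclass(config$sam)[
                     c("n_permutations", "seed", "s0_method",
                       "exhaustive_if_possible", "false_count_summary",
                       "n_deltas")],
                   consensus = unclass(config$consensus)))),
               file.path(outdir, "run_log.yaml"))
  }
  invisible(result)
}

#' Validate against a deposited processed matrix
#'
#' Bypasses preprocessing: reads a GEO series-matrix file, keeps probes
#' measured in every sample, and runs the SAM + leave-one-out consensus
#' and the coding/ncRNA partition on the deposited values.
#'
#' @param series_matrix_path Series-matrix text file.
#' @param metadata Sample metadata tibble mapping the matrix's sample ids
#'   to groups; every matrix column must be covered.
#' @param annotation Optional annotation tibble for the partition step.
#' @param sam A [sam_params()].
#' @param consensus A [consensus_params()].
#' @return List with `expr`, `consensus`, and (when annotation is given)
#'   `partition`.
#' @export
validate_geo <- function(series_matrix_path, metadata,
                         annotation = NULL,
                         sam = sam_params(),
                         consensus = consensus_params()) {
  expr <- read_series_matrix(series_matrix_path)
  unknown <- setdiff(colnames(expr$values), metadata$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("sample-group mapping missing for: %s",
                  paste(unknown, collapse = ", ")))
  }
  keep <- rowSums(expr$expressed) == ncol(expr$expressed)
  mat <- expr$values[keep, , drop = FALSE]
  metadata <- metadata[match(colnames(mat), metadata$sample_id), ,
                       drop = FALSE]
  cons <- run_consensus(mat, metadata, sam, consensus)
  out <- list(expr = expr, consensus = cons)
  if (!is.null(annotation)) {
    out$partition <- partition_coding_noncoding(cons, annotation)
  }
  out
}
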