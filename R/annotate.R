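#' Classify probes against gene models
#'
#' A probe overlapping an exon of a gene on the same strand is `coding`;
#' a probe inside a gene span but not exon-overlapping on the same strand
#' is `intronic` (orientation `sense` when strands match, `antisense`
#' otherwise); a probe outside all spans is `intergenic` and takes the
#' name of the nearest protein-coding gene on its chromosome. Probes
#' overlapping an exon boundary on the same strand are classed coding
#' (any shared base counts). Probes on chromosomes absent from the models
#' are classified intergenic with no host locus and a warning.
#'
#' In production runs on a real platform the shipped annotation is
#' authoritative; this classifier serves synthetic data and consistency
#' checks.
#'
#' @param probes Tibble with probe_id, chrom, start, end, strand.
#' @param gene_models Tibble with locus_name, locus_id, chrom, strand,
#'   start, end and an `exons` list-column of (start, end) tibbles.
#' @return `probes` with probe_class, orientation and host locus_name /
#'   locus_id replaced by the derived values.
#' @export
classify_probes <- function(probes, gene_models) {
  stopifnot(all(c("probe_id", "chrom", "start", "end", "strand") %in%
                  names(probes)))
  out <- probes
  out$probe_class <- NA_character_
  out$orientation <- NA_character_
  out$locus_name <- NA_character_
  out$locus_id <- NA_integer_
  missing_chrom <- character(0)
  for (ch in unique(probes$chrom)) {
    pidx <- which(probes$chrom == ch)
    gm <- gene_models[gene_models$chrom == ch, , drop = FALSE]
    if (nrow(gm) == 0) {
      out$probe_class[pidx] <- "intergenic"
      missing_chrom <- c(missing_chrom, ch)
      next
    }
    for (i in pidx) {
      ps <- probes$start[i]; pe <- probes$end[i]; pstr <- probes$strand[i]
      ov <- which(gm$start <= pe & gm$end >= ps)
      if (length(ov) > 0) {
        # exon overlap on the same strand wins (conservative: coding)
        coding_hit <- NA_integer_
        for (g in ov) {
          if (gm$strand[g] == pstr) {
            ex <- gm$exons[[g]]
            if (any(ex$start <= pe & ex$end >= ps)) { coding_hit <- g; break }
          }
        }
        if (!is.na(coding_hit)) {
          out$probe_class[i] <- "coding"
          out$locus_name[i] <- gm$locus_name[coding_hit]
          out$locus_id[i] <- gm$locus_id[coding_hit]
        } else {
          g <- ov[1]
          out$probe_class[i] <- "intronic"
          out$orientation[i] <- if (gm$strand[g] == pstr) "sense" else "antisense"
          out$locus_name[i] <- gm$locus_name[g]
          out$locus_id[i] <- gm$locus_id[g]
        }
      } else {
        ng <- nearest_gene_idx(ps, pe, gm)
        out$probe_class[i] <- "intergenic"
        out$orientation[i] <- if (gm$strand[ng] == pstr) "sense" else "antisense"
        out$locus_name[i] <- gm$locus_name[ng]
        out$locus_id[i] <- gm$locus_id[ng]
      }
    }
  }
  if (length(missing_chrom) > 0) {
    warn(sprintf("chromosome(s) absent from gene models: %s; probes there classified intergenic without host locus",
                 paste(missing_chrom, collapse = ", ")))
  }
  out
}

nearest_gene_idx <- function(ps, pe, gm) {
  gap <- pmax(gm$start - pe, ps - gm$end, 0)
  hits <- which(gap == min(gap))
  if (length(hits) > 1) {
    inform("nearest-gene tie broken to the lower start coordinate")
    hits <- hits[order(gm$start[hits])]
  }
  hits[1]
}

#' Nearest protein-coding gene on the same chromosome
#'
#' Minimal gap between the probe interval and the gene span (0 when
#' overlapping); equidistant ties break to the gene with the lower start
#' coordinate (logged).
#'
#' @param chrom,start,end Probe interval (1-based inclusive).
#' @param gene_models Gene model tibble (see [classify_probes()]).
#' @return The nearest gene's locus_name.
#' @export
nearest_gene <- function(chrom, start, end, gene_models) {
  gm <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
  if (nrow(gm) == 0) abort(sprintf("no gene models on %s", chrom))
  gm$locus_name[nearest_gene_idx(start, end, gm)]
}

#' Partition a consensus list into coding and ncRNA counts
#'
#' @param consensus A `consensus_result` or its `table` tibble (with
#'   probe_id and direction).
#' @param annotation Annotation tibble covering every consensus probe.
#' @return Tibble with one row per (probe_class_group, direction):
#'   columns class (`coding`/`ncrna`), direction, n; counts sum to the
#'   consensus size.
#' @export
partition_coding_noncoding <- function(consensus, annotation) {
  tbl <- if (inherits(consensus, "consensus_result")) consensus$table else consensus
  missing <- setdiff(tbl$probe_id, annotation$probe_id)
  if (length(missing) > 0) {
    abort(sprintf("unannotated probe(s): %s", paste(missing, collapse = ", ")))
  }
  joined <- tbl %>%
    left_join(annotation %>% select("probe_id", "probe_class"),
              by = "probe_id") %>%
    mutate(class = if_else(.data$probe_class == "coding", "coding", "ncrna"))
  grid <- tidyr::expand_grid(class = c("coding", "ncrna"),
                             direction = c("up", "down"))
  joined %>%
    group_by(.data$class, .data$direction) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("class", "direction")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    arrange(.data$class, .data$direction)
}

#' Locus-level coding/ncRNA concordance
#'
#' For every locus contributing at least one significant ncRNA probe and
#' at least one significant coding probe, forms one pair per ncRNA probe
#' (matched to the locus's lowest-q coding probe when several are
#' significant) and flags it concordant when both directions agree.
#'
#' @inheritParams partition_coding_noncoding
#' @return List with `pairs` (tibble: locus_name, ncrna_probe,
#'   ncrna_direction, coding_probe, coding_direction, concordant) and
#'   `summary` (tibble: n_both_up, n_both_down, n_discordant).
#' @export
locus_concordance <- function(consensus, annotation) {
  tbl <- if (inherits(consensus, "consensus_result")) consensus$table else consensus
  joined <- tbl %>%
    left_join(annotation %>%
                select("probe_id", "locus_name", "probe_class"),
              by = "probe_id")
  coding <- joined %>%
    filter(.data$probe_class == "coding") %>%
    group_by(.data$locus_name) %>%
    dplyr::slice_min(.data$q_value, n = 1, with_ties = FALSE) %>%
    ungroup()
  ncrna <- joined %>% filter(.data$probe_class != "coding")
  pairs <- ncrna %>%
    inner_join(coding %>%
                 select("locus_name", coding_probe = "probe_id",
                        coding_direction = "direction"),
               by = "locus_name") %>%
    mutate(concordant = .data$direction == .data$coding_direction) %>%
    select("locus_name", ncrna_probe = "probe_id",
           ncrna_direction = "direction", "coding_probe",
           "coding_direction", "concordant")
  summary <- tibble(
    n_both_up = sum(pairs$concordant & pairs$ncrna_direction == "up"),
    n_both_down = sum(pairs$concordant & pairs$ncrna_direction == "down"),
    n_discordant = sum(!pairs$concordant)
  )
  list(pairs = pairs, summary = summary)
}

#' Per-probe z-score matrix for heatmap display
#'
#' Each row becomes (x - row mean) / row SD using the population SD
#' (denominator n), i.e. the number of standard deviations above or below
#' the probe's average across all samples. Zero-SD rows become all zero
#' with a warning.
#'
#' @param mat Probes x samples numeric matrix.
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) abort("z-scores need at least 2 samples")
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))
  if (any(sdp == 0)) {
    warn(sprintf("%d zero-variance row(s) set to z = 0", sum(sdp == 0)))
  }
  z <- (mat - mu) / ifelse(sdp == 0, 1, sdp)
  z[sdp == 0, ] <- 0
  z
}

#' UPGMA sample clustering on correlation distance
#'
#' Clusters sample columns by average linkage (UPGMA) on the distance
#' 1 - Pearson correlation between expression profiles. Columns are
#' processed in sample-id order so merge ties resolve deterministically.
#'
#' @param mat Probes x samples numeric matrix.
#' @return List with `hclust` (the tree), `order` (leaf labels left to
#'   right), `dist` (the distance object) and `newick` (Newick string,
#'   present when the ape package is available).
#' @export
upgma_order <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) abort("clustering needs at least 2 samples")
  const <- apply(mat, 2, function(x) sd(x) == 0)
  if (any(const)) {
    abort(sprintf("constant expression column(s): %s (correlation undefined)",
                  paste(colnames(mat)[const], collapse = ", ")))
  }
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- as.dist(1 - cor(mat))
  hc <- hclust(d, method = "average")
  newick <- NULL
  if (requireNamespace("ape", quietly = TRUE)) {
    newick <- ape::write.tree(ape::as.phylo(hc))
  }
  list(hclust = hc, order = hc$labels[hc$order], dist = d, newick = newick)
}

#' Mean patient-control correlation of a matrix
#'
#' Mean Pearson correlation over all patient x control column pairs —
#' the homogeneity summary used to contrast cell compartments.
#'
#' @param mat Probes x samples matrix.
#' @param groups Character vector (`patient`/`control`) aligned to
#'   columns.
#' @return List with `mean_cor` and `cors` (tibble of all pairs).
#' @export
cross_group_correlation <- function(mat, groups) {
  mat <- as.matrix(mat)
  ind <- as_group_indicator(groups, ncol(mat))
  cm <- cor(mat[, ind, drop = FALSE], mat[, !ind, drop = FALSE])
  cors <- tibble(
    patient = rep(rownames(cm), times = ncol(cm)),
    control = rep(colnames(cm), each = nrow(cm)),
    r = as.vector(cm)
  )
  if (nrow(cors) < 2) abort("need at least 2 patient-control pairs")
  list(mean_cor = mean(cors$r), cors = cors)
}

#' Compare cross-group homogeneity of two compartments
#'
#' Wilcoxon rank-sum test on Fisher-z transformed patient-control
#' pairwise correlations from two matrices with disjoint samples. The
#' pairwise correlations are not independent, so the p-value is a
#' descriptive summary rather than an exact test.
#'
#' @param mat1,mat2 Probes x samples matrices for the two compartments.
#' @param groups1,groups2 Group labels aligned to their columns.
#' @return List with `mean_cor_1`, `mean_cor_2`, `p_value`, `statistic`.
#' @export
compare_group_correlation <- function(mat1, groups1, mat2, groups2) {
  c1 <- cross_group_correlation(mat1, groups1)
  c2 <- cross_group_correlation(mat2, groups2)
  wt <- wilcox.test(atanh(c1$cors$r), atanh(c2$cors$r), exact = FALSE)
  list(mean_cor_1 = c1$mean_cor, mean_cor_2 = c2$mean_cor,
       p_value = wt$p.value, statistic = unname(wt$statistic))
}
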