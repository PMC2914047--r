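#' Configuration for the synthetic intron-exon array generator
#'
#' Builds the parameter list consumed by [synth_annotation()],
#' [synth_experiment()] and [synth_qpcr()]. The generator emulates a
#' two-color (Cy3/Cy5) common-reference oligoarray experiment on a platform
#' that mixes exonic probes for protein-coding genes with long intronic
#' (sense and antisense) and intergenic ncRNA probes sharing loci with the
#' coding probes: log-normal intensities, additive local background, a
#' smooth intensity-dependent dye bias, and a configurable fraction of
#' truly differentially expressed probes with known direction and effect.
#'
#' @param n_loci Number of protein-coding gene loci to simulate.
#' @param probe_mix Named probabilities that a locus carries, besides its
#'   mandatory coding probe, an intronic sense probe, an intronic antisense
#'   probe, and a downstream intergenic probe.
#' @param n_patients,n_controls Group sizes (each >= 2; >= 3 for
#'   leave-one-out analyses).
#' @param de_fraction Fraction of probes with a planted group effect.
#' @param effect_sizes Pool of absolute log2 effect sizes sampled for
#'   planted DE probes.
#' @param bio_sd,tech_sd Biological (per sample) and technical (per
#'   channel) noise SD in log2 units.
#' @param baseline_log2_mean,baseline_log2_sd Log2 mean/SD of expressed
#'   probe abundance (log-normal intensities).
#' @param frac_unexpressed Fraction of probes simulated near background.
#' @param baseline_unexpressed Log2 abundance of unexpressed probes.
#' @param de_min_baseline_log2 Minimal log2 baseline abundance of probes
#'   eligible for a planted effect. Planted fold changes are spike-ins:
#'   placing them below the detection floor would measure the expressed
#'   filter rather than the statistic, so effects go on probes
#'   quantifiable in both groups (default 9, about four-fold above a
#'   typical background threshold).
#' @param bg_mean,bg_sd Additive local background mean/SD in intensity
#'   units (normal truncated at zero).
#' @param dye_amplitude Amplitude (log2 units) of the Cy5 dye bias.
#' @param dye_shape `"sine"` for a smooth intensity-dependent bias,
#'   `"constant"` for a flat offset, `"none"` to disable.
#' @param concordance_plan Either `NULL` or a list with integer fields
#'   `down_down`, `up_up`, `discordant`: the number of loci where an ncRNA
#'   probe and the coding probe of the same locus are jointly planted DE
#'   with the stated direction pattern.
#' @param seed Master seed; all generator randomness derives from it.
#'
#' @return A list of class `synth_config`.
#' @seealso [synth_preset()] for ready-made study-shaped designs.
#' @export
synth_config <- function(n_loci = 400,
                         probe_mix = c(intronic_sense = 0.5,
                                       intronic_antisense = 0.3,
                                       intergenic = 0.15),
                         n_patients = 4,
                         n_controls = 4,
                         de_fraction = 0.15,
                         effect_sizes = c(1.0, 1.5, 2.0, 2.5),
                         bio_sd = 0.3,
                         tech_sd = 0.15,
                         baseline_log2_mean = 9,
                         baseline_log2_sd = 1.5,
                         frac_unexpressed = 0.05,
                         baseline_unexpressed = 3,
                         de_min_baseline_log2 = 9,
                         bg_mean = 80,
                         bg_sd = 20,
                         dye_amplitude = 0.4,
                         dye_shape = c("sine", "constant", "none"),
                         concordance_plan = NULL,
                         seed = 1L) {
  dye_shape <- match.arg(dye_shape)
  stopifnot(
    n_loci >= 2,
    all(probe_mix >= 0 & probe_mix <= 1),
    n_patients >= 2, n_controls >= 2,
    de_fraction >= 0, de_fraction <= 1,
    all(effect_sizes > 0),
    bio_sd >= 0, tech_sd >= 0, bg_sd >= 0,
    frac_unexpressed >= 0, frac_unexpressed < 1
  )
  if (!is.null(concordance_plan)) {
    stopifnot(all(c("down_down", "up_up", "discordant") %in%
                    names(concordance_plan)))
  }
  structure(list(
    n_loci = n_loci, probe_mix = probe_mix,
    n_patients = n_patients, n_controls = n_controls,
    de_fraction = de_fraction, effect_sizes = effect_sizes,
    bio_sd = bio_sd, tech_sd = tech_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    frac_unexpressed = frac_unexpressed,
    baseline_unexpressed = baseline_unexpressed,
    de_min_baseline_log2 = de_min_baseline_log2,
    bg_mean = bg_mean, bg_sd = bg_sd,
    dye_amplitude = dye_amplitude, dye_shape = dye_shape,
    concordance_plan = concordance_plan,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Study-shaped synthetic presets
#'
#' `"cd34"` emulates a 4 patient vs 4 control hematopoietic-progenitor
#' design; `"stromal"` a 3 vs 4 bone-marrow stroma design. Both use ~15%
#' planted DE probes with a ~30% ncRNA share of the platform and a
#' 13-locus coding/ncRNA concordance plan of 7 jointly down-regulated,
#' 5 jointly up-regulated and 1 discordant locus.
#'
#' @param name `"cd34"` or `"stromal"`.
#' @param ... Overrides forwarded to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("cd34", "stromal"), ...) {
  name <- match.arg(name)
  base <- list(
    n_loci = 600,
    probe_mix = c(intronic_sense = 0.45, intronic_antisense = 0.35,
                  intergenic = 0.1),
    de_fraction = 0.15,
    effect_sizes = c(1.0, 1.5, 2.0, 2.5),
    concordance_plan = list(down_down = 7, up_up = 5, discordant = 1)
  )
  if (name == "cd34") {
    base$n_patients <- 4; base$n_controls <- 4
  } else {
    base$n_patients <- 3; base$n_controls <- 4
  }
  over <- list(...)
  base[names(over)] <- over
  do.call(synth_config, base)
}

#' Simulate probe annotations and gene models
#'
#' Lays non-overlapping gene spans (three exons each) along a handful of
#' chromosomes and derives probes from them: one coding probe inside the
#' middle exon of every locus, optional intronic probes (sense and
#' antisense) inside the first intron, and optional intergenic probes in
#' the gap downstream of a gene (named after the nearest coding gene, per
#' the platform's annotation convention). The emitted classes are
#' reproducible by [classify_probes()] on the same gene models.
#'
#' @param config A [synth_config()].
#' @return A list with `annotation` (tibble, one row per probe) and
#'   `gene_models` (tibble with an `exons` list-column).
#' @export
synth_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  n <- config$n_loci
  n_chrom <- max(1L, min(8L, ceiling(n / 50)))
  chrom_of <- sprintf("chr%d", ((seq_len(n) - 1L) %% n_chrom) + 1L)

  span_len <- round(runif(n, 20000, 60000))
  gap <- round(runif(n, 20000, 80000))
  gstrand <- sample(c("+", "-"), n, replace = TRUE)
  # lay genes left to right per chromosome, never overlapping
  gstart <- integer(n)
  for (ch in unique(chrom_of)) {
    i <- which(chrom_of == ch)
    gstart[i] <- 10000L + cumsum(c(0, (span_len + gap)[head(i, -1)]))
  }
  gend <- gstart + span_len - 1L
  exon_len <- 300L
  mid <- gstart + round(span_len / 2)
  gene_models <- tibble(
    locus_name = sprintf("GENE%04d", seq_len(n)),
    locus_id = 10000L + seq_len(n),
    chrom = chrom_of, strand = gstrand,
    start = gstart, end = gend,
    exons = purrr::pmap(
      list(gstart, mid, gend),
      function(s1, s2, e3) list(
        start = c(s1, s2, e3 - exon_len + 1L),
        end = c(s1 + exon_len - 1L, s2 + exon_len - 1L, e3)))
  )

  probe_len <- 60L
  mix <- config$probe_mix
  has_is <- runif(n) < mix[["intronic_sense"]]
  has_ias <- runif(n) < mix[["intronic_antisense"]]
  has_ig <- runif(n) < mix[["intergenic"]]
  ig_strand <- sample(c("+", "-"), n, replace = TRUE)
  intron_lo <- gstart + exon_len + 200L  # inside the first intron

  base_cols <- function(idx, start, strand, probe_class, orientation) {
    tibble(locus_idx = idx,
           locus_name = gene_models$locus_name[idx],
           locus_id = gene_models$locus_id[idx],
           chrom = chrom_of[idx],
           start = start, end = start + probe_len - 1L,
           strand = as.character(strand),
           probe_class = probe_class,
           orientation = as.character(orientation))
  }
  annotation <- bind_rows(
    base_cols(seq_len(n), mid + 50L, gstrand, "coding", NA_character_),
    base_cols(which(has_is), intron_lo[has_is], gstrand[has_is],
              "intronic", "sense"),
    base_cols(which(has_ias), intron_lo[has_ias] + 500L,
              ifelse(gstrand[has_ias] == "+", "-", "+"),
              "intronic", "antisense"),
    # placed just downstream so this gene is the nearest on the chromosome
    base_cols(which(has_ig), gend[has_ig] + 1000L, ig_strand[has_ig],
              "intergenic",
              ifelse(ig_strand[has_ig] == gstrand[has_ig],
                     "sense", "antisense"))
  ) %>%
    arrange(.data$locus_idx,
            match(.data$probe_class, c("coding", "intronic", "intergenic")),
            .data$start) %>%
    mutate(probe_id = sprintf("PR%05d", row_number())) %>%
    select("probe_id", "locus_name", "locus_id", "chrom", "start", "end",
           "strand", "probe_class", "orientation")
  list(annotation = annotation, gene_models = gene_models)
}

dye_bias_log2 <- function(A, amplitude, shape) {
  switch(shape,
    none = rep(0, length(A)),
    constant = rep(amplitude, length(A)),
    sine = amplitude * sin(A * pi / 4)
  )
}

#' Simulate a two-color array experiment with known truth
#'
#' Draws a per-probe log2 baseline abundance, plants group effects on a
#' configurable fraction of probes (honouring the locus concordance plan
#' first), and renders each sample as a two-channel scan: the biological
#' sample on Cy5 against a common pooled reference on Cy3, with technical
#' noise, a smooth intensity-dependent dye bias on Cy5, and additive local
#' background in both channels.
#'
#' @param config A [synth_config()].
#' @param annot Output of [synth_annotation()] (list with `annotation`).
#' @return A list with `scans` (named list of `array_scan`), `metadata`
#'   (tibble: sample_id, group, cell_type, dye) and `truth` (tibble:
#'   probe_id, is_de, direction, log2_effect, concordance_class).
#' @export
synth_experiment <- function(config, annot) {
  stopifnot(inherits(config, "synth_config"))
  annotation <- annot$annotation
  set.seed(derive_seed(config$seed, "experiment"))
  p <- nrow(annotation)
  probe_id <- annotation$probe_id

  # --- abundances -------------------------------------------------------
  expressed <- runif(p) >= config$frac_unexpressed
  baseline <- ifelse(
    expressed,
    rnorm(p, config$baseline_log2_mean, config$baseline_log2_sd),
    rnorm(p, config$baseline_unexpressed, 0.3)
  )
  # planted effects are spike-ins: only probes quantifiable in both groups
  eligible_de <- expressed & baseline >= config$de_min_baseline_log2

  # --- plant truth ------------------------------------------------------
  is_de <- rep(FALSE, p)
  direction <- rep(0L, p)
  effect <- rep(0, p)
  conc_class <- rep(NA_character_, p)
  names(conc_class) <- probe_id

  plan <- config$concordance_plan
  planned_loci <- character(0)
  if (!is.null(plan)) {
    eligible <- annotation %>%
      mutate(de_ok = eligible_de) %>%
      group_by(.data$locus_name) %>%
      summarise(has_coding = any(.data$probe_class == "coding" & .data$de_ok),
                has_nc = any(.data$probe_class != "coding" & .data$de_ok)) %>%
      filter(.data$has_coding, .data$has_nc) %>%
      pull(.data$locus_name)
    need <- plan$down_down + plan$up_up + plan$discordant
    if (length(eligible) < need) {
      abort("not enough loci with both coding and ncRNA probes for the concordance plan")
    }
    planned_loci <- sample(eligible, need)
    classes <- rep(c("down_down", "up_up", "discordant"),
                   times = c(plan$down_down, plan$up_up, plan$discordant))
    for (j in seq_along(planned_loci)) {
      loc <- planned_loci[j]
      idx_c <- which(annotation$locus_name == loc &
                       annotation$probe_class == "coding" & eligible_de)[1]
      idx_nc <- which(annotation$locus_name == loc &
                        annotation$probe_class != "coding" & eligible_de)[1]
      dir_pair <- switch(classes[j],
        down_down = c(-1L, -1L),
        up_up = c(1L, 1L),
        discordant = c(-1L, 1L)  # coding down, ncRNA up
      )
      eff <- sample_from(config$effect_sizes, 1L)
      is_de[c(idx_c, idx_nc)] <- TRUE
      direction[idx_c] <- dir_pair[1]
      direction[idx_nc] <- dir_pair[2]
      effect[c(idx_c, idx_nc)] <- eff
      conc_class[annotation$locus_name == loc] <- classes[j]
      # any further ncRNA probes at a planned locus stay non-DE so the
      # planted pair count equals the plan exactly
    }
  }

  n_de_target <- round(config$de_fraction * p)
  free <- which(!is_de & eligible_de &
                  !(annotation$locus_name %in% planned_loci))
  n_extra <- max(0L, n_de_target - sum(is_de))
  if (n_extra > 0 && length(free) > 0) {
    extra <- sample(free, min(n_extra, length(free)))
    is_de[extra] <- TRUE
    direction[extra] <- sample(c(-1L, 1L), length(extra), replace = TRUE)
    effect[extra] <- sample_from(config$effect_sizes, length(extra),
                                 replace = TRUE)
  }

  dir_label <- ifelse(is_de, ifelse(direction > 0, "up", "down"),
                      NA_character_)
  signed_effect <- ifelse(is_de, direction * effect, 0)
  truth <- tibble(
    probe_id = probe_id,
    is_de = is_de,
    direction = dir_label,
    log2_effect = signed_effect,
    concordance_class = unname(conc_class)
  )

  # --- metadata ---------------------------------------------------------
  metadata <- tibble(
    sample_id = c(sprintf("PT%d", seq_len(config$n_patients)),
                  sprintf("CT%d", seq_len(config$n_controls))),
    group = rep(c("patient", "control"),
                c(config$n_patients, config$n_controls)),
    cell_type = "synthetic",
    dye = "Cy5"
  )

  rtrunc0 <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0)

  scans <- vector("list", nrow(metadata))
  names(scans) <- metadata$sample_id
  for (j in seq_len(nrow(metadata))) {
    grp_eff <- if (metadata$group[j] == "patient") truth$log2_effect else 0
    a_sample <- baseline + grp_eff + rnorm(p, 0, config$bio_sd) +
      rnorm(p, 0, config$tech_sd)
    a_ref <- baseline + rnorm(p, 0, config$tech_sd)
    sig5 <- 2^a_sample
    sig3 <- 2^a_ref
    A <- 0.5 * (log2(sig5) + log2(sig3))
    sig5 <- sig5 * 2^dye_bias_log2(A, config$dye_amplitude, config$dye_shape)
    bg5 <- rtrunc0(p, config$bg_mean, config$bg_sd)
    bg3 <- rtrunc0(p, config$bg_mean, config$bg_sd)
    scans[[j]] <- array_scan(
      sample_id = metadata$sample_id[j],
      data = tibble(
        probe_id = probe_id,
        fg_cy3 = sig3 + rtrunc0(p, config$bg_mean, config$bg_sd),
        bg_cy3 = bg3,
        spread_cy3 = rep(config$bg_sd, p),
        fg_cy5 = sig5 + rtrunc0(p, config$bg_mean, config$bg_sd),
        bg_cy5 = bg5,
        spread_cy5 = rep(config$bg_sd, p)
      ),
      sample_channel = "Cy5"
    )
  }

  list(scans = scans, metadata = metadata, truth = truth)
}

#' Simulate qPCR CT tables matching planted array truth
#'
#' Renders triplicate CT measurements for a set of target genes plus a
#' non-regulated reference gene (HPRT-like), under the standard
#' exponential-amplification model: CT decreases one cycle per doubling of
#' template, so a planted log2 effect of e shifts patient CTs by -e
#' relative to controls. With `ct_sd = 0`, 2^-ddCT inverts exactly to the
#' planted fold change.
#'
#' @param truth Truth table from [synth_experiment()].
#' @param config The same [synth_config()].
#' @param genes Probe ids to assay; defaults to up to 8 planted DE probes.
#' @param n_replicates Technical replicates per well (default 3).
#' @param ct_sd Replicate jitter SD in cycles.
#' @param ct_intercept Cycles at unit template.
#' @return Long tibble: sample_id, group, gene, replicate, ct_target,
#'   ct_reference.
#' @export
synth_qpcr <- function(truth, config, genes = NULL, n_replicates = 3,
                       ct_sd = 0.15, ct_intercept = 30) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "qpcr"))
  if (is.null(genes)) {
    genes <- head(truth$probe_id[truth$is_de], 8L)
  }
  missing <- setdiff(genes, truth$probe_id)
  if (length(missing) > 0) {
    abort(sprintf("genes absent from truth table: %s",
                  paste(missing, collapse = ", ")))
  }
  samples <- tibble(
    sample_id = c(sprintf("PT%d", seq_len(config$n_patients)),
                  sprintf("CT%d", seq_len(config$n_controls))),
    group = rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  )
  eff <- truth$log2_effect[match(genes, truth$probe_id)]
  grid <- tidyr::expand_grid(samples, gene = genes,
                             replicate = seq_len(n_replicates))
  grid$eff <- eff[match(grid$gene, genes)]
  grid %>%
    mutate(
      ct_target = ct_intercept -
        ifelse(.data$group == "patient", .data$eff, 0) +
        rnorm(n(), 0, ct_sd),
      ct_reference = ct_intercept - 5 + rnorm(n(), 0, ct_sd)
    ) %>%
    select("sample_id", "group", "gene", "replicate",
           "ct_target", "ct_reference")
}
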