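#' Percentage with one-decimal half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal — the
#' convention used for every percentage in the summary report.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return A single number with one decimal.
#' @examples
#' percentage(3943, 5304)   # 74.3
#' @export
percentage <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  floor(1000 * numerator / denominator + 0.5) / 10
}

#' Default run configuration
#'
#' Returns the full parameter set of the pipeline with the defaults used by
#' the simulation study: a 50-kb synthetic chromosome, 20 planted peaks per
#' transcription-factor fraction with a planted co-occupancy fraction of
#' 0.3, planted peak intensities drawn from the per-fraction Normal
#' distributions (mean 206.8 / SD 120.6 and mean 89.0 / SD 62.0), a planted
#' motif-presence fraction of 0.42, mouse region intensities from
#' Normal(3.1, 1.4) and Normal(5.4, 2.5), and the analysis parameters
#' (250-bp bandwidth and distance, match-score thresholds, 1.5-fold DEG
#' cut, Gli3 intensity cutoff 3.0).
#'
#' @param seed Root seed for all randomness.
#' @return A nested named list; see the package vignette for the meaning
#'   and units of every entry.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(
      chrom_lengths = c(chrS = 50000L),
      gc_fraction = 0.41,
      n_g1 = 20L, n_g2 = 20L,
      cooccupancy_fraction = 0.3,
      min_separation = 1200L,
      intensity_g1 = c(mean = 206.8, sd = 120.6),
      intensity_g2 = c(mean = 89.0, sd = 62.0),
      min_intensity = 5,
      library_size = 1e6,
      frag_len = 250L,
      noise_rate = 0.1,
      motif_fraction = 0.42,
      n_genes = 30L, gene_width = 700L, gene_spacing = 1600L,
      n_deg_up = 5L, n_deg_down = 3L, deg_log2fc = 1.5,
      n_per_group = 4L, noise_sd = 0.15, baseline = 8,
      n_conserved = 15L, conserved_fraction = 0.5,
      n_ctcf = 25L, ctcf_fraction = 0.6,
      n_mg1 = 40L, mg1_fraction = 0.5, mg1_intensity = c(mean = 3.1, sd = 1.4),
      n_mg3 = 120L, mg3_fraction = 0.5, mg3_intensity = c(mean = 5.4, sd = 2.5)
    ),
    motifs = list(gli = "GACCACCCA", ctcf = "CCMMYYCHHGGTGG"),
    thresholds = list(gli = 0.95, ctcf = 0.65),
    background = 2.0,
    bandwidth = 250L, distance = 250L, min_width = 50L,
    flank = 250L,
    fc_threshold = 1.5, alpha = 0.05, adjust = "none",
    gli3_cutoff = 3.0,
    neighbors_per_side = 1L
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, overlays it on [default_config()], and validates
#' every numeric parameter against its domain.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg A configuration list.
#' @export
validate_config <- function(cfg) {
  s <- cfg$simulate
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  chk(identical(cfg$background, "auto") ||
      (is.numeric(cfg$background) && cfg$background >= 0),
      "background must be 'auto' or a non-negative number")
  chk(cfg$bandwidth > 0, "bandwidth must be positive")
  chk(cfg$distance >= 0, "distance must be non-negative")
  chk(cfg$flank > 0, "flank must be positive")
  chk(cfg$fc_threshold >= 1, "fc_threshold must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must lie in (0, 1]")
  chk(all(unlist(cfg$thresholds) >= 0 & unlist(cfg$thresholds) <= 1),
      "match-score thresholds must lie in [0, 1]")
  chk(all(s$chrom_lengths > 0), "chromosome lengths must be positive")
  chk(s$gc_fraction >= 0 && s$gc_fraction <= 1, "gc_fraction must lie in [0, 1]")
  chk(s$cooccupancy_fraction >= 0 && s$cooccupancy_fraction <= 1,
      "cooccupancy_fraction must lie in [0, 1]")
  chk(s$motif_fraction >= 0 && s$motif_fraction <= 1,
      "motif_fraction must lie in [0, 1]")
  chk(s$noise_rate >= 0, "noise_rate must be non-negative")
  chk(s$n_per_group >= 2, "n_per_group must be >= 2")
  invisible(cfg)
}

#' Plant ground-truth peak centres for two fractions
#'
#' Lays out candidate loci on a regular grid (spacing `min_separation`,
#' which keeps distinct loci from merging during detection), assigns loci
#' to fraction 1, co-occupied, or fraction 2 such that a fraction
#' `cooccupancy` of the fraction-2 peaks sits within `d` bp of a fraction-1
#' peak, and draws intensities from the per-fraction Normal parameters
#' (rejection-truncated below `min_intensity`).
#'
#' @param lengths Named chromosome lengths.
#' @param n_g1,n_g2 Peaks per fraction.
#' @param cooccupancy Fraction of fraction-2 peaks planted near a
#'   fraction-1 peak.
#' @param d Co-occupancy distance in bp.
#' @param min_separation Grid spacing between distinct loci in bp.
#' @param intensity_g1,intensity_g2 `c(mean=, sd=)` Normal parameters.
#' @param min_intensity Lower truncation for drawn intensities.
#' @param margin Distance kept free at chromosome ends.
#' @param seed Integer seed.
#' @return A data.frame with `chrom`, `center`, `intensity`, `fraction`
#'   ("GLI1"/"GLI2"), `locus` (shared id for co-occupied pairs) and
#'   `cooccupied` flag.
#' @export
simulate_truth_peaks <- function(lengths, n_g1, n_g2, cooccupancy, d = 250,
                                 min_separation = 1200, intensity_g1,
                                 intensity_g2, min_intensity = 5,
                                 margin = 600, seed = 1) {
  set.seed(seed)
  n_co <- round(n_g2 * cooccupancy)
  n_far2 <- n_g2 - n_co
  if (n_co > n_g1) stop("cannot co-occupy more fraction-2 peaks than fraction-1 loci")
  slots <- do.call(rbind, lapply(names(lengths), function(nm) {
    pos <- seq(margin, lengths[[nm]] - margin, by = min_separation)
    data.frame(chrom = nm, pos = as.integer(pos))
  }))
  need <- n_g1 + n_far2
  if (nrow(slots) < need)
    stop("genome too small for ", need, " separated loci at spacing ",
         min_separation)
  pick <- slots[sample.int(nrow(slots), need), , drop = FALSE]
  rint <- function(n, par) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, par[["mean"]], par[["sd"]])
      out <- c(out, x[x >= min_intensity])
    }
    out[seq_len(n)]
  }
  g1 <- data.frame(chrom = pick$chrom[seq_len(n_g1)],
                   center = pick$pos[seq_len(n_g1)],
                   intensity = rint(n_g1, intensity_g1),
                   fraction = "GLI1",
                   locus = seq_len(n_g1), cooccupied = FALSE)
  co_idx <- if (n_co > 0) sample.int(n_g1, n_co) else integer(0)
  g1$cooccupied[co_idx] <- TRUE
  g2_co <- if (n_co > 0) data.frame(
    chrom = g1$chrom[co_idx],
    center = g1$center[co_idx] + sample(seq(-floor(d / 2), floor(d / 2)), n_co,
                                        replace = TRUE),
    intensity = rint(n_co, intensity_g2), fraction = "GLI2",
    locus = g1$locus[co_idx], cooccupied = TRUE) else NULL
  g2_far <- if (n_far2 > 0) data.frame(
    chrom = pick$chrom[n_g1 + seq_len(n_far2)],
    center = pick$pos[n_g1 + seq_len(n_far2)],
    intensity = rint(n_far2, intensity_g2), fraction = "GLI2",
    locus = n_g1 + seq_len(n_far2), cooccupied = FALSE) else NULL
  out <- rbind(g1, g2_co, g2_far)
  rownames(out) <- NULL
  out
}

# Truth loci (one row per distinct genomic locus) from a truth-peak table.
.truth_loci <- function(truth) {
  loci <- truth[!duplicated(truth$locus), c("chrom", "center", "locus")]
  loci$cooccupied <- loci$locus %in% truth$locus[truth$cooccupied]
  loci[order(loci$locus), ]
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on simulated inputs generated from the
#' configuration: genome and ground-truth simulation, coverage
#' normalisation, IgG subtraction, enrichment-region detection,
#' three-criteria peak selection, co-occupancy partitioning, motif-presence
#' scanning, CTCF co-localisation with motif percentages, mouse-region
#' intensity filtering and conservation binning, differential-expression
#' calling, neighbourhood-based region-to-gene assignment, and the 7-group
#' and conservation-set DEG classifications. All randomness derives from
#' the root seed, so a repeated run writes byte-identical reports.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param outdir If non-`NULL`, directory where all intermediates and the
#'   report (`report.tsv`, `report.json`) are written.
#' @param seed Optional override of `config$seed`.
#' @return A list: `report` (named summary of counts, fractions and
#'   percentages), `truth` (planted ground truth), and the main
#'   intermediate objects (`peaks`, `selected`, `partition`, `ctcf`,
#'   `conservation`, `deg`, `binding_groups`, `conservation_sets`).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  s <- config$simulate
  root <- config$seed
  sd_of <- function(k) (root * 97L + k) %% .Machine$integer.max

  ## --- simulate ----------------------------------------------------------
  genome <- generate_genome(s$chrom_lengths, s$gc_fraction, seed = sd_of(1L))
  truth <- simulate_truth_peaks(
    s$chrom_lengths, s$n_g1, s$n_g2, s$cooccupancy_fraction, d = config$distance,
    min_separation = s$min_separation, intensity_g1 = s$intensity_g1,
    intensity_g2 = s$intensity_g2, min_intensity = s$min_intensity,
    seed = sd_of(2L))
  loci <- .truth_loci(truth)
  gli_wm <- matrix_from_iupac(config$motifs$gli, name = "GLI")
  ctcf_wm <- matrix_from_iupac(config$motifs$ctcf, name = "CTCF")
  n_motif <- round(nrow(loci) * s$motif_fraction)
  set.seed(sd_of(3L))
  motif_loci <- sort(sample.int(nrow(loci), n_motif))
  sites <- data.frame(chrom = loci$chrom[motif_loci],
                      position = as.integer(loci$center[motif_loci] -
                                            floor(gli_wm$length / 2)),
                      strand = "+")
  pl <- plant_motifs(genome, gli_wm, n = nrow(sites), at = sites,
                     seed = sd_of(3L),
                     scrub_threshold = config$thresholds$gli)
  genome <- pl$genome
  loci$has_motif <- seq_len(nrow(loci)) %in% motif_loci

  tr_g1 <- simulate_chip_coverage(genome, truth[truth$fraction == "GLI1", ],
                                  s$library_size, s$frag_len, s$noise_rate,
                                  seed = sd_of(4L))
  tr_g2 <- simulate_chip_coverage(genome, truth[truth$fraction == "GLI2", ],
                                  s$library_size, s$frag_len, s$noise_rate,
                                  seed = sd_of(5L))
  tr_igg <- simulate_chip_coverage(genome, truth[0, ], s$library_size,
                                   s$frag_len, s$noise_rate, seed = sd_of(6L))

  loci_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(pmax(1, loci$center - 125),
                                                     loci$center + 125))
  lens <- chrom_lengths(genome)
  conserved <- generate_region_sets(loci_gr, s$n_conserved,
                                    s$conserved_fraction, lens,
                                    d = config$distance, label = "conserved",
                                    seed = sd_of(7L))
  ctcf <- generate_region_sets(loci_gr, s$n_ctcf, s$ctcf_fraction, lens,
                               d = config$distance, label = "CTCF",
                               seed = sd_of(8L))
  mg1 <- generate_region_sets(loci_gr, s$n_mg1, s$mg1_fraction, lens,
                              d = config$distance,
                              intensity_mean = s$mg1_intensity[["mean"]],
                              intensity_sd = s$mg1_intensity[["sd"]],
                              label = "mG1", seed = sd_of(9L))
  mg3 <- generate_region_sets(loci_gr, s$n_mg3, s$mg3_fraction, lens,
                              d = config$distance,
                              intensity_mean = s$mg3_intensity[["mean"]],
                              intensity_sd = s$mg3_intensity[["sd"]],
                              label = "mG3", seed = sd_of(10L))

  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(s$n_genes)),
    chrom = names(lens)[1],
    start = 500L + (seq_len(s$n_genes) - 1L) * s$gene_spacing,
    end = 500L + (seq_len(s$n_genes) - 1L) * s$gene_spacing + s$gene_width - 1L,
    strand = rep(c("+", "-"), length.out = s$n_genes))
  set.seed(sd_of(11L))
  deg_ids <- sample(genes$gene_id, s$n_deg_up + s$n_deg_down)
  deg_truth <- stats::setNames(
    rep(c(s$deg_log2fc, -s$deg_log2fc), c(s$n_deg_up, s$n_deg_down)), deg_ids)
  expr <- simulate_expression(genes, deg_truth, s$n_per_group, s$noise_sd,
                              s$baseline, seed = sd_of(12L))

  ## --- normalise, subtract, detect, select --------------------------------
  sub_g1 <- subtract_control(normalize_coverage(tr_g1), normalize_coverage(tr_igg))
  sub_g2 <- subtract_control(normalize_coverage(tr_g2), normalize_coverage(tr_igg))
  pk_g1 <- detect_enriched_regions(sub_g1, config$bandwidth, config$background,
                                   config$min_width, fraction = "GLI1")
  pk_g2 <- detect_enriched_regions(sub_g2, config$bandwidth, config$background,
                                   config$min_width, fraction = "GLI2")
  sel_g1 <- select_peaks(pk_g1, conserved, pk_g2, config$distance)
  sel_g2 <- select_peaks(pk_g2, conserved, pk_g1, config$distance)

  ## --- partition, motifs, CTCF, conservation ------------------------------
  part <- classify_gli(sel_g1, sel_g2, config$distance)
  mp <- lapply(list(G1 = part$g1_only, G2 = part$g2_only), function(p)
    if (length(p)) motif_presence(p, genome, gli_wm, config$flank,
                                  config$thresholds$gli)$fraction else NA_real_)
  mp$GIS <- if (length(part$gis)) {
    gis_ctr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(part$gis), IRanges::ranges(part$gis),
      summit = as.integer((GenomicRanges::start(part$gis) +
                           GenomicRanges::end(part$gis)) / 2))
    motif_presence(gis_ctr, genome, gli_wm, config$flank,
                   config$thresholds$gli)$fraction
  } else NA_real_

  cl <- ctcf_colocalize(part, ctcf, config$distance)
  ctcf_motif_pct <- lapply(list(l = cl$l, k = cl$k, n = cl$n), function(set) {
    if (length(set) == 0L) return(NA_real_)
    ctr <- as.integer((GenomicRanges::start(set) + GenomicRanges::end(set)) / 2)
    sm <- S4Vectors::mcols(set)$summit
    if (!is.null(sm) && !anyNA(sm)) ctr <- sm
    set2 <- GenomicRanges::GRanges(GenomicRanges::seqnames(set),
                                   IRanges::ranges(set), summit = ctr)
    percentage(sum(motif_presence(set2, genome, ctcf_wm, config$flank,
                                  config$thresholds$ctcf)$has_motif),
               length(set2))
  })

  mg3_f <- filter_mouse_intensity(mg3, config$gli3_cutoff)
  cons <- conservation_bins(sel_g1, sel_g2, mg1, mg3_f, config$distance)

  ## --- expression integration ---------------------------------------------
  deg <- call_deg(expr, config$fc_threshold, config$alpha, config$adjust)
  nb <- build_neighborhoods(genes, lens, config$neighbors_per_side)
  bind_labels <- assign_regions(list(G1 = part$g1_only, G2 = part$g2_only,
                                     GIS = part$gis), nb)
  groups <- bin_deg_by_binding(deg, bind_labels)
  cons_sel_g1 <- sel_g1[within_distance(sel_g1, conserved, config$distance)]
  cons_sel_g2 <- sel_g2[within_distance(sel_g2, conserved, config$distance)]
  hm_labels <- assign_regions(list(hG1 = cons_sel_g1, hG2 = cons_sel_g2,
                                   mG1 = mg1, mG3 = mg3_f), nb)
  cons_sets <- bin_deg_by_conservation(deg, hm_labels[, c("gene_id", "hG1", "hG2")],
                                       hm_labels[, c("gene_id", "mG1", "mG3")])

  ## --- report --------------------------------------------------------------
  bin_counts <- table(factor(S4Vectors::mcols(cons)$bin,
                             levels = unique(unname(.conservation_letter_map))))
  report <- list(
    seed = root,
    peaks_detected = list(GLI1 = length(pk_g1), GLI2 = length(pk_g2)),
    peaks_selected = list(GLI1 = length(sel_g1), GLI2 = length(sel_g2)),
    partition = list(G1_only = length(part$g1_only),
                     G2_only = length(part$g2_only),
                     GIS = length(part$gis)),
    motif_presence = lapply(mp, function(x) round(x, 6)),
    ctcf = list(
      counts = list(l = length(cl$l), k = length(cl$k), n = length(cl$n)),
      percent_of_class = stats::setNames(as.list(cl$summary$percent),
                                         cl$summary$set),
      motif_percent = ctcf_motif_pct),
    mouse = list(mG1 = length(mg1), mG3_input = length(mg3),
                 mG3_kept = length(mg3_f),
                 mG3_kept_percent = percentage(length(mg3_f), length(mg3))),
    conservation_bins = as.list(stats::setNames(as.integer(bin_counts),
                                                names(bin_counts))),
    deg = list(up = sum(deg$deg_status == "up"),
               down = sum(deg$deg_status == "down"),
               binding_groups = as.list(attr(groups, "counts")),
               conservation_sets = as.list(attr(cons_sets, "counts")))
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(genome, file.path(outdir, "genome.fasta"))
    write_coverage_bedgraph(sub_g1, file.path(outdir, "subtracted_GLI1.bedGraph"))
    write_coverage_bedgraph(sub_g2, file.path(outdir, "subtracted_GLI2.bedGraph"))
    write_regions_bed(sel_g1, file.path(outdir, "selected_GLI1.bed"),
                      extra_cols = c("summit", "selection_reasons"))
    write_regions_bed(sel_g2, file.path(outdir, "selected_GLI2.bed"),
                      extra_cols = c("summit", "selection_reasons"))
    part_all <- c(GenomicRanges::granges(part$g1_only),
                  GenomicRanges::granges(part$g2_only),
                  GenomicRanges::granges(part$gis))
    S4Vectors::mcols(part_all)$name <-
      rep(c("G1only", "G2only", "GIS"),
          c(length(part$g1_only), length(part$g2_only), length(part$gis)))
    write_regions_bed(part_all, file.path(outdir, "partition.bed"))
    utils::write.table(deg, file.path(outdir, "deg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gene_tbl <- merge(merge(deg, bind_labels, by = "gene_id"),
                      hm_labels, by = "gene_id")
    utils::write.table(gene_tbl, file.path(outdir, "gene_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_report(report, outdir)
  }

  list(report = report,
       truth = list(peaks = truth, loci = loci, motifs = pl$motifs,
                    deg = deg_truth, conserved = conserved, ctcf = ctcf,
                    mg1 = mg1, mg3 = mg3, genes = genes),
       genome = genome, expr = expr,
       peaks = list(GLI1 = pk_g1, GLI2 = pk_g2),
       selected = list(GLI1 = sel_g1, GLI2 = sel_g2),
       partition = part, ctcf = cl, conservation = cons,
       deg = deg, binding_groups = groups, conservation_sets = cons_sets)
}

.flatten_report <- function(x, prefix = character(0)) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x))
      out <- c(out, .flatten_report(x[[nm]], c(prefix, nm)))
    out
  } else {
    stats::setNames(list(x), paste(prefix, collapse = "."))
  }
}

.write_report <- function(report, outdir) {
  flat <- .flatten_report(report)
  df <- data.frame(key = names(flat),
                   value = vapply(flat, function(v)
                     format(v, trim = TRUE, scientific = FALSE, digits = 10),
                     character(1)))
  utils::write.table(df, file.path(outdir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(NULL)
}
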