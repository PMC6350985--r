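#' Generate a synthetic genome with i.i.d. bases
#'
#' Draws independent bases with a given GC content, as a stand-in reference
#' genome for simulation studies. Deterministic under `seed`.
#'
#' @param lengths Named integer vector: chromosome name -> length in bp.
#' @param gc_fraction Genome GC proportion in (0, 1); bounds 0 and 1 give
#'   AT-only / GC-only sequence.
#' @param seed Integer seed.
#' @return An object of class `SyntheticGenome`: a list with `seqs`
#'   (a named [Biostrings::DNAStringSet]) and `seed`.
#' @examples
#' g <- generate_genome(c(chrS = 10000), gc_fraction = 0.41, seed = 1)
#' @export
generate_genome <- function(lengths, gc_fraction = 0.41, seed = 1) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("lengths must be a named vector of chromosome sizes")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must lie in [0, 1]")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- Biostrings::DNAStringSet(vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  }, character(1)))
  names(seqs) <- names(lengths)
  structure(list(seqs = seqs, seed = seed), class = "SyntheticGenome")
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat("SyntheticGenome:", length(x$seqs), "chromosome(s),",
      format(sum(Biostrings::width(x$seqs)), big.mark = ","), "bp, seed", x$seed, "\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `SyntheticGenome` or named `DNAStringSet`.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  s <- .as_dnastringset(genome)
  stats::setNames(Biostrings::width(s), names(s))
}

#' Plant motif instances into a synthetic genome
#'
#' Writes `n` non-overlapping copies of the matrix consensus word into the
#' genome at uniformly sampled positions, on a uniformly chosen strand
#' (reverse-strand instances are written as the reverse complement).
#' Planted instances score 1.0 under [match_score()] by construction. With
#' `scrub = TRUE` (default), coincidental high-scoring instances elsewhere
#' in the genome are overwritten with random bases, so the planted positions
#' are the complete ground truth at `scrub_threshold`.
#'
#' @param genome A `SyntheticGenome`.
#' @param matrix A [WeightMatrix].
#' @param n Number of instances to plant.
#' @param seed Integer seed.
#' @param at Optional data.frame with `chrom`, `position` (1-based start)
#'   and optionally `strand`, fixing the placement of the `n` instances
#'   instead of sampling positions.
#' @param scrub Remove incidental instances scoring above `scrub_threshold`.
#' @param scrub_threshold Strict score threshold used for scrubbing;
#'   default 0.95.
#' @param max_tries Placement attempts before giving up.
#' @return A list with `genome` (modified) and `motifs`, a data.frame of
#'   planted instances (`chrom`, `position` 1-based start, `strand`,
#'   `motif`).
#' @export
plant_motifs <- function(genome, matrix, n, seed = 1, at = NULL, scrub = TRUE,
                         scrub_threshold = 0.95, max_tries = 1000L * max(n, 1L)) {
  stopifnot(inherits(genome, "SyntheticGenome"), inherits(matrix, "WeightMatrix"))
  L <- matrix$length
  lens <- chrom_lengths(genome)
  if (n * L >= sum(lens)) stop("cannot place ", n, " instances: genome too small")
  set.seed(seed)
  word <- consensus_word(matrix)
  rcword <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
  placed <- data.frame(chrom = character(0), position = integer(0),
                       strand = character(0), motif = character(0))
  seqs_chr <- lapply(as.character(genome$seqs), function(s) strsplit(s, "")[[1]])
  names(seqs_chr) <- names(genome$seqs)
  if (!is.null(at)) {
    if (nrow(at) != n) stop("'at' must have exactly n rows")
    if (is.null(at$strand)) at$strand <- sample(c("+", "-"), n, replace = TRUE)
    for (i in seq_len(nrow(at))) {
      chrom <- at$chrom[i]; pos <- as.integer(at$position[i])
      if (pos < 1L || pos + L - 1L > lens[[chrom]])
        stop("fixed placement outside chromosome bounds")
      w <- if (at$strand[i] == "+") word else rcword
      seqs_chr[[chrom]][pos:(pos + L - 1L)] <- strsplit(w, "")[[1]]
    }
    placed <- data.frame(chrom = at$chrom, position = as.integer(at$position),
                         strand = at$strand, motif = matrix$name)
  } else if (n > 0) {
    tries <- 0L
    while (nrow(placed) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " non-overlapping instances after ",
             max_tries, " attempts")
      chrom <- sample(names(lens), 1L, prob = lens)
      pos <- sample.int(lens[[chrom]] - L + 1L, 1L)
      same <- placed[placed$chrom == chrom, , drop = FALSE]
      if (nrow(same) && any(abs(same$position - pos) < L)) next
      strand <- sample(c("+", "-"), 1L)
      w <- if (strand == "+") word else rcword
      seqs_chr[[chrom]][pos:(pos + L - 1L)] <- strsplit(w, "")[[1]]
      placed <- rbind(placed, data.frame(chrom = chrom, position = pos,
                                         strand = strand, motif = matrix$name))
    }
  }
  rebuild <- function() {
    s <- Biostrings::DNAStringSet(vapply(seqs_chr, paste, character(1), collapse = ""))
    names(s) <- names(seqs_chr)
    structure(list(seqs = s, seed = genome$seed), class = "SyntheticGenome")
  }
  g2 <- rebuild()
  if (scrub) {
    for (iter in seq_len(25L)) {
      dirty <- FALSE
      for (chrom in names(lens)) {
        hits <- scan_interval(g2, chrom, 1L, lens[[chrom]], matrix,
                              threshold = scrub_threshold)
        if (length(hits) == 0L) next
        truth <- placed$position[placed$chrom == chrom]
        bad <- hits[!(GenomicRanges::start(hits) %in% truth)]
        if (length(bad) == 0L) next
        dirty <- TRUE
        for (i in seq_along(bad)) {
          st <- GenomicRanges::start(bad)[i]
          span <- st:(st + L - 1L)
          # keep planted bases intact if an incidental hit brushes a true one
          prot <- unlist(lapply(truth, function(p) p:(p + L - 1L)))
          span <- setdiff(span, prot)
          if (length(span))
            seqs_chr[[chrom]][span] <- sample(c("A", "C", "G", "T"),
                                              length(span), replace = TRUE)
        }
      }
      g2 <- rebuild()
      if (!dirty) break
    }
  }
  rownames(placed) <- NULL
  list(genome = g2, motifs = placed)
}

# flat-top triangular bump profile: 1 on [-top, top], linear to 0 at +-half
.bump_profile <- function(dx, frag_len) {
  half <- frag_len / 2
  top <- frag_len / 20
  a <- abs(dx)
  ifelse(a <= top, 1, ifelse(a <= half, (half - a) / (half - top), 0))
}

#' Simulate ChIP-seq style coverage with planted peaks
#'
#' Produces a per-base coverage track as homogeneous Poisson background
#' (rate `noise_rate` reads/bp) plus, for every planted peak, a flat-top
#' triangular bump of total width `frag_len` centred on the peak, with
#' plateau height equal to the planted intensity. The bump emulates the
#' pile-up of sonicated fragments around a binding site; `library_size` is
#' recorded for downstream normalisation.
#'
#' @param genome A `SyntheticGenome` (or named length vector via
#'   [chrom_lengths()] semantics).
#' @param peaks A data.frame with columns `chrom`, `center` (1-based bp),
#'   `intensity` (> 0); may have zero rows.
#' @param library_size Total read count to record.
#' @param frag_len Fragment length in bp (bump width); default 250.
#' @param noise_rate Background Poisson rate in reads per bp.
#' @param seed Integer seed.
#' @return A [CoverageTrack].
#' @export
simulate_chip_coverage <- function(genome, peaks, library_size = 1e6,
                                   frag_len = 250, noise_rate = 0.1, seed = 1) {
  lens <- if (inherits(genome, "SyntheticGenome") ||
              methods::is(genome, "DNAStringSet")) chrom_lengths(genome) else genome
  if (frag_len <= 0) stop("frag_len must be positive")
  if (noise_rate < 0) stop("noise_rate must be non-negative")
  if (nrow(peaks) > 0) {
    stopifnot(all(c("chrom", "center", "intensity") %in% names(peaks)))
    if (any(peaks$intensity <= 0)) stop("planted intensities must be positive")
    if (any(!peaks$chrom %in% names(lens)) ||
        any(peaks$center < 1) || any(peaks$center > lens[peaks$chrom]))
      stop("planted peak centers must lie within chromosome bounds")
  }
  set.seed(seed)
  cov <- lapply(names(lens), function(nm) {
    n <- lens[[nm]]
    v <- if (noise_rate > 0) as.numeric(stats::rpois(n, noise_rate)) else numeric(n)
    pk <- peaks[peaks$chrom == nm, , drop = FALSE]
    half <- ceiling(frag_len / 2)
    if (nrow(pk)) for (i in seq_len(nrow(pk))) {
      lo <- max(1L, as.integer(pk$center[i]) - half)
      hi <- min(n, as.integer(pk$center[i]) + half)
      v[lo:hi] <- v[lo:hi] +
        pk$intensity[i] * .bump_profile((lo:hi) - pk$center[i], frag_len)
    }
    S4Vectors::Rle(v)
  })
  names(cov) <- names(lens)
  CoverageTrack(cov, library_size)
}

#' Simulate a treated/control expression table with planted fold changes
#'
#' Per gene, control replicates are drawn `Normal(baseline, noise_sd)` and
#' treated replicates `Normal(baseline + planted log2FC, noise_sd)`, all on
#' the log2 scale — the shape of a two-group microarray comparison.
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (coordinates 1-based inclusive).
#' @param deg_truth Named numeric vector gene_id -> planted log2 fold
#'   change; genes not named get 0.
#' @param n_per_group Replicates per condition (>= 2).
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param baseline Mean log2 expression of the control group.
#' @param seed Integer seed.
#' @return A data.frame: gene annotation columns followed by
#'   `control_1..n` and `treated_1..n` log2 expression values.
#' @export
simulate_expression <- function(genes, deg_truth = NULL, n_per_group = 4,
                                noise_sd = 0.25, baseline = 8, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  set.seed(seed)
  ng <- nrow(genes)
  fc <- stats::setNames(rep(0, ng), genes$gene_id)
  if (!is.null(deg_truth)) fc[names(deg_truth)] <- deg_truth
  ctrl <- matrix(stats::rnorm(ng * n_per_group, baseline, noise_sd), nrow = ng)
  trt <- matrix(stats::rnorm(ng * n_per_group, baseline + fc, noise_sd), nrow = ng)
  colnames(ctrl) <- paste0("control_", seq_len(n_per_group))
  colnames(trt) <- paste0("treated_", seq_len(n_per_group))
  cbind(genes[, c("gene_id", "chrom", "start", "end", "strand")], ctrl, trt)
}

#' Generate a region set with a controlled co-occupancy fraction
#'
#' Produces `n` intervals of which a planted fraction lies within `d` bp
#' (edge gap) of a reference set, and the rest lie strictly farther than `d`
#' from every reference interval — the controlled input for co-occupancy
#' and conservation set algebra. Optionally attaches Normal-distributed
#' intensity scores (the shape of array signal intensities).
#'
#' @param reference `GRanges` of reference intervals.
#' @param n Number of intervals to generate.
#' @param cooccupancy_fraction Proportion in \[0, 1\] planted near the
#'   reference; the planted count is `round(n * fraction)`.
#' @param lengths Named chromosome length vector bounding the placements.
#' @param d Proximity distance in bp (edge gap); default 250.
#' @param width_range Interval widths are drawn uniformly from this range.
#' @param intensity_mean,intensity_sd If non-`NULL`, draw an `intensity`
#'   metadata column from `Normal(intensity_mean, intensity_sd)`.
#' @param label Value for the `label` metadata column.
#' @param seed Integer seed.
#' @return A `GRanges` with metadata columns `truth_near` (logical planted
#'   proximity flag), `label`, and optionally `intensity`.
#' @export
generate_region_sets <- function(reference, n, cooccupancy_fraction,
                                 lengths, d = 250, width_range = c(100, 400),
                                 intensity_mean = NULL, intensity_sd = NULL,
                                 label = "set", seed = 1) {
  if (cooccupancy_fraction < 0 || cooccupancy_fraction > 1)
    stop("cooccupancy_fraction must lie in [0, 1]")
  set.seed(seed)
  n_near <- round(n * cooccupancy_fraction)
  n_far <- n - n_near
  ref <- reference
  mk_near <- function() {
    i <- sample.int(length(ref), 1L)
    chrom <- as.character(GenomicRanges::seqnames(ref)[i])
    w <- sample(width_range[1]:width_range[2], 1L)
    # start anywhere that leaves an edge gap <= d (overlap allowed)
    lo <- GenomicRanges::start(ref)[i] - d - w
    hi <- GenomicRanges::end(ref)[i] + d
    st <- sample(max(1L, lo):min(lengths[[chrom]] - w + 1L, hi), 1L)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(st, width = w))
  }
  mk_far <- function() {
    for (try in seq_len(10000L)) {
      chrom <- sample(names(lengths), 1L, prob = lengths)
      w <- sample(width_range[1]:width_range[2], 1L)
      st <- sample.int(lengths[[chrom]] - w + 1L, 1L)
      g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, width = w))
      if (length(ref) == 0L || !IRanges::overlapsAny(g, ref, maxgap = d))
        return(g)
    }
    stop("could not place an interval farther than ", d, " bp from the reference")
  }
  near <- if (n_near > 0) do.call(c, replicate(n_near, mk_near())) else
    GenomicRanges::GRanges()
  far <- if (n_far > 0) do.call(c, replicate(n_far, mk_far())) else
    GenomicRanges::GRanges()
  out <- c(near, far)
  S4Vectors::mcols(out)$truth_near <- rep(c(TRUE, FALSE), c(n_near, n_far))
  S4Vectors::mcols(out)$label <- rep(label, n)
  if (!is.null(intensity_mean))
    S4Vectors::mcols(out)$intensity <- stats::rnorm(n, intensity_mean, intensity_sd)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
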