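#' Coverage track container
#'
#' A `CoverageTrack` holds per-base signal over a genome as a run-length
#' encoded list (one numeric [S4Vectors::Rle] per chromosome) together with
#' the sequencing library size used for depth normalisation.
#'
#' @param cov A named list of numeric vectors or `Rle` objects (one per
#'   chromosome), or an `RleList`.
#' @param library_size Total number of reads in the library; must be positive.
#' @return An object of class `CoverageTrack` with elements `cov`
#'   (a `SimpleRleList`) and `library_size`.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(0, 0, 5, 5, 0)), library_size = 1e6)
#' @export
CoverageTrack <- function(cov, library_size) {
  if (is.list(cov) && !methods::is(cov, "List")) {
    cov <- IRanges::RleList(lapply(cov, function(v) {
      if (!methods::is(v, "Rle")) v <- S4Vectors::Rle(as.numeric(v))
      v
    }), compress = FALSE)
  }
  if (is.null(names(cov)) || anyDuplicated(names(cov)))
    stop("coverage list must have unique chromosome names")
  library_size <- as.numeric(library_size)
  if (length(library_size) != 1L || !is.finite(library_size) || library_size <= 0)
    stop("library_size must be a single positive number")
  if (any(vapply(cov, function(v) any(S4Vectors::runValue(v) < 0), logical(1))))
    stop("coverage values must be non-negative")
  structure(list(cov = cov, library_size = library_size), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$cov), "chromosome(s),",
      "library size", format(x$library_size, big.mark = ","), "\n")
  for (nm in names(x$cov))
    cat("  ", nm, ": ", length(x$cov[[nm]]), " bp, max ",
        signif(max(as.numeric(S4Vectors::runValue(x$cov[[nm]])), 0), 4), "\n", sep = "")
  invisible(x)
}

#' Library-size normalisation of a coverage track
#'
#' Rescales every per-base value to counts per million mapped reads:
#' each value is multiplied by `1e6 / library_size`. The library size is kept
#' as metadata so the scaling law `normalize(k reads)/k = normalize(reads)`
#' is recoverable.
#'
#' @param track A [CoverageTrack].
#' @return A [CoverageTrack] with rescaled values and the original
#'   `library_size` retained.
#' @export
normalize_coverage <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$library_size <= 0) stop("library_size must be positive")
  f <- 1e6 / track$library_size
  out <- IRanges::RleList(lapply(track$cov, function(v) v * f), compress = FALSE)
  structure(list(cov = out, library_size = track$library_size),
            class = "CoverageTrack")
}

#' Subtract a control (IgG) track from a transcription-factor track
#'
#' Computes per-base `max(0, tf - control)`. Both tracks should already be
#' library-size normalised. Positions present in one track beyond the end of
#' the other are treated as zero in the shorter track; chromosome name sets
#' must be identical.
#'
#' @param tf,control [CoverageTrack] objects on the same genome.
#' @return A [CoverageTrack] with the subtracted signal and the `tf`
#'   library size.
#' @export
subtract_control <- function(tf, control) {
  stopifnot(inherits(tf, "CoverageTrack"), inherits(control, "CoverageTrack"))
  if (!setequal(names(tf$cov), names(control$cov)))
    stop("tf and control tracks cover different chromosomes")
  out <- lapply(names(tf$cov), function(nm) {
    a <- tf$cov[[nm]]
    b <- control$cov[[nm]]
    n <- max(length(a), length(b))
    if (length(a) < n) a <- c(a, S4Vectors::Rle(0, n - length(a)))
    if (length(b) < n) b <- c(b, S4Vectors::Rle(0, n - length(b)))
    d <- a - b
    d * (d > 0)            # floor at zero
  })
  names(out) <- names(tf$cov)
  structure(list(cov = IRanges::RleList(out, compress = FALSE),
                 library_size = tf$library_size),
            class = "CoverageTrack")
}

#' Enrichment-region detection with bandwidth merging
#'
#' Calls enrichment regions on a normalised, control-subtracted track as
#' maximal runs of positions whose value exceeds a background threshold.
#' Isolated runs narrower than `min_run` bp are pruned first (single-base
#' noise excursions would otherwise chain distant regions together during
#' merging), runs closer than `bandwidth` bp are then merged (the bandwidth
#' mirrors the size of sonicated chromatin fragments), regions narrower
#' than `min_width` bp are discarded, and the summit of each region is the
#' leftmost position attaining the region maximum.
#'
#' @param track A [CoverageTrack], normalised and control-subtracted.
#' @param bandwidth Merge radius in bp; runs separated by a gap smaller than
#'   this are fused into one region. Default 250.
#' @param background Either a numeric threshold or `"auto"`, which uses the
#'   genome-wide mean of the non-zero values.
#' @param min_width Minimum region width in bp (default 50); narrower
#'   merged regions are discarded.
#' @param min_run Minimum raw run width in bp (default 5); narrower runs
#'   are treated as noise and removed before merging.
#' @param fraction Label stored on each peak (e.g. `"GLI1"`).
#' @return A [GenomicRanges::GRanges] of peaks with metadata columns
#'   `summit` (1-based genomic position), `intensity` (signal at the summit)
#'   and `fraction`.
#' @export
detect_enriched_regions <- function(track, bandwidth = 250, background = "auto",
                                    min_width = 50, min_run = 5,
                                    fraction = NA_character_) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (identical(background, "auto")) {
    tot <- 0; npos <- 0
    for (nm in names(track$cov)) {
      v <- track$cov[[nm]]
      rv <- as.numeric(S4Vectors::runValue(v)); rl <- S4Vectors::runLength(v)
      pos <- rv > 0
      tot <- tot + sum(rv[pos] * rl[pos]); npos <- npos + sum(rl[pos])
    }
    background <- if (npos > 0) tot / npos else 0
  }
  background <- as.numeric(background)
  res <- lapply(names(track$cov), function(nm) {
    v <- track$cov[[nm]]
    ir <- IRanges::ranges(IRanges::slice(v, lower = background, includeLower = FALSE))
    ir <- ir[IRanges::width(ir) >= min_run]
    if (length(ir) == 0L) return(GenomicRanges::GRanges())
    ir <- IRanges::reduce(ir, min.gapwidth = bandwidth)
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir) == 0L) return(GenomicRanges::GRanges())
    summit <- integer(length(ir)); intensity <- numeric(length(ir))
    for (i in seq_along(ir)) {
      w <- as.numeric(S4Vectors::window(v, IRanges::start(ir)[i], IRanges::end(ir)[i]))
      k <- which.max(w)                      # leftmost maximum
      summit[i] <- IRanges::start(ir)[i] + k - 1L
      intensity[i] <- w[k]
    }
    GenomicRanges::GRanges(nm, ir, summit = summit, intensity = intensity,
                           fraction = fraction)
  })
  out <- suppressWarnings(do.call(c, res))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Mean-plus-one-SD intensity filter
#'
#' Retains peaks whose summit intensity exceeds the mean plus one (sample)
#' standard deviation of the intensities of the input set, the first of the
#' three peak-selection criteria.
#'
#' @param peaks A `GRanges` of peaks with an `intensity` metadata column.
#' @return A list with elements `kept` (the retained peaks), `mean` and `sd`
#'   (the statistics the threshold was computed from).
#' @export
intensity_filter <- function(peaks) {
  intens <- S4Vectors::mcols(peaks)$intensity
  if (is.null(intens)) stop("peaks must carry an 'intensity' metadata column")
  if (length(intens) < 2L)
    stop("at least 2 peaks are required to estimate mean and SD")
  m <- mean(intens); s <- stats::sd(intens)
  list(kept = peaks[intens > m + s], mean = m, sd = s)
}

#' Three-criteria peak selection
#'
#' A peak is selected if it satisfies at least one of: (a) intensity greater
#' than the mean plus one standard deviation of its fraction's peak
#' intensities; (b) overlap (at least 1 bp) with an evolutionarily conserved
#' element; (c) lying within `distance` bp (edge gap; overlap counts as
#' distance zero) of a peak called in the other transcription-factor
#' fraction. Selection reasons are recorded per peak.
#'
#' @param peaks `GRanges` of peaks for one fraction (with `intensity`).
#' @param conserved `GRanges` of conserved elements.
#' @param other_fraction `GRanges` of peaks from the other fraction.
#' @param distance Co-occupancy distance in bp; default 250.
#' @return The selected subset of `peaks`, with a `selection_reasons`
#'   metadata column holding strings over \{"a","b","c"\}.
#' @export
select_peaks <- function(peaks, conserved, other_fraction, distance = 250) {
  if (length(peaks) == 0L) return(peaks)
  a <- if (length(peaks) >= 2L) {
    st <- intensity_filter(peaks)
    S4Vectors::mcols(peaks)$intensity > st$mean + st$sd
  } else rep(FALSE, length(peaks))
  b <- IRanges::overlapsAny(peaks, conserved)
  cc <- IRanges::overlapsAny(peaks, other_fraction, maxgap = distance)
  keep <- a | b | cc
  reasons <- vapply(seq_along(peaks), function(i)
    paste(c("a", "b", "c")[c(a[i], b[i], cc[i])], collapse = ""), character(1))
  out <- peaks[keep]
  S4Vectors::mcols(out)$selection_reasons <- reasons[keep]
  out
}
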