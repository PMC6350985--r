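#' Position frequency matrix with MATCH information vector
#'
#' A `WeightMatrix` stores per-position base frequencies `f(i, b)` for
#' `b` in \{A,C,G,T\} together with the information vector
#' `I(i) = sum_b f(i,b) * ln(4 f(i,b))` (with `0 * ln 0 := 0`), the weights
#' used by the MATCH matrix-similarity score.
#'
#' @param freqs A 4 x L numeric matrix with rownames `A,C,G,T`; each column
#'   must sum to 1 (tolerance 1e-9).
#' @param name Identifier for the motif.
#' @return An object of class `WeightMatrix` with elements `name`, `freqs`,
#'   `length`, `information`, and cached per-position minima/maxima.
#' @export
WeightMatrix <- function(freqs, name = "motif") {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L) stop("freqs must have 4 rows (A, C, G, T)")
  rownames(freqs) <- c("A", "C", "G", "T")
  if (any(freqs < 0)) stop("frequencies must be non-negative")
  if (any(abs(colSums(freqs) - 1) > 1e-9))
    stop("each position's frequencies must sum to 1")
  info <- apply(freqs, 2, function(f) {
    t <- ifelse(f > 0, f * log(4 * f), 0)
    sum(t)
  })
  structure(list(name = name, freqs = freqs, length = ncol(freqs),
                 information = info,
                 col_min = apply(freqs, 2, min),
                 col_max = apply(freqs, 2, max)),
            class = "WeightMatrix")
}

#' @export
print.WeightMatrix <- function(x, ...) {
  cat("WeightMatrix '", x$name, "' (", x$length, " positions), consensus ",
      consensus_word(x), "\n", sep = "")
  invisible(x)
}

# IUPAC nucleotide ambiguity codes
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Build a frequency matrix from an IUPAC consensus string
#'
#' Each consensus position allowing `k` bases assigns frequency `1/k` to
#' each allowed base and 0 to the rest; e.g. `M` gives `f(A)=f(C)=0.5` and
#' `N` a zero-information uniform column.
#'
#' @param consensus A string over the IUPAC nucleotide alphabet.
#' @param name Motif identifier; defaults to the consensus string.
#' @return A [WeightMatrix].
#' @examples
#' wm <- matrix_from_iupac("GACCACCCA", name = "GLI")
#' @export
matrix_from_iupac <- function(consensus, name = consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  if (length(codes) == 0L) stop("empty consensus")
  bad <- setdiff(codes, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  freqs <- vapply(codes, function(cd) {
    f <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
    f[.IUPAC[[cd]]] <- 1 / length(.IUPAC[[cd]])
    f
  }, numeric(4))
  WeightMatrix(freqs, name = name)
}

#' Consensus word of a weight matrix
#'
#' The highest-frequency base at each position; ties broken in A,C,G,T order.
#'
#' @param matrix A [WeightMatrix].
#' @return A character scalar of length `matrix$length`.
#' @export
consensus_word <- function(matrix) {
  paste(rownames(matrix$freqs)[apply(matrix$freqs, 2, which.max)], collapse = "")
}

#' MATCH matrix-similarity score of a DNA window
#'
#' Computes `MSS = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, base_i)`, and `Min`/`Max` substitute the
#' per-position minimal/maximal frequencies. The score lies in \[0, 1\]: 1
#' exactly when every position carries a maximal-frequency base, 0 when
#' every position carries a minimal-frequency base. Windows containing
#' non-ACGT characters score `NA` (skipped by the scanners).
#'
#' @param matrix A [WeightMatrix].
#' @param window A DNA string of exactly `matrix$length` characters.
#' @return A score in \[0, 1\], or `NA` for ambiguous windows.
#' @export
match_score <- function(matrix, window) {
  stopifnot(inherits(matrix, "WeightMatrix"))
  b <- strsplit(toupper(as.character(window)), "")[[1]]
  if (length(b) != matrix$length)
    stop("window length (", length(b), ") != matrix length (", matrix$length, ")")
  idx <- match(b, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  I <- matrix$information
  cur <- sum(I * matrix$freqs[cbind(idx, seq_len(matrix$length))])
  mn <- sum(I * matrix$col_min)
  mx <- sum(I * matrix$col_max)
  if (mx == mn) return(1)   # zero-information matrix: every window is maximal
  (cur - mn) / (mx - mn)
}

# Vectorised MSS over all windows of an encoded sequence (1=A..4=T, NA = other).
# Returns one score per offset; windows containing NA bases score NA.
.scan_scores <- function(idx, matrix) {
  L <- matrix$length
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  I <- matrix$information
  weighted <- sweep(matrix$freqs, 2, I, `*`)        # 4 x L: I(i) * f(i, b)
  cur <- numeric(n)
  nas <- logical(n)
  for (j in seq_len(L)) {
    bj <- idx[j:(j + n - 1L)]
    isna <- is.na(bj)
    nas <- nas | isna
    bj[isna] <- 1L
    cur <- cur + weighted[bj, j]
  }
  mn <- sum(I * matrix$col_min)
  mx <- sum(I * matrix$col_max)
  sc <- if (mx == mn) rep(1, n) else (cur - mn) / (mx - mn)
  sc[nas] <- NA_real_
  sc
}

.encode_dna <- function(seq_chr) {
  match(strsplit(toupper(seq_chr), "")[[1]], c("A", "C", "G", "T"))
}

#' Scan a genomic interval for motif matches on both strands
#'
#' Every offset of the interval is scored with [match_score()] on the forward
#' sequence and on its reverse complement; hits above `threshold` (strict)
#' are returned sorted by position. Intervals extending past chromosome ends
#' are clipped with a warning.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or object coercible to
#'   one) holding the chromosome sequences.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @param matrix A [WeightMatrix].
#' @param threshold Minimum score, exclusive; default 0.65 (the "match score
#'   > 65%" rule).
#' @return A `GRanges` of hits (width = motif length) with metadata columns
#'   `score`, `motif`; strand records which orientation matched.
#' @export
scan_interval <- function(genome, chrom, start, end, matrix, threshold = 0.65) {
  genome <- .as_dnastringset(genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  clen <- Biostrings::width(genome[chrom])
  if (start < 1L || end > clen) {
    warning("interval clipped to chromosome bounds")
    start <- max(1L, start); end <- min(clen, end)
  }
  if (end - start + 1L < matrix$length)
    return(.empty_hits())
  sq <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  idx_f <- .encode_dna(sq)
  sc_f <- .scan_scores(idx_f, matrix)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  sc_r <- .scan_scores(.encode_dna(rc), matrix)
  L <- matrix$length
  n <- length(sc_f)
  hit_f <- which(!is.na(sc_f) & sc_f > threshold)
  hit_r <- which(!is.na(sc_r) & sc_r > threshold)
  # reverse-strand offset o (1-based in rc) covers forward positions
  # (n - o + 1) .. (n - o + L) of the window
  pos_f <- start + hit_f - 1L
  pos_r <- start + (n - hit_r + 1L) - 1L
  gr <- GenomicRanges::GRanges(
    rep(chrom, length(hit_f) + length(hit_r)),
    IRanges::IRanges(c(pos_f, pos_r), width = L),
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(sc_f[hit_f], sc_r[hit_r]),
    motif = rep(matrix$name, length(hit_f) + length(hit_r)))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

.empty_hits <- function() {
  GenomicRanges::GRanges(score = numeric(0), motif = character(0))
}

.as_dnastringset <- function(genome) {
  if (inherits(genome, "SyntheticGenome")) return(genome$seqs)
  if (methods::is(genome, "DNAStringSet")) return(genome)
  Biostrings::DNAStringSet(genome)
}

#' Motif presence around peak summits
#'
#' For each peak, scans the window `[summit - flank, summit + flank)` for
#' motif hits and reports the fraction of peaks with at least one hit
#' above `threshold` — the per-peak-set motif-presence statistic.
#'
#' @param peaks `GRanges` with a `summit` metadata column (1-based).
#' @param genome Chromosome sequences (see [scan_interval()]).
#' @param matrix A [WeightMatrix].
#' @param flank Half-window in bp around the summit; default 250.
#' @param threshold Score threshold (strict); default 0.65.
#' @return A list with `fraction` (peaks with >= 1 hit / total) and
#'   `has_motif` (logical per peak).
#' @export
motif_presence <- function(peaks, genome, matrix, flank = 250, threshold = 0.65) {
  if (length(peaks) == 0L) stop("motif presence is undefined for an empty peak set")
  summit <- S4Vectors::mcols(peaks)$summit
  if (is.null(summit)) stop("peaks must carry a 'summit' metadata column")
  genome <- .as_dnastringset(genome)
  has <- vapply(seq_along(peaks), function(i) {
    hits <- suppressWarnings(scan_interval(
      genome, as.character(GenomicRanges::seqnames(peaks)[i]),
      summit[i] - flank, summit[i] + flank - 1L, matrix, threshold))
    length(hits) > 0L
  }, logical(1))
  list(fraction = mean(has), has_motif = has)
}
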