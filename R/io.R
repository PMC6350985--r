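#' Write / read a genome as FASTA
#'
#' @param genome A `SyntheticGenome` or named `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns a `SyntheticGenome` (seed `NA`).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(.as_dnastringset(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  structure(list(seqs = s, seed = NA_integer_), class = "SyntheticGenome")
}

#' Write / read a coverage track as bedGraph
#'
#' bedGraph uses 0-based half-open intervals; the run-length encoded track
#' is emitted as one line per run with non-zero runs only, and read back
#' into per-base `Rle` form. The library size is not part of the format and
#' must be supplied on read.
#'
#' @param track A [CoverageTrack].
#' @param path bedGraph file path.
#' @param lengths Named chromosome lengths (used on read to restore
#'   trailing zero runs).
#' @param library_size Library size to attach on read.
#' @return `write_coverage_bedgraph` returns `path` invisibly;
#'   `read_coverage_bedgraph` returns a [CoverageTrack].
#' @export
write_coverage_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track$cov)) {
    v <- track$cov[[nm]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- c(0L, ends[-length(ends)])          # 0-based
    vals <- as.numeric(S4Vectors::runValue(v))
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", nm, starts[keep], ends[keep],
                       format(vals[keep], trim = TRUE, scientific = FALSE,
                              digits = 15)), con)
  }
  invisible(path)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path, lengths, library_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- lapply(names(lengths), function(nm) {
    v <- numeric(lengths[[nm]])
    sub <- gr[GenomicRanges::seqnames(gr) == nm]
    if (length(sub))
      for (i in seq_along(sub))
        v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
          S4Vectors::mcols(sub)$score[i]
    S4Vectors::Rle(v)
  })
  names(cov) <- names(lengths)
  CoverageTrack(cov, library_size)
}

#' Write / read a region set as BED6 (plus optional extra columns)
#'
#' Emits 0-based half-open BED with `name` from a metadata column (or the
#' set label), `score` carrying the float-formatted intensity where
#' present, and any further metadata columns appended after the strand
#' (BED6+N). The reader restores 1-based `GRanges` with the same metadata.
#'
#' @param regions A `GRanges`; optional metadata columns `name`,
#'   `intensity`, `summit` and others.
#' @param path BED file path.
#' @param extra_cols Character vector of metadata columns to append after
#'   column 6 (written and read back in order).
#' @return `write_regions_bed` returns `path` invisibly;
#'   `read_regions_bed` returns a `GRanges`.
#' @export
write_regions_bed <- function(regions, path, extra_cols = character(0)) {
  mc <- S4Vectors::mcols(regions)
  nm <- if (!is.null(mc$name)) as.character(mc$name)
        else if (!is.null(mc$label)) as.character(mc$label)
        else if (!is.null(mc$fraction)) as.character(mc$fraction)
        else rep(".", length(regions))
  sc <- if (!is.null(mc$intensity)) format(mc$intensity, trim = TRUE,
                                           scientific = FALSE, digits = 15)
        else if (!is.null(mc$score)) format(mc$score, trim = TRUE,
                                            scientific = FALSE, digits = 15)
        else rep("0", length(regions))
  str <- as.character(GenomicRanges::strand(regions))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   name = nm, score = sc, strand = str,
                   stringsAsFactors = FALSE)
  for (cc in extra_cols) df[[cc]] <- mc[[cc]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path, extra_cols = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", extra_cols),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         rep(NA, length(extra_cols))))
  str <- df$strand
  str[str == "."] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = str)
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$intensity <- df$score
  for (cc in extra_cols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
  gr
}

#' Write / read an expression table as TSV
#' @param expr Expression data.frame (see [simulate_expression()]).
#' @param path TSV path.
#' @return Invisible `path` / the data.frame.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
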