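# Independent brute-force oracles used to cross-check the sweep/overlap
# implementations. Everything here is written naively (O(n^2), per-element
# formulas) and never calls the code paths it is checking.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# Pairwise edge-gap matrix between two GRanges (Inf across chromosomes;
# 0 when the intervals overlap or touch).
oracle_gap_matrix <- function(a, b) {
  s1 <- start(a); e1 <- end(a); s2 <- start(b); e2 <- end(b)
  g <- pmax(outer(s1, e2, "-") - 1, t(outer(s2, e1, "-") - 1), 0)
  diffchrom <- outer(as.character(seqnames(a)), as.character(seqnames(b)), "!=")
  g[diffchrom] <- Inf
  g
}

oracle_within <- function(a, b, d) {
  if (length(b) == 0L) return(rep(FALSE, length(a)))
  apply(oracle_gap_matrix(a, b) <= d, 1, any)
}

# Strict >= 1 bp intersection (adjacency does not count).
oracle_overlap <- function(a, b) {
  if (length(b) == 0L) return(rep(FALSE, length(a)))
  ok <- outer(start(a), start(b), pmax) <= outer(end(a), end(b), pmin)
  samechrom <- outer(as.character(seqnames(a)), as.character(seqnames(b)), "==")
  apply(ok & samechrom, 1, any)
}

# Single-linkage components over the union of two peak sets at edge gap <= d,
# via an explicit union-find; returns per-peak component ids and per-peak
# class ("g1_only" / "g2_only" / "gis").
oracle_classify <- function(g1, g2, d) {
  both <- c(granges(g1), granges(g2))
  src <- rep(c("g1", "g2"), c(length(g1), length(g2)))
  n <- length(both)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    g <- oracle_gap_matrix(both, both)
    idx <- which(g <= d & upper.tri(g), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- find(idx[r, 1]); b <- find(idx[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  has1 <- tapply(src == "g1", comp, any)
  has2 <- tapply(src == "g2", comp, any)
  gis_comp <- as.integer(names(has1))[has1 & has2]
  cls <- ifelse(comp %in% gis_comp, "gis",
                ifelse(src == "g1", "g1_only", "g2_only"))
  list(comp = comp, class = cls, src = src,
       n_gis = length(gis_comp),
       n_g1_only = sum(cls == "g1_only"),
       n_g2_only = sum(cls == "g2_only"))
}

# Naive MATCH matrix-similarity score of a single window (character vector
# of bases), computed position by position from the defining formula.
oracle_mss <- function(freqs, window) {
  L <- ncol(freqs)
  info <- numeric(L); cur <- 0; mn <- 0; mx <- 0
  for (i in seq_len(L)) {
    I <- 0
    for (b in 1:4) if (freqs[b, i] > 0) I <- I + freqs[b, i] * log(4 * freqs[b, i])
    bi <- match(window[i], c("A", "C", "G", "T"))
    cur <- cur + I * freqs[bi, i]
    mn <- mn + I * min(freqs[, i])
    mx <- mx + I * max(freqs[, i])
  }
  if (mx == mn) return(1)
  (cur - mn) / (mx - mn)
}

# All DNA words of length L in a fixed order.
all_words <- function(L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                              stringsAsFactors = FALSE))
}

# Welch two-sample test recomputed from the closed-form statistic.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

# Uniform random region set for oracle comparisons.
random_regions <- function(n, lengths = c(chrA = 200000L, chrB = 150000L),
                           wmax = 500L) {
  chrom <- sample(names(lengths), n, replace = TRUE)
  w <- sample.int(wmax, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i)
    sample.int(lengths[[chrom[i]]] - w[i], 1L), integer(1))
  GRanges(chrom, IRanges(st, width = w))
}

# Copy of the 7-subset letter order used for DEG binding groups, kept here
# so group assignments can be recomputed without touching package internals.
oracle_group_letter <- function(g1, g2, gis) {
  key <- paste0(as.integer(g1), as.integer(g2), as.integer(gis))
  c(`100` = "a", `010` = "b", `110` = "c", `001` = "d",
    `101` = "e", `011` = "f", `111` = "g")[key]
}
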