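#' Call differentially expressed genes from a two-group table
#'
#' Per gene, runs a Welch two-sample t-test on the log2 expression values of
#' the treated vs control replicate columns. A gene is `up` when its mean
#' log2 fold change is at least `log2(fc_threshold)` with `p < alpha`,
#' `down` for the symmetric condition, `none` otherwise.
#'
#' @param expr A data.frame as produced by [simulate_expression()]:
#'   annotation columns plus `control_*` and `treated_*` log2 columns.
#' @param fc_threshold Fold-change threshold (linear scale); default 1.5.
#' @param alpha Significance level; default 0.05.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   default `"none"`.
#' @return A data.frame of gene records: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `log2fc`, `p_value`, `deg_status`.
#' @export
call_deg <- function(expr, fc_threshold = 1.5, alpha = 0.05, adjust = "none") {
  ctrl_cols <- grep("^control_", names(expr), value = TRUE)
  trt_cols <- grep("^treated_", names(expr), value = TRUE)
  if (length(ctrl_cols) < 2L || length(trt_cols) < 2L)
    stop("at least 2 replicates per group are required")
  ctrl <- as.matrix(expr[, ctrl_cols, drop = FALSE])
  trt <- as.matrix(expr[, trt_cols, drop = FALSE])
  log2fc <- rowMeans(trt) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- trt[i, ]; y <- ctrl[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  lfc_cut <- log2(fc_threshold)
  status <- ifelse(log2fc >= lfc_cut & p < alpha, "up",
                   ifelse(log2fc <= -lfc_cut & p < alpha, "down", "none"))
  data.frame(gene_id = expr$gene_id, chrom = expr$chrom, start = expr$start,
             end = expr$end, strand = expr$strand,
             log2fc = log2fc, p_value = p, deg_status = status,
             stringsAsFactors = FALSE)
}

#' Gene regulatory neighbourhoods
#'
#' For each gene, the neighbourhood spans from the end of the nearest
#' upstream gene body to the start of the nearest downstream gene body
#' (in chromosome coordinates, irrespective of strand), always containing
#' the gene's own body, clipped to the chromosome. With
#' `neighbors_per_side = 2` the span reaches to the second gene on each
#' side.
#'
#' @param genes A data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @param lengths Named chromosome length vector.
#' @param neighbors_per_side How many flanking genes bound the span
#'   (1 or 2); default 1.
#' @return A `GRanges` of neighbourhood spans, one per gene, with
#'   `gene_id` metadata.
#' @export
build_neighborhoods <- function(genes, lengths, neighbors_per_side = 1) {
  k <- as.integer(neighbors_per_side)
  if (k < 1L) stop("neighbors_per_side must be >= 1")
  parts <- lapply(split(genes, genes$chrom), function(gg) {
    gg <- gg[order(gg$start, gg$end), , drop = FALSE]
    n <- nrow(gg)
    clen <- lengths[[gg$chrom[1]]]
    lo <- integer(n); hi <- integer(n)
    for (i in seq_len(n)) {
      up <- i - k; dn <- i + k
      lo[i] <- if (up >= 1L) gg$end[up] + 1L else 1L
      hi[i] <- if (dn <= n) gg$start[dn] - 1L else clen
      lo[i] <- min(lo[i], gg$start[i])   # span always contains the body
      hi[i] <- max(hi[i], gg$end[i])
      lo[i] <- max(1L, lo[i]); hi[i] <- min(clen, hi[i])
    }
    GenomicRanges::GRanges(gg$chrom[1], IRanges::IRanges(lo, hi),
                           gene_id = gg$gene_id)
  })
  out <- suppressWarnings(do.call(c, unname(parts)))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Assign binding-region classes to genes via their neighbourhoods
#'
#' A gene carries a class label (e.g. `G1`, `G2`, `GIS`) when at least one
#' region of that class intersects its neighbourhood by at least 1 bp.
#' Because neighbouring genes share their intergenic span, an intergenic
#' region may label both flanking genes.
#'
#' @param regions A named list of `GRanges`, one element per class label
#'   (e.g. `list(G1 = ..., G2 = ..., GIS = ...)`).
#' @param neighborhoods Output of [build_neighborhoods()].
#' @return A data.frame with `gene_id` and one logical column per class.
#' @export
assign_regions <- function(regions, neighborhoods) {
  out <- data.frame(gene_id = S4Vectors::mcols(neighborhoods)$gene_id,
                    stringsAsFactors = FALSE)
  for (lab in names(regions))
    out[[lab]] <- IRanges::overlapsAny(neighborhoods, regions[[lab]],
                                       ignore.strand = TRUE)
  out
}

# Fixed letter order for the 7 nonempty subsets of {G1, G2, GIS}:
# vectors ordered as binary numbers (GIS, G2, G1).
.binding_group_letters <- c(`100` = "a", `010` = "b", `110` = "c",
                            `001` = "d", `101` = "e", `011` = "f",
                            `111` = "g")

#' Seven-group classification of DEGs by GLI binding
#'
#' Differentially expressed genes carrying at least one binding-class label
#' are partitioned into the 7 nonempty subsets of \{G1, G2, GIS\}, lettered
#' a-g in a fixed documented order (a = G1 only, b = G2 only, c = G1+G2,
#' d = GIS only, e = G1+GIS, f = G2+GIS, g = all three).
#'
#' @param deg Gene records from [call_deg()].
#' @param labels Output of [assign_regions()] with columns `G1`, `G2`,
#'   `GIS`.
#' @return A data.frame of the labelled DEGs with a `group` column, plus
#'   attribute `counts` (named group sizes over a-g).
#' @export
bin_deg_by_binding <- function(deg, labels) {
  m <- merge(deg, labels, by = "gene_id")
  m <- m[m$deg_status != "none" & (m$G1 | m$G2 | m$GIS), , drop = FALSE]
  key <- paste0(as.integer(m$G1), as.integer(m$G2), as.integer(m$GIS))
  m$group <- unname(.binding_group_letters[key])
  m <- m[order(m$group, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  counts <- table(factor(m$group, levels = letters[1:7]))
  attr(m, "counts") <- stats::setNames(as.integer(counts), names(counts))
  m
}

# Conservation set letters over (hG1|hG2 human flag, mG1, mG3):
# a' = mG1 + human, b' = mG1 only, c' = mG3 only, d' = mG3 + human,
# e' = human only, f' = both mouse without human, g' = both mouse + human.
.conservation_set <- function(human, mG1, mG3) {
  ifelse(mG1 & mG3, ifelse(human, "g'", "f'"),
  ifelse(mG1, ifelse(human, "a'", "b'"),
  ifelse(mG3, ifelse(human, "d'", "c'"),
  ifelse(human, "e'", NA_character_))))
}

#' Conservation-set classification of DEGs
#'
#' Classifies differentially expressed genes by the species origin of the
#' conserved binding regions in their neighbourhood: mouse-only sets
#' (b' = mouse Gli1, c' = mouse Gli3, f' = both mouse factors),
#' human-only (e'), and human-mouse common-target sets (a', d', g').
#' A gene with mouse Gli3 plus human GLI1/GLI2 binding, for example,
#' falls in set d'. The sets are disjoint and exhaustive over genes with
#' at least one flag.
#'
#' @param deg Gene records from [call_deg()].
#' @param human_labels data.frame from [assign_regions()] with logical
#'   columns `hG1`, `hG2` (plus `gene_id`).
#' @param mouse_labels data.frame with logical columns `mG1`, `mG3`.
#' @return A data.frame of classified DEGs with a `conserved_set` column
#'   and attribute `counts`.
#' @export
bin_deg_by_conservation <- function(deg, human_labels, mouse_labels) {
  m <- merge(merge(deg, human_labels, by = "gene_id"), mouse_labels,
             by = "gene_id")
  m <- m[m$deg_status != "none", , drop = FALSE]
  m$conserved_set <- .conservation_set(m$hG1 | m$hG2, m$mG1, m$mG3)
  m <- m[!is.na(m$conserved_set), , drop = FALSE]
  m <- m[order(m$conserved_set, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  lev <- paste0(letters[1:7], "'")
  counts <- table(factor(m$conserved_set, levels = lev))
  attr(m, "counts") <- stats::setNames(as.integer(counts), names(counts))
  m
}

#' Delta-delta-Ct fold change from a qPCR cycle-threshold table
#'
#' Implements the comparative threshold-cycle method: per sample and target
#' gene, `dCt = Ct(target) - mean Ct(endogenous controls)`;
#' `ddCt = dCt - mean dCt over carrier samples`; fold change `2^(-ddCt)`,
#' expressed relative to the carrier mean.
#'
#' @param ct A data.frame with columns `sample`, `condition` (values
#'   `"treated"` / `"carrier"`), `gene`, `ct` (positive finite cycles).
#' @param controls Character vector of endogenous control gene names
#'   (e.g. `c("ACTB", "GAPDH")`).
#' @return A data.frame with `sample`, `condition`, `gene`, `dct`, `ddct`,
#'   `fold_change`, one row per sample x target gene.
#' @export
ddct_fold_change <- function(ct, controls = c("ACTB", "GAPDH")) {
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive and finite")
  targets <- setdiff(unique(ct$gene), controls)
  rows <- list()
  for (s in unique(ct$sample)) {
    sub <- ct[ct$sample == s, , drop = FALSE]
    ctrl_ct <- sub$ct[sub$gene %in% controls]
    if (length(ctrl_ct) == 0L)
      stop("sample ", s, " has no endogenous control measurements")
    for (g in targets) {
      tg <- sub$ct[sub$gene == g]
      if (length(tg) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, condition = sub$condition[1], gene = g,
        dct = mean(tg) - mean(ctrl_ct))
    }
  }
  out <- do.call(rbind, rows)
  ref <- tapply(out$dct[out$condition == "carrier"],
                out$gene[out$condition == "carrier"], mean)
  if (any(!targets %in% names(ref)))
    stop("every target gene needs at least one carrier sample")
  out$ddct <- out$dct - unname(ref[out$gene])
  out$fold_change <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}
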