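#' Within-distance flags between two region sets
#'
#' Flags each region of `a` that lies within `d` bp of some region of `b`,
#' where distance is the edge-to-edge gap and overlapping regions have
#' distance 0. `d = 0` therefore flags touching or overlapping regions.
#'
#' @param a,b `GRanges` on the same genome.
#' @param d Maximum edge gap in bp; default 250.
#' @return Logical vector over the regions of `a`.
#' @export
within_distance <- function(a, b, d = 250) {
  if (d < 0) stop("d must be non-negative")
  IRanges::overlapsAny(a, b, maxgap = d, ignore.strand = TRUE)
}

#' Partition two peak fractions into unique and co-occupied regions
#'
#' Clusters the union of the two fractions' peaks by single linkage at edge
#' gap `<= d`. Clusters containing peaks from both fractions become
#' co-occupied ("GIS") records — one record per cluster, spanning the union
#' of its members; remaining peaks stay as fraction-unique records. The
#' three classes are disjoint and jointly cover every input peak.
#'
#' @param g1,g2 `GRanges` of selected peaks for the two fractions.
#' @param d Co-occupancy distance in bp; default 250.
#' @return A list with `g1_only`, `g2_only` (subsets of the inputs) and
#'   `gis` (cluster spans with metadata columns `n_g1`, `n_g2`).
#' @export
classify_gli <- function(g1, g2, d = 250) {
  both <- c(GenomicRanges::granges(g1), GenomicRanges::granges(g2))
  src <- rep(c("g1", "g2"), c(length(g1), length(g2)))
  if (length(both) == 0L)
    return(list(g1_only = g1, g2_only = g2,
                gis = GenomicRanges::GRanges(n_g1 = integer(0), n_g2 = integer(0))))
  clusters <- GenomicRanges::reduce(both, min.gapwidth = d + 1, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(both, clusters, ignore.strand = TRUE)
  cl <- integer(length(both))
  cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  n_g1 <- tabulate(cl[src == "g1"], nbins = length(clusters))
  n_g2 <- tabulate(cl[src == "g2"], nbins = length(clusters))
  is_gis <- n_g1 > 0 & n_g2 > 0
  gis <- clusters[is_gis]
  S4Vectors::mcols(gis)$n_g1 <- n_g1[is_gis]
  S4Vectors::mcols(gis)$n_g2 <- n_g2[is_gis]
  gis_cl <- which(is_gis)
  in_gis_g1 <- cl[src == "g1"] %in% gis_cl
  in_gis_g2 <- cl[src == "g2"] %in% gis_cl
  list(g1_only = g1[!in_gis_g1], g2_only = g2[!in_gis_g2], gis = gis)
}

#' CTCF co-localisation of a peak partition
#'
#' Intersects each class of a [classify_gli()] partition with a CTCF
#' binding-region set at edge gap `<= d`, yielding the sets conventionally
#' labelled l (fraction-1-unique near CTCF), k (fraction-2-unique near
#' CTCF) and n (co-occupied near CTCF), with per-class counts and
#' percentages.
#'
#' @param partition Output of [classify_gli()].
#' @param ctcf `GRanges` of CTCF binding regions.
#' @param d Distance in bp; default 250.
#' @return A list with `l`, `k`, `n` (GRanges subsets) and `summary`, a
#'   data.frame of class sizes, co-localised counts and percentages.
#' @export
ctcf_colocalize <- function(partition, ctcf, d = 250) {
  l <- partition$g1_only[within_distance(partition$g1_only, ctcf, d)]
  k <- partition$g2_only[within_distance(partition$g2_only, ctcf, d)]
  n <- partition$gis[within_distance(partition$gis, ctcf, d)]
  sizes <- c(g1_only = length(partition$g1_only),
             g2_only = length(partition$g2_only),
             gis = length(partition$gis))
  counts <- c(length(l), length(k), length(n))
  pct <- ifelse(sizes > 0, vapply(seq_along(sizes), function(i)
    if (sizes[i] > 0) percentage(counts[i], sizes[i]) else NA_real_,
    numeric(1)), NA_real_)
  list(l = l, k = k, n = n,
       summary = data.frame(set = c("l", "k", "n"),
                            class = names(sizes),
                            class_size = as.integer(sizes),
                            near_ctcf = counts,
                            percent = pct))
}

# Fixed letter map for human/mouse membership combinations.
# p = mouse-Gli1-specific, q = mouse-Gli3-specific; every other combination
# over (hG1, hG2, mG1, mG3) gets a letter from r onwards in lexicographic
# order of the flag vector read as a binary number. Letters are labels with
# no further semantics.
.conservation_letter_map <- local({
  combos <- expand.grid(hG1 = c(FALSE, TRUE), hG2 = c(FALSE, TRUE),
                        mG1 = c(FALSE, TRUE), mG3 = c(FALSE, TRUE))
  combos <- combos[combos$mG1 | combos$mG3, ]
  key <- apply(combos, 1, function(r) paste(as.integer(r), collapse = ""))
  val <- apply(combos, 1, function(r) as.integer(r) %*% c(8L, 4L, 2L, 1L))
  ord <- order(val)
  key <- key[ord]; combos <- combos[ord, ]
  lab <- character(length(key))
  lab[key == "0010"] <- "p"
  lab[key == "0001"] <- "q"
  rest <- which(!lab %in% c("p", "q"))
  lab[rest] <- c(letters[18:26], "zz")[seq_along(rest)]
  stats::setNames(lab, key)
})

.membership_key <- function(hG1, hG2, mG1, mG3) {
  paste0(as.integer(hG1), as.integer(hG2), as.integer(mG1), as.integer(mG3))
}

#' Conservation binning of mouse binding regions against human fractions
#'
#' Assigns every mouse region (from the pre-lifted mouse Gli1 and Gli3
#' sets) a membership vector over \{hG1, hG2, mG1, mG3\} using the
#' within-distance rule, then maps each vector to a fixed bin letter:
#' `p` = mouse-Gli1-specific (no human, no mouse-Gli3 flag), `q` =
#' mouse-Gli3-specific, and remaining combinations `r` onwards in a fixed
#' documented order. Bins are disjoint and exhaustive over the mouse
#' regions. The mouse Gli3 set is expected to be pre-filtered with
#' [filter_mouse_intensity()].
#'
#' @param hG1,hG2 `GRanges` of human fraction-specific binding regions.
#' @param mG1,mG3 `GRanges` of mouse binding regions in human coordinates.
#' @param d Distance in bp; default 250.
#' @return A `GRanges` of all mouse regions with metadata columns `source`
#'   ("mG1"/"mG3"), the four membership flags, and `bin`.
#' @export
conservation_bins <- function(hG1, hG2, mG1, mG3, d = 250) {
  univ <- c(GenomicRanges::granges(mG1), GenomicRanges::granges(mG3))
  src <- rep(c("mG1", "mG3"), c(length(mG1), length(mG3)))
  f_h1 <- within_distance(univ, hG1, d)
  f_h2 <- within_distance(univ, hG2, d)
  f_m1 <- src == "mG1" | within_distance(univ, mG1, d)
  f_m3 <- src == "mG3" | within_distance(univ, mG3, d)
  S4Vectors::mcols(univ)$source <- src
  S4Vectors::mcols(univ)$hG1 <- f_h1
  S4Vectors::mcols(univ)$hG2 <- f_h2
  S4Vectors::mcols(univ)$mG1 <- f_m1
  S4Vectors::mcols(univ)$mG3 <- f_m3
  S4Vectors::mcols(univ)$bin <-
    unname(.conservation_letter_map[.membership_key(f_h1, f_h2, f_m1, f_m3)])
  univ
}

#' Intensity filter for the mouse Gli3 region set
#'
#' Retains regions with intensity strictly greater than `cutoff`, the rule
#' used to keep the high-signal majority of genome-wide array binding
#' regions.
#'
#' @param regions `GRanges` with an `intensity` metadata column.
#' @param cutoff Strict lower intensity bound; default 3.0.
#' @return The retained subset.
#' @export
filter_mouse_intensity <- function(regions, cutoff = 3.0) {
  intens <- S4Vectors::mcols(regions)$intensity
  if (is.null(intens)) stop("regions must carry an 'intensity' metadata column")
  regions[intens > cutoff]
}
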