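make_genes <- function(n, chrom = "c1", spacing = 1000L, width = 400L,
                       offset = 101L) {
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
             start = offset + (seq_len(n) - 1L) * spacing,
             end = offset + (seq_len(n) - 1L) * spacing + width - 1L,
             strand = rep(c("+", "-"), length.out = n))
}

test_that("DEG calling applies fold and significance thresholds", {
  genes <- make_genes(3)
  e <- simulate_expression(genes, c(g01 = 1.14, g02 = 0), n_per_group = 4,
                           noise_sd = 0.05, seed = 71)
  d <- call_deg(e, fc_threshold = 1.5, alpha = 0.05)
  expect_identical(d$deg_status[d$gene_id == "g01"], "up")   # 2.2-fold effect
  expect_identical(d$deg_status[d$gene_id == "g02"], "none")

  # degenerate completeness: thresholds off -> every gene labelled
  d_all <- call_deg(e, fc_threshold = 1, alpha = 1)
  expect_true(all(d_all$deg_status != "none"))

  expect_error(call_deg(e[, !grepl("control_[234]", names(e))]), "2 replicates")
})

test_that("DEG flags agree with an independent Welch-test recomputation", {
  genes <- make_genes(50)
  set.seed(72)
  fx <- setNames(sample(c(-2, -1, 0, 0, 1, 2), 50, replace = TRUE),
                 genes$gene_id)
  e <- simulate_expression(genes, fx, n_per_group = 5, noise_sd = 0.4, seed = 73)
  d <- call_deg(e, fc_threshold = 1.5, alpha = 0.05)
  ctrl <- as.matrix(e[, grep("^control_", names(e))])
  trt <- as.matrix(e[, grep("^treated_", names(e))])
  for (i in 1:50) {
    p <- oracle_welch_p(trt[i, ], ctrl[i, ])
    lfc <- mean(trt[i, ]) - mean(ctrl[i, ])
    expect_equal(d$p_value[i], p, tolerance = 1e-12)
    expect_equal(d$log2fc[i], lfc, tolerance = 1e-12)
    status <- if (lfc >= log2(1.5) && p < 0.05) "up"
      else if (lfc <= -log2(1.5) && p < 0.05) "down" else "none"
    expect_identical(d$deg_status[i], status)
  }
})

test_that("neighbourhoods span flanking gene bodies and tile the gene territory", {
  genes <- data.frame(gene_id = c("A", "B", "C"), chrom = "c1",
                      start = c(101L, 501L, 901L), end = c(200L, 600L, 1000L),
                      strand = "+")
  nb <- build_neighborhoods(genes, c(c1 = 5000L))
  b <- nb[S4Vectors::mcols(nb)$gene_id == "B"]
  expect_equal(GenomicRanges::start(b), 201)   # [200, 900) in BED coordinates
  expect_equal(GenomicRanges::end(b), 900)

  single <- build_neighborhoods(genes[2, ], c(c1 = 5000L))
  expect_equal(GenomicRanges::start(single), 1)
  expect_equal(GenomicRanges::end(single), 5000)

  # spans contain gene bodies; no orphaned gaps between adjacent genes
  set.seed(74)
  g2 <- make_genes(20, spacing = 700L, width = 300L)
  nb2 <- build_neighborhoods(g2, c(c1 = 50000L))
  expect_true(all(GenomicRanges::start(nb2) <= g2$start[order(g2$start)] &
                  GenomicRanges::end(nb2) >= g2$end[order(g2$start)]))
  covered <- GenomicRanges::reduce(nb2)
  expect_length(covered, 1)
  expect_lte(GenomicRanges::start(covered), min(g2$start))
  expect_gte(GenomicRanges::end(covered), max(g2$end))

  # two neighbours per side reach one gene further
  nb_k2 <- build_neighborhoods(genes, c(c1 = 5000L), neighbors_per_side = 2)
  b2 <- nb_k2[S4Vectors::mcols(nb_k2)$gene_id == "B"]
  expect_equal(GenomicRanges::start(b2), 1)
  expect_equal(GenomicRanges::end(b2), 5000)
})

test_that("region-to-gene assignment matches all-pairs intersection", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "c1",
                      start = c(101L, 2001L), end = c(500L, 2400L), strand = "+")
  nb <- build_neighborhoods(genes, c(c1 = 10000L))
  inside_A <- GenomicRanges::GRanges("c1", IRanges::IRanges(150, 200))
  between <- GenomicRanges::GRanges("c1", IRanges::IRanges(1000, 1100))
  lab <- assign_regions(list(G1 = inside_A, G2 = between), nb)
  expect_true(lab$G1[lab$gene_id == "A"])
  expect_false(lab$G1[lab$gene_id == "B"])
  expect_true(all(lab$G2))   # intergenic region labels both flanking genes

  set.seed(75)
  for (rep in 1:10) {
    gg <- make_genes(15, spacing = 1200L)
    nb <- build_neighborhoods(gg, c(c1 = 100000L))
    regs <- list(G1 = random_regions(30, c(c1 = 100000L)),
                 G2 = random_regions(30, c(c1 = 100000L)),
                 GIS = random_regions(10, c(c1 = 100000L)))
    lab <- assign_regions(regs, nb)
    for (cls in names(regs))
      expect_identical(lab[[cls]], oracle_overlap(nb, regs[[cls]]))
  }
})

test_that("binding groups partition labelled DEGs in the fixed letter order", {
  deg <- data.frame(gene_id = sprintf("g%02d", 1:9), chrom = "c1",
                    start = 1:9 * 100L, end = 1:9 * 100L + 50L, strand = "+",
                    log2fc = 2, p_value = 0.001,
                    deg_status = c(rep("up", 8), "none"))
  labels <- data.frame(gene_id = deg$gene_id,
                       G1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
                       G2 = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
                       GIS = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  grp <- bin_deg_by_binding(deg, labels)
  got <- setNames(grp$group, grp$gene_id)
  expect_identical(unname(got[c("g01", "g02", "g03", "g04", "g05", "g06", "g07")]),
                   c("a", "b", "c", "d", "e", "f", "g"))
  expect_false("g08" %in% grp$gene_id)  # no label
  expect_false("g09" %in% grp$gene_id)  # not a DEG
  expect_equal(sum(attr(grp, "counts")), nrow(grp))
})

test_that("conservation sets separate mouse-only and human-mouse common targets", {
  deg <- data.frame(gene_id = sprintf("g%02d", 1:8), chrom = "c1",
                    start = 1:8 * 100L, end = 1:8 * 100L + 50L, strand = "+",
                    log2fc = 2, p_value = 0.001, deg_status = "up")
  hum <- data.frame(gene_id = deg$gene_id,
                    hG1 = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
                    hG2 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  mus <- data.frame(gene_id = deg$gene_id,
                    mG1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                    mG3 = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  cs <- bin_deg_by_conservation(deg, hum, mus)
  got <- setNames(cs$conserved_set, cs$gene_id)
  expect_identical(unname(got[c("g01", "g02", "g03", "g04", "g05", "g07")]),
                   c("b'", "c'", "f'", "d'", "a'", "g'"))
  expect_false("g08" %in% cs$gene_id)  # no flags at all
  expect_equal(sum(attr(cs, "counts")), nrow(cs))
})

test_that("delta-delta-Ct reproduces closed-form and spreadsheet arithmetic", {
  base <- expand.grid(sample = c("t1", "c1"), gene = c("TGT", "ACTB", "GAPDH"),
                      stringsAsFactors = FALSE)
  base$condition <- ifelse(base$sample == "t1", "treated", "carrier")
  base$ct <- c(20, 20, 18, 18, 19, 19)   # treated == carrier
  out <- ddct_fold_change(base)
  expect_equal(out$fold_change[out$condition == "treated"], 1.0)

  # ddCt of -1 doubles expression
  shifted <- base
  shifted$ct[shifted$sample == "t1" & shifted$gene == "TGT"] <- 19
  out2 <- ddct_fold_change(shifted)
  expect_equal(out2$fold_change[out2$condition == "treated"], 2.0)

  # random table against manual recomputation
  set.seed(76)
  tab <- expand.grid(sample = c("t1", "t2", "c1", "c2"),
                     gene = c("TGT", "ACTB", "GAPDH"), stringsAsFactors = FALSE)
  tab$condition <- ifelse(grepl("^t", tab$sample), "treated", "carrier")
  tab$ct <- runif(nrow(tab), 15, 30)
  out3 <- ddct_fold_change(tab)
  dct <- sapply(c("t1", "t2", "c1", "c2"), function(s) {
    sub <- tab[tab$sample == s, ]
    sub$ct[sub$gene == "TGT"] - mean(sub$ct[sub$gene %in% c("ACTB", "GAPDH")])
  })
  ref <- mean(dct[c("c1", "c2")])
  for (s in c("t1", "t2", "c1", "c2"))
    expect_equal(out3$fold_change[out3$sample == s], 2^(-(dct[[s]] - ref)),
                 tolerance = 1e-12)

  bad <- tab[tab$gene == "TGT", ]
  expect_error(ddct_fold_change(bad), "control")
})
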