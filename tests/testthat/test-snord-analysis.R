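test_that("box C/D motifs are located with the stated windows and tie-breaks", {
  g <- paste0("GG", "AUGAUGA", paste(rep("A", 52), collapse = ""), "CUGA",
              "GGGGG")
  b <- find_boxes(g)
  expect_equal(b$box_c, c(3, 9))
  expect_equal(b$box_d, c(62, 65))

  expect_error(find_boxes(paste(rep("A", 60), collapse = "")), "no box D")
  expect_error(find_boxes("AUGAUGA"), "too short")

  # two CUGA matches near the 3' end: the 3'-most is chosen
  g2 <- paste0("GG", "AUGAUGA", paste(rep("A", 40), collapse = ""),
               "CUGAGCUGA", "G")
  b2 <- find_boxes(g2)
  expect_equal(b2$box_d, c(55, 58))

  # one mismatch outside the UGA core is tolerated in box C
  g3 <- paste0("GG", "AUCAUGA", paste(rep("A", 52), collapse = ""), "CUGA")
  expect_equal(find_boxes(g3)$box_c, c(3, 9))
  # but the 3' UGA core must be exact
  g4 <- paste0("GG", "AUGAUCA", paste(rep("A", 52), collapse = ""), "CUGA")
  expect_true("no box C found in 5' third" %in% find_boxes(g4)$notes)

  # DNA alphabet input is normalised
  b5 <- find_boxes(gsub("U", "T", g))
  expect_equal(b5$box_c, b$box_c)

  # modest padding that keeps boxes inside their windows leaves calls intact
  core <- paste0("AUGAUGA", paste(rep("A", 52), collapse = ""), "CUGA")
  for (pad in 1:3) {
    left <- paste(rep("C", pad), collapse = "")
    bp <- find_boxes(paste0(left, core, left))
    expect_equal(bp$box_c[1], pad + 1)
    expect_equal(diff(bp$box_d), 3)
  }
})

test_that("internal D'/C' boxes are found between box C and box D", {
  g <- paste0("GG", "AUGAUGA", "AAAAAAAAAA", "CUGA", "AA", "GUGAUGA",
              paste(rep("A", 20), collapse = ""), "CUGA")
  b <- find_boxes(g)
  expect_equal(b$box_d_prime, c(20, 23))
  expect_equal(b$box_c_prime, c(26, 32))
  r <- snord_record("x", g)
  expect_equal(r$ase_d_prime, c(10, 19))
  expect_equal(r$ase_d[2], b$box_d[1] - 1)
})

test_that("target prediction applies the fifth-nucleotide rule", {
  set.seed(99)
  tgt <- random_rna(200)
  guide <- make_guide(tgt, window_start = 101, duplex_len = 12)
  rec <- snord_record("g1", guide)
  hits <- predict_targets(rec, tgt, min_duplex = 10)
  expect_true(105 %in% hits$position) # base paired to guide position -5
  expect_equal(hits$via[hits$position == 105][1], "D")
  expect_gte(max(hits$duplex_length), 12)

  # no sufficient complementarity -> empty result
  rec2 <- snord_record("g2", paste0("GG", "AUGAUGA",
                                    paste(rep("A", 30), collapse = ""),
                                    "CUGA"))
  none <- predict_targets(rec2, paste(rep("A", 100), collapse = ""),
                          min_duplex = 10)
  expect_equal(nrow(none), 0)

  # a G.U wobble inside the duplex is tolerated
  tgt3 <- paste(rep("C", 40), collapse = "")
  guide3 <- make_guide(tgt3, 10, 12) # ASE is GGGG... pairing C
  tgt3_wob <- tgt3
  substr(tgt3_wob, 15, 15) <- "U" # G.U pair mid-duplex
  hits3 <- predict_targets(snord_record("g3", guide3), tgt3_wob,
                           min_duplex = 12)
  expect_true(14 %in% hits3$position)

  expect_error(predict_targets(rec, tgt, min_duplex = 4), ">= 5")
})

test_that("random guide/target constructions are always recovered", {
  set.seed(2024)
  ok <- vapply(1:50, function(i) {
    gp <- draw_guide_pair()
    rec <- snord_record(paste0("g", i), gp$guide)
    hits <- predict_targets(rec, gp$target, min_duplex = 10)
    (gp$window_start + 4) %in% hits$position
  }, logical(1))
  expect_true(all(ok))
})

test_that("guide lookup returns the annotated SNORDs", {
  cat <- snord_target_catalog()
  expect_identical(lookup_guide(cat, "SSU-C1272"), "SNORD66")
  expect_identical(lookup_guide(cat, "LSU-G4593"), "SNORD78")
  expect_identical(lookup_guide(cat, "SSU-X9999"), character(0))
})

test_that("differential expression filters, tests and adjusts as specified", {
  # identical counts across samples -> nothing significant
  cts <- matrix(50L, 20, 6,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  groups <- rep(c("a", "b"), each = 3)
  de <- diff_expression(cts, groups)
  expect_false(any(de$significant))
  expect_true(all(de$log2fc == 0))

  # low-count genes are removed before testing and carry no p
  cts2 <- cts
  cts2[1, ] <- c(2L, 1L, 0L, 3L, 1L, 1L)
  de2 <- diff_expression(cts2, groups)
  expect_true(de2$filtered[1])
  expect_true(is.na(de2$p[1]))
  expect_true(is.na(de2$p_adj[1]))
  # BH adjustment m equals the post-filter gene count
  expect_equal(sum(!is.na(de2$p_adj)), 19)
  expect_true(all(de2$p_adj >= de2$p, na.rm = TRUE))
  expect_true(all(de2$p_adj <= 1, na.rm = TRUE))

  # planted fold change is detected with the published thresholds
  sim <- simulate_snord_counts(200, 3, 4, 200, 0.05, de_index = 1:10,
                               lfc = 2, seed = 8L)
  de3 <- diff_expression(sim$counts, sim$groups)
  expect_gt(mean(de3$significant[1:10]), 0.5)
  expect_lt(mean(de3$significant[11:200]), 0.05)
  expect_gt(mean(de3$log2fc[1:10]), 1.5)

  expect_error(diff_expression(cts, rep("a", 6)), "two levels")
  expect_error(diff_expression(cts[, 1:3], c("a", "a", "b")), ">= 2")
  cts3 <- cts; cts3[, 2] <- 0L
  expect_error(diff_expression(cts3, groups), "all-zero")
})

test_that("diff_expression agrees with DESeq2 on a planted dataset", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_snord_counts(300, 4, 4, 150, 0.05, de_index = 1:15,
                               lfc = 2, seed = 33L)
  de <- diff_expression(sim$counts, sim$groups)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = sim$counts,
      colData = data.frame(group = sim$groups),
      design = ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("group", "group2", "group1"))
  })
  keep <- !de$filtered & !is.na(res$padj)
  expect_gt(cor(de$log2fc[keep], res$log2FoldChange[keep]), 0.95)
  ours <- de$gene[de$significant]
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                            abs(res$log2FoldChange) > 1]
  expect_gt(length(intersect(ours, theirs)) /
              max(1, length(union(ours, theirs))), 0.7)
})

test_that("site-guide matching flags concordant pairs", {
  cat <- snord_target_catalog()
  meth <- data.frame(
    site_id = c("SSU-C1272", "LSU-G4593", "SSU-G436", "SSU-A40"),
    delta = c(-0.3, 0.4, -0.2, -0.25),
    category = c("sharp_decrease", "gain_from_nonmethylation",
                 "sharp_decrease", "sharp_decrease"),
    significant = TRUE, stringsAsFactors = FALSE)
  de <- data.frame(
    gene = c("SNORD66", "SNORD78", "SNORD14e"),
    log2fc = c(-2.1, 1.8, 0.1), p_adj = c(0.001, 0.002, 0.9),
    significant = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  m <- match_snords_to_sites(de, meth, cat)
  expect_true(m$concordant[m$site_id == "SSU-C1272"])  # site down, guide down
  expect_true(m$concordant[m$site_id == "LSU-G4593"])  # site up, guide up
  expect_false(m$concordant[m$site_id == "SSU-G436"])  # guide not significant
  expect_true(is.na(m$snord[m$site_id == "SSU-A40"]))  # no annotated guide
  expect_false(m$concordant[m$site_id == "SSU-A40"])
})
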