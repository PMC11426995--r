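test_that("pooled and paired t tests match their closed forms and t.test", {
  r <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)

  rp <- ttest_paired(c(1.1, 2.2, 3.3), c(1, 2, 3))
  expect_equal(rp$t, 3.464102, tolerance = 1e-6)
  expect_equal(rp$df, 2)
  expect_equal(rp$p, 0.0741799, tolerance = 1e-6)

  set.seed(77)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    mine <- ttest_unpaired(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    if (length(a) == length(b)) {
      minep <- ttest_paired(a, b)
      refp <- t.test(a, b, paired = TRUE)
      expect_equal(minep$t, unname(refp$statistic), tolerance = 1e-12)
      expect_equal(minep$p, refp$p.value, tolerance = 1e-12)
    }
  }
})

test_that("degenerate zero-variance inputs follow the stated contract", {
  r <- ttest_unpaired(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)

  r2 <- ttest_unpaired(c(0.2, 0.2), c(0.8, 0.8))
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)

  a <- c(0.3, 0.6, 0.9)
  rp <- ttest_paired(a, a)
  expect_equal(rp$t, 0)
  expect_equal(rp$p, 1)
  expect_true(rp$degenerate)

  rp2 <- ttest_paired(c(0.25, 0.5), c(0.125, 0.375)) # constant difference
  expect_equal(rp2$p, 0)
  expect_true(rp2$degenerate)

  expect_error(ttest_unpaired(1, c(1, 2)), ">= 2")
  expect_error(ttest_paired(1:3, 1:2), "equal length")
})

test_that("change-type classification matches the published taxonomy", {
  expect_equal(classify_change(0.90, 0.70, 0.01), "sharp_decrease")
  expect_equal(classify_change(0.90, 0.82, 0.01), "slight_decrease")
  expect_equal(classify_change(0.02, 0.40, 0.01), "gain_from_nonmethylation")
  expect_equal(classify_change(0.50, 0.70, 0.01), "increase")
  expect_equal(classify_change(0.90, 0.70, 0.2), "not_significant")
  # the 0.15 boundary belongs to the sharp class
  expect_equal(classify_change(0.80, 0.65, 0.01), "sharp_decrease")
  expect_error(classify_change(1.2, 0.5, 0.01), "\\[0, 1\\]")

  # partition property: every significant site gets exactly one category,
  # non-significant sites get not_significant
  set.seed(5)
  ms <- runif(500); mm <- runif(500); p <- runif(500, 0, 0.1)
  cats <- classify_change(ms, mm, p)
  expect_true(all(cats[p >= 0.05] == "not_significant"))
  expect_true(all(cats[p < 0.05] %in%
                    c("sharp_decrease", "slight_decrease",
                      "gain_from_nonmethylation", "increase")))
})

test_that("row Z-scoring normalises and reports degenerate rows", {
  expect_equal(unname(zscore_rows(matrix(c(0.2, 0.4, 0.6), 1))[1, ]),
               c(-1, 0, 1))
  m <- rbind(a = c(0.2, 0.4, 0.6), b = c(0.5, 0.5, 0.5), c = c(1, 2, 4))
  expect_warning(z <- zscore_rows(m), "zero-variance")
  expect_identical(attr(z, "dropped"), "b")
  expect_equal(unname(rowMeans(z)), rep(0, 2))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 2))
  expect_error(zscore_rows(matrix(1:3, 3)), ">= 2 samples")
})

test_that("hierarchical clustering recovers planted structure deterministically", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  cl <- hcluster(m, zscore = FALSE)
  expect_equal(cl$heights, 0) # identical rows merge at height 0

  set.seed(13)
  g1 <- matrix(rnorm(60, 10, 0.1), 10)
  g2 <- matrix(rnorm(60, -10, 0.1), 10)
  m2 <- rbind(g1, g2)
  rownames(m2) <- paste0("s", 1:20)
  cl2 <- hcluster(m2, zscore = FALSE)
  ct <- stats::cutree(cl2$hclust, k = 2)
  expect_equal(length(unique(ct[1:10])), 1)
  expect_equal(length(unique(ct[11:20])), 1)
  expect_false(ct[1] == ct[11])

  # permutation equivariance: permuting rows permutes leaves identically
  perm <- sample(20)
  cl3 <- hcluster(m2[perm, ], zscore = FALSE)
  expect_identical(sort(cl3$row_order), sort(cl2$row_order))
  expect_equal(sort(cl3$heights), sort(cl2$heights))
  expect_identical(stats::cutree(cl3$hclust, 2)[rownames(m2)] ==
                     stats::cutree(cl3$hclust, 2)[[rownames(m2)[1]]],
                   ct[rownames(m2)] == ct[[rownames(m2)[1]]])

  expect_error(hcluster(rbind(c(1, NA), c(2, 3))), "missing")
  one <- hcluster(matrix(c(1, 2), 1, dimnames = list("x", NULL)),
                  zscore = FALSE)
  expect_null(one$hclust)
  expect_identical(one$row_order, "x")
})

test_that("significant-site intersection is exact and catalog-ordered", {
  expect_identical(intersect_significant(c("a", "b"), c("c", "d")),
                   character(0))
  expect_identical(intersect_significant(c("a", "b"), c("a", "b", "c")),
                   c("a", "b"))

  printed <- mov7d_changed_sites()$site_id
  expect_equal(length(printed), 30)
  decoys <- c("SSU-A512x", "LSU-G9999", "SSU-U1", "LSU-A2", "5.8S-G3")
  other <- c(ribotag_overlap_sites(), decoys)
  got <- intersect_significant(printed, other, catalog = site_catalog())
  expect_setequal(got, ribotag_overlap_sites())
  expect_equal(length(got), 7)
})

test_that("score-table comparison assembles tests, flags and categories", {
  set.seed(31)
  sham <- matrix(runif(30, 0.7, 0.9), 10, 3,
                 dimnames = list(paste0("site", 1:10), NULL))
  mov <- sham
  mov[1:3, ] <- mov[1:3, ] - 0.4 # strong planted drop
  res <- compare_score_tables(sham, mov)
  expect_equal(res$site_id, paste0("site", 1:10))
  expect_true(all(res$significant[1:3]))
  expect_true(all(res$category[1:3] == "sharp_decrease"))
  expect_equal(res$delta, res$mean_mov - res$mean_sham)

  # missing scores propagate to NA statistics, never to significance
  mov[5, 2] <- NA
  res2 <- compare_score_tables(sham, mov)
  expect_true(is.na(res2$p[5]))
  expect_false(res2$significant[5])
  expect_equal(res2$category[5], "not_significant")

  # BH option adds a monotone adjusted column used for the flag
  res3 <- compare_score_tables(sham, mov, adjust = "BH")
  expect_true(all(res3$p_adj >= res3$p, na.rm = TRUE))
})
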