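#' Pooled-variance two-sample Student t test
#'
#' Two-tailed unpaired Student t test with pooled variance and
#' `df = n_a + n_b - 2`. Degenerate inputs follow an explicit contract: zero
#' pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives `p = 0` (signed infinite `t`) with the
#' `degenerate` flag set.
#'
#' @param a,b Numeric vectors (each of length `>= 2`).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
ttest_unpaired <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(d) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Paired two-tailed Student t test
#'
#' One-sample t test on the paired differences `a - b`, `df = n - 1`.
#' Zero-variance differences are handled as in [ttest_unpaired()].
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
ttest_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  n <- length(a)
  if (n < 2) stop("need >= 2 pairs")
  d <- a - b
  df <- n - 1
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Classify the type of methylation change at a site
#'
#' Applies the change-type taxonomy used for overload vs. sham comparisons:
#' non-significant sites are `not_significant`; significant sites with
#' `delta = mean_mov - mean_sham <= -sharp_threshold` are `sharp_decrease`;
#' significant decreases smaller than that are `slight_decrease`; significant
#' increases from a near-zero sham level (`mean_sham < nonmeth_eps`) are
#' `gain_from_nonmethylation`; remaining significant increases are
#' `increase`. A delta of exactly `-sharp_threshold` is assigned to
#' `sharp_decrease`.
#'
#' @param mean_sham,mean_mov Group mean scores in `[0, 1]` (vectorised).
#' @param p P-value(s) from the site-level test.
#' @param alpha Significance level (default 0.05).
#' @param sharp_threshold RMS-score difference separating sharp from slight
#'   decreases (default 0.15).
#' @param nonmeth_eps Sham-mean ceiling defining "non-methylated in sham"
#'   (default 0.05).
#' @return Character vector of categories.
#' @export
classify_change <- function(mean_sham, mean_mov, p, alpha = 0.05,
                            sharp_threshold = 0.15, nonmeth_eps = 0.05) {
  if (any(c(mean_sham, mean_mov) < 0 | c(mean_sham, mean_mov) > 1,
          na.rm = TRUE))
    stop("means must lie in [0, 1]")
  delta <- mean_mov - mean_sham
  out <- rep("not_significant", length(delta))
  sig <- !is.na(p) & p < alpha
  out[sig & delta <= -sharp_threshold] <- "sharp_decrease"
  out[sig & delta > -sharp_threshold & delta < 0] <- "slight_decrease"
  out[sig & delta > 0 & mean_sham < nonmeth_eps] <- "gain_from_nonmethylation"
  out[sig & out == "not_significant"] <- "increase"
  out
}

#' Site-level comparison of two score tables
#'
#' Runs a per-site Student t test (unpaired pooled-variance by default,
#' paired if `paired = TRUE`) between replicate score matrices and classifies
#' each significant site with [classify_change()]. Sites with any missing
#' score are reported with `NA` statistics and `not_significant`. No
#' multiple-testing correction is applied by default (site significance is
#' raw `p < alpha`); set `adjust = "BH"` to add a `p_adj` column and use it
#' for the significance flag instead.
#'
#' @param sham,mov Numeric matrices (sites x replicates) with identical row
#'   names (site ids).
#' @param paired Use the paired test (requires equal replicate counts).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param ... Passed to [classify_change()].
#' @return Data frame with columns `site_id`, `mean_sham`, `mean_mov`,
#'   `delta`, `t`, `p` (and `p_adj` if requested), `significant`,
#'   `degenerate`, `category`.
#' @export
compare_score_tables <- function(sham, mov, paired = FALSE, alpha = 0.05,
                                 adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  if (!identical(rownames(sham), rownames(mov)))
    stop("score matrices must share row names (site ids)")
  res <- data.frame(site_id = rownames(sham),
                    mean_sham = rowMeans(sham), mean_mov = rowMeans(mov),
                    t = NA_real_, p = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$delta <- res$mean_mov - res$mean_sham
  for (i in seq_len(nrow(sham))) {
    a <- mov[i, ]; b <- sham[i, ]
    if (anyNA(a) || anyNA(b)) next
    tt <- if (paired) ttest_paired(a, b) else ttest_unpaired(a, b)
    res$t[i] <- tt$t; res$p[i] <- tt$p; res$degenerate[i] <- tt$degenerate
  }
  p_use <- res$p
  if (adjust == "BH") {
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    p_use <- res$p_adj
  }
  res$significant <- !is.na(p_use) & p_use < alpha
  res$category <- classify_change(res$mean_sham, res$mean_mov, p_use,
                                  alpha = alpha, ...)
  res[, c("site_id", "mean_sham", "mean_mov", "delta", "t", "p",
          if (adjust == "BH") "p_adj", "significant", "degenerate",
          "category")]
}

#' Row-wise Z-score normalisation
#'
#' Subtracts the row mean and divides by the row sample standard deviation.
#' Zero-variance rows cannot be normalised; they are dropped with a warning
#' and reported in the `"dropped"` attribute.
#'
#' @param m Numeric matrix with `>= 2` columns.
#' @return The Z-scored matrix (possibly fewer rows), with attribute
#'   `dropped` naming excluded rows.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2) stop("need >= 2 samples (columns) per row")
  sds <- apply(m, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance row(s) dropped: ",
            paste(utils::head(rownames(m)[drop], 5), collapse = ", "))
  }
  z <- (m[!drop, , drop = FALSE] - rowMeans(m[!drop, , drop = FALSE])) /
    sds[!drop]
  attr(z, "dropped") <- rownames(m)[drop]
  z
}

#' Hierarchical clustering of a (Z-scored) score matrix
#'
#' Agglomerative clustering of matrix rows with Euclidean distance and, by
#' default, complete linkage, as used for heatmaps of significantly changed
#' sites. Rows are Z-scored first unless `zscore = FALSE`. Ties in the merge
#' sequence follow the deterministic conventions of [stats::hclust()], so the
#' result is reproducible for a given row order.
#'
#' @param m Numeric matrix (sites x samples); must not contain missing
#'   values (exclude low-coverage sites upstream).
#' @param metric Distance metric for [stats::dist()] (default `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param zscore Z-score rows before clustering (default `TRUE`).
#' @return A list of class `cluster_result`: `hclust` (the merge tree),
#'   `row_order` (leaf order, row names), `col_order` (input column order),
#'   `heights`, `matrix` (the clustered, Z-scored matrix), `dropped`
#'   (zero-variance rows excluded by Z-scoring).
#' @export
hcluster <- function(m, metric = "euclidean", linkage = "complete",
                     zscore = TRUE) {
  if (anyNA(m)) stop("matrix contains missing values; exclude those sites")
  dropped <- character()
  if (zscore) {
    m <- zscore_rows(m)
    dropped <- attr(m, "dropped")
  }
  if (nrow(m) < 2) {
    return(structure(list(hclust = NULL, row_order = rownames(m),
                          col_order = colnames(m), heights = numeric(),
                          matrix = m, dropped = dropped),
                     class = "cluster_result"))
  }
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  structure(list(hclust = hc, row_order = rownames(m)[hc$order],
                 col_order = colnames(m), heights = hc$height, matrix = m,
                 dropped = dropped),
            class = "cluster_result")
}

#' Intersect significant-site sets
#'
#' Exact set intersection of two site-id sets, e.g. the significant sites
#' from a whole-muscle comparison and from a myofiber-specific (RiboTag)
#' comparison. Output order follows the catalog when one is supplied,
#' otherwise the order of `set_a`.
#'
#' @param set_a,set_b Character vectors of site ids (one catalog namespace).
#' @param catalog Optional catalog data frame (with `site_id`) fixing the
#'   output order.
#' @return Character vector of shared site ids.
#' @export
intersect_significant <- function(set_a, set_b, catalog = NULL) {
  common <- intersect(set_a, set_b)
  if (!is.null(catalog)) {
    common <- catalog$site_id[catalog$site_id %in% common]
  }
  common
}
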