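#' The 64 codons in canonical order
#'
#' @return Character vector of the 64 DNA codons, lower case, alphabetical.
#' @export
codons <- function() {
  b <- c("a", "c", "g", "t")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Codon frequencies and GC content of one coding sequence
#'
#' Counts codons 2..L/3 (the start codon is excluded from both the codon
#' frequencies and the GC content) and normalises to frequencies. Stop codons
#' are counted like any other codon.
#'
#' @param cds Coding sequence (character or Biostrings object; `U` accepted
#'   and treated as `T`). Length must be `>= 6` and divisible by 3.
#' @return List with `freq` (named 64-vector summing to 1), `gc` (GC fraction
#'   of the post-start region) and `n_codons` (total codons including the
#'   start); or `NULL` with a warning when the sequence contains ambiguous
#'   bases.
#' @export
codon_freq <- function(cds) {
  s <- toupper(as.character(cds))
  s <- gsub("U", "T", s, fixed = TRUE)
  L <- nchar(s)
  if (L < 6 || L %% 3 != 0)
    stop("coding sequence length must be >= 6 and divisible by 3")
  if (grepl("[^ACGT]", s)) {
    warning("ambiguous bases; transcript skipped")
    return(NULL)
  }
  body <- substr(s, 4, L)
  starts <- seq(1, nchar(body), by = 3)
  cod <- tolower(substring(body, starts, starts + 2))
  counts <- table(factor(cod, levels = codons()))
  freq <- as.numeric(counts) / length(cod)
  names(freq) <- codons()
  gc <- sum(strsplit(body, "")[[1]] %in% c("G", "C")) / nchar(body)
  list(freq = freq, gc = gc, n_codons = L / 3)
}

#' Codon profiles for a set of coding sequences
#'
#' Applies [codon_freq()] to each sequence; transcripts with ambiguous bases
#' are skipped with a warning.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @return List with `freq` (matrix transcripts x 64), `gc` (named vector)
#'   and `ids`.
#' @export
codon_profiles <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("tx_%04d", seq_along(seqs))
  profs <- lapply(seq_along(seqs), function(i) codon_freq(seqs[[i]]))
  keep <- !vapply(profs, is.null, logical(1))
  freq <- do.call(rbind, lapply(profs[keep], `[[`, "freq"))
  rownames(freq) <- ids[keep]
  list(freq = freq,
       gc = stats::setNames(vapply(profs[keep], `[[`, numeric(1), "gc"),
                            ids[keep]),
       ids = ids[keep])
}

# Two-sample Wilcoxon rank-sum p-value: exact enumeration-equivalent p for
# small tie-free groups, normal approximation with tie correction otherwise.
.wilcox_p <- function(x, y) {
  if (stats::var(c(x, y)) == 0 || all(is.na(c(x, y)))) return(1)
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value
  )
}

#' Compare codon composition of a transcript set against background
#'
#' Per codon, the per-transcript frequencies of the set are compared with the
#' background by a two-sided Wilcoxon rank-sum test (exact for tie-free
#' groups of size <= 8, normal approximation with tie correction otherwise),
#' Bonferroni-corrected over the 64 codons. GC content is compared the same
#' way as a separate, single test (not pooled into the Bonferroni family).
#' The set may be a subset of the background (the usual comparison is against
#' all detected transcripts).
#'
#' @param set_profiles,background_profiles Outputs of [codon_profiles()]
#'   (each with `>= 2` transcripts).
#' @param k Size of the ranked top list (default 5).
#' @param alpha Significance level for the top list (default 0.05).
#' @return List of class `codon_comparison`: `codons` (data frame `codon`,
#'   `median_set`, `median_bg`, `diff`, `p`, `p_adj`, `rank`, ordered by rank:
#'   adjusted p, then absolute difference), `top` (up to `k` codons with
#'   `p_adj < alpha`), `gc` (list `median_set`, `median_bg`, `diff`, `p`).
#' @export
compare_sets <- function(set_profiles, background_profiles, k = 5,
                         alpha = 0.05) {
  fs <- set_profiles$freq
  fb <- background_profiles$freq
  if (is.null(fs) || nrow(fs) < 2 || is.null(fb) || nrow(fb) < 2)
    stop("each group needs >= 2 transcripts")
  res <- data.frame(codon = codons(),
                    median_set = apply(fs, 2, stats::median),
                    median_bg = apply(fb, 2, stats::median),
                    p = vapply(seq_len(64), function(j)
                      .wilcox_p(fs[, j], fb[, j]), numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$diff <- res$median_set - res$median_bg
  res$p_adj <- pmin(1, res$p * 64)
  ord <- order(res$p_adj, -abs(res$diff))
  res <- res[ord, c("codon", "median_set", "median_bg", "diff", "p", "p_adj")]
  res$rank <- seq_len(64)
  rownames(res) <- NULL
  gc <- list(median_set = stats::median(set_profiles$gc),
             median_bg = stats::median(background_profiles$gc),
             diff = stats::median(set_profiles$gc) -
               stats::median(background_profiles$gc),
             p = .wilcox_p(set_profiles$gc, background_profiles$gc))
  structure(list(codons = res,
                 top = utils::head(res$codon[res$p_adj < alpha], k),
                 gc = gc),
            class = "codon_comparison")
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` for the overlap between a
#' list of differentially expressed ids and each gene set, with
#' Benjamini-Hochberg adjustment across the supplied sets.
#'
#' @param de_ids Character vector of selected (e.g. DE) ids, a subset of the
#'   universe.
#' @param gene_sets Named list of character vectors (or a single character
#'   vector), each a subset of the universe.
#' @param universe_ids Character vector of all testable ids.
#' @return Data frame with columns `set`, `set_size`, `de_size`, `overlap`,
#'   `p`, `p_adj`.
#' @export
ora_enrich <- function(de_ids, gene_sets, universe_ids) {
  if (!length(universe_ids)) stop("empty universe")
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set%d", seq_along(gene_sets))
  de_ids <- unique(de_ids)
  universe_ids <- unique(universe_ids)
  if (!all(de_ids %in% universe_ids))
    stop("`de_ids` must be a subset of the universe")
  N <- length(universe_ids)
  n <- length(de_ids)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- unique(gene_sets[[nm]])
    if (!all(gs %in% universe_ids))
      stop("gene set '", nm, "' is not a subset of the universe")
    K <- length(gs)
    k <- length(intersect(gs, de_ids))
    data.frame(set = nm, set_size = K, de_size = n, overlap = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
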