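.as_rna <- function(x) {
  x <- toupper(as.character(x))
  gsub("T", "U", x, fixed = TRUE)
}

# Match the box C consensus RUGAUGA at position s of an RNA string:
# the 3' UGA core (positions 5-7) must be exact, position 1 must be A or G,
# and at most `max_mm` mismatches are allowed over positions 1-4.
.match_box_c <- function(seq, s, max_mm = 1L) {
  if (s + 6L > nchar(seq)) return(FALSE)
  x <- strsplit(substr(seq, s, s + 6L), "")[[1]]
  if (!identical(x[5:7], c("U", "G", "A"))) return(FALSE)
  mm <- sum(c(!x[1] %in% c("A", "G"),
              x[2] != "U", x[3] != "G", x[4] != "A"))
  mm <= max_mm
}

#' Locate box C/D motifs in a snoRNA sequence
#'
#' Box C is the first match to the consensus `RUGAUGA` (R = A/G; the 3' `UGA`
#' core must be exact, at most one mismatch elsewhere) starting within the 5'
#' third of the sequence. Box D is the 3'-most exact `CUGA` within the last
#' 10 nt. The optional internal boxes D' (`CUGA`) and C' (`RUGAUGA`, same
#' relaxed rule) are searched between box C and box D, D' first. A box D is
#' mandatory; other missing boxes are reported in `notes`.
#'
#' @param sequence snoRNA sequence (character or Biostrings object; DNA or
#'   RNA alphabet, normalised to RNA).
#' @return List with integer `c(start, end)` intervals `box_c`, `box_d`, and
#'   possibly `box_d_prime`, `box_c_prime` (absent boxes are `NULL`), plus
#'   `length` and a character vector `notes`.
#' @export
find_boxes <- function(sequence) {
  seq <- .as_rna(sequence)
  L <- nchar(seq)
  if (L < 20) stop("sequence too short (need >= 20 nt)")
  notes <- character()

  box_c <- NULL
  for (s in seq_len(max(1L, floor(L / 3)))) {
    if (.match_box_c(seq, s)) { box_c <- c(s, s + 6L); break }
  }
  if (is.null(box_c)) notes <- c(notes, "no box C found in 5' third")

  # 3'-most exact CUGA whose start lies within the last 10 nt
  box_d <- NULL
  for (s in seq(L - 3L, max(1L, L - 9L))) {
    if (substr(seq, s, s + 3L) == "CUGA") { box_d <- c(s, s + 3L); break }
  }
  if (is.null(box_d)) stop("no box D (CUGA) found within the last 10 nt")

  lo <- if (!is.null(box_c)) box_c[2] + 1L else 1L
  hi <- box_d[1] - 1L
  box_d_prime <- NULL
  if (hi - lo + 1L >= 4L) {
    for (s in seq(lo, hi - 3L)) {
      if (substr(seq, s, s + 3L) == "CUGA") {
        box_d_prime <- c(s, s + 3L); break
      }
    }
  }
  box_c_prime <- NULL
  if (!is.null(box_d_prime) && hi - box_d_prime[2] >= 7L) {
    for (s in seq(box_d_prime[2] + 1L, hi - 6L)) {
      if (.match_box_c(seq, s)) { box_c_prime <- c(s, s + 6L); break }
    }
  }
  if (is.null(box_d_prime)) notes <- c(notes, "no box D' found")
  if (is.null(box_c_prime)) notes <- c(notes, "no box C' found")

  list(box_c = box_c, box_d = box_d, box_d_prime = box_d_prime,
       box_c_prime = box_c_prime, length = L, notes = notes)
}

#' Assemble an annotated box C/D SNORD record
#'
#' Runs [find_boxes()] and derives the antisense elements: the stretch
#' immediately 5' of box D (and of box D' when present), limited to `ase_max`
#' nt and not crossing the preceding box. These elements base-pair with the
#' rRNA target to position the fibrillarin methyltransferase.
#'
#' @param name SNORD name.
#' @param sequence snoRNA sequence (DNA or RNA alphabet).
#' @param host_gene Optional host-gene label.
#' @param targets Optional character vector of annotated target site ids.
#' @param ase_max Maximum antisense-element length considered (default 20).
#' @return List of class `snord_record` with `name`, `sequence` (RNA),
#'   `boxes`, `ase_d`, `ase_d_prime` (integer intervals or `NULL`),
#'   `host_gene`, `targets`.
#' @export
snord_record <- function(name, sequence, host_gene = NA_character_,
                         targets = character(), ase_max = 20L) {
  seq <- .as_rna(sequence)
  boxes <- find_boxes(seq)
  floor_d <- max(1L,
                 if (!is.null(boxes$box_c_prime)) boxes$box_c_prime[2] + 1L
                 else if (!is.null(boxes$box_d_prime)) boxes$box_d_prime[2] + 1L
                 else if (!is.null(boxes$box_c)) boxes$box_c[2] + 1L else 1L,
                 boxes$box_d[1] - ase_max)
  ase_d <- if (boxes$box_d[1] - floor_d >= 1L)
    c(floor_d, boxes$box_d[1] - 1L) else NULL
  ase_d_prime <- NULL
  if (!is.null(boxes$box_d_prime)) {
    floor_dp <- max(1L,
                    if (!is.null(boxes$box_c)) boxes$box_c[2] + 1L else 1L,
                    boxes$box_d_prime[1] - ase_max)
    if (boxes$box_d_prime[1] - floor_dp >= 1L)
      ase_d_prime <- c(floor_dp, boxes$box_d_prime[1] - 1L)
  }
  structure(list(name = name, sequence = seq, boxes = boxes, ase_d = ase_d,
                 ase_d_prime = ase_d_prime, host_gene = host_gene,
                 targets = targets),
            class = "snord_record")
}

# Watson-Crick plus G.U wobble pairing in the RNA alphabet
.pairs_rna <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Predict rRNA 2'-O-Me target positions of a SNORD
#'
#' For each box D/D', the guide's antisense element is scanned against the
#' target sequence for a contiguous duplex of at least `min_duplex` base
#' pairs (Watson-Crick, G.U wobble allowed, no mismatches) that abuts the
#' box: the guide nucleotide immediately 5' of the box pairs with the 5'-most
#' target base of the duplex, and the duplex extends antiparallel from there.
#' The predicted methylated nucleotide follows the fifth-nucleotide rule:
#' counting the first box nucleotide as position 0, the guide base at -5
#' pairs with the methylated target base, i.e. the fifth target base of the
#' duplex window.
#'
#' @param snord A [snord_record()].
#' @param target_sequence Target (rRNA) sequence, DNA or RNA alphabet.
#' @param min_duplex Minimum duplex length in nt (`>= 5`, default 10).
#' @return Data frame with columns `position` (predicted methylated target
#'   nucleotide, 1-based), `via` (`"D"` or `"D'"`), `duplex_length`, sorted
#'   by decreasing duplex length; zero rows when nothing pairs.
#' @export
predict_targets <- function(snord, target_sequence, min_duplex = 10) {
  stopifnot(inherits(snord, "snord_record"))
  if (min_duplex < 5) stop("`min_duplex` must be >= 5 (fifth-nucleotide rule)")
  tgt <- strsplit(.as_rna(target_sequence), "")[[1]]
  Lt <- length(tgt)
  gseq <- strsplit(snord$sequence, "")[[1]]

  scan_box <- function(ase, box_start, via) {
    if (is.null(ase)) return(NULL)
    len_max <- ase[2] - ase[1] + 1L
    hits <- list()
    for (u in seq_len(Lt)) {
      j <- 0L
      while (j < len_max && u + j <= Lt &&
             .pairs_rna(gseq[box_start - 1L - j], tgt[u + j])) {
        j <- j + 1L
      }
      if (j >= min_duplex) {
        hits[[length(hits) + 1L]] <-
          data.frame(position = u + 4L, via = via, duplex_length = j,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }

  if (is.null(snord$ase_d) && is.null(snord$ase_d_prime))
    stop("SNORD has no antisense element")
  out <- rbind(scan_box(snord$ase_d, snord$boxes$box_d[1], "D"),
               if (!is.null(snord$boxes$box_d_prime))
                 scan_box(snord$ase_d_prime, snord$boxes$box_d_prime[1], "D'"))
  if (is.null(out)) {
    return(data.frame(position = integer(), via = character(),
                      duplex_length = integer(), stringsAsFactors = FALSE))
  }
  out <- out[order(-out$duplex_length, out$position), ]
  rownames(out) <- NULL
  out
}

#' Guide SNORDs annotated to a site
#'
#' @param catalog SNORD-target catalog (see [snord_target_catalog()]).
#' @param site_id Site identifier, e.g. `"SSU-C1272"`.
#' @return Character vector of SNORD names (empty if none annotated).
#' @export
lookup_guide <- function(catalog, site_id) {
  catalog$snord[catalog$site_id == site_id]
}

#' Differential SNORD expression (simplified negative-binomial Wald test)
#'
#' Genes with fewer than `min_total` total counts are removed before testing.
#' Remaining genes are normalised with median-of-ratios size factors, a
#' per-gene NB dispersion is estimated by pooled within-group method of
#' moments, stabilised by flooring each gene at the genome-wide median
#' estimate (and at 1e-8), and the log2 fold change (second group level
#' vs. first) is tested with a Wald statistic referenced against a t
#' distribution with the residual degrees of freedom (a small-sample guard
#' against the anticonservatism of the plain normal reference).
#' P-values are Benjamini-Hochberg adjusted over the post-filter genes, and
#' significance requires both `p_adj < alpha` and `|log2fc| > lfc_threshold`.
#' A 0.5 pseudocount on the group means keeps fold changes finite when a
#' group mean is zero.
#'
#' @param counts Integer matrix (genes x samples) with row names.
#' @param groups Factor/character of length `ncol(counts)` with two levels,
#'   each represented by `>= 2` samples. Fold changes are second level vs.
#'   first.
#' @param min_total Total-count filter threshold (default 10).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @return Data frame with one row per input gene: `gene`, `base_mean`,
#'   `log2fc`, `p`, `p_adj`, `significant`, `filtered`. Filtered genes carry
#'   `NA` statistics.
#' @export
diff_expression <- function(counts, groups, min_total = 10, alpha = 0.05,
                            lfc_threshold = 1) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (length(groups) != ncol(counts))
    stop("`groups` length must match the number of samples")
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))

  keep <- rowSums(counts) >= min_total

  # median-of-ratios size factors; library-size ratios when no gene row is
  # positive in all samples
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - loggeo)))
  } else {
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls)))
  }
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(counts, 2, sf, "/")

  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  base_mean <- rowMeans(norm)

  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  # per-gene method-of-moments dispersion, stabilised by flooring at the
  # genome-wide median: with a handful of replicates the raw estimate
  # regularly undershoots (even below zero), which would collapse the Wald
  # SE to Poisson level and inflate false positives
  disp_mom <- (v - mu) / mu^2
  common <- stats::median(disp_mom[is.finite(disp_mom)], na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  disp <- pmax(disp_mom, common, 1e-8)

  lfc <- log2((mu2 + 0.5) / (mu1 + 0.5))
  se <- sqrt((1 / (mu1 + 0.5) + disp) / n1 +
               (1 / (mu2 + 0.5) + disp) / n2) / log(2)
  # Wald statistic referenced against t with the residual df: with 3-4
  # replicates the plug-in SE is noisy enough that the normal reference is
  # visibly anticonservative
  z <- lfc / se
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)

  out <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    log2fc = lfc, p = p, p_adj = NA_real_,
                    significant = FALSE, filtered = !keep,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$log2fc[!keep] <- NA_real_
  out$p[!keep] <- NA_real_
  out$p_adj[keep] <- stats::p.adjust(out$p[keep], method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha &
    abs(out$log2fc) > lfc_threshold
  out
}

#' Pair differentially methylated sites with their guide SNORDs
#'
#' For every significant site in a methylation comparison, emits one row per
#' annotated guide SNORD with that guide's differential-expression status.
#' A pair is `concordant` when the guide change is significant and points the
#' same way as the methylation change (site hypomethylated with guide down,
#' or site hypermethylated with guide up).
#'
#' @param de Output of [diff_expression()].
#' @param meth Output of [compare_score_tables()].
#' @param catalog SNORD-target catalog (see [snord_target_catalog()]).
#' @return Data frame with columns `site_id`, `delta`, `category`, `snord`,
#'   `snord_log2fc`, `snord_p_adj`, `snord_significant`, `concordant`.
#'   Sites without an annotated guide get a single row with `NA` guide
#'   fields.
#' @export
match_snords_to_sites <- function(de, meth, catalog) {
  sig <- meth[meth$significant, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    guides <- lookup_guide(catalog, sig$site_id[i])
    if (!length(guides)) guides <- NA_character_
    idx <- match(guides, de$gene)
    data.frame(site_id = sig$site_id[i], delta = sig$delta[i],
               category = sig$category[i], snord = guides,
               snord_log2fc = de$log2fc[idx], snord_p_adj = de$p_adj[idx],
               snord_significant = !is.na(idx) & de$significant[idx],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), delta = numeric(),
               category = character(), snord = character(),
               snord_log2fc = numeric(), snord_p_adj = numeric(),
               snord_significant = logical(), stringsAsFactors = FALSE)
  out$concordant <- out$snord_significant & !is.na(out$snord_log2fc) &
    sign(out$snord_log2fc) == sign(out$delta)
  out
}
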