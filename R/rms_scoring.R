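#' Per-bond cleavage counts from a read-end profile
#'
#' Cleavage at the bond 3' of nucleotide `i` leaves a fragment 3' end at `i`
#' and a fragment 5' end at `i + 1`, so the per-bond event count is
#' `n_i = end3_count(i) + end5_count(i + 1)` for `i` in `1..L-1`.
#'
#' @param profile End-count data frame with columns `molecule`, `position`,
#'   `end5_count`, `end3_count` and contiguous positions `1..L` per molecule.
#' @return For a single-molecule profile, a numeric vector of length `L - 1`;
#'   otherwise a named list of such vectors, one per molecule.
#' @export
bond_end_counts <- function(profile) {
  if (nrow(profile) == 0) stop("empty profile")
  .validate_profile(profile)
  out <- lapply(split(profile, profile$molecule), function(p) {
    p <- p[order(p$position), ]
    L <- nrow(p)
    p$end3_count[-L] + p$end5_count[-1L]
  })
  if (length(out) == 1L) out[[1L]] else out
}

.validate_profile <- function(profile) {
  need <- c("molecule", "position", "end5_count", "end3_count")
  if (!all(need %in% names(profile)))
    stop("profile must have columns ", paste(need, collapse = ", "))
  if (any(profile$end5_count < 0) || any(profile$end3_count < 0))
    stop("negative end counts")
  for (p in split(profile, profile$molecule)) {
    pos <- sort(p$position)
    if (!identical(as.integer(pos), seq_len(nrow(p))))
      stop("positions not contiguous 1..L for molecule '", p$molecule[1],
           "' (first gap near position ",
           min(setdiff(seq_len(max(pos)), pos), Inf), ")")
  }
  invisible(TRUE)
}

# Score C at one bond; returns score, flank mean and weighted flank mean.
.score_c_one <- function(n, i, k) {
  L <- length(n)
  lambda <- (k - seq_len(k) + 1) / k # linearly decaying flank weights
  left <- i - seq_len(k)
  right <- i + seq_len(k)
  ok_l <- left >= 1L
  ok_r <- right <= L
  vals <- c(n[left[ok_l]], n[right[ok_r]])
  wts <- c(lambda[ok_l], lambda[ok_r])
  w <- sum(wts * vals) / sum(wts)
  list(w = w, flank_mean = mean(vals))
}

#' Fractional methylation at one bond (score C)
#'
#' Compares the cleavage count at bond `i` with a weighted average of its
#' flanking bonds: with linearly decaying weights `lambda_j = (k - j + 1)/k`,
#' `w_i = sum_j lambda_j (n_{i-j} + n_{i+j}) / (2 sum_j lambda_j)`
#' (out-of-range neighbours are dropped and the weights renormalised), and
#' `score = max(0, 1 - n_i / w_i)`. A methylated ribose protects its 3' bond
#' from alkaline cleavage, so a dip relative to the local background reads out
#' the fraction of molecules methylated.
#'
#' @param n Per-bond count vector (from [bond_end_counts()]).
#' @param i Bond index; must have at least one in-range flanking bond on each
#'   side (`2 <= i <= length(n) - 1`).
#' @param k Flank half-width (default 6).
#' @param min_coverage Coverage floor: if the unweighted mean flank count is
#'   below this, the score is reported missing (`NA`) because the ratio is
#'   unstable at low depth.
#' @return A score in `[0, 1]`, or `NA` below the coverage floor.
#' @export
score_c <- function(n, i, k = 6, min_coverage = 10) {
  if (k < 1) stop("`k` must be >= 1")
  if (i < 2 || i > length(n) - 1)
    stop("bond index ", i, " needs at least one flanking bond on each side")
  s <- .score_c_one(n, i, k)
  if (s$flank_mean < min_coverage || s$w == 0) return(NA_real_)
  max(0, 1 - n[i] / s$w)
}

#' Score every catalogued site in a profile
#'
#' The score for a site at nucleotide `p` is computed at the bond between
#' nucleotides `p` and `p + 1` (methylation of the ribose at `p` protects its
#' 3' bond). All computation uses local (mouse-numbering) coordinates; the
#' human-numbering alias in the catalog is display-only.
#'
#' @param profile End-count data frame (may span several molecules).
#' @param catalog Site catalog data frame with columns `site_id`, `molecule`,
#'   `position_local` (see [site_catalog()]).
#' @param k Flank half-width passed to [score_c()].
#' @param min_coverage Coverage floor passed to [score_c()].
#' @param sample Sample label recorded in the output.
#' @return Data frame with one row per catalog site: `site_id`, `molecule`,
#'   `position`, `score`, `coverage_flag` (`"ok"` or `"low_coverage"`),
#'   `sample`.
#' @export
score_catalog <- function(profile, catalog, k = 6, min_coverage = 10,
                          sample = "sample1") {
  if (nrow(catalog) == 0) {
    return(data.frame(site_id = character(), molecule = character(),
                      position = integer(), score = numeric(),
                      coverage_flag = character(), sample = character(),
                      stringsAsFactors = FALSE))
  }
  bonds <- bond_end_counts(profile)
  if (!is.list(bonds)) {
    bonds <- stats::setNames(list(bonds), unique(profile$molecule))
  }
  missing_mol <- setdiff(unique(catalog$molecule), names(bonds))
  if (length(missing_mol))
    stop("catalog molecules absent from profile: ",
         paste(missing_mol, collapse = ", "))
  score <- numeric(nrow(catalog))
  flag <- character(nrow(catalog))
  for (r in seq_len(nrow(catalog))) {
    n <- bonds[[catalog$molecule[r]]]
    pos <- catalog$position_local[r]
    if (pos < 2 || pos > length(n) - 1)
      stop("site ", catalog$site_id[r], " outside scorable range of molecule ",
           catalog$molecule[r])
    score[r] <- score_c(n, pos, k = k, min_coverage = min_coverage)
    flag[r] <- if (is.na(score[r])) "low_coverage" else "ok"
  }
  data.frame(site_id = catalog$site_id, molecule = catalog$molecule,
             position = catalog$position_local, score = score,
             coverage_flag = flag, sample = sample, stringsAsFactors = FALSE)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count Mapped read count(s) (non-negative).
#' @param length_nt Transcript length in nucleotides (positive).
#' @param total_mapped Library size in mapped reads (positive).
#' @return `count / ((length_nt / 1000) * (total_mapped / 1e6))`, vectorised.
#' @export
rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("`length_nt` must be positive")
  if (any(total_mapped <= 0)) stop("`total_mapped` must be positive")
  if (any(count < 0)) stop("`count` must be non-negative")
  count / ((length_nt / 1000) * (total_mapped / 1e6))
}
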