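#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one top-level seed. Independent
#' streams (per molecule, per replicate, per simulation round) are derived
#' deterministically from that seed and a stream index, so partial re-runs
#' reproduce the same draws.
#'
#' @param seed Integer top-level seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # Lehmer-style mix; operands stay well below 2^53 so the arithmetic is exact
  as.integer(((abs(seed) %% 2147483647) * 48271 + index) %% 2147483647)
}

#' Simulation configuration for alkaline-fragmentation end counts
#'
#' @param depth Expected cleavage events per unprotected bond (positive).
#' @param protection Efficiency in `[0, 1]` with which methylation suppresses
#'   cleavage at the bond 3' of the methylated ribose. The default 1 means a
#'   fully methylated molecule is never cleaved at that bond, so score C reads
#'   out the fraction of molecules methylated.
#' @param bias_sd Standard deviation (log scale) of the log-normal positional
#'   cleavage bias track.
#' @param bias_smoothness Width (in bonds) of the centred moving-average
#'   smoother applied to the bias track; 0 or 1 disables smoothing. Score C
#'   assumes locally smooth background cleavage, so this is an explicit knob.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(depth = 1000, protection = 1, bias_sd = 0.2,
                       bias_smoothness = 5, seed = 1L) {
  if (!is.numeric(depth) || depth <= 0) stop("`depth` must be positive")
  if (!is.numeric(protection) || protection < 0 || protection > 1)
    stop("`protection` must be in [0, 1]")
  if (!is.numeric(bias_sd) || bias_sd < 0) stop("`bias_sd` must be >= 0")
  if (bias_smoothness < 0 || bias_smoothness != round(bias_smoothness))
    stop("`bias_smoothness` must be a non-negative integer")
  structure(list(depth = depth, protection = protection, bias_sd = bias_sd,
                 bias_smoothness = as.integer(bias_smoothness),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Smoothed, median-1 log-normal bias track over n_bonds bonds.
# Edges that the centred window cannot cover keep their raw values.
.bias_track <- function(n_bonds, bias_sd, bias_smoothness) {
  if (bias_sd == 0) return(rep(1, n_bonds))
  b <- stats::rlnorm(n_bonds, meanlog = 0, sdlog = bias_sd)
  w <- bias_smoothness
  if (w >= 2) {
    sm <- as.numeric(stats::filter(b, rep(1 / w, w), sides = 2))
    b <- ifelse(is.na(sm), b, sm)
  }
  b / stats::median(b)
}

#' Simulate a RiboMeth-seq read-end count profile
#'
#' Models alkaline fragmentation of a molecule whose catalogued sites are
#' methylated at ground-truth fractions `m`. The cleavage count at the bond 3'
#' of nucleotide `i` is Poisson with mean
#' `depth * b_i * (1 - protection * m_i)`, where `b` is a smoothed log-normal
#' bias track with median 1. Each cleavage event is observed as either the 3'
#' end of the upstream fragment (recorded at position `i`) or the 5' end of
#' the downstream fragment (recorded at `i + 1`), chosen by a fair Bernoulli
#' split, so [bond_end_counts()] recovers the per-bond event count exactly.
#'
#' @param ref_length Molecule length in nucleotides (`>= 13`, i.e. at least
#'   twice the default flank half-width plus one).
#' @param truth Data frame with columns `position` (1-based nucleotide, must
#'   be `< ref_length`) and `m` (ground-truth methylated fraction in
#'   `[0, 1]`). Positions absent from `truth` have `m = 0`.
#' @param cfg A [sim_config()].
#' @param molecule Molecule identifier used in the output tables.
#' @return A list with `profile` (data frame `molecule`, `position`,
#'   `end5_count`, `end3_count`, one row per nucleotide) and `truth` (data
#'   frame `molecule`, `position`, `m_true`), serialising the ground truth
#'   alongside the counts.
#' @export
simulate_end_counts <- function(ref_length, truth, cfg = sim_config(),
                                molecule = "mol") {
  stopifnot(inherits(cfg, "sim_config"))
  ref_length <- as.integer(ref_length)
  if (ref_length < 13L)
    stop("`ref_length` too small: need >= 13 nt (2 * flank half-width + 1)")
  if (is.null(truth)) truth <- data.frame(position = integer(), m = numeric())
  stopifnot(all(c("position", "m") %in% names(truth)))
  if (any(truth$m < 0 | truth$m > 1)) stop("ground-truth `m` outside [0, 1]")
  if (any(truth$position < 1 | truth$position >= ref_length))
    stop("catalog positions must lie in [1, ref_length - 1]")
  if (anyDuplicated(truth$position)) stop("duplicated positions in `truth`")

  n_bonds <- ref_length - 1L
  m <- numeric(n_bonds)
  m[truth$position] <- truth$m

  set.seed(cfg$seed)
  b <- .bias_track(n_bonds, cfg$bias_sd, cfg$bias_smoothness)
  n <- stats::rpois(n_bonds, cfg$depth * b * (1 - cfg$protection * m))
  x3 <- stats::rbinom(n_bonds, n, 0.5)

  end3 <- integer(ref_length)
  end5 <- integer(ref_length)
  end3[seq_len(n_bonds)] <- x3
  end5[seq_len(n_bonds) + 1L] <- n - x3

  list(
    profile = data.frame(molecule = molecule, position = seq_len(ref_length),
                         end5_count = end5, end3_count = end3,
                         stringsAsFactors = FALSE),
    truth = data.frame(molecule = rep(molecule, nrow(truth)),
                       position = truth$position, m_true = truth$m,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate a multi-molecule, multi-replicate RMS dataset
#'
#' Convenience wrapper around [simulate_end_counts()] for a site catalog
#' spanning several molecules. Each (replicate, molecule) pair draws from its
#' own sub-stream derived from `cfg$seed` via [derive_seed()].
#'
#' @param catalog Site catalog (see [site_catalog()]); `position_local` is the
#'   1-based mouse-numbering coordinate used for simulation.
#' @param m Named numeric vector of ground-truth methylated fractions keyed by
#'   `site_id` (sites omitted default to 0).
#' @param n_replicates Number of replicate profiles.
#' @param cfg A [sim_config()].
#' @param ref_lengths Named vector of molecule lengths; defaults to
#'   `max(position) + 50` per molecule.
#' @return A list with `profiles` (list of per-replicate end-count data
#'   frames) and `truth` (data frame `molecule`, `position`, `m_true`).
#' @export
simulate_rms_samples <- function(catalog, m, n_replicates = 3,
                                 cfg = sim_config(), ref_lengths = NULL) {
  mols <- unique(catalog$molecule)
  if (is.null(ref_lengths)) {
    ref_lengths <- vapply(mols, function(mo)
      max(catalog$position_local[catalog$molecule == mo]) + 50L, integer(1))
  }
  m_all <- stats::setNames(numeric(nrow(catalog)), catalog$site_id)
  m_all[names(m)] <- m
  truths <- lapply(mols, function(mo) {
    idx <- catalog$molecule == mo
    data.frame(position = catalog$position_local[idx],
               m = unname(m_all[catalog$site_id[idx]]))
  })
  names(truths) <- mols
  profiles <- lapply(seq_len(n_replicates), function(r) {
    parts <- lapply(seq_along(mols), function(j) {
      sub <- sim_config(cfg$depth, cfg$protection, cfg$bias_sd,
                        cfg$bias_smoothness,
                        seed = derive_seed(cfg$seed, r * 1000L + j))
      simulate_end_counts(ref_lengths[[mols[j]]], truths[[mols[j]]], sub,
                          molecule = mols[j])$profile
    })
    do.call(rbind, parts)
  })
  truth <- do.call(rbind, lapply(mols, function(mo)
    data.frame(molecule = mo, position = truths[[mo]]$position,
               m_true = truths[[mo]]$m, stringsAsFactors = FALSE)))
  list(profiles = profiles, truth = truth)
}

#' Simulate a negative-binomial SNORD count matrix with planted fold changes
#'
#' Counts are drawn NB with mean `mu` and variance `mu + dispersion * mu^2`
#' (`dispersion = 0` gives the Poisson limit). Genes in `de_index` have their
#' group-2 mean multiplied by `2^lfc`.
#'
#' @param n_snords Number of genes (rows).
#' @param n_group1,n_group2 Samples per group (each `>= 2`).
#' @param base_mean Expected count per gene (scalar or length-`n_snords`).
#' @param dispersion NB dispersion (`>= 0`).
#' @param de_index Integer indices of differentially expressed genes.
#' @param lfc Planted log2 fold change (group 2 vs group 1); scalar or one
#'   value per element of `de_index`.
#' @param seed Integer RNG seed.
#' @param names Optional row names; defaults to zero-padded `SNORD_simNNN`.
#' @return List with `counts` (matrix genes x samples), `groups` (factor with
#'   levels `group1`, `group2`) and `is_de` (logical truth labels).
#' @export
simulate_snord_counts <- function(n_snords, n_group1, n_group2, base_mean,
                                  dispersion, de_index = integer(), lfc = 0,
                                  seed = 1L, names = NULL) {
  if (n_group1 < 2 || n_group2 < 2) stop("each group needs >= 2 samples")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (any(base_mean <= 0)) stop("`base_mean` must be positive")
  de_index <- as.integer(de_index)
  if (length(de_index) && (min(de_index) < 1 || max(de_index) > n_snords))
    stop("`de_index` out of range")
  lfc <- rep_len(lfc, max(1L, length(de_index)))

  mu1 <- rep_len(base_mean, n_snords)
  mu2 <- mu1
  mu2[de_index] <- mu1[de_index] * 2^lfc[seq_along(de_index)]
  mu <- cbind(matrix(mu1, n_snords, n_group1),
              matrix(mu2, n_snords, n_group2))

  set.seed(seed)
  counts <- if (dispersion == 0) {
    matrix(stats::rpois(length(mu), mu), n_snords)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_snords)
  }
  if (is.null(names))
    names <- sprintf("SNORD_sim%03d", seq_len(n_snords))
  rownames(counts) <- names
  colnames(counts) <- c(sprintf("group1_s%d", seq_len(n_group1)),
                        sprintf("group2_s%d", seq_len(n_group2)))
  groups <- factor(rep(c("group1", "group2"), c(n_group1, n_group2)),
                   levels = c("group1", "group2"))
  is_de <- rep(FALSE, n_snords)
  is_de[de_index] <- TRUE
  names(is_de) <- names
  list(counts = counts, groups = groups, is_de = is_de)
}

#' Simulate a coding-sequence set with controlled codon bias
#'
#' Every sequence is the start codon `ATG` followed by `n_codons - 1` codons
#' drawn i.i.d. from the normalised `codon_weights`, so the post-start codon
#' composition (the region [codon_freq()] analyses) follows the weights.
#'
#' @param n Number of sequences.
#' @param n_codons Total codons per sequence including the start (`>= 2`).
#' @param codon_weights Non-negative 64-vector named by the codons of
#'   [codons()] (DNA alphabet, lower case). Unnamed vectors are taken in
#'   [codons()] order.
#' @param seed Integer RNG seed.
#' @return A named [Biostrings::DNAStringSet] (`cds_0001`, ...).
#' @export
simulate_cds_set <- function(n, n_codons, codon_weights, seed = 1L) {
  if (n_codons < 2) stop("`n_codons` must be >= 2")
  all64 <- codons()
  if (is.null(names(codon_weights))) {
    if (length(codon_weights) != 64) stop("expected a 64-codon weight vector")
    names(codon_weights) <- all64
  }
  w <- stats::setNames(numeric(64), all64)
  w[names(codon_weights)] <- codon_weights
  if (any(w < 0)) stop("codon weights must be non-negative")
  if (sum(w) <= 0) stop("all-zero codon weights")
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(sample(all64, n_codons - 1L, replace = TRUE,
                               prob = w), collapse = ""))
  }, character(1))
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- sprintf("cds_%04d", seq_len(n))
  out
}
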