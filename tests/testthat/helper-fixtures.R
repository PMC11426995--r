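# Shared fixture builders for the test suite.

# End-count profile whose per-bond counts are exactly `n` (all events
# recorded as 3' ends, none as 5' ends).
profile_from_bonds <- function(n, molecule = "mol") {
  L <- length(n) + 1L
  data.frame(molecule = molecule, position = seq_len(L),
             end5_count = 0L, end3_count = c(as.integer(n), 0L),
             stringsAsFactors = FALSE)
}

rc_rna <- function(x) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

random_rna <- function(n, rng_blacklist = NULL) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Build a box C/D guide whose D-box antisense element is the reverse
# complement of target[window_start .. window_start + duplex_len - 1].
# Returns the guide sequence (RNA).
make_guide <- function(target, window_start, duplex_len) {
  window <- substr(target, window_start, window_start + duplex_len - 1L)
  ase <- rc_rna(window)
  # spacer between box C and the ASE, free of CUGA by construction
  paste0("GG", "AUGAUGA", paste(rep("A", 15), collapse = ""), ase, "CUGA",
         "GG")
}

# Random (target, window, guide) construction for the fifth-nucleotide-rule
# recovery property. Windows whose reverse complement would itself contain a
# CUGA (i.e. introduce a spurious internal box D') are redrawn, since such a
# guide has a genuinely different box architecture.
draw_guide_pair <- function(target_len = 300, duplex_range = 10:14) {
  repeat {
    tgt <- random_rna(target_len)
    ws <- sample(30:(target_len - 20), 1)
    dl <- sample(duplex_range, 1)
    ase <- rc_rna(substr(tgt, ws, ws + dl - 1L))
    if (!grepl("CUGA", ase, fixed = TRUE)) {
      return(list(target = tgt, window_start = ws, duplex_len = dl,
                  guide = make_guide(tgt, ws, dl)))
    }
  }
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n1 + n2, n1) group assignments (tie-free data assumed).
wilcox_exact_enum <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of x
  combs <- utils::combn(length(ranks), n1)
  us <- apply(combs, 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= obs)
  hi <- mean(us >= obs)
  min(1, 2 * min(lo, hi))
}

# Uniform weights over the 61 sense codons.
sense_weights <- function() {
  w <- stats::setNames(rep(1, 64), codons())
  w[c("taa", "tag", "tga")] <- 0
  w
}
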