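.clamp01 <- function(x) pmin(1, pmax(0, x))

.load_catalog <- function(spec) {
  if (identical(spec, "builtin")) site_catalog()
  else if (identical(spec, "mini")) mini_site_catalog()
  else site_catalog(spec)
}

# site x replicate score matrix from per-replicate score_catalog outputs
.score_matrix <- function(tabs, site_ids) {
  m <- vapply(tabs, function(t) t$score[match(site_ids, t$site_id)],
              numeric(length(site_ids)))
  rownames(m) <- site_ids
  colnames(m) <- vapply(tabs, function(t) t$sample[1], character(1))
  m
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> score -> differential methylation (-> SNORD
#' differential expression and matching -> codon comparison) under a single
#' seeded configuration, writing every result as TSV plus a resolved copy of
#' the configuration and a timing log into `out_dir`. All randomness derives
#' from `config$seed`, so re-running with the same configuration reproduces
#' every output byte-for-byte (the timing log is the only non-deterministic
#' file and is excluded from the returned checksums).
#'
#' The default methylation stage simulates two datasets emulating the study
#' design — a whole-muscle comparison (unpaired test) and a second,
#' myofiber-specific dataset — with a configurable set of sites planted at
#' `baseline_m + planted_delta` in the overloaded condition, then intersects
#' the two significant-site sets.
#'
#' @param config Configuration list as produced by [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `out_dir`, `files` (written data files), `checksums`
#'   (named md5 strings, log excluded), `comparison`, `comparison2`,
#'   `overlap`, `snord_de`, `matches`, `codon`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.null(config$seed)) config$seed <- 1L
  config <- merge_validate(default_run_config(config$seed), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- c(sprintf("ribometh pipeline, seed %d", seed))
  t_stage <- function(label, t0) sprintf("%-12s %.2f s", label,
                                         as.numeric(Sys.time()) - t0)
  files <- character()
  out <- function(name) file.path(out_dir, name)
  comparison <- comparison2 <- overlap <- de <- matches <- cc <- NULL

  if (isTRUE(config$stages$methylation)) {
    t0 <- as.numeric(Sys.time())
    catalog <- .load_catalog(config$rms_sim$catalog)
    rs <- config$rms_sim
    m_sham <- stats::setNames(rep(rs$baseline_m, nrow(catalog)),
                              catalog$site_id)
    m_mov <- m_sham
    planted <- intersect(rs$planted_sites, catalog$site_id)
    m_mov[planted] <- .clamp01(m_mov[planted] + rs$planted_delta)

    datasets <- if (isTRUE(rs$second_dataset)) c("muscle", "ribotag")
                else "muscle"
    comps <- list()
    for (d in seq_along(datasets)) {
      mats <- list()
      for (cond_i in 1:2) {
        cond <- c("sham", "mov")[cond_i]
        cfg <- sim_config(rs$depth, rs$protection, rs$bias_sd,
                          rs$bias_smoothness,
                          seed = derive_seed(seed, d * 100L + cond_i * 10L))
        sim <- simulate_rms_samples(catalog,
                                    if (cond == "sham") m_sham else m_mov,
                                    n_replicates = rs$n_replicates, cfg = cfg)
        tabs <- lapply(seq_along(sim$profiles), function(r)
          score_catalog(sim$profiles[[r]], catalog, k = config$scoring$k,
                        min_coverage = config$scoring$min_coverage,
                        sample = sprintf("%s_%s_r%d", datasets[d], cond, r)))
        write_tsv(do.call(rbind, tabs),
                  out(sprintf("scores_%s_%s.tsv", datasets[d], cond)))
        files <- c(files, sprintf("scores_%s_%s.tsv", datasets[d], cond))
        mats[[cond]] <- .score_matrix(tabs, catalog$site_id)
        if (d == 1L) {
          tr <- sim$truth
          names(tr)[names(tr) == "m_true"] <- paste0("m_", cond)
          write_tsv(tr, out(sprintf("truth_%s.tsv", cond)))
          files <- c(files, sprintf("truth_%s.tsv", cond))
        }
      }
      paired <- d == 2L && isTRUE(config$diffmeth$paired_second)
      comps[[d]] <- compare_score_tables(
        mats$sham, mats$mov, paired = paired,
        alpha = config$diffmeth$alpha,
        sharp_threshold = config$diffmeth$sharp_threshold,
        nonmeth_eps = config$diffmeth$nonmeth_eps)
      write_tsv(comps[[d]], out(sprintf("comparison_%s.tsv", datasets[d])))
      files <- c(files, sprintf("comparison_%s.tsv", datasets[d]))
    }
    comparison <- comps[[1L]]
    if (length(comps) > 1L) {
      comparison2 <- comps[[2L]]
      overlap <- intersect_significant(
        comparison$site_id[comparison$significant],
        comparison2$site_id[comparison2$significant], catalog)
      write_tsv(data.frame(site_id = overlap), out("overlap_sites.tsv"))
      files <- c(files, "overlap_sites.tsv")
    }

    sig <- comparison$site_id[comparison$significant]
    cl_tab <- data.frame(site_id = character(), order = integer(),
                         cluster = integer())
    if (length(sig) >= 2) {
      # replicate-level matrix for the significant sites of dataset 1
      tabs1 <- read_tsv(out("scores_muscle_sham.tsv"))
      tabs2 <- read_tsv(out("scores_muscle_mov.tsv"))
      long <- rbind(tabs1, tabs2)
      wide <- stats::reshape(long[, c("site_id", "sample", "score")],
                             idvar = "site_id", timevar = "sample",
                             direction = "wide")
      rn <- wide$site_id
      wide <- as.matrix(wide[, -1, drop = FALSE])
      rownames(wide) <- rn
      wide <- wide[sig, , drop = FALSE]
      wide <- wide[stats::complete.cases(wide), , drop = FALSE]
      if (nrow(wide) >= 2) {
        cl <- suppressWarnings(hcluster(wide))
        if (!is.null(cl$hclust)) {
          ct <- stats::cutree(cl$hclust, k = min(2L, nrow(cl$matrix)))
          cl_tab <- data.frame(site_id = cl$row_order,
                               order = seq_along(cl$row_order),
                               cluster = unname(ct[cl$row_order]))
        }
      }
    }
    write_tsv(cl_tab, out("clusters.tsv"))
    files <- c(files, "clusters.tsv")
    log_lines <- c(log_lines, t_stage("methylation", t0))
  }

  if (isTRUE(config$stages$snord)) {
    t0 <- as.numeric(Sys.time())
    sc <- snord_target_catalog()
    ss <- config$snord_sim
    gene_names <- c(sc$snord,
                    sprintf("SNORD_sim%03d",
                            seq_len(max(0L, ss$n_snords - nrow(sc)))))
    de_index <- match(ss$planted_snords, gene_names)
    sim <- simulate_snord_counts(length(gene_names), ss$n_group1, ss$n_group2,
                                 ss$base_mean, ss$dispersion,
                                 de_index = de_index, lfc = ss$planted_lfc,
                                 seed = derive_seed(seed, 7L),
                                 names = gene_names)
    de <- diff_expression(sim$counts, sim$groups, min_total = ss$min_total,
                          alpha = ss$alpha, lfc_threshold = ss$lfc_threshold)
    write_tsv(cbind(data.frame(gene = rownames(sim$counts)),
                    as.data.frame(sim$counts)), out("snord_counts.tsv"))
    write_tsv(de, out("snord_de.tsv"))
    files <- c(files, "snord_counts.tsv", "snord_de.tsv")
    if (!is.null(comparison)) {
      matches <- match_snords_to_sites(de, comparison, sc)
      write_tsv(matches, out("snord_site_matches.tsv"))
      files <- c(files, "snord_site_matches.tsv")
    }
    log_lines <- c(log_lines, t_stage("snord", t0))
  }

  if (isTRUE(config$stages$codon)) {
    t0 <- as.numeric(Sys.time())
    cs <- config$codon_sim
    w <- stats::setNames(rep(1, 64), codons())
    w[c("taa", "tag", "tga")] <- 0
    w_set <- w
    w_set[cs$boosted_codon] <- w_set[cs$boosted_codon] * cs$boost
    set_seqs <- simulate_cds_set(cs$n_set, cs$n_codons, w_set,
                                 seed = derive_seed(seed, 8L))
    bg_seqs <- simulate_cds_set(cs$n_background, cs$n_codons, w,
                                seed = derive_seed(seed, 9L))
    cc <- compare_sets(codon_profiles(set_seqs), codon_profiles(bg_seqs),
                       k = cs$top_k)
    write_tsv(cc$codons, out("codon_comparison.tsv"))
    write_tsv(data.frame(median_set = cc$gc$median_set,
                         median_bg = cc$gc$median_bg, diff = cc$gc$diff,
                         p = cc$gc$p), out("codon_gc.tsv"))
    files <- c(files, "codon_comparison.tsv", "codon_gc.tsv")
    log_lines <- c(log_lines, t_stage("codon", t0))
  }

  yaml::write_yaml(config, out("resolved_config.yaml"))
  files <- c(files, "resolved_config.yaml")
  writeLines(log_lines, out("log.txt"))

  sums <- tools::md5sum(file.path(out_dir, sort(files)))
  names(sums) <- sort(files)
  list(out_dir = out_dir, files = files, checksums = sums,
       comparison = comparison, comparison2 = comparison2, overlap = overlap,
       snord_de = de, matches = matches, codon = cc)
}
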