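#' Packaged mouse rRNA 2'-O-Me site catalog
#'
#' Loads the bundled catalog of 108 mouse rRNA 2'-O-methylation sites, or a
#' user-supplied TSV with the same columns. Site identifiers follow the
#' human-numbering display convention (e.g. `SSU-C1272`: small subunit 18S,
#' cytidine, position 1272). The bundled file is a synthetic stand-in for a
#' full published catalog: the 30 sites reported as differentially methylated
#' after 7 days of mechanical overload carry their published identifiers,
#' while the remaining 78 rows are synthetic placeholder sites (and the
#' local mouse coordinates are set equal to the human-numbering aliases).
#'
#' @param path Optional path to a catalog TSV with columns `site_id`,
#'   `molecule`, `position_local`, `position_human`, `nucleotide`,
#'   `guide_snords` (comma-separated, possibly empty).
#' @return Data frame with one row per site; `site_id` is unique.
#' @export
site_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mouse_2ome_sites_synthetic.tsv",
                        package = "ribometh", mustWork = TRUE)
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("site_id", "molecule", "position_local", "position_human",
            "nucleotide", "guide_snords")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  cat$position_local <- as.integer(cat$position_local)
  cat$position_human <- as.integer(cat$position_human)
  if (anyDuplicated(cat$site_id))
    stop("duplicate site_id in catalog: ",
         cat$site_id[duplicated(cat$site_id)][1])
  if (!all(cat$nucleotide %in% c("A", "C", "G", "U")))
    stop("nucleotide must be one of A, C, G, U")
  cat
}

#' Compact catalog subset for small simulation studies
#'
#' A 24-site subset of [site_catalog()]: the seven sites found differentially
#' methylated in both whole-muscle and myofiber-specific (RiboTag) datasets,
#' plus 17 additional well-separated sites that act as nulls in planted
#' simulations.
#'
#' @return Data frame in [site_catalog()] format.
#' @export
mini_site_catalog <- function() {
  cat <- site_catalog()
  keep <- ribotag_overlap_sites()
  rest <- cat$site_id[!cat$site_id %in% keep]
  cat <- cat[cat$site_id %in% c(keep, rest[seq(1, length(rest),
                                               length.out = 17)]), ]
  rownames(cat) <- NULL
  cat
}

#' Packaged SNORD-to-target-site catalog
#'
#' Links box C/D snoRNA guides to the rRNA 2'-O-Me sites they direct. The
#' bundled file covers the ten SNORDs with significantly altered myonuclear
#' expression after 3 days of mechanical overload; the SNORD66 -> SSU-C1272
#' and SNORD78 -> LSU-G4593 pairings are as published, the remaining target
#' assignments are synthetic placeholders.
#'
#' @param path Optional path to a TSV with columns `snord`, `site_id`,
#'   `host_gene`.
#' @return Data frame with one row per (SNORD, target site) pair.
#' @export
snord_target_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snord_targets_synthetic.tsv",
                        package = "ribometh", mustWork = TRUE)
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snord", "site_id", "host_gene")
  if (!all(need %in% names(cat)))
    stop("SNORD catalog must have columns ", paste(need, collapse = ", "))
  cat
}

#' Published 7-day overload change-type site lists
#'
#' The three change-type categories reported for whole-muscle rRNA after 7
#' days of mechanical overload: 7 sites with sharply decreased methylation
#' (>= 0.15 drop in RMS score), 22 with slightly decreased methylation and 1
#' with a gain from non-methylation, 30 sites in total.
#'
#' @return Data frame with columns `site_id` and `category`.
#' @export
mov7d_changed_sites <- function() {
  path <- system.file("extdata", "mov7d_changed_sites.tsv",
                      package = "ribometh", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Sites differentially methylated in both whole-muscle and RiboTag datasets
#'
#' The seven sites with decreased methylation shared between the whole-muscle
#' 7-day overload comparison and the myofiber-specific (RiboTag) comparison.
#'
#' @return Character vector of site identifiers.
#' @export
ribotag_overlap_sites <- function() {
  c("SSU-U121", "SSU-G436", "SSU-G867", "SSU-U1804",
    "LSU-G1303", "LSU-A4541", "5.8S-U14")
}
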