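#' Ulcerative-colitis signature genes
#'
#' UC versus normal colon (UC biopsies are colonic) using the same adaptive
#' test and CI non-overlap machinery as the CD comparisons: a gene is in the
#' signature when `p <= alpha_sig` and the 95% CIs are disjoint. Comparing
#' UC to the pooled controls (NMC + NMI) is available behind a flag.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata including UC samples.
#' @param cfg An [analysis_config()].
#' @param pooled_controls Compare UC to NMC and NMI pooled (default FALSE).
#' @return Character vector of UC signature gene ids.
#' @export
uc_signature <- function(m, meta, cfg = analysis_config(),
                         pooled_controls = FALSE) {
  if (!"UC" %in% meta$group) stop("UC group absent from metadata")
  if (pooled_controls) {
    meta2 <- meta
    meta2$group[meta2$group %in% c("NMC", "NMI")] <- "NMC"
    meta2$tissue[meta2$group == "NMC"] <- "colon"
    meta <- meta2
  }
  res <- run_comparison(m, meta, "UC", "NMC", cfg)
  res$gene_id[pass_flag(res)]
}

#' Remove UC-shared characteristics from CCG/ICG candidate sets
#'
#' Plain set algebra: retained sets are the candidates minus the UC
#' signature; shared sets are the intersections. The IBD-common set
#' (UC signature genes also in CCG, ICG or CD-common) is reported for
#' description only and does not affect retention.
#'
#' @param ccg,icg Character vectors of candidate gene ids.
#' @param uc UC signature gene ids.
#' @param cd_common Optional CD-common gene ids (for the descriptive
#'   IBD-common set).
#' @return A list of class `uc_filtration_result` with elements `uc_degs`,
#'   `shared_with_ccg`, `shared_with_icg`, `ibd_common`, `retained_ccg`,
#'   `retained_icg`.
#' @export
filter_uc <- function(ccg, icg, uc, cd_common = character(0)) {
  ccg <- unique(as.character(ccg)); icg <- unique(as.character(icg))
  uc <- unique(as.character(uc))
  structure(list(
    uc_degs = uc,
    shared_with_ccg = intersect(uc, ccg),
    shared_with_icg = intersect(uc, icg),
    ibd_common = intersect(uc, union(union(ccg, icg), cd_common)),
    retained_ccg = setdiff(ccg, uc),
    retained_icg = setdiff(icg, uc)
  ), class = "uc_filtration_result")
}

#' Write a UC filtration result: gene-set files plus a size summary JSON
#' @param res A `uc_filtration_result`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_uc_filtration <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(res)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(res[[nm]], p)
    paths[nm] <- p
  }
  sp <- file.path(dir, "uc_filtration_summary.json")
  jsonlite::write_json(lapply(res, length), sp, auto_unbox = TRUE)
  paths["summary"] <- sp
  invisible(paths)
}
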