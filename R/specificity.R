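COMPARISONS <- list(CCDvsNMC = c("CCD", "NMC"), ICDvsNMI = c("ICD", "NMI"),
                    CCDvsICD = c("CCD", "ICD"), NMCvsNMI = c("NMC", "NMI"))

#' Run the four standard pairwise comparisons
#'
#' CCD vs NMC, ICD vs NMI, CCD vs ICD, and NMC vs NMI, each with the adaptive
#' test and CI non-overlap filter applied.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata (all four non-UC groups present).
#' @param cfg An [analysis_config()].
#' @param prefilter Passed through to [run_comparison()].
#' @return Named list of four `comparison_result` tables.
#' @export
build_comparison_set <- function(m, meta, cfg = analysis_config(),
                                 prefilter = FALSE) {
  missing <- setdiff(c("CCD", "ICD", "NMC", "NMI"), unique(meta$group))
  if (length(missing)) stop("missing group(s): ", paste(missing, collapse = ", "))
  lapply(COMPARISONS, function(pair) {
    run_comparison(m, meta, pair[1], pair[2], cfg, prefilter = prefilter)
  })
}

pass_flag <- function(tab) tab$is_deg & tab$is_ci_disjoint

# The six admissible subsets of passed comparisons that distinguish CCD from
# ICD: every case contains CCDvsICD plus at least one disease-vs-control pass.
venn_case_ok <- function(p12, p13, p14) p12 & (p13 | p14)

#' Classify genes as colonic-CD (CCG), ileal-CD (ICG) or CD-common
#'
#' The candidate pool is the set of genes passing the DEG + CI filter in
#' CCD vs ICD that fall in one of the six admissible intersection cases
#' (the pass must be accompanied by at least one disease-vs-control pass).
#' Within the pool the dual-threshold criteria apply: a CCG needs
#' `p(CCDvsICD) <= alpha_sig`, `p(CCDvsNMC) <= alpha_sig` (both CI-disjoint)
#' and `p(ICDvsNMI) > alpha_ns`; an ICG mirrors this. Genes in the
#' `(alpha_sig, alpha_ns]` buffer on the "no difference" comparison belong to
#' neither class. Independently, genes passing both disease-vs-control
#' comparisons (p and CI) are labeled CD-common.
#'
#' @param tables The four comparison tables from [build_comparison_set()].
#' @param cfg An [analysis_config()].
#' @return A data.frame of class `gene_class_assignment` with columns
#'   gene_id, gene_class (CCG/ICG/CD_common/none), venn_case
#'   (comma-separated passed comparisons), and the four p-values.
#' @export
classify_tissue_specific <- function(tables, cfg = analysis_config()) {
  need <- names(COMPARISONS)
  if (!all(need %in% names(tables))) stop("need all four comparison tables")
  ids <- tables[[1]]$gene_id
  for (t in tables[need]) {
    if (!identical(t$gene_id, ids)) stop("comparison tables disagree on gene universe")
  }
  p <- lapply(tables[need], `[[`, "p_value")
  pass <- lapply(tables[need], pass_flag)
  in_pool <- venn_case_ok(pass$CCDvsICD, pass$CCDvsNMC, pass$ICDvsNMI)

  ccg <- in_pool & pass$CCDvsICD & pass$CCDvsNMC & p$ICDvsNMI > cfg$alpha_ns
  icg <- in_pool & pass$CCDvsICD & pass$ICDvsNMI & p$CCDvsNMC > cfg$alpha_ns
  common <- pass$CCDvsNMC & pass$ICDvsNMI & !ccg & !icg

  cls <- rep("none", length(ids))
  cls[common] <- "CD_common"
  cls[icg] <- "ICG"
  cls[ccg] <- "CCG"

  pass_mat <- cbind(pass$CCDvsNMC, pass$ICDvsNMI, pass$CCDvsICD, pass$NMCvsNMI)
  venn <- apply(pass_mat, 1, function(fl) paste(need[fl], collapse = ","))

  out <- data.frame(gene_id = ids, gene_class = cls, venn_case = venn,
                    p_CCDvsNMC = p$CCDvsNMC, p_ICDvsNMI = p$ICDvsNMI,
                    p_CCDvsICD = p$CCDvsICD, p_NMCvsNMI = p$NMCvsNMI,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_class_assignment", class(out))
  out
}

#' Export gene lists per class
#' @param assignment Result of [classify_tissue_specific()].
#' @param dir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_gene_classes <- function(assignment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(assignment, file.path(dir, "gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(table = file.path(dir, "gene_classes.tsv"))
  for (cl in c("CCG", "ICG", "CD_common")) {
    p <- file.path(dir, paste0(tolower(cl), "_genes.txt"))
    writeLines(assignment$gene_id[assignment$gene_class == cl], p)
    paths[cl] <- p
  }
  invisible(paths)
}
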