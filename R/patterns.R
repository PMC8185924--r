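#' Per-group median and quartiles for a set of genes
#'
#' @param m Expression matrix.
#' @param meta Sample metadata.
#' @param genes Gene ids (must be rows of `m`).
#' @param groups Groups to summarize (default the four CD/control groups).
#' @return A data.frame with one row per gene and columns
#'   `<group>_median`, `<group>_q25`, `<group>_q75`.
#' @export
summarize_groups <- function(m, meta, genes = rownames(m),
                             groups = c("CCD", "NMC", "ICD", "NMI")) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (g in groups) {
    ids <- group_samples(meta, g)
    sub <- m[genes, ids, drop = FALSE]
    qs <- t(apply(sub, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                  type = 7))
    out[[paste0(g, "_q25")]] <- unname(qs[, 1])
    out[[paste0(g, "_median")]] <- unname(qs[, 2])
    out[[paste0(g, "_q75")]] <- unname(qs[, 3])
  }
  out
}

# Median of one group for one gene from a summary row.
smed <- function(srow, group) srow[[paste0(group, "_median")]]

#' Assign one of the six expression-pattern types to a tissue-specific gene
#'
#' For a colonic gene (CCG; focal disease CCD, focal control NMC, mirrored
#' for ICGs): types A/B require both focal-tissue groups significantly above
#' the other tissue (disease-vs-disease and control-vs-control comparisons
#' pass with the focal side up), with the focal disease above (A) or below
#' (B) its control by median; types C/D are the mirrored down-in-focal-tissue
#' cases; types E/F require no difference (p > alpha_ns) among the focal
#' control, other control, and other disease groups, with the focal disease
#' above (E) or below (F) all three by median. `unclassified` if no case
#' matches.
#'
#' @param summary_row One row of [summarize_groups()] output for the gene.
#' @param flags List with elements `ccd_icd` and `nmc_nmi`, each a list with
#'   `pass` (DEG + CI) and `direction` (`a_up` = first group of the standard
#'   comparison higher); `p_icd_nmi`, `p_nmc_nmi`, `p_cross` (the
#'   disease-vs-other-control p-value: NMC vs ICD for a CCG, NMI vs CCD for
#'   an ICG).
#' @param gene_class "CCG" or "ICG".
#' @param alpha_ns "No difference" threshold (default 0.1).
#' @return Character scalar: "A".."F" or "unclassified".
#' @export
assign_pattern <- function(summary_row, flags, gene_class,
                           alpha_ns = 0.1) {
  if (!gene_class %in% c("CCG", "ICG")) {
    stop("patterns are defined for CCG/ICG genes only")
  }
  if (gene_class == "CCG") {
    focal_d <- "CCD"; focal_c <- "NMC"; other_d <- "ICD"; other_c <- "NMI"
    dd_up <- flags$ccd_icd$direction == "a_up"   # CCD above ICD
    cc_up <- flags$nmc_nmi$direction == "a_up"   # NMC above NMI
    p_other_dc <- flags$p_icd_nmi                # other disease vs its control
  } else {
    focal_d <- "ICD"; focal_c <- "NMI"; other_d <- "CCD"; other_c <- "NMC"
    dd_up <- flags$ccd_icd$direction == "b_up"   # ICD above CCD
    cc_up <- flags$nmc_nmi$direction == "b_up"   # NMI above NMC
    p_other_dc <- flags$p_ccd_nmc
  }
  med_fd <- smed(summary_row, focal_d)
  med_fc <- smed(summary_row, focal_c)
  med_od <- smed(summary_row, other_d)
  med_oc <- smed(summary_row, other_c)
  disease_up <- med_fd > med_fc

  both_pass <- flags$ccd_icd$pass && flags$nmc_nmi$pass
  if (both_pass && dd_up && cc_up) return(if (disease_up) "A" else "B")
  if (both_pass && !dd_up && !cc_up) return(if (disease_up) "C" else "D")

  # E/F: the three non-focal groups mutually indistinct
  ns3 <- flags$p_nmc_nmi > alpha_ns && p_other_dc > alpha_ns &&
    flags$p_cross > alpha_ns
  if (ns3) {
    if (med_fd > max(med_fc, med_od, med_oc)) return("E")
    if (med_fd < min(med_fc, med_od, med_oc)) return("F")
  }
  "unclassified"
}

#' Assign expression patterns to every CCG and ICG in an assignment table
#'
#' Direction calls use group medians combined with the significance flags
#' already computed by the four standard comparisons; the one extra
#' cross-tissue comparison needed for the E/F "no difference among three
#' groups" condition (focal-tissue control versus other-tissue disease) is
#' computed here with the same adaptive test.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata.
#' @param assignment [classify_tissue_specific()] output.
#' @param tables The four comparison tables.
#' @param cfg An [analysis_config()].
#' @return A data.frame of class `pattern_assignment` with columns gene_id,
#'   tissue, gene_class, pattern.
#' @export
assign_patterns <- function(m, meta, assignment, tables,
                            cfg = analysis_config()) {
  keep <- assignment$gene_class %in% c("CCG", "ICG")
  genes <- assignment$gene_id[keep]
  classes <- assignment$gene_class[keep]
  if (!length(genes)) {
    out <- data.frame(gene_id = character(0), tissue = character(0),
                      gene_class = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("pattern_assignment", class(out))
    return(out)
  }
  summ <- summarize_groups(m, meta, genes)
  idx <- match(genes, tables$CCDvsICD$gene_id)
  nmc <- match(group_samples(meta, "NMC"), colnames(m))
  nmi <- match(group_samples(meta, "NMI"), colnames(m))
  icd <- match(group_samples(meta, "ICD"), colnames(m))
  ccd <- match(group_samples(meta, "CCD"), colnames(m))

  pat <- character(length(genes))
  for (j in seq_along(genes)) {
    i <- idx[j]
    gi <- match(genes[j], rownames(m))
    # cross-tissue comparison: focal control vs other-tissue disease
    cross <- if (classes[j] == "CCG") {
      two_group_pvalue(m[gi, nmc], m[gi, icd],
                       choose_test(m[gi, nmc], m[gi, icd], cfg$alpha_gate))
    } else {
      two_group_pvalue(m[gi, nmi], m[gi, ccd],
                       choose_test(m[gi, nmi], m[gi, ccd], cfg$alpha_gate))
    }
    flags <- list(
      ccd_icd = list(pass = pass_flag(tables$CCDvsICD)[i],
                     direction = tables$CCDvsICD$direction[i]),
      nmc_nmi = list(pass = pass_flag(tables$NMCvsNMI)[i],
                     direction = tables$NMCvsNMI$direction[i]),
      p_icd_nmi = tables$ICDvsNMI$p_value[i],
      p_ccd_nmc = tables$CCDvsNMC$p_value[i],
      p_nmc_nmi = tables$NMCvsNMI$p_value[i],
      p_cross = cross)
    pat[j] <- assign_pattern(summ[j, ], flags, classes[j], cfg$alpha_ns)
  }
  out <- data.frame(gene_id = genes,
                    tissue = ifelse(classes == "CCG", "colon", "ileum"),
                    gene_class = classes, pattern = pat,
                    stringsAsFactors = FALSE)
  class(out) <- c("pattern_assignment", class(out))
  out
}

#' Pattern-count contingency table
#'
#' @param assignments A `pattern_assignment` data.frame.
#' @return A tissue x pattern (A..F) integer matrix of counts; unclassified
#'   genes are excluded.
#' @export
pattern_counts <- function(assignments) {
  counts <- matrix(0L, nrow = 2, ncol = 6,
                   dimnames = list(c("colon", "ileum"), LETTERS[1:6]))
  keep <- assignments$pattern %in% LETTERS[1:6]
  if (any(keep)) {
    tab <- table(factor(assignments$tissue[keep], c("colon", "ileum")),
                 factor(assignments$pattern[keep], LETTERS[1:6]))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Hierarchical-clustering leaf orders for genes and samples
#'
#' Average-linkage clustering on log2(FPKM + 1): gene distance is
#' 1 - Pearson correlation, sample distance 1 - Spearman correlation.
#' Constant (zero-variance) genes get maximal distance to everything, with a
#' warning.
#'
#' @param m Expression matrix.
#' @param genes Genes to cluster (>= 2).
#' @param meta Sample metadata (unused beyond validation; samples clustered
#'   are the matrix columns).
#' @return List with `gene_order` and `sample_order` (ids in leaf order).
#' @export
cluster_order <- function(m, genes = rownames(m), meta = NULL) {
  if (length(genes) < 2 || ncol(m) < 2) stop("need >= 2 genes and >= 2 samples")
  if (!is.null(meta)) check_meta_matches(m, meta)
  lg <- log2(m[genes, , drop = FALSE] + 1)
  sds <- apply(lg, 1, stats::sd)
  if (any(sds == 0)) warning("constant gene(s) assigned maximal distance")
  gcor <- suppressWarnings(stats::cor(t(lg), method = "pearson"))
  gcor[!is.finite(gcor)] <- -1
  gd <- stats::as.dist(1 - gcor)
  scor <- suppressWarnings(stats::cor(lg, method = "spearman"))
  scor[!is.finite(scor)] <- -1
  sd_ <- stats::as.dist(1 - scor)
  gh <- stats::hclust(gd, method = "average")
  sh <- stats::hclust(sd_, method = "average")
  list(gene_order = genes[gh$order], sample_order = colnames(m)[sh$order])
}
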