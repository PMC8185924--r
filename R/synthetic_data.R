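#' Simulation configuration for synthetic five-group cohorts
#'
#' Defaults mirror the statistical structure the pipeline assumes: cohorts of
#' roughly a dozen biopsies per group, log-normal FPKM noise with a log2-scale
#' within-group standard deviation of 0.5, and planted effects of 2 on the
#' log2 scale (4-fold).
#'
#' @param n_per_group Samples per group (CCD, ICD, NMC, NMI, UC).
#' @param sigma_within Within-group sd on the log2 scale.
#' @param effect_log2 Planted effect size on the log2 scale.
#' @param n_null Number of null genes (one mean shared by all groups).
#' @param n_per_pattern Planted genes per pattern type per tissue; a scalar
#'   or a named length-6 vector (A..F).
#' @param n_uc_shared Genes shifted together in UC and CCD relative to NMC.
#' @param n_cd_common Genes shifted together in CCD and ICD vs. controls.
#' @param n_discriminative Genes differing between CCD and ICD only.
#' @param base_range Range of per-gene baseline log2 means (drawn uniformly).
#' @param contam_frac Fraction of samples drawn with inflated noise, to force
#'   the Wilcoxon branch of the adaptive test (default 0 = clean log-normal).
#' @param contam_factor Noise-sd multiplier for contaminated samples.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = 12, sigma_within = 0.5,
                              effect_log2 = 2.0, n_null = 500,
                              n_per_pattern = 5, n_uc_shared = 20,
                              n_cd_common = 20, n_discriminative = 20,
                              base_range = c(2, 8), contam_frac = 0,
                              contam_factor = 4, seed = 1L) {
  if (length(n_per_pattern) == 1) {
    n_per_pattern <- stats::setNames(rep(n_per_pattern, 6), LETTERS[1:6])
  }
  stopifnot(all(names(n_per_pattern) == LETTERS[1:6]),
            n_per_group >= 1, sigma_within > 0, effect_log2 >= 0,
            n_null >= 0, all(n_per_pattern >= 0), n_uc_shared >= 0,
            n_cd_common >= 0, n_discriminative >= 0,
            contam_frac >= 0, contam_frac < 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 sigma_within = sigma_within, effect_log2 = effect_log2,
                 n_null = as.integer(n_null),
                 n_per_pattern = stats::setNames(as.integer(n_per_pattern),
                                                 LETTERS[1:6]),
                 n_uc_shared = as.integer(n_uc_shared),
                 n_cd_common = as.integer(n_cd_common),
                 n_discriminative = as.integer(n_discriminative),
                 base_range = base_range, contam_frac = contam_frac,
                 contam_factor = contam_factor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-group log2 means realizing one of the six expression patterns
#'
#' For a colonic (CCG-type) gene: types A and B are up in both colon groups
#' relative to ileum, with the disease group above (A) or below (B) its
#' control; types C and D are down in both colon groups relative to ileum,
#' disease above (C) or below (D) control; types E and F leave the control
#' groups and the other-tissue disease group at a shared baseline with the
#' focal disease group above (E) or below (F) all three. Ileal (ICG-type)
#' genes use the mirrored assignment with the roles of (CCD, NMC) and
#' (ICD, NMI) exchanged.
#'
#' @param pattern One of "A".."F".
#' @param tissue "colon" or "ileum" (the focal tissue).
#' @param base Baseline log2 mean.
#' @param effect_log2 Effect size e > 0 on the log2 scale.
#' @return Named numeric vector of log2 means for (CCD, NMC, ICD, NMI).
#' @export
pattern_means <- function(pattern, tissue = c("colon", "ileum"),
                          base, effect_log2) {
  tissue <- match.arg(tissue)
  if (!pattern %in% LETTERS[1:6]) stop("unknown pattern: ", pattern)
  if (effect_log2 <= 0) stop("effect_log2 must be > 0")
  e <- effect_log2
  # (focal disease, focal control, other disease, other control)
  v <- switch(pattern,
              A = c(base + 2 * e, base + e, base, base),
              B = c(base + e, base + 2 * e, base, base),
              C = c(base + e, base, base + 2 * e, base + 2 * e),
              D = c(base, base + e, base + 2 * e, base + 2 * e),
              E = c(base + e, base, base, base),
              F = c(base - e, base, base, base))
  if (tissue == "colon") {
    stats::setNames(v, c("CCD", "NMC", "ICD", "NMI"))
  } else {
    stats::setNames(v, c("ICD", "NMI", "CCD", "NMC"))[c("CCD", "NMC", "ICD", "NMI")]
  }
}

# Build the per-gene, per-group log2 mean table and truth labels for a config.
# Baselines are drawn here, so call under the generator's seed.
plant_genes <- function(cfg) {
  rows <- list()
  add <- function(class, n, mean_fun) {
    if (n == 0) return()
    base <- stats::runif(n, cfg$base_range[1], cfg$base_range[2])
    for (i in seq_len(n)) {
      rows[[length(rows) + 1]] <<- c(list(class = class), mean_fun(base[i]))
    }
  }
  e <- cfg$effect_log2
  add("null", cfg$n_null, function(b) {
    list(CCD = b, NMC = b, ICD = b, NMI = b, UC = b)
  })
  for (tis in c("colon", "ileum")) {
    pre <- if (tis == "colon") "CCG" else "ICG"
    for (p in LETTERS[1:6]) {
      add(paste0(pre, "-", p), cfg$n_per_pattern[[p]], function(b) {
        mu <- pattern_means(p, tis, b, e)
        c(as.list(mu), list(UC = mu[["NMC"]]))  # UC biopsies track normal colon
      })
    }
  }
  add("UC-shared", cfg$n_uc_shared, function(b) {
    list(CCD = b + e, NMC = b, ICD = b, NMI = b, UC = b + e)
  })
  add("CD-common", cfg$n_cd_common, function(b) {
    list(CCD = b + e, NMC = b, ICD = b + e, NMI = b, UC = b)
  })
  add("discriminative", cfg$n_discriminative, function(b) {
    list(CCD = b + e, NMC = b + e / 2, ICD = b, NMI = b + e / 2, UC = b + e / 2)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$gene_id <- sprintf("g%05d", seq_len(nrow(df)))
  df
}

#' Generate a seeded synthetic five-group FPKM cohort with planted truth
#'
#' FPKM values are drawn as `2^N(mean, sigma_within)` per gene and sample
#' (log-normal noise). Null genes share one mean across all five groups;
#' planted pattern genes follow [pattern_means()]; UC-shared genes shift UC
#' and CCD together relative to NMC; CD-common genes shift CCD and ICD
#' together relative to their controls; discriminative genes differ between
#' CCD and ICD only (controls and UC sit halfway). With `contam_frac > 0` a
#' random subset of cells is drawn with `contam_factor`-fold noise sd to
#' produce heavy tails.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `matrix` (expression matrix), `metadata` (sample
#'   metadata) and `truth` (data.frame gene_id, class).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  plan <- plant_genes(cfg)
  groups <- GROUP_LEVELS
  n <- cfg$n_per_group
  sample_ids <- unlist(lapply(groups, function(g) sprintf("%s_%02d", g, seq_len(n))))
  meta <- sample_metadata(sample_ids, rep(groups, each = n))
  ng <- nrow(plan)
  vals <- matrix(0, nrow = ng, ncol = length(sample_ids))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mu <- plan[[g]]
    idx <- (gi - 1) * n + seq_len(n)
    z <- matrix(stats::rnorm(ng * n), ng, n)
    if (cfg$contam_frac > 0) {
      heavy <- matrix(stats::runif(ng * n) < cfg$contam_frac, ng, n)
      z[heavy] <- z[heavy] * cfg$contam_factor
    }
    vals[, idx] <- 2^(mu + cfg$sigma_within * z)
  }
  m <- expression_matrix(vals, gene_ids = plan$gene_id, sample_ids = sample_ids)
  truth <- data.frame(gene_id = plan$gene_id, class = plan$class,
                      stringsAsFactors = FALSE)
  list(matrix = m, metadata = meta, truth = truth)
}

#' Write a synthetic cohort's matrix, metadata and truth labels to TSV
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix(cohort$matrix, paths[["matrix"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
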