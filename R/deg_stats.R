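#' Levene's test for equality of variances between two groups
#'
#' Classic Levene procedure: a one-way ANOVA F-test on the absolute
#' deviations of each observation from its group center (mean by default,
#' median for the Brown-Forsythe variant).
#'
#' @param a,b Numeric vectors.
#' @param center "mean" (Levene) or "median" (Brown-Forsythe).
#' @return The two-group F-test p-value.
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  cfun <- if (center == "mean") mean else stats::median
  z <- c(abs(a - cfun(a)), abs(b - cfun(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

shapiro_p <- function(x) {
  if (length(unique(x)) < 3) return(0)  # constant/near-constant: non-normal
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Choose the two-group test for a gene
#'
#' Normality (Shapiro-Wilk in both groups) gates the t-family; variance
#' equality (Levene) then chooses pooled versus Welch. If either group fails
#' the normality gate the Wilcoxon rank-sum test is used. Constant vectors,
#' for which Shapiro-Wilk is undefined, are treated as non-normal.
#'
#' @param a,b Numeric vectors with at least 3 observations each.
#' @param alpha Gate alpha for both Shapiro and Levene (default 0.05).
#' @return One of `"t_equal_var"`, `"t_welch"`, `"wilcoxon"`.
#' @export
choose_test <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 observations per group")
  if (shapiro_p(a) > alpha && shapiro_p(b) > alpha) {
    if (levene_test(a, b) > alpha) "t_equal_var" else "t_welch"
  } else {
    "wilcoxon"
  }
}

#' Two-sided p-value for the named two-group test
#'
#' The Wilcoxon rank-sum p-value is exact for small samples without ties and
#' uses the tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors.
#' @param test One of `"t_equal_var"`, `"t_welch"`, `"wilcoxon"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
two_group_pvalue <- function(a, b, test) {
  switch(test,
         t_equal_var = stats::t.test(a, b, var.equal = TRUE)$p.value,
         t_welch = stats::t.test(a, b)$p.value,
         wilcoxon = {
           if (length(unique(c(a, b))) == 1) 1  # all tied: no evidence
           else suppressWarnings(stats::wilcox.test(a, b)$p.value)
         },
         stop("unknown test: ", test))
}

#' t-based confidence interval of a group mean
#'
#' `mean(x) +/- t_{(1+level)/2, n-1} * sd(x)/sqrt(n)`. The lower bound is the
#' LCI and the upper the HCI of the non-overlap filter.
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level in (0, 1).
#' @return List with `lci`, `hci`, `level`.
#' @export
group_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need >= 2 values for a confidence interval")
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, n - 1) * stats::sd(values) / sqrt(n)
  list(lci = m - half, hci = m + half, level = level)
}

#' Strict confidence-interval non-overlap test
#'
#' A gene passes the filter for a comparison when the lowest CI bound (LCI)
#' of one group is strictly larger than the highest CI bound (HCI) of the
#' other; touching intervals do not pass.
#'
#' @param ci_a,ci_b Confidence intervals from [group_ci()].
#' @return List with `disjoint` (logical) and `direction`
#'   (`"a_up"`, `"b_up"`, or `"none"`).
#' @export
ci_disjoint <- function(ci_a, ci_b) {
  if (ci_a$lci > ci_b$hci) {
    list(disjoint = TRUE, direction = "a_up")
  } else if (ci_b$lci > ci_a$hci) {
    list(disjoint = TRUE, direction = "b_up")
  } else {
    list(disjoint = FALSE, direction = "none")
  }
}

# Adaptive test + CI filter for one gene; returns a one-row list.
compare_gene <- function(a, b, ci_level, alpha_sig, alpha_gate) {
  test <- choose_test(a, b, alpha_gate)
  p <- two_group_pvalue(a, b, test)
  ca <- group_ci(a, ci_level)
  cb <- group_ci(b, ci_level)
  dj <- ci_disjoint(ca, cb)
  list(test_used = test, p_value = p,
       lci_a = ca$lci, hci_a = ca$hci, lci_b = cb$lci, hci_b = cb$hci,
       is_deg = p <= alpha_sig, is_ci_disjoint = dj$disjoint,
       direction = dj$direction)
}

#' Run one pairwise group comparison over all genes
#'
#' For every gene: pick the test adaptively ([choose_test]), compute the
#' two-sided p-value, the per-group confidence intervals on the FPKM scale,
#' the DEG flag (`p <= alpha_sig`) and the strict CI non-overlap flag.
#' With `prefilter = TRUE` the all-colon versus all-ileum CI non-overlap
#' screen is applied first and genes failing it are marked ineligible
#' (column `prefilter_pass`); by default all genes are eligible.
#'
#' @param m Expression matrix.
#' @param meta Sample metadata.
#' @param group_a,group_b Group labels; direction `a_up` means `group_a`
#'   higher.
#' @param cfg An [analysis_config()].
#' @param prefilter Apply the colon-vs-ileum CI screen first (default FALSE).
#' @return A data.frame of class `comparison_result`, one row per gene, with
#'   columns gene_id, comparison, test_used, p_value, lci_a, hci_a, lci_b,
#'   hci_b, is_deg, is_ci_disjoint, direction.
#' @export
run_comparison <- function(m, meta, group_a, group_b,
                           cfg = analysis_config(), prefilter = FALSE) {
  check_meta_matches(m, meta)
  for (g in c(group_a, group_b)) {
    if (!g %in% meta$group) stop("unknown or absent group label: ", g)
    if (sum(meta$group == g) < 3) stop("group ", g, " has < 3 samples")
  }
  ia <- match(group_samples(meta, group_a), colnames(m))
  ib <- match(group_samples(meta, group_b), colnames(m))
  rows <- lapply(seq_len(nrow(m)), function(i) {
    compare_gene(m[i, ia], m[i, ib], cfg$ci_level, cfg$alpha_sig,
                 cfg$alpha_gate)
  })
  out <- data.frame(
    gene_id = rownames(m),
    comparison = paste0(group_a, "vs", group_b),
    test_used = vapply(rows, `[[`, "", "test_used"),
    p_value = vapply(rows, `[[`, 0, "p_value"),
    lci_a = vapply(rows, `[[`, 0, "lci_a"),
    hci_a = vapply(rows, `[[`, 0, "hci_a"),
    lci_b = vapply(rows, `[[`, 0, "lci_b"),
    hci_b = vapply(rows, `[[`, 0, "hci_b"),
    is_deg = vapply(rows, `[[`, TRUE, "is_deg"),
    is_ci_disjoint = vapply(rows, `[[`, TRUE, "is_ci_disjoint"),
    direction = vapply(rows, `[[`, "", "direction"),
    stringsAsFactors = FALSE)
  if (prefilter) {
    colon <- meta$sample_id[meta$tissue == "colon"]
    ileum <- meta$sample_id[meta$tissue == "ileum"]
    pass <- vapply(seq_len(nrow(m)), function(i) {
      ci_disjoint(group_ci(m[i, colon], cfg$ci_level),
                  group_ci(m[i, ileum], cfg$ci_level))$disjoint
    }, TRUE)
    out$prefilter_pass <- pass
  }
  # BH-adjusted p-values are reported for users but never drive selection
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("comparison_result", class(out))
  out
}

#' Write a comparison-result table to TSV
#' @param res Result of [run_comparison()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
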