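test_that("summarize_groups matches a sort-based quantile oracle", {
  co <- tiny_cohort(matrix(4, 6, 4), n = 5, sigma = 0.8, seed = 71)
  s <- summarize_groups(co$matrix, co$meta)
  for (g in c("CCD", "NMC", "ICD", "NMI")) {
    ids <- co$meta$sample_id[co$meta$group == g]
    for (i in 1:6) {
      v <- unname(sort(co$matrix[i, ids]))
      expect_equal(s[[paste0(g, "_median")]][i], v[3])
      expect_equal(s[[paste0(g, "_q25")]][i],
                   unname(quantile(v, 0.25)))
      expect_true(s[[paste0(g, "_q25")]][i] <= s[[paste0(g, "_median")]][i])
      expect_true(s[[paste0(g, "_median")]][i] <= s[[paste0(g, "_q75")]][i])
    }
  }
  expect_error(summarize_groups(co$matrix, co$meta, "nope"), "unknown gene")
})

test_that("order statistics behave on simple vectors", {
  m <- expression_matrix(matrix(c(1, 2, 3, 4, 5), 1, 5), "g1", paste0("s", 1:5))
  meta <- sample_metadata(paste0("s", 1:5), rep("CCD", 5))
  s <- summarize_groups(m, meta, groups = "CCD")
  expect_equal(s$CCD_median, 3)
  expect_equal(s$CCD_q25, 2)
  expect_equal(s$CCD_q75, 4)
  mc <- expression_matrix(matrix(7, 1, 5), "g1", paste0("s", 1:5))
  sc <- summarize_groups(mc, meta, groups = "CCD")
  expect_true(sc$CCD_q25 == sc$CCD_median && sc$CCD_median == sc$CCD_q75)
})

make_flags <- function(pass12, dir12, pass34, dir34,
                       p_icd_nmi = 0.01, p_ccd_nmc = 0.01,
                       p_nmc_nmi = 0.01, p_cross = 0.01) {
  list(ccd_icd = list(pass = pass12, direction = dir12),
       nmc_nmi = list(pass = pass34, direction = dir34),
       p_icd_nmi = p_icd_nmi, p_ccd_nmc = p_ccd_nmc,
       p_nmc_nmi = p_nmc_nmi, p_cross = p_cross)
}

srow <- function(ccd, nmc, icd, nmi) {
  data.frame(gene_id = "g", CCD_median = ccd, NMC_median = nmc,
             ICD_median = icd, NMI_median = nmi)
}

test_that("assign_pattern reproduces the six-type taxonomy", {
  # colonic gene down in CCD vs NMC, colon above ileum -> B
  expect_identical(
    assign_pattern(srow(6, 8, 2, 2),
                   make_flags(TRUE, "a_up", TRUE, "a_up"), "CCG"), "B")
  # disease-up variant -> A
  expect_identical(
    assign_pattern(srow(8, 6, 2, 2),
                   make_flags(TRUE, "a_up", TRUE, "a_up"), "CCG"), "A")
  # colon below ileum -> C / D by disease direction
  expect_identical(
    assign_pattern(srow(4, 2, 8, 8),
                   make_flags(TRUE, "b_up", TRUE, "b_up"), "CCG"), "C")
  expect_identical(
    assign_pattern(srow(2, 4, 8, 8),
                   make_flags(TRUE, "b_up", TRUE, "b_up"), "CCG"), "D")
  # E: other three groups indistinct, CCD above all
  expect_identical(
    assign_pattern(srow(6, 3, 3, 3),
                   make_flags(TRUE, "a_up", FALSE, "none",
                              p_icd_nmi = 0.5, p_nmc_nmi = 0.5,
                              p_cross = 0.5), "CCG"), "E")
  # F: CCD below all
  expect_identical(
    assign_pattern(srow(1, 3, 3, 3),
                   make_flags(TRUE, "b_up", FALSE, "none",
                              p_icd_nmi = 0.5, p_nmc_nmi = 0.5,
                              p_cross = 0.5), "CCG"), "F")
  # mirrored ileal gene: ICD above all others -> E for an ICG
  expect_identical(
    assign_pattern(srow(3, 3, 6, 3),
                   make_flags(TRUE, "b_up", FALSE, "none",
                              p_ccd_nmc = 0.5, p_nmc_nmi = 0.5,
                              p_cross = 0.5), "ICG"), "E")
  # E/F blocked when any of the three pairwise p-values is <= alpha_ns
  expect_identical(
    assign_pattern(srow(6, 3, 3, 3),
                   make_flags(FALSE, "none", FALSE, "none",
                              p_icd_nmi = 0.08, p_nmc_nmi = 0.5,
                              p_cross = 0.5), "CCG"), "unclassified")
  expect_error(assign_pattern(srow(1, 1, 1, 1), make_flags(TRUE, "a_up",
                                                           TRUE, "a_up"),
                              "CD_common"), "CCG/ICG")
})

test_that("pattern_counts is a permutation-invariant contingency", {
  a <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  tissue = c("colon", "colon", "ileum", "colon"),
                  gene_class = c("CCG", "CCG", "ICG", "CCG"),
                  pattern = c("A", "A", "F", "unclassified"))
  ct <- pattern_counts(a)
  expect_equal(ct["colon", "A"], 2)
  expect_equal(ct["ileum", "F"], 1)
  expect_equal(sum(ct), 3)  # unclassified excluded
  expect_identical(pattern_counts(a[sample(4), ]), ct)
  empty <- pattern_counts(a[0, ])
  expect_true(all(empty == 0))
})

test_that("cluster_order groups planted structure contiguously", {
  set.seed(91)
  base <- rnorm(30, 6)
  m <- expression_matrix(
    2^cbind(sapply(1:4, function(i) base + rnorm(30, sd = 0.1)),
            sapply(1:4, function(i) base + 5 + rnorm(30, sd = 0.1)),
            sapply(1:4, function(i) rev(base) + rnorm(30, sd = 0.1))),
    gene_ids = sprintf("g%02d", 1:30), sample_ids = sprintf("s%02d", 1:12))
  ord <- cluster_order(m)
  cl <- rep(1:3, each = 4)[match(sprintf("s%02d", 1:12), ord$sample_order)]
  # planted sample clusters come out contiguous in leaf order
  runs <- rle(cl[order(match(sprintf("s%02d", 1:12), ord$sample_order))])
  expect_lte(length(runs$lengths), 3)

  # two identical genes sit adjacent
  m2 <- expression_matrix(rbind(m[1, ], m[1, ] * 2, m[5:10, ]),
                          gene_ids = paste0("h", 1:8),
                          sample_ids = colnames(m))
  o2 <- cluster_order(m2)
  pos <- match(c("h1", "h2"), o2$gene_order)
  expect_equal(abs(diff(pos)), 1)
  expect_warning(
    cluster_order(expression_matrix(rbind(rep(1, 4), c(1, 2, 3, 4)),
                                    c("a", "b"), paste0("s", 1:4))),
    "constant")
  expect_error(cluster_order(m[1, , drop = FALSE]), ">= 2")
})
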