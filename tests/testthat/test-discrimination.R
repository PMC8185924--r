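cd_meta <- function(n_ccd, n_icd) {
  sample_metadata(c(sprintf("c%02d", seq_len(n_ccd)),
                    sprintf("i%02d", seq_len(n_icd))),
                  rep(c("CCD", "ICD"), c(n_ccd, n_icd)))
}

test_that("stratified_split preserves class proportions and partitions", {
  meta <- cd_meta(10, 10)
  sp <- stratified_split(meta, 0.7, seed = 3)
  expect_length(sp$train, 14)
  expect_length(sp$test, 6)
  tr_groups <- meta$group[match(sp$train, meta$sample_id)]
  expect_equal(unname(table(tr_groups)), c(7L, 7L), ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$sample_id)
  expect_identical(stratified_split(meta, 0.7, seed = 3), sp)
  expect_false(identical(stratified_split(meta, 0.7, seed = 4), sp))
  expect_error(stratified_split(cd_meta(1, 5), 0.7), "< 2 samples")
})

test_that("kfold_indices partitions evenly with single validation use", {
  meta <- cd_meta(10, 10)
  folds <- kfold_indices(meta$sample_id, 10, seed = 5,
                         labels = meta$group)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), meta$sample_id)
  expect_equal(anyDuplicated(unlist(folds)), 0)       # only once
  # uneven n: sizes differ by at most one
  f2 <- kfold_indices(meta$sample_id[1:17], 5, seed = 5)
  expect_lte(diff(range(lengths(f2))), 1)
  expect_error(kfold_indices(meta$sample_id[1:4], 10), "exceeds")
})

test_that("the logistic fit matches glm and flags separation", {
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(30); y <- rbinom(30, 1, plogis(0.8 * x))
    if (length(unique(y)) < 2) next
    f <- crohnsig:::fit_logistic1(x, y)
    g <- suppressWarnings(glm(y ~ x, family = binomial,
                              control = glm.control(epsilon = 1e-12)))
    if (!f$separated) {
      expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
      expect_equal(f$p, summary(g)$coefficients[2, 4], tolerance = 1e-5)
    }
  }
  sep <- crohnsig:::fit_logistic1(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separated)
  expect_equal(sep$p, 0)
})

test_that("single-gene evaluation separates planted from null genes", {
  cfg <- simulation_config(n_per_group = 12, n_null = 3, n_per_pattern = 0,
                           n_uc_shared = 0, n_cd_common = 0,
                           n_discriminative = 3, seed = 47)
  co <- generate_cohort(cfg)
  ac <- analysis_config(n_repeats = 25, seed = 47)
  null_id <- co$truth$gene_id[co$truth$class == "null"][1]
  disc_id <- co$truth$gene_id[co$truth$class == "discriminative"][1]
  en <- evaluate_single_gene(co$matrix, null_id, co$metadata, ac)
  ed <- evaluate_single_gene(co$matrix, disc_id, co$metadata, ac)
  expect_false(en$selected)
  expect_true(ed$selected)
  expect_gt(ed$test_auc, 0.95)
  expect_error(evaluate_single_gene(co$matrix, "nope", co$metadata, ac),
               "unknown gene")
})

test_that("select_features is deterministic and threshold-monotone", {
  cfg <- simulation_config(n_per_group = 12, n_null = 10, n_per_pattern = 0,
                           n_uc_shared = 0, n_cd_common = 0,
                           n_discriminative = 4, seed = 53)
  co <- generate_cohort(cfg)
  ac <- analysis_config(n_repeats = 20, seed = 53)
  s1 <- select_features(co$matrix, co$truth$gene_id, co$metadata, ac)
  s2 <- select_features(co$matrix, co$truth$gene_id, co$metadata, ac)
  expect_identical(s1$selected, s2$selected)
  # tightening any threshold never enlarges the selection
  ev <- s1$evaluations
  for (col_thr in list(c("test_auc", 0.9), c("test_accuracy", 0.9))) {
    tighter <- ev$gene_id[ev$selected &
                            ev[[col_thr[1]]] >= as.numeric(col_thr[2])]
    expect_true(all(tighter %in% s1$selected))
    expect_lte(length(tighter), length(s1$selected))
  }
  expect_error(select_features(co$matrix, character(0), co$metadata, ac),
               "empty candidate")
})

test_that("random forest is seeded, fits separable data, generalizes", {
  set.seed(61)
  n <- 20
  x <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 3), n, 3))
  colnames(x) <- paste0("f", 1:3)
  y <- rep(c("ICD", "CCD"), each = n)
  m1 <- rf_fit(x, y, positive = "CCD", ntree = 100, seed = 8)
  m2 <- rf_fit(x, y, positive = "CCD", ntree = 100, seed = 8)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_true(all((predict(m1, x) > 0.5) == (y == "CCD")))
  expect_error(rf_fit(x, rep("CCD", 2 * n), positive = "CCD"),
               "single class")
})

test_that("the trained discriminator achieves high held-out AUC", {
  cfg <- simulation_config(n_per_group = 12, n_null = 5, n_per_pattern = 0,
                           n_uc_shared = 0, n_cd_common = 0,
                           n_discriminative = 5, seed = 67)
  co <- generate_cohort(cfg)
  disc <- co$truth$gene_id[co$truth$class == "discriminative"]
  cd <- co$metadata[co$metadata$group %in% c("CCD", "ICD"), ]
  sp <- stratified_split(cd, 0.7, seed = 67)
  model <- train_discriminator(co$matrix, disc, sp$train, co$metadata,
                               seed = 67, ntree = 200)
  rep_ <- evaluate_discriminator(model, co$matrix, sp$test,
                                 cd$group[match(sp$test, cd$sample_id)])
  expect_gte(rep_$auc, 0.9)
  expect_identical(sum(rep_$confusion), length(sp$test))
  expect_equal(rep_$accuracy,
               (rep_$confusion[["tp"]] + rep_$confusion[["tn"]]) /
                 length(sp$test))
})

test_that("classifier_report implements the PPV/NPV arithmetic", {
  r <- classifier_report(tp = 9, fp = 1, tn = 8, fn = 2)
  expect_equal(r$ppv, 0.9)
  expect_equal(r$npv, 0.8)
  expect_equal(r$accuracy, 0.85)
  perfect <- classifier_report(tp = 5, fp = 0, tn = 5, fn = 0, auc = 1)
  expect_true(all(c(perfect$accuracy, perfect$auc, perfect$ppv,
                    perfect$npv) == 1))
  degen <- classifier_report(tp = 0, fp = 0, tn = 3, fn = 2)
  expect_true(is.na(degen$ppv))
})

test_that("missing model genes are dropped and one-class sets warn", {
  cfg <- simulation_config(n_per_group = 8, n_null = 2, n_per_pattern = 0,
                           n_uc_shared = 0, n_cd_common = 0,
                           n_discriminative = 3, seed = 71)
  co <- generate_cohort(cfg)
  disc <- co$truth$gene_id[co$truth$class == "discriminative"]
  cd <- co$metadata[co$metadata$group %in% c("CCD", "ICD"), ]
  model <- train_discriminator(co$matrix, disc, cd$sample_id, co$metadata,
                               seed = 71, ntree = 50)
  m_small <- co$matrix[setdiff(rownames(co$matrix), disc[1]), ]
  class(m_small) <- class(co$matrix)
  expect_message(
    r <- evaluate_discriminator(model, m_small, cd$sample_id, cd$group),
    "dropped")
  expect_identical(r$n_genes, length(disc) - 1L)
  ccd_only <- cd$sample_id[cd$group == "CCD"]
  expect_warning(
    r1 <- evaluate_discriminator(model, co$matrix, ccd_only,
                                 rep("CCD", length(ccd_only))),
    "single class")
  expect_true(is.na(r1$auc))
})

test_that("shuffled-label AUC centers at one half", {
  set.seed(77)
  prob <- runif(40)
  aucs <- replicate(200, crohnsig:::auc_score(prob, sample(rep(0:1, 20))))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("three_group_test behaves under null, shift and relabeling", {
  cfg <- simulation_config(n_per_group = 12, n_null = 2, n_per_pattern = 0,
                           n_uc_shared = 0, n_cd_common = 0,
                           n_discriminative = 0, seed = 83)
  co <- generate_cohort(cfg)
  g <- co$truth$gene_id[1]
  p_null <- three_group_test(co$matrix, g, co$metadata)
  expect_gt(p_null, 0.001)  # null gene: rarely extreme

  # one group shifted by ~10 sd
  m2 <- co$matrix
  uc_ids <- co$metadata$sample_id[co$metadata$group == "UC"]
  m2[g, uc_ids] <- m2[g, uc_ids] * 2^5
  class(m2) <- class(co$matrix)
  expect_lt(three_group_test(m2, g, co$metadata), 1e-4)

  # identical groups: p about 1, invariant to relabeling equal groups
  m3 <- co$matrix
  m3[g, ] <- 7
  class(m3) <- class(co$matrix)
  expect_gt(three_group_test(m3, g, co$metadata), 0.99)
  meta_swap <- co$metadata
  meta_swap$group[meta_swap$group == "CCD"] <- "tmp"
  meta_swap$group[meta_swap$group == "ICD"] <- "CCD"
  meta_swap$group[meta_swap$group == "tmp"] <- "ICD"
  expect_equal(three_group_test(m3, g, co$metadata),
               three_group_test(m3, g, meta_swap))
  meta_small <- co$metadata[co$metadata$group != "UC" |
                              co$metadata$sample_id == uc_ids[1], ]
  m4 <- co$matrix[, meta_small$sample_id]
  class(m4) <- class(co$matrix)
  expect_error(three_group_test(m4, g, meta_small), "< 2 samples")
})
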