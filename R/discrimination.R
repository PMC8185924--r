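#' Stratified 70/30 split of the CD samples
#'
#' Splits the CCD and ICD samples into train and test sets preserving class
#' proportions; the per-class training count is `round(fraction * n_class)`,
#' clamped so both sides keep at least one sample per class.
#'
#' @param meta Sample metadata.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors of sample ids;
#'   disjoint and jointly exhaustive over the CD samples.
#' @export
stratified_split <- function(meta, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  train <- character(0); test <- character(0)
  for (g in c("CCD", "ICD")) {
    ids <- group_samples(meta, g)
    if (length(ids) < 2) stop("class ", g, " has < 2 samples")
    n_tr <- min(max(round(fraction * length(ids)), 1L), length(ids) - 1L)
    perm <- sample(ids)
    train <- c(train, perm[seq_len(n_tr)])
    test <- c(test, perm[-seq_len(n_tr)])
  }
  list(train = train, test = test)
}

#' Stratified k-fold partition of a training set
#'
#' Every sample appears in exactly one validation fold; fold sizes differ by
#' at most one, and each class is dealt across folds as evenly as possible
#' (classes are dealt to the currently smallest folds first).
#'
#' @param train_ids Character vector of sample ids.
#' @param k Number of folds (2 <= k <= length(train_ids)).
#' @param seed Integer seed.
#' @param labels Optional class labels (same order as `train_ids`) for
#'   stratification; unstratified when NULL.
#' @return List of k character vectors (the validation folds).
#' @export
kfold_indices <- function(train_ids, k, seed = 1L, labels = NULL) {
  n <- length(train_ids)
  if (k > n) stop("k exceeds number of training samples")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  folds <- vector("list", k)
  classes <- if (is.null(labels)) list(train_ids) else
    split(train_ids, as.character(labels))
  for (ids in classes) {
    ids <- sample(ids)
    for (id in ids) {
      sizes <- lengths(folds)
      target <- which(sizes == min(sizes))[1]
      folds[[target]] <- c(folds[[target]], id)
    }
  }
  folds
}

# Logistic fit of a binary outcome on one predictor: Newton/IRLS on the
# two-parameter model, hand-rolled for speed (this sits in the innermost
# loop of feature selection). Returns the Wald p-value of the slope;
# complete separation (deviance ~ 0) is flagged and, per the selection
# convention, counted as p = 0.
fit_logistic1 <- function(x, y01, max_iter = 100) {
  n <- length(x)
  # exact 1-D separation check: the class ranges do not overlap
  x1 <- x[y01 == 1]; x0 <- x[y01 == 0]
  separable <- length(x1) && length(x0) &&
    (min(x1) > max(x0) || max(x1) < min(x0))
  b0 <- 0; b1 <- 0
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    r <- y01 - mu
    # 2x2 information matrix
    s0 <- sum(w); s1 <- sum(w * x); s2 <- sum(w * x * x)
    det <- s0 * s2 - s1 * s1
    if (!is.finite(det) || det < 1e-12) break
    g0 <- sum(r); g1 <- sum(r * x)
    d0 <- (s2 * g0 - s1 * g1) / det
    d1 <- (s0 * g1 - s1 * g0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    mu2 <- 1 / (1 + exp(-(b0 + b1 * x)))
    mu2 <- pmin(pmax(mu2, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y01 * log(mu2) + (1 - y01) * log(1 - mu2))
    if (abs(dev_old - dev) < 1e-12 * (abs(dev) + 0.1)) { dev_old <- dev; break }
    dev_old <- dev
  }
  separated <- separable || (is.finite(dev_old) && dev_old < 1e-6)
  p <- if (separated) 0 else {
    eta <- b0 + b1 * x
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    s0 <- sum(w); s1 <- sum(w * x); s2 <- sum(w * x * x)
    det <- s0 * s2 - s1 * s1
    se2 <- if (det > 1e-12) s0 / det else Inf
    if (!is.finite(se2) || se2 <= 0) 1 else
      2 * stats::pnorm(-abs(b1 / sqrt(se2)))
  }
  list(beta = c(b0, b1), p = p, separated = separated)
}

predict_logistic1 <- function(fit, x) {
  stats::plogis(fit$beta[1] + fit$beta[2] * x)
}

#' Precompute the seeded split/fold plan shared by all single-gene
#' evaluations
#'
#' Repetition r uses split seed `(seed + 7919 * r) mod (2^31 - 1)`; folds
#' are stratified by class within the training set.
#'
#' @param cd_meta Metadata restricted to the CCD/ICD samples.
#' @param cfg An [analysis_config()].
#' @return List of `cfg$n_repeats` elements, each with `train`, `test`,
#'   `folds`.
#' @export
make_repetition_plan <- function(cd_meta, cfg) {
  y <- stats::setNames(as.integer(cd_meta$group == "CCD"), cd_meta$sample_id)
  lapply(seq_len(cfg$n_repeats), function(r) {
    sp_seed <- (cfg$seed + 7919L * r) %% 2147483647L
    sp <- stratified_split(cd_meta, cfg$split_fraction, seed = sp_seed)
    sp$folds <- kfold_indices(sp$train, min(cfg$cv_folds, length(sp$train)),
                              seed = sp_seed + 1L, labels = y[sp$train])
    sp
  })
}

# Empirical AUC (Mann-Whitney with midranks).
auc_score <- function(prob, y01) {
  n1 <- sum(y01); n0 <- sum(1 - y01)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated single-gene logistic evaluation
#'
#' For each of `cfg$n_repeats` repetitions: draw a fresh seeded stratified
#' 70/30 split of the CD samples, fit an intercept-plus-one-gene logistic
#' model of CCD vs ICD on log2(FPKM + 1) of the training set, record the
#' Wald p-value of the gene coefficient, the stratified k-fold CV accuracy
#' on the training set, and the accuracy and AUC on the held-out test set.
#' Repetition summaries are aggregated by median (configurable to mean) and
#' the gene is `selected` when the aggregated values pass
#' `p <= alpha_sig & accuracy >= acc_threshold & AUC >= auc_threshold`.
#' Splits depend only on `cfg$seed` and the repetition index, so every gene
#' sees the same sequence of splits. Completely separated fits count as
#' p = 0; genes constant on a training set are recorded as not selected with
#' a warning.
#'
#' @param m Expression matrix.
#' @param gene Gene id.
#' @param meta Sample metadata.
#' @param cfg An [analysis_config()].
#' @param aggregate "median" (default) or "mean".
#' @param plan Optional precomputed repetition plan from
#'   [make_repetition_plan()]; built from `cfg` when NULL. Because splits
#'   depend only on the seed and repetition index, one plan serves every
#'   gene of a cohort.
#' @return One-row data.frame: gene_id, repeats, coefficient_p, cv_accuracy,
#'   test_accuracy, test_auc, selected.
#' @export
evaluate_single_gene <- function(m, gene, meta, cfg = analysis_config(),
                                 aggregate = c("median", "mean"),
                                 plan = NULL) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "median") stats::median else mean
  if (!gene %in% rownames(m)) stop("unknown gene: ", gene)
  cd <- meta[meta$group %in% c("CCD", "ICD"), , drop = FALSE]
  if (is.null(plan)) plan <- make_repetition_plan(cd, cfg)
  x_all <- log2(m[gene, cd$sample_id] + 1)
  y_all <- stats::setNames(as.integer(cd$group == "CCD"), cd$sample_id)

  ps <- cvs <- accs <- aucs <- rep(NA_real_, cfg$n_repeats)
  degenerate <- FALSE
  for (r in seq_len(cfg$n_repeats)) {
    sp <- plan[[r]]
    xtr <- x_all[sp$train]; ytr <- y_all[sp$train]
    xte <- x_all[sp$test]; yte <- y_all[sp$test]
    if (stats::sd(xtr) == 0) { degenerate <- TRUE; next }
    fit <- fit_logistic1(xtr, ytr)
    ps[r] <- fit$p
    correct <- 0L
    for (fold in sp$folds) {
      tr <- setdiff(sp$train, fold)
      if (stats::sd(x_all[tr]) == 0 || length(unique(y_all[tr])) < 2) next
      f <- fit_logistic1(x_all[tr], y_all[tr])
      pr <- predict_logistic1(f, x_all[fold])
      correct <- correct + sum((pr > 0.5) == (y_all[fold] == 1))
    }
    cvs[r] <- correct / length(sp$train)
    pr_te <- predict_logistic1(fit, xte)
    accs[r] <- mean((pr_te > 0.5) == (yte == 1))
    aucs[r] <- auc_score(pr_te, yte)
  }
  if (degenerate) warning("gene ", gene, " constant on >= 1 training set")
  ok <- !is.na(ps)
  res <- data.frame(
    gene_id = gene, repeats = cfg$n_repeats,
    coefficient_p = if (any(ok)) agg(ps[ok]) else NA_real_,
    cv_accuracy = if (any(ok)) agg(cvs[ok]) else NA_real_,
    test_accuracy = if (any(ok)) agg(accs[ok]) else NA_real_,
    test_auc = if (any(ok)) agg(aucs[ok], na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
  res$selected <- !degenerate && any(ok) &&
    !is.na(res$coefficient_p) && res$coefficient_p <= cfg$alpha_sig &&
    !is.na(res$test_accuracy) && res$test_accuracy >= cfg$acc_threshold &&
    !is.na(res$test_auc) && res$test_auc >= cfg$auc_threshold
  res
}

#' Select discriminative genes by repeated single-gene logistic regression
#'
#' Applies [evaluate_single_gene()] to every candidate and returns the genes
#' passing the triple criterion. Deterministic given `cfg$seed`.
#'
#' @param m Expression matrix.
#' @param candidates Candidate gene ids (typically the UC-filtered
#'   CCG and ICG union).
#' @param meta Sample metadata.
#' @param cfg An [analysis_config()].
#' @param aggregate Aggregation rule, see [evaluate_single_gene()].
#' @return List with `selected` (gene ids) and `evaluations` (data.frame).
#' @export
select_features <- function(m, candidates, meta, cfg = analysis_config(),
                            aggregate = "median") {
  candidates <- as.character(candidates)
  if (!length(candidates)) stop("empty candidate set")
  cd <- meta[meta$group %in% c("CCD", "ICD"), , drop = FALSE]
  plan <- make_repetition_plan(cd, cfg)
  evals <- do.call(rbind, lapply(candidates, function(g) {
    evaluate_single_gene(m, g, meta, cfg, aggregate, plan = plan)
  }))
  list(selected = evals$gene_id[evals$selected], evaluations = evals)
}

#' Train the CCD-vs-ICD random-forest discriminator
#'
#' Features are log2(FPKM + 1) of the selected genes; the positive class is
#' CCD. Forest defaults: 500 trees, `floor(sqrt(n_features))` features per
#' split.
#'
#' @param m Expression matrix.
#' @param genes Selected gene ids (>= 1).
#' @param train_ids Training sample ids (must carry both classes).
#' @param meta Sample metadata.
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return A `crohnsig_rf` model.
#' @export
train_discriminator <- function(m, genes, train_ids, meta, seed = 1L,
                                ntree = 500) {
  if (!length(genes)) stop("need >= 1 selected gene")
  labs <- meta$group[match(train_ids, meta$sample_id)]
  x <- t(log2(m[genes, train_ids, drop = FALSE] + 1))
  rf_fit(x, labs, positive = "CCD", ntree = ntree, seed = seed)
}

#' Classifier report from confusion counts
#'
#' Accuracy = (TP+TN)/N, PPV = TP/(TP+FP), NPV = TN/(TN+FN); the positive
#' class is CCD. AUC is carried through from the probability-based
#' evaluation when available.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @param auc Optional AUC.
#' @param n_genes Optional number of model genes.
#' @return A list of class `classifier_report`.
#' @export
classifier_report <- function(tp, fp, tn, fn, auc = NA_real_,
                              n_genes = NA_integer_) {
  n <- tp + fp + tn + fn
  structure(list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    accuracy = (tp + tn) / n,
    auc = auc,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    n_genes = n_genes
  ), class = "classifier_report")
}

#' Evaluate a discriminator on labeled samples
#'
#' Confusion counts at probability threshold 0.5 (positive class CCD), AUC
#' from the predicted probabilities, and PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). Genes absent from the evaluation matrix are dropped
#' with a message before prediction; a single-class evaluation set yields a
#' missing AUC with a warning.
#'
#' @param model A `crohnsig_rf` from [train_discriminator()].
#' @param m Expression matrix of the evaluation cohort.
#' @param sample_ids Samples to evaluate.
#' @param labels Class labels ("CCD"/"ICD") in `sample_ids` order.
#' @return A `classifier_report` list: confusion, accuracy, auc, ppv, npv,
#'   n_genes.
#' @export
evaluate_discriminator <- function(model, m, sample_ids, labels) {
  genes <- intersect(model$features, rownames(m))
  dropped <- length(model$features) - length(genes)
  if (dropped > 0) {
    message(dropped, " model gene(s) absent from evaluation matrix; dropped")
    if (!length(genes)) stop("no model genes present in evaluation matrix")
  }
  x <- t(log2(m[genes, sample_ids, drop = FALSE] + 1))
  prob <- stats::predict(model, x)
  y01 <- as.integer(labels == "CCD")
  pred <- as.integer(prob > 0.5)
  rep_ <- classifier_report(tp = sum(pred == 1 & y01 == 1),
                            fp = sum(pred == 1 & y01 == 0),
                            tn = sum(pred == 0 & y01 == 0),
                            fn = sum(pred == 0 & y01 == 1),
                            n_genes = length(genes))
  if (length(unique(y01)) < 2) {
    warning("evaluation set has a single class; AUC undefined")
  } else {
    rep_$auc <- auc_score(prob, y01)
  }
  rep_
}

#' Write a classifier report to JSON
#' @param report A `classifier_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path) {
  jsonlite::write_json(list(confusion = as.list(report$confusion),
                            accuracy = report$accuracy, auc = report$auc,
                            ppv = report$ppv, npv = report$npv,
                            n_genes = report$n_genes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Kruskal-Wallis comparison of one gene across CCD, ICD and UC
#'
#' @param m Expression matrix.
#' @param gene Gene id.
#' @param meta Sample metadata with all three groups (>= 2 samples each).
#' @param groups Groups compared (default CCD, ICD, UC).
#' @return The Kruskal-Wallis p-value.
#' @export
three_group_test <- function(m, gene, meta, groups = c("CCD", "ICD", "UC")) {
  for (g in groups) {
    if (sum(meta$group == g) < 2) stop("group ", g, " has < 2 samples")
  }
  keep <- meta$group %in% groups
  vals <- m[gene, meta$sample_id[keep]]
  if (length(unique(vals)) == 1) return(1)  # all tied: statistic undefined
  stats::kruskal.test(vals, factor(meta$group[keep]))$p.value
}
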