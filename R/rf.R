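# Compact CART-based random forest for two-class discrimination.
# Bootstrap-aggregated binary trees with Gini splits and random feature
# subsampling (mtry = floor(sqrt(p)) by default). Written in-package because
# no random-forest package is available in the target environment; the scale
# here (tens of samples, tens of features) does not need compiled code.

gini_impurity <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# Best threshold on one feature; returns NULL when no split reduces impurity.
best_split_feature <- function(x, y01) {
  ord <- order(x)
  xs <- x[ord]; ys <- y01[ord]
  n <- length(xs)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  # candidate split after position i (between distinct values)
  cand <- which(diff(xs) > 0)
  if (!length(cand)) return(NULL)
  nl <- cand
  nr <- n - nl
  imp <- (nl * gini_impurity(cum1[cand], nl) +
          nr * gini_impurity(tot1 - cum1[cand], nr)) / n
  best <- which.min(imp)
  list(threshold = (xs[cand[best]] + xs[cand[best] + 1]) / 2,
       impurity = imp[best])
}

grow_tree <- function(x, y01, mtry, min_node) {
  n <- length(y01)
  n1 <- sum(y01)
  if (n1 == 0 || n1 == n || n <= min_node) {
    return(list(leaf = TRUE, prob = n1 / n))
  }
  feats <- sample.int(ncol(x), mtry)
  best <- NULL
  node_imp <- gini_impurity(n1, n)
  for (f in feats) {
    sp <- best_split_feature(x[, f], y01)
    if (!is.null(sp) && sp$impurity < node_imp - 1e-12 &&
        (is.null(best) || sp$impurity < best$impurity)) {
      best <- c(sp, feature = f)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, prob = n1 / n))
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(x[left, , drop = FALSE], y01[left], mtry, min_node),
       right = grow_tree(x[!left, , drop = FALSE], y01[!left], mtry, min_node))
}

predict_tree <- function(tree, x) {
  if (tree$leaf) return(rep(tree$prob, nrow(x)))
  out <- numeric(nrow(x))
  left <- x[, tree$feature] <= tree$threshold
  if (any(left)) out[left] <- predict_tree(tree$left, x[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(tree$right, x[!left, , drop = FALSE])
  out
}

#' Fit a random forest for two-class probabilities
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Two-level factor or character vector; `positive` names the class
#'   whose probability is predicted.
#' @param positive Positive class label.
#' @param ntree Number of bootstrap trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param min_node Minimum node size to attempt a split.
#' @param seed Integer seed; the fit is fully reproducible.
#' @return An object of class `crohnsig_rf`.
#' @export
rf_fit <- function(x, y, positive, ntree = 500,
                   mtry = max(1L, floor(sqrt(ncol(x)))), min_node = 1,
                   seed = 1L) {
  x <- as.matrix(x)
  y01 <- as.integer(as.character(y) == positive)
  if (all(y01 == 1) || all(y01 == 0)) stop("training set has a single class")
  set.seed(seed)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
    trees[[b]] <- grow_tree(x[idx, , drop = FALSE], y01[idx], mtry, min_node)
  }
  structure(list(trees = trees, positive = positive,
                 features = colnames(x),
                 feature_medians = apply(x, 2, stats::median),
                 ntree = ntree, mtry = mtry, seed = seed),
            class = "crohnsig_rf")
}

#' Predict positive-class probabilities from a fitted forest
#'
#' Features absent from `newdata` are imputed at their training medians
#' (splits on them become deterministic), so a model can be applied to an
#' external cohort missing some model genes.
#'
#' @param object A `crohnsig_rf` fit.
#' @param newdata Numeric matrix with (a subset of) the training features as
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive class.
#' @export
predict.crohnsig_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features)) {
    full <- matrix(rep(object$feature_medians, each = nrow(newdata)),
                   nrow = nrow(newdata),
                   dimnames = list(rownames(newdata), object$features))
    present <- intersect(object$features, colnames(newdata))
    if (!length(present)) stop("no model features present in newdata")
    full[, present] <- newdata[, present]
    newdata <- full
  }
  probs <- vapply(object$trees, predict_tree, numeric(nrow(newdata)),
                  x = newdata)
  if (nrow(newdata) == 1) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}
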