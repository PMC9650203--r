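# Coarse classification tree: CART-style greedy growth with Gini
# impurity, at most `max_splits` internal splits, candidate thresholds at
# midpoints between sorted distinct feature values, and deterministic
# tie-breaks (lower feature index, then lower threshold, then lower node
# id) so training is invariant to record order.

gini_ <- function(labels, classes) {
  p <- tabulate(match(labels, classes), length(classes)) / length(labels)
  1 - sum(p^2)
}

majority_ <- function(labels, classes) {
  cnt <- tabulate(match(labels, classes), length(classes))
  classes[which.max(cnt)]  # tie -> first listed class
}

# best (feature, threshold) for one node; NULL when no split helps
best_split_ <- function(X, labels, classes, min_leaf) {
  n <- length(labels)
  parent <- gini_(labels, classes)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2L) next
    thr <- (v[-1L] + v[-length(v)]) / 2
    for (th in thr) {
      left <- X[, f] < th
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      dec <- parent - (nl * gini_(labels[left], classes) +
                       nr * gini_(labels[!left], classes)) / n
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(feature = f, threshold = th, decrease = dec)
      }
    }
  }
  if (!is.null(best) && best$decrease <= 1e-12) best <- NULL
  best
}

#' Fit a coarse classification tree
#'
#' Grows a binary CART-style tree on the asymmetry features predicting
#' the module-pattern dichotomy, using Gini impurity, candidate
#' thresholds at midpoints between sorted distinct feature values, and
#' best-first growth stopped at `max_splits` internal splits (the
#' "coarse" preset) or purity. The left branch takes records with
#' `feature < threshold`. Training is deterministic and invariant to the
#' order of records.
#'
#' @param data Data frame holding the feature columns and the label
#'   column. Rows with missing features are dropped (listwise) with a
#'   warning.
#' @param features Feature column names, in tie-break priority order
#'   (default CST then CRP asymmetry).
#' @param label Label column name; single-class data yields a one-leaf
#'   tree.
#' @param max_splits Maximum number of internal splits (default 4).
#' @param min_leaf Minimum records per leaf (default 1).
#' @param classes Optional fixed class order (first class wins majority
#'   ties); defaults to sorted unique labels.
#' @return An object of class `coarse_tree`.
#' @export
fit_coarse_tree <- function(data, features = c("asymm_cst", "asymm_crp"),
                            label = "pattern_class", max_splits = 4,
                            min_leaf = 1, classes = NULL) {
  if (!all(c(features, label) %in% names(data))) {
    stop_mw("invalid_argument", "feature or label column missing from data")
  }
  X <- as.matrix(data[, features, drop = FALSE])
  y <- as.character(data[[label]])
  ok <- stats::complete.cases(X) & !is.na(y)
  if (!all(ok)) {
    warning(sprintf("dropping %d record(s) with missing features or label",
                    sum(!ok)))
    X <- X[ok, , drop = FALSE]; y <- y[ok]
  }
  if (!length(y)) stop_mw("invalid_argument", "no complete records")
  if (is.null(classes)) classes <- sort(unique(y))
  nodes <- data.frame(id = 1L, parent = NA_integer_, is_leaf = TRUE,
                      feature = NA_character_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_,
                      class = majority_(y, classes), n = length(y),
                      stringsAsFactors = FALSE)
  members <- list(seq_along(y))
  n_splits <- 0L
  while (n_splits < max_splits) {
    # best-first: evaluate the best split of every current leaf
    cand <- NULL
    for (nd in nodes$id[nodes$is_leaf]) {
      idx <- members[[nd]]
      if (length(unique(y[idx])) < 2L) next
      bs <- best_split_(X[idx, , drop = FALSE], y[idx], classes, min_leaf)
      if (is.null(bs)) next
      w <- bs$decrease * length(idx)  # impurity decrease weighted by size
      if (is.null(cand) || w > cand$w + 1e-12) {
        cand <- list(node = nd, bs = bs, w = w)
      }
    }
    if (is.null(cand)) break
    nd <- cand$node; bs <- cand$bs
    idx <- members[[nd]]
    go_left <- X[idx, bs$feature] < bs$threshold
    lid <- nrow(nodes) + 1L; rid <- nrow(nodes) + 2L
    nodes$is_leaf[nd] <- FALSE
    nodes$feature[nd] <- features[bs$feature]
    nodes$threshold[nd] <- bs$threshold
    nodes$left[nd] <- lid; nodes$right[nd] <- rid
    nodes <- rbind(nodes, data.frame(
      id = c(lid, rid), parent = nd, is_leaf = TRUE,
      feature = NA_character_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_,
      class = c(majority_(y[idx][go_left], classes),
                majority_(y[idx][!go_left], classes)),
      n = c(sum(go_left), sum(!go_left)), stringsAsFactors = FALSE))
    members[[lid]] <- idx[go_left]
    members[[rid]] <- idx[!go_left]
    n_splits <- n_splits + 1L
  }
  structure(list(nodes = nodes, features = features, classes = classes,
                 n_splits = n_splits),
            class = "coarse_tree")
}

#' Build a coarse tree from explicit rules
#'
#' Constructs a `coarse_tree` from a nested rule list, e.g. the printed
#' cutoffs of a published model, for use as a fixed classifier. Each
#' internal node is `list(feature =, threshold =, left =, right =)` where
#' `left`/`right` are either class labels (leaves) or further nodes; the
#' left branch takes `feature < threshold`.
#'
#' @param rules Nested rule list.
#' @param features Feature names the tree may reference.
#' @param classes Class labels.
#' @return A `coarse_tree`.
#' @export
#' @examples
#' fig_tree <- coarse_tree_from_rules(
#'   list(feature = "asymm_crp", threshold = 0.27,
#'        left = "two_modules",
#'        right = list(feature = "asymm_cst", threshold = -0.02,
#'                     left = "two_modules", right = "more_than_two")))
coarse_tree_from_rules <- function(rules,
                                   features = c("asymm_cst", "asymm_crp"),
                                   classes = c("more_than_two",
                                               "two_modules")) {
  nodes <- data.frame(id = integer(), parent = integer(),
                      is_leaf = logical(), feature = character(),
                      threshold = numeric(), left = integer(),
                      right = integer(), class = character(), n = integer(),
                      stringsAsFactors = FALSE)
  add <- function(x, parent) {
    id <- nrow(nodes) + 1L
    if (is.character(x)) {
      nodes[id, ] <<- list(id, parent, TRUE, NA_character_, NA_real_,
                           NA_integer_, NA_integer_, x, NA_integer_)
      return(id)
    }
    if (!x$feature %in% features) {
      stop_mw("invalid_argument",
              sprintf("unknown feature '%s' in rules", x$feature))
    }
    nodes[id, ] <<- list(id, parent, FALSE, x$feature, x$threshold,
                         NA_integer_, NA_integer_, NA_character_,
                         NA_integer_)
    nodes$left[id] <<- add(x$left, id)
    nodes$right[id] <<- add(x$right, id)
    id
  }
  add(rules, NA_integer_)
  structure(list(nodes = nodes, features = features, classes = classes,
                 n_splits = sum(!nodes$is_leaf)),
            class = "coarse_tree")
}

#' @export
print.coarse_tree <- function(x, ...) {
  cat(sprintf("<coarse_tree> %d split(s), classes: %s\n", x$n_splits,
              paste(x$classes, collapse = ", ")))
  rec <- function(id, indent) {
    nd <- x$nodes[x$nodes$id == id, ]
    pad <- strrep("  ", indent)
    if (nd$is_leaf) {
      cat(sprintf("%s-> %s\n", pad, nd$class))
    } else {
      cat(sprintf("%sif %s < %g:\n", pad, nd$feature, nd$threshold))
      rec(nd$left, indent + 1L)
      cat(sprintf("%selse:\n", pad))
      rec(nd$right, indent + 1L)
    }
  }
  rec(1L, 0L)
  invisible(x)
}

#' Predict classes from a coarse tree
#'
#' Deterministic path evaluation; the left branch takes records with
#' `feature < threshold` (strict, matching printed rules such as
#' "CRP asymmetry < 0.27").
#'
#' @param model A `coarse_tree`.
#' @param newdata Data frame containing the model's feature columns.
#' @return Character vector of predicted classes.
#' @export
predict_tree <- function(model, newdata) {
  stopifnot(inherits(model, "coarse_tree"))
  miss <- setdiff(unique(stats::na.omit(model$nodes$feature)),
                  names(newdata))
  if (length(miss)) {
    stop_mw("missing_feature", sprintf(
      "feature(s) missing from newdata: %s", paste(miss, collapse = ", ")))
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- 1L
    repeat {
      nd <- model$nodes[model$nodes$id == id, ]
      if (nd$is_leaf) return(nd$class)
      v <- newdata[[nd$feature]][i]
      if (is.na(v)) {
        stop_mw("missing_feature",
                sprintf("missing value for feature '%s'", nd$feature))
      }
      id <- if (v < nd$threshold) nd$left else nd$right
    }
  }, character(1))
}

#' @export
predict.coarse_tree <- function(object, newdata, ...) {
  predict_tree(object, newdata)
}

#' Stratified k-fold cross-validation of the coarse tree
#'
#' Builds seeded class-stratified folds, refits the tree on each training
#' set, pools the out-of-fold predictions into a cross-validated
#' confusion summary, and also reports the resubstitution confusion of
#' the full-data tree (published classification counts are typically
#' resubstitution-style, so both views are returned).
#'
#' @inheritParams fit_coarse_tree
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `model` (full-data tree), `cv_confusion`,
#'   `cv_accuracy`, `resub_confusion`, `resub_accuracy`, `folds`.
#' @export
cross_validate_tree <- function(data, features = c("asymm_cst", "asymm_crp"),
                                label = "pattern_class", k_folds = 5,
                                seed = 1, max_splits = 4, min_leaf = 1) {
  y <- as.character(data[[label]])
  ok <- stats::complete.cases(data[, features, drop = FALSE]) & !is.na(y)
  data <- data[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(data)
  if (n < k_folds) {
    stop_mw("invalid_argument", "need at least k_folds records")
  }
  classes <- sort(unique(y))
  folds <- integer(n)
  with_seed_(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  truth <- character(0); pred <- character(0)
  for (f in seq_len(k_folds)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    if (length(unique(as.character(train[[label]]))) < 2L) {
      warning(sprintf("fold %d skipped: a class is absent from training", f))
      next
    }
    fit <- fit_coarse_tree(train, features, label, max_splits, min_leaf,
                           classes = classes)
    truth <- c(truth, as.character(test[[label]]))
    pred <- c(pred, predict_tree(fit, test))
  }
  full <- fit_coarse_tree(data, features, label, max_splits, min_leaf,
                          classes = classes)
  resub <- confusion_report(y, predict_tree(full, data))
  cv <- confusion_report(truth, pred)
  list(model = full, cv_confusion = cv, cv_accuracy = cv$overall_pct,
       resub_confusion = resub, resub_accuracy = resub$overall_pct,
       folds = folds)
}

#' FMA-LE threshold classifier for the module dichotomy
#'
#' Classifies subjects from the 22-point synergy subsection of the
#' lower-extremity Fugl-Meyer assessment: scores strictly below the
#' cutoff (default 15) predict a two-module pattern, since such subjects
#' are theoretically unable to move outside a mass flexion-extension
#' co-excitation pattern.
#'
#' @param fma_le_synergy Scores in `[0, 22]`.
#' @param cutoff Threshold (default 15, strict less-than).
#' @return Character vector, `"two_modules"` or `"more_than_two"`.
#' @export
fma_threshold_classifier <- function(fma_le_synergy, cutoff = 15) {
  if (any(!is.finite(fma_le_synergy) | fma_le_synergy < 0 |
          fma_le_synergy > 22)) {
    stop_mw("invalid_input", "FMA-LE synergy scores must lie in [0, 22]")
  }
  ifelse(fma_le_synergy < cutoff, "two_modules", "more_than_two")
}

#' Confusion summary with display percentages
#'
#' Exact integer counts per (true, predicted) class, per-class and
#' overall percent correct, and a false-positive rate for two-module
#' predictions (the fraction of truly more-than-two-module subjects
#' labeled two-module). Display percentages are truncated toward zero to
#' whole percent, the convention used when such counts are reported
#' (e.g. 7/13 is displayed as 53%).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param positive Class treated as "positive" for the false-positive
#'   rate (default `"two_modules"`).
#' @return An object of class `confusion_summary` with `counts`,
#'   `per_class_pct`, `overall_pct`, `fpr_positive`, and truncated
#'   `display` values.
#' @export
confusion_report <- function(true_labels, predicted_labels,
                             positive = "two_modules") {
  if (length(true_labels) != length(predicted_labels)) {
    stop_mw("invalid_input", "label vectors must have equal length")
  }
  classes <- sort(unique(c(true_labels, predicted_labels)))
  counts <- table(factor(true_labels, classes),
                  factor(predicted_labels, classes),
                  dnn = c("true", "predicted"))
  correct <- diag(as.matrix(counts))
  class_n <- rowSums(counts)
  per_class <- ifelse(class_n > 0, 100 * correct / class_n, NA_real_)
  overall <- 100 * sum(correct) / length(true_labels)
  neg <- true_labels != positive
  fpr <- if (any(neg)) {
    100 * sum(neg & predicted_labels == positive) / sum(neg)
  } else NA_real_
  structure(list(counts = counts, per_class_pct = per_class,
                 overall_pct = overall, fpr_positive = fpr,
                 display = list(per_class_pct = floor(per_class),
                                overall_pct = floor(overall),
                                fpr_positive = if (is.na(fpr)) NA
                                               else floor(fpr)),
                 n = length(true_labels)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> n = %d, overall %.1f%% (displays as %d%%)\n",
              x$n, x$overall_pct, x$display$overall_pct))
  print(x$counts)
  invisible(x)
}
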