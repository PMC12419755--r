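## Exact Shapley attributions for tree ensembles.
##
## A fitted forest/boosting model is first converted into a plain
## tree-ensemble representation (per tree: feature, split, children, leaf
## value, node cover, topologically ordered). The conditional expectation
## v_S(x) of the ensemble output given only the features in S is evaluated
## by top-down weight propagation: at a split on a feature in S the weight
## follows x; at any other split it divides between the children in
## proportion to their training cover. Shapley values are then computed
## exactly by enumerating all 2^p feature subsets; by the efficiency
## property the attributions satisfy local accuracy,
## baseline + sum(phi) = model output, up to floating-point error.
## This exact enumeration is intended for the small interpretable feature
## sets of the explanation layer (p <= 15).

new_tree_ensemble <- function(trees, feature_names, base_offset = 0,
                              split_rule = c("le", "lt"), float32 = FALSE) {
  split_rule <- match.arg(split_rule)
  structure(list(trees = trees, feature_names = feature_names,
                 base_offset = base_offset, split_rule = split_rule,
                 float32 = float32),
            class = "rr_tree_ensemble")
}

## Round to single precision, matching engines that compare in float32.
as_float32 <- function(v)
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
          n = length(v), size = 4)

#' @export
print.rr_tree_ensemble <- function(x, ...) {
  cat(sprintf("tree ensemble: %d tree(s), %d feature(s)\n",
              length(x$trees), length(x$feature_names)))
  invisible(x)
}

## Reorder one tree's node arrays (BFS) so parents precede children, which
## lets v_S propagation run as a single forward sweep.
reindex_tree <- function(tr) {
  n <- length(tr$feature)
  order <- integer(0)
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    if (tr$feature[i] > 0) queue <- c(queue, tr$yes[i], tr$no[i])
  }
  stopifnot(length(order) == n)
  pos <- integer(n); pos[order] <- seq_len(n)
  internal <- tr$feature[order] > 0
  remap <- function(child) {
    out <- integer(n)
    out[internal] <- pos[child[order][internal]]
    out
  }
  list(feature = tr$feature[order], split = tr$split[order],
       yes = remap(tr$yes), no = remap(tr$no),
       value = tr$value[order], cover = tr$cover[order])
}

#' Convert a randomForest classifier to the attribution representation
#'
#' Leaf values are the tree's class votes (0/1), so the ensemble output is
#' the fraction of trees voting for the treatment class. Node covers are
#' recomputed by routing the supplied training matrix through each tree.
#'
#' @param rf A fitted [randomForest::randomForest()] classification model
#'   with two classes labelled "0" and "1".
#' @param x_train The training feature matrix (used only to compute node
#'   covers).
#' @return An `rr_tree_ensemble`.
#' @export
rr_ensemble_from_rf <- function(rf, x_train) {
  stopifnot(inherits(rf, "randomForest"),
            identical(rf$type, "classification"))
  x_train <- as.matrix(x_train)
  ntree <- rf$ntree
  trees <- vector("list", ntree)
  for (k in seq_len(ntree)) {
    gt <- randomForest::getTree(rf, k, labelVar = FALSE)
    leaf <- gt[, "status"] == -1
    tr <- list(feature = ifelse(leaf, 0L, as.integer(gt[, "split var"])),
               split = as.numeric(gt[, "split point"]),
               yes = as.integer(gt[, "left daughter"]),
               no = as.integer(gt[, "right daughter"]),
               value = ifelse(leaf, as.numeric(gt[, "prediction"]) - 1, 0),
               cover = numeric(nrow(gt)))
    tr <- reindex_tree(tr)
    tr$cover <- tree_covers(tr, x_train)
    trees[[k]] <- tr
  }
  new_tree_ensemble(trees, colnames(x_train) %||%
                      paste0("x", seq_len(ncol(x_train))),
                    base_offset = 0)
}

## Route a data matrix through a tree, counting arrivals per node.
## randomForest convention: x <= split point goes to the left daughter.
tree_covers <- function(tr, x) {
  n <- length(tr$feature)
  cover <- numeric(n)
  idx_at <- vector("list", n)
  idx_at[[1]] <- seq_len(nrow(x))
  for (i in seq_len(n)) {
    rows <- idx_at[[i]]
    cover[i] <- length(rows)
    if (tr$feature[i] > 0 && length(rows)) {
      go_yes <- x[rows, tr$feature[i]] <= tr$split[i]
      idx_at[[tr$yes[i]]] <- c(idx_at[[tr$yes[i]]], rows[go_yes])
      idx_at[[tr$no[i]]] <- c(idx_at[[tr$no[i]]], rows[!go_yes])
    }
  }
  pmax(cover, 1e-12)
}

#' Convert an xgboost model to the attribution representation
#'
#' Leaf values are the boosting margins; the ensemble output is the summed
#' margin plus `base_offset`. Node covers are xgboost's stored covers.
#'
#' @param model A fitted `xgb.Booster` (binary:logistic or linear).
#' @param feature_names Feature names in training column order.
#' @param base_offset Margin offset (0 for the default base score of 0.5).
#' @return An `rr_tree_ensemble`.
#' @export
rr_ensemble_from_xgb <- function(model, feature_names, base_offset = 0) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  dt <- as.data.frame(dt)
  trees <- lapply(split(dt, dt$Tree), function(td) {
    td <- td[order(td$Node), ]
    id2node <- stats::setNames(seq_len(nrow(td)), td$ID)
    leaf <- td$Feature == "Leaf"
    tr <- list(feature = ifelse(leaf, 0L,
                                match(td$Feature, feature_names)),
               split = ifelse(leaf, 0, suppressWarnings(as.numeric(td$Split))),
               yes = ifelse(leaf, 0L, id2node[td$Yes]),
               no = ifelse(leaf, 0L, id2node[td$No]),
               value = ifelse(leaf, td$Gain, 0),
               cover = td$Cover)
    tr$split <- as_float32(tr$split)
    if (anyNA(tr$feature)) stop2("unknown feature name in xgboost dump")
    tr$yes[is.na(tr$yes)] <- 0L
    tr$no[is.na(tr$no)] <- 0L
    reindex_tree(tr)
  })
  new_tree_ensemble(unname(trees), feature_names, base_offset = base_offset,
                    split_rule = "lt", float32 = TRUE)
}

## Ensemble aggregation: vote fraction for forests, summed margin for
## boosters. Controlled by `average`.
ensemble_scale <- function(ens) {
  has_vote_leaves <- all(vapply(ens$trees, function(tr)
    all(tr$value[tr$feature == 0] %in% c(0, 1)), logical(1)))
  if (has_vote_leaves) 1 / length(ens$trees) else 1
}

## "Goes to the yes child" condition per internal node and instance.
ensemble_conds <- function(ensemble, x) {
  le <- identical(ensemble$split_rule %||% "le", "le")
  if (isTRUE(ensemble$float32))
    x <- matrix(as_float32(x), nrow(x), ncol(x))
  lapply(ensemble$trees, function(tr) {
    lapply(seq_along(tr$feature), function(i) {
      if (tr$feature[i] == 0) return(NULL)
      if (le) x[, tr$feature[i]] <= tr$split[i]
      else x[, tr$feature[i]] < tr$split[i]
    })
  })
}

## v_S for every instance, one tree. cond[[i]]: logical vector, instance
## goes to `yes` at node i. smask: logical over features.
tree_vs <- function(tr, cond, smask, n_inst) {
  n <- length(tr$feature)
  W <- vector("list", n)
  W[[1]] <- rep(1, n_inst)
  v <- numeric(n_inst)
  for (i in seq_len(n)) {
    wi <- W[[i]]
    if (is.null(wi)) next
    f <- tr$feature[i]
    if (f == 0) {
      v <- v + tr$value[i] * wi
    } else if (smask[f]) {
      ci <- cond[[i]]
      y <- tr$yes[i]; no <- tr$no[i]
      W[[y]] <- if (is.null(W[[y]])) wi * ci else W[[y]] + wi * ci
      W[[no]] <- if (is.null(W[[no]])) wi * (!ci) else W[[no]] + wi * (!ci)
    } else {
      y <- tr$yes[i]; no <- tr$no[i]
      py <- tr$cover[y] / tr$cover[i]
      W[[y]] <- if (is.null(W[[y]])) wi * py else W[[y]] + wi * py
      W[[no]] <- if (is.null(W[[no]])) wi * (1 - py) else W[[no]] + wi * (1 - py)
    }
  }
  v
}

#' Exact Shapley attributions for a tree ensemble
#'
#' Computes, for every instance, the exact Shapley value of each feature
#' with respect to the cover-weighted conditional expectation of the
#' ensemble output, by full subset enumeration. The attributions satisfy
#' local accuracy by construction; the function verifies it and fails hard
#' beyond `tol`.
#'
#' @param ensemble An `rr_tree_ensemble` (see [rr_ensemble_from_rf()],
#'   [rr_ensemble_from_xgb()]).
#' @param x Instance matrix (instances x features, columns in the
#'   representation's feature order).
#' @param tol Local-accuracy tolerance (default 1e-6).
#' @return Object of class `rr_attribution`: list with `shap` (instances x
#'   features), `baseline`, `output`, `ranking` (feature names by mean
#'   absolute attribution), and `order` (instance order by model output,
#'   the heatmap convention).
#' @export
rr_shap_attribution <- function(ensemble, x, tol = 1e-6) {
  stopifnot(inherits(ensemble, "rr_tree_ensemble"))
  x <- as.matrix(x)
  p <- length(ensemble$feature_names)
  stopifnot(ncol(x) == p)
  if (p > 15) stop2("exact subset enumeration is limited to <= 15 features")
  if (anyNA(x)) stop2("instances must not contain missing values")
  n_inst <- nrow(x)
  scale <- ensemble_scale(ensemble)

  ## per-tree split conditions, computed once
  conds <- ensemble_conds(ensemble, x)

  n_masks <- bitwShiftL(1L, p)
  V <- matrix(0, n_masks, n_inst)
  smask <- logical(p)
  for (m in seq_len(n_masks) - 1L) {
    for (j in seq_len(p)) smask[j] <- bitwAnd(m, bitwShiftL(1L, j - 1L)) > 0
    acc <- numeric(n_inst)
    for (k in seq_along(ensemble$trees))
      acc <- acc + tree_vs(ensemble$trees[[k]], conds[[k]], smask, n_inst)
    V[m + 1L, ] <- acc * scale
  }

  ## Shapley combination over subsets
  fact <- factorial(0:p)
  sizes <- vapply(seq_len(n_masks) - 1L, function(m) sum(
    bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) > 0), numeric(1))
  shap <- matrix(0, n_inst, p, dimnames = list(NULL, ensemble$feature_names))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_masks) - 1L, bit) == 0)
    for (m1 in without) {
      s <- sizes[m1]
      wgt <- fact[s + 1] * fact[p - s] / fact[p + 1]
      shap[, j] <- shap[, j] + wgt * (V[m1 + bit, ] - V[m1, ])
    }
  }

  baseline <- V[1, 1] + ensemble$base_offset
  output <- V[n_masks, ] + ensemble$base_offset
  err <- max(abs(baseline + rowSums(shap) - output))
  if (err > tol)
    stop2("local accuracy violated: max |baseline + sum(shap) - output| = ",
          format(err))
  ranking <- colnames(shap)[order(-colMeans(abs(shap)))]
  structure(list(shap = shap, baseline = baseline, output = output,
                 ranking = ranking, order = order(output),
                 local_accuracy_error = err),
            class = "rr_attribution")
}

#' @export
print.rr_attribution <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d instance(s) x %d feature(s)\n",
              nrow(x$shap), ncol(x$shap)))
  cat(sprintf("  baseline %.4f; local-accuracy error %.2e\n",
              x$baseline, x$local_accuracy_error))
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

## Predict ensemble output directly from the representation (v of the full
## feature set); used by tests as a consistency probe.
ensemble_output <- function(ensemble, x) {
  x <- as.matrix(x)
  p <- length(ensemble$feature_names)
  conds <- ensemble_conds(ensemble, x)
  acc <- numeric(nrow(x))
  for (k in seq_along(ensemble$trees))
    acc <- acc + tree_vs(ensemble$trees[[k]], conds[[k]], rep(TRUE, p), nrow(x))
  acc * ensemble_scale(ensemble) + ensemble$base_offset
}
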