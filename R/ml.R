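#' Group-aware evaluation harness
#'
#' Trains a gradient-boosted tree classifier (xgboost) on descriptor
#' tables with group-shuffle partitioning (clusters never straddle
#' partitions), early stopping on the held-out Matthews correlation
#' coefficient, and permutation importance.
#'
#' @name ml_harness
NULL

#' Matthews correlation coefficient from confusion counts
#'
#' @param tp,fp,fn,tn confusion-matrix counts, or `tp` may be a named
#'   vector/list with those four elements.
#' @return MCC in `[-1, 1]`; 0 by convention when a denominator term is
#'   zero (e.g. all predictions in one class).
#' @export
compute_mcc <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.null(fp)) { x <- tp; tp <- x[["tp"]]; fp <- x[["fp"]]
                     fn <- x[["fn"]]; tn <- x[["tn"]] }
  if (any(c(tp, fp, fn, tn) < 0)) stop("compute_mcc: negative count")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Evaluation metrics from labels and predictions
#'
#' @param truth 0/1 vector; `prob` predicted probabilities;
#'   `cutoff` classification threshold.
#' @return list with confusion counts, `mcc`, `accuracy`, `precision`,
#'   `balanced_accuracy` (mean of sensitivity and specificity),
#'   `auroc` and `auprc`.
#' @export
eval_metrics <- function(truth, prob, cutoff = 0.5) {
  pred <- as.integer(prob >= cutoff)
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    mcc = compute_mcc(tp, fp, fn, tn),
    accuracy = (tp + tn) / length(truth),
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    balanced_accuracy = (sens + spec) / 2,
    auroc = .auroc(truth, prob),
    auprc = .auprc(truth, prob))
}

# rank-based AUROC (Mann-Whitney), ties handled by midranks
.auroc <- function(truth, prob) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-wise average precision
.auprc <- function(truth, prob) {
  if (sum(truth == 1) == 0) return(NA_real_)
  ord <- order(prob, decreasing = TRUE)
  t <- truth[ord]
  prec <- cumsum(t) / seq_along(t)
  sum(prec[t == 1]) / sum(t == 1)
}

#' Group-shuffle split of cluster identifiers
#'
#' Clusters are permuted with a seeded RNG; the first `ceiling(ratio *
#' n)` clusters form the larger (training) partition.  51 clusters at a
#' 2:1 ratio give a 34/17 split.  Clusters never straddle partitions.
#'
#' @param cluster_ids vector of cluster ids, one per row (or the unique
#'   cluster ids themselves).
#' @param ratio share of clusters in the first partition, in (0, 1)
#'   (2/3 for a 2:1 split).
#' @param seed RNG seed.
#' @return list with `train` and `test` cluster id vectors and
#'   `assignment`, a factor over `cluster_ids`.
#' @export
group_shuffle_split <- function(cluster_ids, ratio = 2 / 3, seed = 1) {
  if (ratio <= 0 || ratio >= 1) stop("group_shuffle_split: ratio outside (0, 1)")
  clusters <- unique(cluster_ids)
  if (length(clusters) < 2) stop("group_shuffle_split: need >= 2 clusters")
  perm <- withr::with_seed(seed, sample(clusters))
  n_train <- ceiling(ratio * length(clusters))
  train <- perm[seq_len(n_train)]
  test <- setdiff(perm, train)
  list(train = train, test = test,
       assignment = factor(ifelse(cluster_ids %in% train, "train", "test"),
                           levels = c("train", "test")))
}

.mcc_metric <- function(preds, dtrain) {
  truth <- xgboost::getinfo(dtrain, "label")
  list(metric = "mcc",
       value = eval_metrics(truth, preds)$mcc)
}

#' Train a gradient-boosted classifier with MCC early stopping
#'
#' Clusters are split into model-building, early-stopping and
#' evaluation partitions (default shares 64/16/20).  Training uses a
#' binary logistic objective, learning rate 0.025, a 20,000-round cap
#' and early stopping after 100 rounds without MCC improvement on the
#' early-stopping partition.  All randomness is seeded.
#'
#' @param x numeric feature matrix (rows = structures, columns =
#'   descriptors).
#' @param y 0/1 labels.
#' @param groups cluster id per row.
#' @param seed RNG seed.
#' @param shares length-3 shares of clusters for train / early-stop /
#'   eval (normalized internally).
#' @param eta learning rate; `nrounds` boosting cap;
#'   `early_stopping_rounds` patience; `params` extra xgboost params.
#' @return list with `model`, `metrics` ([eval_metrics()] on the eval
#'   partition), `split` (cluster assignment) and `best_iteration`.
#' @export
train_classifier <- function(x, y, groups, seed = 1,
                             shares = c(0.64, 0.16, 0.20), eta = 0.025,
                             nrounds = 20000, early_stopping_rounds = 100,
                             params = list()) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("train_classifier: single-class labels")
  shares <- shares / sum(shares)
  s1 <- group_shuffle_split(groups, ratio = shares[1] + shares[2], seed = seed)
  inner <- groups %in% s1$train
  s2 <- group_shuffle_split(groups[inner],
                            ratio = shares[1] / (shares[1] + shares[2]),
                            seed = seed + 1)
  idx_build <- inner & groups %in% s2$train
  idx_stop <- inner & groups %in% s2$test
  idx_eval <- !inner
  if (length(unique(y[idx_build])) < 2)
    stop("train_classifier: single-class labels in the build partition")
  dbuild <- xgboost::xgb.DMatrix(x[idx_build, , drop = FALSE],
                                 label = y[idx_build])
  dstop <- xgboost::xgb.DMatrix(x[idx_stop, , drop = FALSE],
                                label = y[idx_stop])
  p <- utils::modifyList(list(objective = "binary:logistic", eta = eta,
                              nthread = 1, seed = seed), params)
  model <- withr::with_seed(seed, xgboost::xgb.train(
    params = p, data = dbuild, nrounds = nrounds,
    evals = list(stop = dstop), custom_metric = .mcc_metric,
    early_stopping_rounds = early_stopping_rounds, maximize = TRUE,
    verbose = 0))
  prob <- stats::predict(model, xgboost::xgb.DMatrix(x[idx_eval, , drop = FALSE]))
  metrics <- eval_metrics(y[idx_eval], prob)
  list(model = model, metrics = metrics,
       split = list(build = which(idx_build), stop = which(idx_stop),
                    eval = which(idx_eval)),
       best_iteration = xgboost::xgb.attr(model, "best_iteration"))
}

#' Permutation importance on held-out data
#'
#' Each feature column is shuffled `n_repeats` times; the mean drop of
#' the MCC from the unpermuted baseline (and its sd) is the importance.
#' Constant columns have importance zero by construction.
#'
#' @param model fitted xgboost model.
#' @param x feature matrix; `y` 0/1 labels.
#' @param n_repeats shuffles per feature (default 100).
#' @param seed RNG seed.
#' @return data frame with `feature`, `mean_drop`, `sd_drop`.
#' @export
permutation_importance <- function(model, x, y, n_repeats = 100, seed = 1) {
  x <- as.matrix(x)
  baseline <- eval_metrics(y, stats::predict(model, xgboost::xgb.DMatrix(x)))$mcc
  out <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        baseline - eval_metrics(
          y, stats::predict(model, xgboost::xgb.DMatrix(xp)))$mcc
      }, numeric(1))
      data.frame(feature = colnames(x)[j] %||% paste0("f", j),
                 mean_drop = mean(drops),
                 sd_drop = if (n_repeats > 1) stats::sd(drops) else 0)
    }))
  })
  out[order(-out$mean_drop), ]
}

#' Small config-driven hyperparameter grid search
#'
#' Repeatedly splits clusters, trains with each parameter combination
#' and returns the combination with the best mean evaluation MCC.
#'
#' @param x,y,groups as in [train_classifier()].
#' @param grid named list of parameter vectors (expanded with
#'   [expand.grid()]).
#' @param n_repeats resampling repeats per combination.
#' @param seed RNG seed.
#' @param ... passed to [train_classifier()].
#' @return list with `best` (parameter list) and `results` data frame.
#' @export
grid_search <- function(x, y, groups,
                        grid = list(max_depth = c(3, 6)),
                        n_repeats = 3, seed = 1, ...) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    pars <- as.list(combos[i, , drop = FALSE])
    mccs <- vapply(seq_len(n_repeats), function(r)
      train_classifier(x, y, groups, seed = seed + 1000 * i + r,
                       params = pars, ...)$metrics$mcc, numeric(1))
    cbind(combos[i, , drop = FALSE], mean_mcc = mean(mccs))
  })
  results <- do.call(rbind, res)
  best <- as.list(combos[which.max(results$mean_mcc), , drop = FALSE])
  list(best = best, results = results)
}
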