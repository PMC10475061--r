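# Evaluation: confusion counts, classification metrics, Dice/IoU, ROC-AUC,
# 180-degree rotation augmentation, and k-fold cross-validation with
# mean +/- sd reporting. "present" is the positive class throughout.

#' Confusion counts
#'
#' @param pred_labels,true_labels equal-length vectors of
#'   `"present"`/`"absent"` (or logical, `TRUE` = present)
#' @return list with integer `TP`, `FP`, `TN`, `FN`
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop_contract("label vectors differ in length")
  p <- as_present(pred_labels); t <- as_present(true_labels)
  list(TP = sum(p & t), FP = sum(p & !t), TN = sum(!p & !t), FN = sum(!p & t))
}

as_present <- function(x) {
  if (is.logical(x)) return(x)
  if (!all(x %in% SVP_CLASSES)) stop_contract("labels must be 'present'/'absent'")
  x == "present"
}

#' Classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/total, F1 = 2*prec*sens/(prec+sens), NPV TN/(TN+FN).
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param cc confusion counts from [confusion()]
#' @return list of metrics in \[0,1\] (or `NA` where undefined)
#' @export
classification_metrics <- function(cc) {
  total <- cc$TP + cc$FP + cc$TN + cc$FN
  if (total == 0) stop_data("empty confusion counts")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(cc$TP, cc$TP + cc$FN)
  spec <- frac(cc$TN, cc$TN + cc$FP)
  prec <- frac(cc$TP, cc$TP + cc$FP)
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = (cc$TP + cc$TN) / total, f1 = f1,
       npv = frac(cc$TN, cc$TN + cc$FN))
}

#' Dice and IoU between two binary masks
#'
#' @param a,b binary masks of equal shape
#' @return list with `dice` = 2|A.B|/(|A|+|B|) and `iou` = |A.B|/|A u B|;
#'   both 1 for two empty masks by convention
#' @export
dice_iou <- function(a, b) {
  if (length(a) != length(b)) stop_contract("mask shapes differ")
  inter <- sum(a * b)
  sa <- sum(a); sb <- sum(b)
  uni <- sa + sb - inter
  list(dice = if (sa + sb == 0) 1 else 2 * inter / (sa + sb),
       iou = if (uni == 0) 1 else inter / uni)
}

#' ROC area under the curve
#'
#' Trapezoidal AUC over all score thresholds; equivalently the probability
#' that a random positive outscores a random negative, ties counting half.
#'
#' @param scores numeric scores (higher = more "present")
#' @param true_labels `"present"`/`"absent"` or logical
#' @return AUC in \[0,1\]
#' @export
roc_auc <- function(scores, true_labels) {
  t <- as_present(true_labels)
  if (!any(t) || all(t)) stop_data("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  np <- sum(t); nn <- sum(!t)
  (sum(r[t]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' @param scores,true_labels as in [roc_auc()]
#' @return data.frame with threshold, fpr, tpr (sorted for plotting/export)
#' @export
roc_curve <- function(scores, true_labels) {
  t <- as_present(true_labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(th, function(s) {
    pred <- scores >= s
    c(fpr = sum(pred & !t) / max(sum(!t), 1),
      tpr = sum(pred & t) / max(sum(t), 1))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Rotate a clip by 180 degrees
#'
#' Every frame's pixel (r, c) maps to (H-1-r, W-1-c); the SVP label is
#' preserved and applying the augmentation twice restores the original clip
#' bit-exactly.
#'
#' @param clip classifier input array (frames, rows, cols, channels)
#' @return rotated clip of identical shape
#' @export
augment_rotate180 <- function(clip) {
  d <- dim(clip)
  clip[, d[2]:1, d[3]:1, , drop = FALSE]
}

#' Seeded balanced k-fold assignment
#'
#' @param n number of samples
#' @param k number of folds (default 5)
#' @param seed integer seed for the shuffle
#' @return integer vector of fold indices (1..k), fold sizes differing by
#'   at most 1, every sample in exactly one fold
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (k < 2 || k > n) stop_data("need 2 <= k <= n")
  folds <- integer(n)
  folds[with_seed(seed, sample.int(n))] <- rep_len(seq_len(k), n)
  folds
}

#' Iterate train/test index pairs of a fold assignment
#'
#' @param folds output of [kfold_split()]
#' @return list of `list(train = ..., test = ...)` per fold
#' @export
kfold_iter <- function(folds) {
  lapply(sort(unique(folds)), function(f)
    list(train = which(folds != f), test = which(folds == f)))
}

#' K-fold cross-validation of an SVP classifier
#'
#' Trains a fresh model per fold on the k-1 training folds - with
#' 180-degree-rotation augmentation applied to the training folds only, so
#' augmented copies never straddle the train/test boundary - and evaluates on
#' the held-out fold. Reports per-fold metrics plus the mean and standard
#' deviation across folds (population sd by default).
#'
#' `builder(cfg)` must return a list with `fit(inputs, labels)` and
#' `predict_prob(input)` (returning P(present)); [classifier_builder()] wraps
#' the package's network classifiers in this interface.
#'
#' @param builder model factory (see above)
#' @param inputs list of classifier inputs
#' @param labels character labels
#' @param cfg configuration passed to `builder`
#' @param k number of folds
#' @param seed seed for the fold shuffle
#' @param augment apply rotation augmentation to training folds
#' @param sd_type `"population"` (n divisor) or `"sample"` (n-1 divisor)
#' @return list with `per_fold` (data.frame), `mean`, `sd`, and `folds`
#' @export
cross_validate <- function(builder, inputs, labels, cfg = NULL, k = 5L,
                           seed = 1L, augment = TRUE,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(inputs)
  folds <- kfold_split(n, k, seed)
  metric_names <- c("sensitivity", "specificity", "precision", "accuracy",
                    "f1", "npv", "auc")
  rows <- list()
  for (sp in kfold_iter(folds)) {
    tr_x <- inputs[sp$train]; tr_y <- labels[sp$train]
    if (augment) {
      tr_x <- c(tr_x, lapply(inputs[sp$train], augment_rotate180))
      tr_y <- c(tr_y, labels[sp$train])
    }
    model <- builder(cfg)
    model$fit(tr_x, tr_y)
    probs <- vapply(inputs[sp$test], model$predict_prob, 0)
    preds <- ifelse(probs >= 0.5, "present", "absent")
    m <- classification_metrics(confusion(preds, labels[sp$test]))
    m$auc <- if (length(unique(labels[sp$test])) == 2)
      roc_auc(probs, labels[sp$test]) else NA_real_
    rows[[length(rows) + 1L]] <- as.data.frame(m)
  }
  per_fold <- do.call(rbind, rows)
  per_fold <- cbind(fold = seq_len(nrow(per_fold)), per_fold)
  mu <- vapply(metric_names, function(nm) mean(per_fold[[nm]], na.rm = TRUE), 0)
  sdv <- vapply(metric_names, function(nm) {
    v <- per_fold[[nm]][!is.na(per_fold[[nm]])]
    if (length(v) < 2) return(0)
    if (sd_type == "population") sqrt(mean((v - mean(v))^2)) else stats::sd(v)
  }, 0)
  list(per_fold = per_fold, mean = mu, sd = sdv, folds = folds)
}

#' Wrap a network classifier as a cross-validation builder
#'
#' @param architecture,preset,... forwarded to [classifier_config()]
#' @return a builder function for [cross_validate()]
#' @export
classifier_builder <- function(architecture = "convlstm", preset = "small", ...) {
  args <- list(architecture = architecture, preset = preset, ...)
  function(cfg = NULL) {
    config <- do.call(classifier_config, args)
    model <- build_classifier(config)
    list(
      fit = function(inputs, labels) train_classifier(model, inputs, labels),
      predict_prob = function(input) predict_svp(model, input)$probability)
  }
}

#' Format a cross-validation result like a per-fold report table
#'
#' @param cv output of [cross_validate()]
#' @return data.frame of percentages with per-fold rows and an `Ave.` row
#' @export
cv_report <- function(cv) {
  pf <- cv$per_fold
  metric_names <- setdiff(names(pf), "fold")
  tab <- round(100 * pf[metric_names])
  tab <- cbind(fold = as.character(pf$fold), tab)
  ave <- c(fold = "Ave.",
           as.list(sprintf("%.0f +/- %.0f", 100 * cv$mean, 100 * cv$sd)))
  rbind(tab, as.data.frame(ave, col.names = names(tab)))
}
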