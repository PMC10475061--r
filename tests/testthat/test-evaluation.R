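# Metrics, augmentation, and cross-validation machinery.

test_that("confusion tallies match a brute-force loop", {
  expect_equal(confusion(c("present", "absent"), c("present", "absent")),
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(confusion(c("absent", "present"), c("present", "absent")),
               list(TP = 0L, FP = 1L, TN = 0L, FN = 1L))
  set.seed(140)
  for (rep in 1:10) {
    p <- sample(c("present", "absent"), 50, TRUE)
    t <- sample(c("present", "absent"), 50, TRUE)
    cc <- confusion(p, t)
    tp <- fp <- tn <- fn <- 0L
    for (i in 1:50) {
      if (p[i] == "present" && t[i] == "present") tp <- tp + 1L
      if (p[i] == "present" && t[i] == "absent") fp <- fp + 1L
      if (p[i] == "absent" && t[i] == "absent") tn <- tn + 1L
      if (p[i] == "absent" && t[i] == "present") fn <- fn + 1L
    }
    expect_equal(cc, list(TP = tp, FP = fp, TN = tn, FN = fn))
  }
  expect_error(confusion("present", c("present", "absent")),
               class = "svpnet_contract_error")
})

test_that("classification metrics follow their closed forms", {
  all1 <- classification_metrics(list(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_true(all(unlist(all1) == 1))
  m <- classification_metrics(list(TP = 2, FP = 1, TN = 2, FN = 1))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$npv, 2 / 3)
  # zero denominator -> undefined (NA), not zero
  deg <- classification_metrics(list(TP = 0, FP = 0, TN = 3, FN = 2))
  expect_true(is.na(deg$precision))
  expect_equal(deg$specificity, 1)
  # identity sens * (TP + FN) == TP on random counts
  set.seed(141)
  for (rep in 1:50) {
    cc <- as.list(setNames(rpois(4, 5) + c(1, 0, 1, 0), c("TP", "FP", "TN", "FN")))
    mm <- classification_metrics(cc)
    expect_equal(mm$sensitivity * (cc$TP + cc$FN), cc$TP)
  }
})

test_that("dice and iou satisfy their algebraic identity", {
  m <- random_mask(8, 8)
  expect_equal(dice_iou(m, m), list(dice = 1, iou = 1))
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 1, 1), 2)
  expect_equal(dice_iou(a, b), list(dice = 0, iou = 0))
  ov <- dice_iou(matrix(c(1, 1, 1, 1, 0, 0), 2), matrix(c(0, 0, 1, 1, 1, 1), 2))
  expect_equal(ov$dice, 0.5)
  expect_equal(ov$iou, 1 / 3)
  set.seed(142)
  for (rep in 1:100) {
    x <- random_mask(6, 6); y <- random_mask(6, 6)
    di <- dice_iou(x, y)
    expect_equal(di$dice, 2 * di$iou / (1 + di$iou), tolerance = 1e-12)
    expect_gte(di$dice, di$iou)
  }
})

test_that("roc_auc equals the all-pairs oracle and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("present", "present", "absent", "absent")), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("present", "absent"), 5)), 0.5)
  set.seed(143)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    lb <- sample(c("present", "absent"), n, TRUE)
    if (length(unique(lb)) < 2) next
    pos <- sc[lb == "present"]; neg <- sc[lb == "absent"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(sc, lb), mean(pairs), tolerance = 1e-12)
    expect_equal(roc_auc(qlogis(pmin(pmax(sc, 1e-6), 1 - 1e-6)), lb),
                 roc_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c("present", "present", "present")),
               class = "svpnet_data_error")
})

test_that("rotation augmentation is an involution with the right index map", {
  set.seed(144)
  clip <- array(runif(30 * 8 * 6), c(30, 8, 6, 1))
  rot <- augment_rotate180(clip)
  expect_identical(dim(rot), dim(clip))
  expect_identical(augment_rotate180(rot), clip)
  # index oracle: (r, c) -> (H-1-r, W-1-c)
  for (k in 1:20) {
    t <- sample(30, 1); r <- sample(8, 1); c <- sample(6, 1)
    expect_identical(rot[t, r, c, 1], clip[t, 8 + 1 - r, 6 + 1 - c, 1])
  }
})

test_that("kfold_split partitions with balanced sizes", {
  f10 <- kfold_split(10, 5, seed = 1)
  expect_equal(as.integer(table(f10)), rep(2L, 5))
  f11 <- kfold_split(11, 5, seed = 1)
  expect_setequal(as.integer(table(f11)), c(3L, 2L))
  # every index tested exactly once across folds
  it <- kfold_iter(f11)
  tested <- sort(unlist(lapply(it, `[[`, "test")))
  expect_identical(tested, 1:11)
  for (sp in it) expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(kfold_split(20, 5, seed = 3), kfold_split(20, 5, seed = 3))
  expect_error(kfold_split(3, 5), class = "svpnet_data_error")
})

# a deterministic stand-in classifier: thresholds the mean absolute temporal
# difference of the clip (the pulsation signature), with the threshold fitted
# on the training folds
variance_builder <- function(cfg = NULL) {
  env <- new.env()
  feat <- function(x) mean(abs(x[2:30, , , 1] - x[1:29, , , 1]))
  list(
    fit = function(inputs, labels) {
      f <- vapply(inputs, feat, 0)
      env$thr <- (max(f[labels == "absent"]) + min(f[labels == "present"])) / 2
      env$n_train <- length(inputs)
    },
    predict_prob = function(x) ifelse(feat(x) > env$thr, 0.9, 0.1),
    env = env)
}

test_that("cross_validate trains per fold, augments only training folds", {
  spec <- clip_phantom_spec(pulsation_amplitude = 0.5, noise_sd = 0.002)
  ds <- make_dataset(0, 20, spec, seed = 55)
  inputs <- clips_to_classifier_inputs(ds$clips)
  labels <- vapply(ds$clips, `[[`, "", "label")
  sizes <- integer(0)
  builder <- function(cfg) {
    b <- variance_builder(cfg)
    fit0 <- b$fit
    b$fit <- function(inputs, labels) {
      fit0(inputs, labels)
      sizes <<- c(sizes, length(inputs))
    }
    b
  }
  cv <- cross_validate(builder, inputs, labels, k = 5, seed = 2)
  expect_equal(nrow(cv$per_fold), 5)
  # augmentation doubles every training fold (16 -> 32), never the test fold
  expect_equal(sizes, rep(32L, 5))
  expect_true(all(cv$per_fold$accuracy == 1))
  expect_equal(unname(cv$sd["accuracy"]), 0)
  # deterministic
  cv2 <- cross_validate(variance_builder, inputs, labels, k = 5, seed = 2)
  expect_equal(cv$per_fold, cv2$per_fold)
})

test_that("mean +/- sd reporting matches hand arithmetic (population sd)", {
  folds <- c(78, 99, 91, 88, 99) / 100
  mu <- mean(folds)
  expect_equal(round(100 * mu), 91)
  sd_pop <- sqrt(mean((folds - mu)^2))
  sd_smp <- stats::sd(folds)
  expect_lt(sd_pop, sd_smp)
  expect_equal(round(100 * sd_pop), 8)
})
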