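# Confusion-count metric suite and focal loss.

test_that("confusion counts match hand enumeration and identity cases", {
  # 2x2 case enumerated pixel by pixel: pred (0,1,1,1), true (0,0,1,1)
  pred <- matrix(c(0, 1, 1, 1), 2)
  true <- matrix(c(0, 0, 1, 1), 2)
  cc <- confusion_counts(pred, true, 2)
  expect_equal(unname(cc$tp["class1"]), 2)
  expect_equal(unname(cc$fp["class1"]), 1)
  expect_equal(unname(cc$fn["class1"]), 0)
  expect_equal(unname(cc$tn["class1"]), 1)

  # identical masks: no confusion, tp sums to pixel count
  m <- random_mask(8, 3, seed = 4)
  cc <- confusion_counts(m, m, 3)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  expect_equal(sum(cc$tp), length(m))

  # class absent from both masks: all tallies in tn
  z <- matrix(0L, 3, 3)
  cc <- confusion_counts(z, z, 2)
  expect_equal(unname(cc$tp["class1"]), 0)
  expect_equal(unname(cc$fp["class1"]), 0)
  expect_equal(unname(cc$fn["class1"]), 0)
  expect_equal(unname(cc$tn["class1"]), 9)

  # per-class tallies always partition the image
  for (cl in 0:1)
    expect_equal(cc$tp[cl + 1] + cc$fp[cl + 1] + cc$fn[cl + 1] +
                   cc$tn[cl + 1], unname(9), ignore_attr = TRUE)

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3), 2), "shape")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2), 2),
               "num_classes")
})

test_that("ratio metrics follow their formulas on fixed counts", {
  cc <- confusion_counts(matrix(c(rep(1, 4), rep(0, 2), rep(1, 2), rep(0, 4)), 3),
                         matrix(c(rep(1, 3), rep(0, 3), rep(1, 4), rep(0, 2)), 3), 2)
  # force the documented arithmetic instead: tp=3, fp=1, fn=2 style example
  k <- list(tp = 3, fp = 1, fn = 2)
  cc$tp["class1"] <- k$tp; cc$fp["class1"] <- k$fp; cc$fn["class1"] <- k$fn
  cc$tn["class1"] <- cc$total - k$tp - k$fp - k$fn
  expect_equal(iou(cc, 1), 0.5)
  expect_equal(dice(cc, 1), 2 * 3 / (6 + 1 + 2))
  expect_equal(precision(cc, 1), 0.75)
  expect_equal(recall(cc, 1), 0.6)

  cc$tp["class1"] <- 1; cc$fp["class1"] <- 1; cc$fn["class1"] <- 2
  expect_equal(dice(cc, 1), 0.4)
  expect_equal(iou(cc, 1), 0.25)
})

test_that("perfect prediction scores 1 everywhere", {
  m <- random_mask(16, 2, seed = 2)
  rep <- metrics_report(confusion_counts(m, m, 2))
  expect_equal(rep$miou, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$dice_score, 1)
  expect_true(all(rep$per_class$iou == 1))
})

test_that("metric suite agrees exactly with the set-based oracle", {
  set.seed(99)
  for (trial in 1:60) {
    nc <- sample(2:3, 1)
    pred <- random_mask(16, nc, seed = 1000 + trial)
    true <- random_mask(16, nc, seed = 2000 + trial)
    cc <- confusion_counts(pred, true, nc)
    or <- oracle_report(pred, true, nc)
    for (cl in 0:(nc - 1)) {
      expect_identical(iou(cc, cl), or$iou[cl + 1])
      expect_identical(precision(cc, cl), or$prec[cl + 1])
      expect_identical(recall(cc, cl), or$rec[cl + 1])
      expect_identical(dice(cc, cl), or$dice[cl + 1])
    }
    rep <- metrics_report(cc)
    expect_identical(rep$miou, mean(or$iou))
    expect_identical(rep$dice_score, mean(or$dice[-1]))
  }
})

test_that("sparse masks exercise the empty-denominator convention", {
  # class 2 absent from both masks scores 1; predicted-only or truth-only
  # classes score 0
  pred <- matrix(0L, 4, 4); pred[1, 1] <- 1L
  true <- matrix(0L, 4, 4); true[4, 4] <- 1L
  cc <- confusion_counts(pred, true, 3)
  expect_equal(iou(cc, 2), 1)
  expect_equal(dice(cc, 2), 1)
  expect_equal(precision(cc, 1), 0)
  expect_equal(recall(cc, 1), 0)
  expect_false(any(is.nan(unlist(metrics_report(cc)[c("miou", "f1")]))))
})

test_that("IoU/Dice identities hold on random counts", {
  set.seed(7)
  for (trial in 1:100) {
    pred <- random_mask(8, 3, seed = 300 + trial)
    true <- random_mask(8, 3, seed = 400 + trial)
    cc <- confusion_counts(pred, true, 3)
    for (cl in 0:2) {
      d <- dice(cc, cl); i <- iou(cc, cl)
      expect_equal(i, d / (2 - d), tolerance = 1e-12)
      expect_equal(d, 2 * i / (1 + i), tolerance = 1e-12)
    }
  }
  # harmonic mean of equal arguments is the identity
  for (x in c(0.1, 0.5, 0.9738)) expect_equal(f1_score(x, x), x)
})

test_that("F1 from macro precision/recall reproduces published arithmetic", {
  expect_equal(round(f1_score(0.9738, 0.9693), 4), 0.9715)
  expect_equal(round(f1_score(0.9455, 0.9480), 4), 0.9467)
  expect_equal(round(f1_score(0.9644, 0.9661), 4), 0.9652)
})

test_that("single-foreground-class dice equals the class-level F1", {
  # algebraic identity: dice = 2PR/(P+R) of that class's precision/recall,
  # distinct from the macro-mean F1
  set.seed(5)
  for (trial in 1:20) {
    pred <- random_mask(12, 2, seed = 500 + trial)
    true <- random_mask(12, 2, seed = 600 + trial)
    cc <- confusion_counts(pred, true, 2)
    expect_equal(dice(cc, 1), f1_score(precision(cc, 1), recall(cc, 1)),
                 tolerance = 1e-12)
  }
})

test_that("focal loss matches analytic values", {
  expect_equal(focal_loss(0.5, 1), 0.5 * 0.25 * log(2), tolerance = 1e-9)
  expect_equal(focal_loss(1, 1), 0, tolerance = 1e-6)
  # gamma = 0 reduces to alpha-weighted cross-entropy
  set.seed(3)
  p <- runif(50, 0.05, 0.95)
  y <- rbinom(50, 1, 0.5)
  fl <- focal_loss(p, y, focal_loss_params(alpha = 0.5, gamma = 0))
  ce <- mean(ifelse(y == 1, -0.5 * log(p), -0.5 * log(1 - p)))
  expect_equal(fl, ce, tolerance = 1e-9)
})

test_that("focal loss is monotone in p and focused by gamma", {
  p <- seq(0.05, 0.95, by = 0.05)
  l <- vapply(p, function(pp) focal_loss(pp, 1), 0)
  expect_true(all(diff(l) < 0))  # decreasing in p when y = 1
  # larger gamma never increases the loss of well-classified pixels
  for (pp in c(0.6, 0.8, 0.95)) {
    l2 <- focal_loss(pp, 1, focal_loss_params(gamma = 2))
    l4 <- focal_loss(pp, 1, focal_loss_params(gamma = 4))
    expect_lte(l4, l2)
  }
  expect_gte(focal_loss(runif(1), rbinom(1, 1, 0.5)), 0)
})

test_that("multi-class focal loss gathers the true-class probability", {
  prob <- array(0, c(2, 2, 3))
  prob[, , 1] <- 0.2; prob[, , 2] <- 0.5; prob[, , 3] <- 0.3
  target <- matrix(1L, 2, 2)  # true class 1 everywhere -> p_t = 0.5
  expect_equal(focal_loss(prob, target), 0.5 * 0.25 * log(2),
               tolerance = 1e-9)
  expect_error(focal_loss_params(gamma = -1), "gamma")
  expect_error(focal_loss_params(alpha = 1.5), "alpha")
})
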