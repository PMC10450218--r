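# Cosine schedule, freeze-thaw, checkpoints, the training loop, evaluation.

test_that("cosine learning rate matches the closed form", {
  expect_equal(cosine_lr(0, 200, 1e-4), 1e-4)
  expect_equal(cosine_lr(200, 200, 1e-4), 0)
  expect_equal(cosine_lr(100, 200, 1e-4), 5e-5)
  for (t in 0:50)
    expect_equal(cosine_lr(t, 50, 3e-3), 3e-3 * 0.5 * (1 + cos(pi * t / 50)),
                 tolerance = 1e-12)
  expect_error(cosine_lr(51, 50), "\\[0, T\\]")
  expect_error(cosine_lr(-1, 50), "\\[0, T\\]")
})

make_tiny_samples <- function(n = 4, size = 32, seed = 31) {
  spec <- synthetic_spec(image_size = size, seed = seed)
  lapply(seq_len(n), function(i)
    generate_sample(spec, seed = seed + i, id = paste0("s", i)))
}

test_that("freeze keeps encoder weights bit-identical through a step", {
  m <- caunet(tiny_config())
  samples <- make_tiny_samples()
  freeze_backbone(m)
  freeze_backbone(m)  # idempotent
  expect_gt(length(m$state$frozen), 0)
  enc_before <- lapply(grep("^enc\\.", caunet:::param_names(m), value = TRUE),
                       function(nm) m$params[[nm]])
  dec_before <- m$params[["dec.end.proj.w"]]
  tc <- train_config(batch_size = 4, epochs = 1, lr0 = 1e-3,
                     freeze_epochs = 0, eval_every = 10, seed = 1)
  ## run one epoch manually with the freeze in place
  m$state$frozen <- grep("^enc\\.", caunet:::param_names(m), value = TRUE)
  fit <- caunet_train(samples, m, tc)
  NULL
  enc_after <- lapply(grep("^enc\\.", caunet:::param_names(m), value = TRUE),
                      function(nm) m$params[[nm]])
  expect_identical(enc_before, enc_after)
  expect_false(identical(dec_before, m$params[["dec.end.proj.w"]]))

  thaw(m)
  expect_length(m$state$frozen, 0)
  fit <- caunet_train(samples, m, tc)
  enc_thawed <- lapply(grep("^enc\\.", caunet:::param_names(m), value = TRUE),
                       function(nm) m$params[[nm]])
  expect_false(identical(enc_before, enc_thawed))
})

test_that("freeze-thaw schedule inside the loop flips at freeze_epochs", {
  m <- caunet(tiny_config())
  samples <- make_tiny_samples()
  enc_names <- grep("^enc\\.", caunet:::param_names(m), value = TRUE)
  snap <- lapply(enc_names, function(nm) m$params[[nm]])
  tc <- train_config(batch_size = 4, epochs = 2, lr0 = 1e-3,
                     freeze_epochs = 1, eval_every = 10, seed = 1)
  caunet_train(samples, m, tc)
  after <- lapply(enc_names, function(nm) m$params[[nm]])
  expect_false(identical(snap, after))  # thaw phase updated the encoder
  expect_error(train_config(epochs = 10, freeze_epochs = 10), "freeze_epochs")
})

test_that("checkpoints round-trip and strict loading enforces shapes", {
  m <- caunet(tiny_config(seed = 2))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  x <- random_image_batch(32, n = 1, seed = 3)
  expect_identical(caunet_forward(m, x), caunet_forward(m2, x))

  # same-config archive: zero skipped keys
  m3 <- caunet(tiny_config(seed = 9))
  rep <- load_pretrained(m3, f)
  expect_length(rep$skipped, 0)
  expect_setequal(rep$loaded, caunet:::param_names(m))
  expect_identical(caunet_forward(m3, x), caunet_forward(m, x))

  # empty archive: everything skipped, model unchanged, strict errors
  empty <- tempfile(fileext = ".rds")
  saveRDS(list(params = list(), buffers = list()), empty)
  m4 <- caunet(tiny_config(seed = 5))
  before <- m4$params[["enc.init.conv.w"]]
  rep <- load_pretrained(m4, empty)
  expect_length(rep$loaded, 0)
  expect_identical(m4$params[["enc.init.conv.w"]], before)
  expect_error(load_pretrained(m4, empty, strict = TRUE), "strict")

  # shape clash on a matching key
  clash <- tempfile(fileext = ".rds")
  saveRDS(list(params = list(`enc.init.conv.w` = array(0, c(1, 1, 3, 4))),
               buffers = list()), clash)
  expect_error(load_pretrained(m4, clash), "shape mismatch")
  unlink(c(f, empty, clash))
})

test_that("the loss at step 0 equals an independent focal evaluation", {
  m <- caunet(tiny_config(seed = 7))
  samples <- make_tiny_samples(4)
  b <- as_batch(samples)
  # independent route: plain forward probabilities through the numeric
  # focal loss
  logits <- caunet_forward(m, b$x, train = TRUE)
  dm <- dim(logits)
  lp <- matrix(aperm(logits, c(1, 2, 4, 3)), prod(dm[c(1, 2, 4)]), dm[3])
  pr <- exp(lp - apply(lp, 1, max))
  pr <- pr / rowSums(pr)
  prob <- array(pr, c(dm[1], dm[2], dm[4], dm[3]))
  independent <- focal_loss(prob, array(b$y, dm[c(1, 2, 4)]))
  wired <- caunet_loss(m, b$x, b$y, train = TRUE)
  expect_equal(wired, independent, tolerance = 1e-9)
})

test_that("training is reproducible and the log matches the closed-form lr", {
  samples <- make_tiny_samples(4)
  tc <- train_config(batch_size = 4, epochs = 3, lr0 = 1e-3,
                     freeze_epochs = 0, eval_every = 10, seed = 1)
  f1 <- caunet_train(samples, caunet(tiny_config(seed = 3)), tc)
  f2 <- caunet_train(samples, caunet(tiny_config(seed = 3)), tc)
  expect_identical(f1$log$train_loss, f2$log$train_loss)
  expect_equal(f1$log$lr, cosine_lr(0:2, 3, 1e-3), tolerance = 1e-12)
  expect_identical(coef(f1$model), coef(f2$model))
})

test_that("evaluate pools counts and matches the metric oracle", {
  m <- caunet(tiny_config(num_classes = 2, seed = 8))
  samples <- make_tiny_samples(3)
  rep <- evaluate(m, samples)
  # recompute from pooled counts dumped sample by sample
  tot <- list(tp = c(0, 0), fp = c(0, 0), fn = c(0, 0), tn = c(0, 0))
  for (s in samples) {
    cc <- confusion_counts(predict(m, s$image), s$mask, 2)
    for (f in names(tot)) tot[[f]] <- tot[[f]] + unname(cc[[f]])
  }
  d1 <- 2 * tot$tp[2] / (2 * tot$tp[2] + tot$fp[2] + tot$fn[2])
  expect_equal(rep$dice_score, d1, tolerance = 1e-12)

  # ground truth as prediction: every ratio is 1
  perfect <- metrics_report(confusion_counts(samples[[1]]$mask,
                                             samples[[1]]$mask, 2))
  expect_equal(perfect$miou, 1)
  expect_equal(perfect$f1, 1)

  # all-background predictions: zero foreground recall
  cc <- confusion_counts(samples[[1]]$mask * 0L, samples[[1]]$mask, 2)
  expect_equal(recall(cc, 1), 0)
})
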