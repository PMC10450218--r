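#' Cosine-annealed learning rate
#'
#' `lr0 * (1 + cos(pi * t / T)) / 2`: starts at `lr0` (t = 0), halves at
#' `t = T/2`, reaches 0 at `t = T`.
#'
#' @param t epoch index, `0 <= t <= T`.
#' @param T total epochs.
#' @param lr0 initial learning rate.
#' @return the learning rate at epoch `t`.
#' @examples
#' cosine_lr(0, 200, 1e-4)
#' @export
cosine_lr <- function(t, T, lr0 = 1e-4) {
  if (any(t < 0 | t > T)) stop("`t` must lie in [0, T]")
  if (lr0 <= 0) stop("`lr0` must be positive")
  lr0 * 0.5 * (1 + cos(pi * t / T))
}

#' Training settings
#'
#' @param batch_size samples per optimization step.
#' @param epochs total training epochs.
#' @param lr0 initial learning rate, annealed to 0 by [cosine_lr()].
#' @param momentum_beta Adam first-moment decay; the optimizer is Adam with
#'   `beta1 = momentum_beta`, `beta2 = 0.999`.
#' @param freeze_epochs epochs during which encoder weights stay frozen
#'   (the freeze phase of freeze-thaw fine-tuning); must be < `epochs`.
#'   Meaningful with pretrained weights; use 0 when training from scratch.
#' @param train_fraction train share if the sample list is split internally;
#'   `NULL` trains on everything.
#' @param loss a [focal_loss_params()] object.
#' @param clip_norm clip the global gradient norm to this value before each
#'   Adam step (`Inf` disables clipping).
#' @param eval_every compute test metrics every this many epochs.
#' @param seed seed controlling shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(batch_size = 12, epochs = 200, lr0 = 1e-4,
                         momentum_beta = 0.975, freeze_epochs = 0,
                         train_fraction = NULL, loss = focal_loss_params(),
                         clip_norm = 1, eval_every = 10, seed = 1L) {
  if (freeze_epochs >= epochs) stop("`freeze_epochs` must be < `epochs`")
  if (lr0 <= 0) stop("`lr0` must be positive")
  if (clip_norm <= 0) stop("`clip_norm` must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 momentum_beta = momentum_beta,
                 freeze_epochs = as.integer(freeze_epochs),
                 train_fraction = train_fraction, loss = loss,
                 clip_norm = clip_norm, eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

clip_grads <- function(grads, clip_norm) {
  if (!is.finite(clip_norm)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (nrm > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / nrm))
  grads
}

#' Freeze the encoder (backbone) weights
#'
#' Marks every encoder parameter non-trainable so optimizer steps leave the
#' backbone untouched; decoder and skip-transformer weights keep training.
#' Idempotent. The model is updated in place and returned invisibly.
#'
#' @param model a [caunet()] model.
#' @export
freeze_backbone <- function(model) {
  model$state$frozen <- grep("^enc\\.", param_names(model), value = TRUE)
  invisible(model)
}

#' Unfreeze all weights
#' @param model a [caunet()] model.
#' @export
thaw <- function(model) {
  model$state$frozen <- character()
  invisible(model)
}

#' Save model weights (and config) to a checkpoint file
#'
#' A single serialized archive keyed by parameter path, with the model
#' config and batch-norm running statistics embedded.
#'
#' @param model a [caunet()] model or a [caunet_train()] fit.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "caunet_fit")) model <- model$model
  obj <- list(config = model$config,
              params = as.list(model$params),
              buffers = as.list(model$buffers))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint into a fresh model
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a [caunet()] model.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- caunet(obj$config)
  for (nm in names(obj$params)) model$params[[nm]] <- obj$params[[nm]]
  for (nm in names(obj$buffers)) model$buffers[[nm]] <- obj$buffers[[nm]]
  model
}

#' Load pretrained weights into a model (transfer-learning hook)
#'
#' Copies every archive tensor whose key exists in the model; a shape clash
#' on a matching key is always an error. With `strict = TRUE` any key
#' present on one side only is also an error; otherwise such keys are
#' skipped and reported.
#'
#' @param model a [caunet()] model (updated in place).
#' @param path checkpoint file.
#' @param strict require an exact key match.
#' @return (invisibly) a list with `loaded` and `skipped` key vectors.
#' @export
load_pretrained <- function(model, path, strict = FALSE) {
  obj <- readRDS(path)
  have <- param_names(model)
  loaded <- character(); skipped <- character()
  for (nm in names(obj$params)) {
    if (!nm %in% have) { skipped <- c(skipped, nm); next }
    new <- obj$params[[nm]]
    cur <- model$params[[nm]]
    if (!identical(dim(new), dim(cur)) || length(new) != length(cur))
      stop("shape mismatch for '", nm, "'")
    model$params[[nm]] <- new
    loaded <- c(loaded, nm)
  }
  missing <- setdiff(have, names(obj$params))
  if (strict && (length(skipped) || length(missing)))
    stop("strict loading failed: ", length(skipped), " unknown and ",
         length(missing), " missing keys")
  for (nm in names(obj$buffers))
    if (!is.null(model$buffers[[nm]])) model$buffers[[nm]] <- obj$buffers[[nm]]
  invisible(list(loaded = loaded, skipped = c(skipped, missing)))
}

## ---- Adam -----------------------------------------------------------------

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

adam_step <- function(model, grads, opt, lr, beta1, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  frozen <- model$state$frozen
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    m <- opt$m[[nm]]
    if (is.null(m)) { m <- g * 0; opt$v[[nm]] <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] -
      lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  invisible(NULL)
}

## ---- batching helpers -----------------------------------------------------

#' Stack image samples into model input arrays
#'
#' Normalizes each image with [normalize_minmax()] (unless already
#' normalized) and stacks images and masks into `(H, W, 3, N)` and
#' `(H, W, N)` arrays.
#'
#' @param samples list of image samples.
#' @return list with `x` and `y`.
#' @export
as_batch <- function(samples) {
  n <- length(samples)
  dm <- dim(samples[[1]]$image)
  x <- array(0, c(dm[1], dm[2], 3, n))
  y <- array(0L, c(dm[1], dm[2], n))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    if (!isTRUE(samples[[i]]$normalized)) img <- normalize_minmax(img)
    x[, , , i] <- img
    y[, , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

focal_alpha_vec <- function(params, num_classes) {
  c(1 - params$alpha, rep(params$alpha, num_classes - 1))
}

#' One traced forward + focal loss evaluation (no update)
#'
#' Builds the computation on the autodiff tape and returns the scalar focal
#' loss of the current weights on a batch; used by the training loop and
#' handy for wiring checks.
#'
#' @param model a [caunet()] model.
#' @param x input batch `(H, W, 3, N)`.
#' @param y integer target masks `(H, W, N)`.
#' @param loss_params a [focal_loss_params()].
#' @param train batch-norm mode.
#' @return scalar loss (plain number).
#' @export
caunet_loss <- function(model, x, y, loss_params = focal_loss_params(),
                        train = FALSE) {
  logits <- caunet_forward(model, x, train = train)
  av <- focal_alpha_vec(loss_params, model$config$num_classes)
  vof(ag_focal_from_logits(logits, y, av, loss_params$gamma))
}

## ---- training loop --------------------------------------------------------

#' Train the network
#'
#' Seeded Adam training with cosine-annealed learning rate and an optional
#' freeze phase: during the first `freeze_epochs` epochs all encoder weights
#' are frozen, after which the whole network thaws. Per-epoch learning rate,
#' training loss and periodic mIoU/F1/Dice are logged. Checkpoint selection
#' keeps the weights with the highest mIoU on the held-out split — or, when
#' nothing is held out, on the training set — measured every `eval_every`
#' epochs.
#'
#' @param samples list of image samples, or a manifest CSV path.
#' @param model a [caunet()] model, updated in place; or a [caunet_config()]
#'   from which a fresh model is built.
#' @param config a [train_config()].
#' @return an object of class `caunet_fit`: list with the trained `model`,
#'   the per-epoch `log` data frame, `best` (epoch and mIoU of the retained
#'   weights) and the split ids.
#' @export
caunet_train <- function(samples, model, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (is.character(samples)) samples <- read_manifest(samples)
  if (length(samples) == 0) stop("no training samples")
  if (inherits(model, "caunet_config")) model <- caunet(model)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  test <- list()
  if (!is.null(config$train_fraction)) {
    sp <- split_dataset(seq_along(samples), config$train_fraction,
                        seed = config$seed)
    test <- samples[sp$test]
    samples <- samples[sp$train]
  }
  if (length(samples) == 0) stop("empty training split")
  nb <- max(1L, ceiling(length(samples) / config$batch_size))
  opt <- adam_state()
  av <- focal_alpha_vec(config$loss, model$config$num_classes)

  ## a schedule freeze starts here; a manual freeze_backbone() persists
  if (config$freeze_epochs > 0) freeze_backbone(model)
  log <- vector("list", config$epochs)
  best <- list(miou = -Inf, epoch = NA_integer_, params = NULL,
               buffers = NULL)
  for (epoch in seq_len(config$epochs)) {
    if (epoch == config$freeze_epochs + 1L && config$freeze_epochs > 0)
      thaw(model)
    lr <- cosine_lr(epoch - 1L, config$epochs, config$lr0)
    ord <- sample(length(samples))
    eloss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[seq.int((b - 1L) * config$batch_size + 1L,
                         min(b * config$batch_size, length(samples)))]
      batch <- as_batch(samples[idx])
      ag_start()
      xs <- new_node(batch$x)
      logits <- caunet_forward(model, xs, train = TRUE)
      loss <- ag_focal_from_logits(logits, batch$y, av, config$loss$gamma)
      ag_backward(loss)
      grads <- ag_leaf_grads()
      eloss <- eloss + vof(loss) * length(idx)
      ag_stop()
      grads <- clip_grads(grads, config$clip_norm)
      adam_step(model, grads, opt, lr, config$momentum_beta)
    }
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = eloss / length(samples),
                      test_miou = NA_real_, test_f1 = NA_real_,
                      test_dice = NA_real_)
    if (epoch %% config$eval_every == 0 || epoch == config$epochs) {
      ## checkpoint selection: highest mIoU on the held-out split, or on
      ## the training set itself when nothing is held out
      rep <- evaluate(model, if (length(test)) test else samples)
      row$test_miou <- rep$miou
      row$test_f1 <- rep$f1
      row$test_dice <- rep$dice_score
      if (rep$miou > best$miou)
        best <- list(miou = rep$miou, epoch = epoch,
                     params = as.list(model$params),
                     buffers = as.list(model$buffers))
    }
    log[[epoch]] <- row
  }
  if (!is.null(best$params)) {
    for (nm in names(best$params)) model$params[[nm]] <- best$params[[nm]]
    for (nm in names(best$buffers)) model$buffers[[nm]] <- best$buffers[[nm]]
  } else best <- list(miou = NA_real_, epoch = config$epochs)
  structure(list(model = model, log = do.call(rbind, log),
                 best = best[c("miou", "epoch")],
                 n_train = length(samples), n_test = length(test)),
            class = "caunet_fit")
}

#' @export
print.caunet_fit <- function(x, ...) {
  cat("Trained segmentation network\n")
  cat(sprintf("  %d epochs on %d samples (%d held out)\n",
              nrow(x$log), x$n_train, x$n_test))
  cat(sprintf("  final train loss %.5f\n", utils::tail(x$log$train_loss, 1)))
  if (!is.na(x$best$miou))
    cat(sprintf("  best test mIoU %.4f at epoch %d\n", x$best$miou,
                x$best$epoch))
  invisible(x)
}

#' Plot training curves
#' @param x a [caunet_train()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.caunet_fit <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$train_loss, type = "l",
                 xlab = "epoch", ylab = "focal loss", ...)
  if (any(!is.na(x$log$test_miou))) {
    ok <- !is.na(x$log$test_miou)
    graphics::lines(x$log$epoch[ok], x$log$test_miou[ok], lty = 2)
    graphics::legend("topright", c("train loss", "test mIoU"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' @export
predict.caunet_fit <- function(object, image, ...) {
  predict(object$model, image, ...)
}

#' Evaluate a model on a sample set
#'
#' Predicts every sample, pools confusion counts over all images (micro
#' aggregation), then computes the metric report (macro over classes).
#'
#' @param model a [caunet()] model, [caunet_train()] fit, or checkpoint
#'   path.
#' @param samples list of image samples or a manifest CSV path.
#' @return a [metrics_report()].
#' @export
evaluate <- function(model, samples) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "caunet_fit")) model <- model$model
  if (is.character(samples)) samples <- read_manifest(samples)
  if (length(samples) == 0) stop("no samples to evaluate")
  nc <- model$config$num_classes
  if (max(vapply(samples, function(s) max(s$mask), 0)) >= nc)
    stop("mask classes exceed the model's class count")
  pooled <- NULL
  for (s in samples) {
    pred <- predict(model, s$image)
    cc <- confusion_counts(pred, s$mask, nc)
    if (is.null(pooled)) pooled <- cc
    else for (f in c("tp", "fp", "fn", "tn"))
      pooled[[f]] <- pooled[[f]] + cc[[f]]
  }
  pooled$total <- sum(pooled$tp + pooled$fp)
  metrics_report(pooled)
}
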