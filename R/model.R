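#' Network configuration
#'
#' Hyperparameters of the channel cross-attention U-style network: four
#' encoder stages of widths `C1..C4` (each halves the spatial size), a
#' skip-connection transformer with `layers` stacked channel cross-attention
#' blocks of `heads` heads over token sequences of length `token_len`, and a
#' mirrored attention decoder.
#'
#' @param num_classes classes including background (2 or 3 for the nasal
#'   bleeding label schemes).
#' @param input_size square input side in pixels; must be divisible by 16.
#' @param widths channel widths `C1..C4` of the four encoder stages.
#' @param groups group count of the grouped convolution inside each Down
#'   Block (parameter count shrinks by exactly `1/groups`).
#' @param se_reduction bottleneck reduction of the squeeze-and-excitation
#'   gate and the decoder channel-attention MLP.
#' @param heads attention heads; must divide `token_len`.
#' @param layers stacked transformer layers on the skip path.
#' @param token_len common token sequence length `d`; must be a perfect
#'   square whose root divides `input_size / 16`. Defaults to
#'   `(input_size / 16)^2`.
#' @param expand channel expansion factor of the Down Block bottleneck.
#' @param seed seed for weight initialization.
#' @return a list of class `caunet_config`.
#' @export
caunet_config <- function(num_classes = 2, input_size = 224,
                          widths = c(32, 64, 128, 256), groups = 4,
                          se_reduction = 4, heads = 4, layers = 4,
                          token_len = NULL, expand = 2, seed = 1L) {
  if (input_size %% 16 != 0) stop("`input_size` must be divisible by 16")
  if (length(widths) != 4) stop("`widths` must give four channel counts")
  if (is.null(token_len)) token_len <- (input_size / 16)^2
  gt <- sqrt(token_len)
  if (gt != round(gt)) stop("`token_len` must be a perfect square")
  if ((input_size / 16) %% gt != 0)
    stop("sqrt(token_len) must divide input_size / 16")
  if (token_len %% heads != 0) stop("`heads` must divide `token_len`")
  if (layers < 1) stop("`layers` must be at least 1")
  c0 <- widths[1]
  prev <- c(c0, widths[1:3])
  for (i in 1:4) {
    ce <- expand * prev[i]
    if (ce %% groups != 0)
      stop("expanded width ", ce, " not divisible by groups = ", groups)
    if (ce %% se_reduction != 0)
      stop("expanded width ", ce, " not divisible by se_reduction = ",
           se_reduction)
  }
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 widths = as.integer(widths), groups = as.integer(groups),
                 se_reduction = as.integer(se_reduction),
                 heads = as.integer(heads), layers = as.integer(layers),
                 token_len = as.integer(token_len),
                 expand = as.integer(expand), seed = as.integer(seed)),
            class = "caunet_config")
}

#' Weight count of a grouped convolution
#'
#' A `k x k` convolution from `c_in` to `c_out` channels split into `g`
#' groups carries `k^2 * c_in * c_out / g` weights: exactly `1/g` of the
#' ungrouped count.
#'
#' @param c_in,c_out input/output channel counts, both divisible by `g`.
#' @param k kernel side.
#' @param g group count.
#' @return the weight count (biases excluded).
#' @examples
#' grouped_conv_param_count(8, 8, 3, 2)  # 288 = 576 / 2
#' @export
grouped_conv_param_count <- function(c_in, c_out, k, g) {
  if (c_in %% g != 0 || c_out %% g != 0)
    stop("`g` must divide both channel counts")
  k^2 * c_in * c_out / g
}

init_conv <- function(dims) {
  fan_in <- prod(dims[1:3])
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

init_linear <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

add_bn <- function(params, buffers, key, C) {
  params[[paste0(key, ".gamma")]] <- rep(1, C)
  params[[paste0(key, ".beta")]] <- rep(0, C)
  buffers[[paste0(key, ".mean")]] <- rep(0, C)
  buffers[[paste0(key, ".var")]] <- rep(1, C)
}

#' Build the channel cross-attention U-style segmentation network
#'
#' Constructs the full model: initialization block, four
#' squeeze-and-excitation gated grouped-convolution Down Blocks, the
#' channel cross-attention skip transformer, four Up Attention Blocks with
#' channel+spatial attention fusion, and the End Block projecting to
#' per-pixel class scores. Weights are freshly initialized from
#' `config$seed`. The returned object is environment-backed: training and
#' weight loading update it in place.
#'
#' @param config a [caunet_config()].
#' @return an object of class `caunet`.
#' @seealso [caunet_train()], [predict.caunet()], [encode()],
#'   [sc_transformer()], [caunet_forward()]
#' @export
caunet <- function(config = caunet_config()) {
  stopifnot(inherits(config, "caunet_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  P <- new.env(parent = emptyenv())
  B <- new.env(parent = emptyenv())
  w <- config$widths; c0 <- w[1]
  r <- config$se_reduction
  ## encoder
  P[["enc.init.conv.w"]] <- init_conv(c(3, 3, 3, c0))
  add_bn(P, B, "enc.init.bn", c0)
  prev <- c(c0, w[1:3])
  for (i in 1:4) {
    cp <- prev[i]; ce <- config$expand * cp; ci <- w[i]
    pre <- paste0("enc.down", i, ".")
    P[[paste0(pre, "expand.w")]] <- init_conv(c(1, 1, cp, ce))
    add_bn(P, B, paste0(pre, "expand.bn"), ce)
    P[[paste0(pre, "gconv.w")]] <- init_conv(c(3, 3, ce / config$groups, ce))
    add_bn(P, B, paste0(pre, "gconv.bn"), ce)
    h <- ce / r
    P[[paste0(pre, "se.w1")]] <- init_linear(h, ce)
    P[[paste0(pre, "se.b1")]] <- rep(0, h)
    P[[paste0(pre, "se.w2")]] <- init_linear(ce, h)
    P[[paste0(pre, "se.b2")]] <- rep(0, ce)
    P[[paste0(pre, "reduce.w")]] <- init_conv(c(1, 1, ce, cp))
    add_bn(P, B, paste0(pre, "reduce.bn"), cp)
    P[[paste0(pre, "conv1.w")]] <- init_conv(c(3, 3, cp, ci))
    add_bn(P, B, paste0(pre, "conv1.bn"), ci)
    P[[paste0(pre, "conv2.w")]] <- init_conv(c(3, 3, ci, ci))
    add_bn(P, B, paste0(pre, "conv2.bn"), ci)
  }
  ## skip transformer
  d <- config$token_len
  dh <- d / config$heads
  csum <- sum(w)
  for (l in seq_len(config$layers)) {
    pre <- paste0("sct.l", l, ".")
    P[[paste0(pre, "k.w")]] <- init_linear(csum, d)
    P[[paste0(pre, "v.w")]] <- init_linear(csum, d)
    for (i in 1:4) {
      ci <- w[i]
      P[[paste0(pre, "q", i, ".w")]] <- init_linear(ci, d)
      P[[paste0(pre, "o", i, ".w")]] <- init_linear(dh, ci)
      P[[paste0(pre, "ln", i, ".gamma")]] <- rep(1, ci)
      P[[paste0(pre, "ln", i, ".beta")]] <- rep(0, ci)
      P[[paste0(pre, "mlp", i, ".w1")]] <- init_linear(ci, 4 * ci)
      P[[paste0(pre, "mlp", i, ".b1")]] <- rep(0, 4 * ci)
      P[[paste0(pre, "mlp", i, ".w2")]] <- init_linear(4 * ci, ci)
      P[[paste0(pre, "mlp", i, ".b2")]] <- rep(0, ci)
    }
  }
  ## decoder
  nxt <- c(c0, w[1:3])  # output width of up block i is nxt[i]
  for (i in 1:4) {
    ci <- w[i]
    pre <- paste0("dec.up", i, ".")
    h <- max(2, ci %/% r)
    P[[paste0(pre, "ca.w1")]] <- init_linear(h, 2 * ci)
    P[[paste0(pre, "ca.b1")]] <- rep(0, h)
    P[[paste0(pre, "ca.w2")]] <- init_linear(ci, h)
    P[[paste0(pre, "ca.b2")]] <- rep(0, ci)
    P[[paste0(pre, "sa.w")]] <- init_conv(c(3, 3, 2, 1))
    P[[paste0(pre, "sa.b")]] <- 0
    P[[paste0(pre, "conv1.w")]] <- init_conv(c(3, 3, 2 * ci, ci))
    add_bn(P, B, paste0(pre, "conv1.bn"), ci)
    P[[paste0(pre, "conv2.w")]] <- init_conv(c(3, 3, ci, ci))
    add_bn(P, B, paste0(pre, "conv2.bn"), ci)
    P[[paste0(pre, "upconv.w")]] <- init_conv(c(3, 3, ci, nxt[i]))
    add_bn(P, B, paste0(pre, "upconv.bn"), nxt[i])
  }
  P[["dec.end.conv.w"]] <- init_conv(c(3, 3, c0, 2 * c0))
  add_bn(P, B, "dec.end.bn", 2 * c0)
  P[["dec.end.conv2.w"]] <- init_conv(c(3, 3, 2 * c0, 2 * c0))
  add_bn(P, B, "dec.end.bn2", 2 * c0)
  P[["dec.end.proj.w"]] <- init_conv(c(1, 1, 2 * c0, config$num_classes))
  P[["dec.end.proj.b"]] <- rep(0, config$num_classes)
  state <- new.env(parent = emptyenv())
  state$frozen <- character()
  structure(list(config = config, params = P, buffers = B, state = state),
            class = "caunet")
}

param_names <- function(model) sort(ls(model$params))

n_params <- function(model, prefix = "") {
  nms <- param_names(model)
  if (nzchar(prefix)) nms <- nms[startsWith(nms, prefix)]
  sum(vapply(nms, function(n) length(model$params[[n]]), 0))
}

make_pget <- function(model, traced) {
  if (!traced) return(function(name) model$params[[name]])
  cache <- new.env(parent = emptyenv())
  function(name) {
    nd <- cache[[name]]
    if (is.null(nd)) {
      nd <- ag_leaf(model$params[[name]], name)
      cache[[name]] <- nd
    }
    nd
  }
}

#' @export
print.caunet <- function(x, ...) {
  cfg <- x$config
  cat("Channel cross-attention U-style segmentation network\n")
  cat(sprintf("  input %dx%dx3 -> %d classes\n", cfg$input_size,
              cfg$input_size, cfg$num_classes))
  cat(sprintf("  encoder widths %s (groups %d, SE reduction %d)\n",
              paste(cfg$widths, collapse = "/"), cfg$groups,
              cfg$se_reduction))
  cat(sprintf("  skip transformer: %d layers, %d heads, token length %d\n",
              cfg$layers, cfg$heads, cfg$token_len))
  cat(sprintf("  parameters: %s (%s frozen)\n",
              format(n_params(x), big.mark = ","),
              if (length(x$state$frozen)) "encoder" else "none"))
  invisible(x)
}

#' @export
summary.caunet <- function(object, ...) {
  parts <- c(encoder = "enc.", transformer = "sct.", decoder = "dec.")
  counts <- vapply(parts, function(p) n_params(object, p), 0)
  out <- list(config = object$config, parameters = counts,
              total = sum(counts), frozen = object$state$frozen)
  class(out) <- "summary.caunet"
  out
}

#' @export
print.summary.caunet <- function(x, ...) {
  cat("Parameters by component:\n")
  for (nm in names(x$parameters))
    cat(sprintf("  %-12s %s\n", nm, format(x$parameters[[nm]], big.mark = ",")))
  cat(sprintf("  %-12s %s\n", "total", format(x$total, big.mark = ",")))
  if (length(x$frozen)) cat("Encoder is frozen.\n")
  invisible(x)
}

#' @export
coef.caunet <- function(object, ...) {
  nms <- param_names(object)
  stats::setNames(lapply(nms, function(n) object$params[[n]]), nms)
}
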