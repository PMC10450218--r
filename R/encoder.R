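## Encoder: initialization block plus four Down Blocks. Each Down Block is a
## residual bottleneck (1x1 expand -> grouped 3x3 convolution -> SE gate ->
## 1x1 reduce, with an identity shortcut around the stack) followed by 2x2
## max pooling and two 3x3 convolution blocks. All convolutions use batch
## normalization and the Swish activation x * sigmoid(x).

## conv + BN + Swish where weights live at "<key>.w" and BN at "<bnkey>.*"
block_conv <- function(x, pget, model, key, bnkey, pad = 1L, groups = 1L,
                       train = FALSE, act = TRUE) {
  y <- ag_conv2d(x, pget(paste0(key, ".w")), NULL, pad = pad, groups = groups)
  y <- ag_batchnorm(y, pget(paste0(bnkey, ".gamma")),
                    pget(paste0(bnkey, ".beta")), model, bnkey, train)
  if (act) ag_swish(y) else y
}

#' Initialization block: 3x3 convolution + batch norm + Swish
#'
#' Lifts a normalized RGB batch to `C1` feature channels at full resolution
#' (stride 1, spatial size preserved).
#'
#' @param model a [caunet()] model.
#' @param x input array `(H, W, 3, N)` with values in `[0, 1]`.
#' @param train use batch statistics (TRUE) or running statistics (FALSE).
#' @return feature array `(H, W, C1, N)`.
#' @export
init_block <- function(model, x, train = FALSE) {
  if (dim(vof(x))[3] != 3) stop("input must have 3 channels")
  block_conv(x, make_pget(model, is_node(x)), model, "enc.init.conv",
             "enc.init.bn", train = train)
}

#' Squeeze-and-excitation channel gate
#'
#' Global average pooling to one descriptor per channel, a two-layer 1x1
#' bottleneck (reduction `r`) with Swish, then a sigmoid producing gates in
#' `(0, 1)` that rescale the input channels. Shape is preserved; zero input
#' yields zero output because the gating is multiplicative.
#'
#' @param x feature array `(H, W, C, N)`.
#' @param w1,b1,w2,b2 bottleneck weights: `w1` is `(C/r) x C`, `w2` is
#'   `C x (C/r)`.
#' @param return_gates also return the per-channel gate matrix `(C, N)`.
#' @return the gated array, or a list `(y, gates)` if `return_gates`.
#' @export
se_gate <- function(x, w1, b1, w2, b2, return_gates = FALSE) {
  z <- ag_gap(x)
  h <- ag_swish(ag_dense(z, w1, b1))
  g <- ag_sigmoid(ag_dense(h, w2, b2))
  y <- ag_scale_channels(x, g)
  if (return_gates) list(y = y, gates = g) else y
}

down_block_fwd <- function(x, i, pget, model, train) {
  cfg <- model$config
  pre <- paste0("enc.down", i, ".")
  ## residual bottleneck at the incoming resolution
  h <- block_conv(x, pget, model, paste0(pre, "expand"),
                  paste0(pre, "expand.bn"), pad = 0L, train = train)
  h <- block_conv(h, pget, model, paste0(pre, "gconv"),
                  paste0(pre, "gconv.bn"), pad = 1L, groups = cfg$groups,
                  train = train)
  h <- se_gate(h, pget(paste0(pre, "se.w1")), pget(paste0(pre, "se.b1")),
               pget(paste0(pre, "se.w2")), pget(paste0(pre, "se.b2")))
  h <- block_conv(h, pget, model, paste0(pre, "reduce"),
                  paste0(pre, "reduce.bn"), pad = 0L, train = train,
                  act = FALSE)
  h <- ag_add(h, x)  # identity shortcut (channel counts match by design)
  ## downsample and refine
  h <- ag_maxpool2(h)
  h <- block_conv(h, pget, model, paste0(pre, "conv1"),
                  paste0(pre, "conv1.bn"), train = train)
  block_conv(h, pget, model, paste0(pre, "conv2"), paste0(pre, "conv2.bn"),
             train = train)
}

#' One encoder Down Block
#'
#' Residual squeeze-and-excitation bottleneck (1x1 expand, grouped 3x3
#' convolution, SE gate, 1x1 reduce, identity shortcut) followed by 2x2 max
#' pooling and two 3x3 convolution blocks; spatial size halves and channels
#' become `widths[i]`.
#'
#' @param model a [caunet()] model.
#' @param x features entering stage `i` (`C_{i-1}` channels, even spatial
#'   size).
#' @param i stage index 1-4.
#' @param train batch-norm mode.
#' @return feature array at half the spatial size with `widths[i]` channels.
#' @export
down_block <- function(model, x, i, train = FALSE) {
  dm <- dim(vof(x))
  if (dm[1] %% 2 != 0 || dm[2] %% 2 != 0)
    stop("spatial size must be even to downsample")
  exp_in <- dim(model$params[[paste0("enc.down", i, ".expand.w")]])[3]
  if (dm[3] != exp_in) stop("input channel count does not match stage ", i)
  down_block_fwd(x, i, make_pget(model, is_node(x)), model, train)
}

encode_fwd <- function(x, pget, model, train) {
  h <- block_conv(x, pget, model, "enc.init.conv", "enc.init.bn",
                  train = train)
  levels <- vector("list", 4)
  for (i in 1:4) {
    h <- down_block_fwd(h, i, pget, model, train)
    levels[[i]] <- h
  }
  levels
}

#' Encode an image batch into the four-scale feature pyramid
#'
#' @param model a [caunet()] model.
#' @param x array `(H, W, 3, N)` of normalized images, `H = W` divisible
#'   by 16.
#' @param train batch-norm mode.
#' @return a list of four feature arrays at scales 1/2, 1/4, 1/8, 1/16 with
#'   channels `C1..C4`.
#' @export
encode <- function(model, x, train = FALSE) {
  dm <- dim(vof(x))
  if (dm[1] %% 16 != 0 || dm[2] %% 16 != 0)
    stop("input size must be divisible by 16")
  if (dm[3] != 3) stop("input must have 3 channels")
  encode_fwd(x, make_pget(model, is_node(x)), model, train)
}
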