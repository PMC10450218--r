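## Decoder: four Up Attention Blocks and an End Block. Block i fuses the
## refined skip tokens of scale i with the decoder state at the same scale
## through the CSA (channel + spatial attention) module, concatenates state
## and fused skip, doubles the spatial size by bilinear interpolation, and
## restores the next stage's channel width with two 3x3 convolution blocks.
## The End Block projects the full-resolution features to per-pixel class
## scores.

csa_fuse_fwd <- function(tokmap, state, pget, model, i, train,
                         return_parts = FALSE) {
  pre <- paste0("dec.up", i, ".")
  ## channel attention: pooled descriptors of both streams through an MLP
  z <- ag_gap(ag_concat_c(list(tokmap, state)))
  h <- ag_swish(ag_dense(z, pget(paste0(pre, "ca.w1")),
                         pget(paste0(pre, "ca.b1"))))
  gates <- ag_sigmoid(ag_dense(h, pget(paste0(pre, "ca.w2")),
                               pget(paste0(pre, "ca.b2"))))
  fc <- ag_scale_channels(tokmap, gates)
  ## spatial attention: channel-wise mean and max maps, concatenated to a
  ## 2-channel descriptor, convolved and squashed
  mm <- ag_concat_c(list(ag_channel_mean(fc), ag_channel_max(fc)))
  smap <- ag_sigmoid(ag_conv2d(mm, pget(paste0(pre, "sa.w")),
                               pget(paste0(pre, "sa.b")), pad = 1L))
  out <- ag_scale_spatial(fc, smap)
  if (return_parts)
    list(out = out, gates = gates, smap = smap, descriptor = mm)
  else out
}

#' CSA fusion of skip tokens and decoder features
#'
#' Reshapes nothing itself (pass a token map from [tokens_to_feature_map()]);
#' computes a channel attention vector from the globally pooled descriptors
#' of both streams through a bottleneck MLP and sigmoid, rescales the token
#' map, then a spatial attention map from its channel-wise mean and max
#' (a 2-channel descriptor) through a 3x3 convolution and sigmoid. Output
#' shape equals the input shape.
#'
#' @param model a [caunet()] model.
#' @param tokmap skip-token feature map `(H, W, C_i, N)`.
#' @param state decoder feature map of the same shape.
#' @param i decoder stage 1-4 (selects the weights).
#' @param train batch-norm mode (unused here; kept for interface symmetry).
#' @param return_parts also return the channel gates, spatial map and the
#'   2-channel mean/max descriptor.
#' @return the reweighted feature map, or a list when `return_parts`.
#' @export
csa_fuse <- function(model, tokmap, state, i, train = FALSE,
                     return_parts = FALSE) {
  if (!identical(dim(vof(tokmap)), dim(vof(state))))
    stop("token map and decoder state must share a shape")
  traced <- is_node(tokmap) || is_node(state)
  csa_fuse_fwd(tokmap, state, make_pget(model, traced), model, i, train,
               return_parts)
}

#' Broadcast skip tokens back to a feature map
#'
#' Inverts the tokenizer's grid pooling by nearest-neighbour broadcast: each
#' pixel takes the token of the grid patch it falls in.
#'
#' @param tokens `(d, C, N)` token array.
#' @param H,W target spatial size (multiples of `sqrt(d)`).
#' @return array `(H, W, C, N)`.
#' @export
tokens_to_feature_map <- function(tokens, H, W) {
  d <- dim(vof(tokens))[1]
  gt <- sqrt(d)
  ag_tokens_to_map(tokens, gt, gt, H, W)
}

up_block_fwd <- function(state, tokens_i, i, pget, model, train) {
  dm <- dim(vof(state))
  pre <- paste0("dec.up", i, ".")
  tokmap <- tokens_to_feature_map(tokens_i, dm[1], dm[2])
  fused <- csa_fuse_fwd(tokmap, state, pget, model, i, train)
  h <- ag_concat_c(list(state, fused))
  h <- block_conv(h, pget, model, paste0(pre, "conv1"),
                  paste0(pre, "conv1.bn"), train = train)
  h <- block_conv(h, pget, model, paste0(pre, "conv2"), paste0(pre, "conv2.bn"),
                  train = train)
  ## upsample x2 = bilinear interpolation + convolution
  h <- ag_upsample2(h)
  block_conv(h, pget, model, paste0(pre, "upconv"), paste0(pre, "upconv.bn"),
             train = train)
}

#' One Up Attention Block
#'
#' Fuses the stage-`i` skip tokens with the decoder state at scale `1/2^i`
#' (CSA fusion + concatenation + two 3x3 convolution blocks restoring the
#' stage width), then doubles the spatial size with the upsampling operator
#' (bilinear x2 followed by a convolution to the next stage's width).
#'
#' @param model a [caunet()] model.
#' @param state decoder features `(H_i, W_i, C_i, N)`.
#' @param tokens_i refined skip tokens `(d, C_i, N)` for this stage.
#' @param i stage index 4 down to 1.
#' @param train batch-norm mode.
#' @return features `(2 H_i, 2 W_i, C_{i-1}, N)` (width `C1` feeds stage 0).
#' @export
up_attention_block <- function(model, state, tokens_i, i, train = FALSE) {
  ci <- model$config$widths[i]
  if (dim(vof(state))[3] != ci)
    stop("decoder state has wrong channel count for stage ", i)
  traced <- is_node(state) || is_node(tokens_i)
  up_block_fwd(state, tokens_i, i, make_pget(model, traced), model, train)
}

end_block_fwd <- function(state, pget, model, train) {
  h <- block_conv(state, pget, model, "dec.end.conv", "dec.end.bn",
                  train = train)
  h <- block_conv(h, pget, model, "dec.end.conv2", "dec.end.bn2",
                  train = train)
  ag_conv2d(h, pget("dec.end.proj.w"), pget("dec.end.proj.b"), pad = 0L)
}

#' End Block: project full-resolution features to class logits
#'
#' Two 3x3 convolution blocks widening to `2 C1` — the full-resolution
#' refinement that sharpens boundaries re-synthesized from the coarse token
#' grid — followed by a 1x1 projection to `num_classes` channels.
#'
#' @param model a [caunet()] model.
#' @param state features `(H, W, C1, N)` at full resolution.
#' @param train batch-norm mode.
#' @return logits `(H, W, num_classes, N)`.
#' @export
end_block <- function(model, state, train = FALSE) {
  end_block_fwd(state, make_pget(model, is_node(state)), model, train)
}

decode_fwd <- function(pyramid, tokens, pget, model, train) {
  state <- pyramid[[4]]
  for (i in 4:1)
    state <- up_block_fwd(state, tokens[[i]], i, pget, model, train)
  end_block_fwd(state, pget, model, train)
}

#' Full forward pass: images to per-pixel class logits
#'
#' Encoder, skip transformer and decoder chained; maps `(S, S, 3, N)` to
#' `(S, S, num_classes, N)` for any `S` divisible by 16.
#'
#' @param model a [caunet()] model.
#' @param x normalized image batch `(H, W, 3, N)`; a single `(H, W, 3)`
#'   image is promoted to a batch of one.
#' @param train batch-norm mode.
#' @return the logit array.
#' @export
caunet_forward <- function(model, x, train = FALSE) {
  vx <- vof(x)
  if (length(dim(vx)) == 3) {
    vx <- array(vx, c(dim(vx), 1))
    if (!is_node(x)) x <- vx
  }
  pget <- make_pget(model, is_node(x))
  pyr <- encode_fwd(x, pget, model, train)
  tokens <- sc_transformer_fwd(pyr, pget, model$config)
  decode_fwd(pyr, tokens, pget, model, train)
}

#' Predict a class-index mask for an image
#'
#' Runs the forward pass in inference mode and takes the per-pixel argmax
#' over class channels; ties break toward the lowest class index.
#'
#' @param object a [caunet()] model.
#' @param image `(H, W, 3)` image (raw 0-255 or already normalized) or an
#'   `(H, W, 3, N)` batch.
#' @param ... unused.
#' @return an `H x W` integer mask (or `H x W x N` for a batch).
#' @export
predict.caunet <- function(object, image, ...) {
  if (max(image) > 1) image <- normalize_minmax(image)
  single <- length(dim(image)) == 3
  if (single) dim(image) <- c(dim(image), 1)
  logits <- caunet_forward(object, image, train = FALSE)
  m <- logits_to_mask(logits)
  if (single) m[, , 1] else m
}

#' Convert a logit array to class-index masks
#'
#' Per-pixel argmax over the channel axis; exact ties go to the lowest
#' class index.
#'
#' @param logits array `(H, W, C, N)`.
#' @return integer array `(H, W, N)` of 0-based class indices.
#' @export
logits_to_mask <- function(logits) {
  dm <- dim(logits)
  lp <- matrix(aperm(logits, c(1, 2, 4, 3)), dm[1] * dm[2] * dm[4], dm[3])
  am <- max.col(lp, ties.method = "first") - 1L
  aperm(array(am, c(dm[1], dm[2], dm[4])), c(1, 2, 3))
}
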