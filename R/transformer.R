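## Skip-connection transformer: multi-scale tokenization of the feature
## pyramid, multi-head channel cross-attention between each scale's tokens
## and the channel-wise concatenation of all scales, and a residual MLP with
## layer normalization, stacked `layers` deep.
##
## Shapes. Tokens T_i are d x C_i (sequence length d, encoder channel width
## C_i, unchanged through the skip path). With projections W_Qi (C_i x d),
## W_K and W_V (C_sum x d): Q_i = T_i W_Qi, K = sumT W_K, V = sumT W_V, all
## d x d. Attention runs over the projected channel axes: per head (columns
## split into d/heads blocks) the similarity M = sigmoid(instnorm(Q_h' K_h /
## C_sum)) is computed, the head output is taken in token orientation
## V_h M' (the transpose of M V_h'), heads are averaged (not concatenated),
## and a per-scale reconstruction W_Oi (d/heads x C_i) returns to token
## space before the residual MLP block
##   O_i = MCA_i + MLP(LN(Q_i) + MCA_i),
## with MLP = linear(C_i -> 4 C_i), GELU, linear(4 C_i -> C_i).

#' Tokenize the feature pyramid
#'
#' Average-pools every pyramid level onto the same `sqrt(d) x sqrt(d)` grid
#' so that all four token sequences share length `d` while keeping their
#' channel widths, then concatenates them channel-wise.
#'
#' @param pyramid list of four feature arrays `(H_i, W_i, C_i, N)` from
#'   [encode()].
#' @param d token sequence length; `sqrt(d)` must be an integer dividing
#'   every level's spatial size.
#' @return a list with `tokens` (four `(d, C_i, N)` arrays) and `tsum`
#'   (their `(d, sum C_i, N)` channel-wise concatenation).
#' @export
tokenize <- function(pyramid, d) {
  gt <- sqrt(d)
  if (gt != round(gt)) stop("`d` must be a perfect square")
  tokens <- lapply(pyramid, function(f) {
    dm <- dim(vof(f))
    if (dm[1] %% gt != 0 || dm[2] %% gt != 0)
      stop("token grid ", gt, " does not divide level size ", dm[1])
    ag_avgpool_grid(f, gt, gt)
  })
  list(tokens = tokens, tsum = ag_concat2_3(tokens))
}

#' Single-head channel cross-attention (plain matrices)
#'
#' The attention arithmetic for one scale and one head, on plain numeric
#' matrices: `Q = T W_q`, `K = S W_k`, `V = S W_v`, similarity
#' `M = sigmoid(instnorm(Q' K / C_sum))` with `instnorm` normalizing the
#' whole similarity matrix to zero mean and unit variance, and output
#' `V M'` (the token-orientation transpose of `M V'`). This is the exact
#' computation the skip transformer performs per head; it is exported so the
#' attention core can be checked in isolation.
#'
#' @param tokens `d x C_i` token matrix of the query scale.
#' @param tsum `d x C_sum` concatenated tokens of all scales.
#' @param wq,wk,wv projection matrices (`C_i x d`, `C_sum x d`,
#'   `C_sum x d`).
#' @param c_sum scaling denominator; defaults to the channel total
#'   `ncol(tsum)`.
#' @return a list with `Q`, `K`, `V`, `M` (entries in (0, 1)) and the
#'   `d x d` attention output `CA` in token orientation.
#' @export
channel_cross_attention <- function(tokens, tsum, wq, wk, wv,
                                    c_sum = ncol(tsum)) {
  if (nrow(tokens) != nrow(tsum)) stop("query and key streams disagree in d")
  Q <- tokens %*% wq
  K <- tsum %*% wk
  V <- tsum %*% wv
  S <- crossprod(Q, K) / c_sum
  Sn <- (S - mean(S)) / sqrt(mean((S - mean(S))^2) + 1e-5)
  M <- 1 / (1 + exp(-Sn))
  list(Q = Q, K = K, V = V, M = M, CA = V %*% t(M))
}

#' Average head outputs (multi-head combination)
#'
#' Heads are combined by the arithmetic mean `(CA_1 + ... + CA_N) / N`, not
#' by concatenation.
#'
#' @param heads nonempty list of equal-shaped head outputs.
#' @return their mean.
#' @export
mca <- function(heads) {
  if (length(heads) == 0) stop("need at least one head output")
  ag_mean_list(heads)
}

sc_layer_fwd <- function(tokens, pget, cfg, l) {
  d <- cfg$token_len
  N <- cfg$heads
  dh <- d / N
  csum <- sum(cfg$widths)
  pre <- paste0("sct.l", l, ".")
  tsum <- ag_concat2_3(tokens)
  K <- ag_bmm3(tsum, pget(paste0(pre, "k.w")))
  V <- ag_bmm3(tsum, pget(paste0(pre, "v.w")))
  out <- vector("list", 4)
  for (i in 1:4) {
    Q <- ag_bmm3(tokens[[i]], pget(paste0(pre, "q", i, ".w")))
    ca_heads <- vector("list", N)
    q_heads <- vector("list", N)
    for (h in seq_len(N)) {
      cols <- (h - 1) * dh + seq_len(dh)
      Qh <- ag_cols3(Q, cols)
      Kh <- ag_cols3(K, cols)
      Vh <- ag_cols3(V, cols)
      S <- ag_scale(ag_bmm_tA(Qh, Kh), 1 / csum)
      M <- ag_sigmoid(ag_instnorm3(S))
      ca_heads[[h]] <- ag_bmm_tB(Vh, M)  # token orientation: V_h M'
      q_heads[[h]] <- Qh
    }
    MCA <- mca(ca_heads)
    Qbar <- ag_mean_list(q_heads)
    Wo <- pget(paste0(pre, "o", i, ".w"))
    MCAc <- ag_bmm3(MCA, Wo)
    Qc <- ag_bmm3(Qbar, Wo)
    Z <- ag_add(ag_layernorm3(Qc, pget(paste0(pre, "ln", i, ".gamma")),
                              pget(paste0(pre, "ln", i, ".beta"))), MCAc)
    H1 <- ag_gelu(ag_bias2_3(ag_bmm3(Z, pget(paste0(pre, "mlp", i, ".w1"))),
                             pget(paste0(pre, "mlp", i, ".b1"))))
    MLP <- ag_bias2_3(ag_bmm3(H1, pget(paste0(pre, "mlp", i, ".w2"))),
                      pget(paste0(pre, "mlp", i, ".b2")))
    out[[i]] <- ag_add(MCAc, MLP)
  }
  out
}

#' One skip-transformer layer
#'
#' Applies multi-head channel cross-attention and the residual MLP block to
#' a token set; token shapes `(d, C_i, N)` are preserved.
#'
#' @param model a [caunet()] model.
#' @param tokens list of four `(d, C_i, N)` token arrays.
#' @param layer which layer's weights to use (1-based).
#' @return refined tokens, same shapes.
#' @export
sc_layer <- function(model, tokens, layer = 1L) {
  traced <- any(vapply(tokens, is_node, TRUE))
  sc_layer_fwd(tokens, make_pget(model, traced), model$config, layer)
}

sc_transformer_fwd <- function(pyramid, pget, cfg) {
  tk <- tokenize(pyramid, cfg$token_len)
  tokens <- tk$tokens
  for (l in seq_len(cfg$layers))
    tokens <- sc_layer_fwd(tokens, pget, cfg, l)
  tokens
}

#' Run the full skip transformer over a feature pyramid
#'
#' Tokenizes all four encoder scales and applies `config$layers` stacked
#' channel cross-attention layers.
#'
#' @param model a [caunet()] model.
#' @param pyramid feature pyramid from [encode()].
#' @return list of four refined token arrays `(d, C_i, N)`.
#' @export
sc_transformer <- function(model, pyramid) {
  if (model$config$layers < 1) stop("need at least one transformer layer")
  traced <- any(vapply(pyramid, is_node, TRUE))
  sc_transformer_fwd(pyramid, make_pget(model, traced), model$config)
}
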