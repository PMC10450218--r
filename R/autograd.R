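## Reverse-mode automatic differentiation on a flat tape.
##
## Every op accepts either a plain numeric array or an `ag_node`; when tracing
## is active and at least one input is a node, the op records itself on the
## tape with a backward closure. With tracing off (or plain inputs) the same
## code path returns plain arrays, so the network wiring is written once and
## serves both training and inference.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE

#' @keywords internal
ag_start <- function() {
  .ag$on <- TRUE
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$leaves <- new.env(parent = emptyenv())
  invisible(NULL)
}

#' @keywords internal
ag_stop <- function() {
  .ag$on <- FALSE
  .ag$tape <- NULL
  .ag$leaves <- NULL
  invisible(NULL)
}

is_node <- function(x) inherits(x, "ag_node")

vof <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$backward <- backward
  class(e) <- "ag_node"
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
  .ag$tape[[n]] <- e
  .ag$n <- n
  e
}

acc_grad <- function(node, g) {
  if (!is_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_leaf <- function(value, name) {
  e <- new_node(value)
  assign(name, e, envir = .ag$leaves)
  e
}

tracing <- function(...) {
  if (!isTRUE(.ag$on)) return(FALSE)
  for (a in list(...)) if (is_node(a)) return(TRUE)
  FALSE
}

#' Run backpropagation from a scalar loss node
#' @keywords internal
ag_backward <- function(out) {
  stopifnot(is_node(out), length(out$value) == 1L)
  out$grad <- 1
  for (i in seq.int(.ag$n, 1L)) {
    e <- .ag$tape[[i]]
    if (!is.null(e$backward) && !is.null(e$grad)) e$backward(e$grad)
  }
  invisible(NULL)
}

#' @keywords internal
ag_leaf_grads <- function() {
  out <- list()
  for (nm in ls(.ag$leaves)) {
    g <- get(nm, envir = .ag$leaves)$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

## ---- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  v <- vof(a) + vof(b)
  if (!tracing(a, b)) return(v)
  new_node(v, function(g) { acc_grad(a, g); acc_grad(b, g) })
}

ag_mul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  v <- va * vb
  if (!tracing(a, b)) return(v)
  new_node(v, function(g) { acc_grad(a, g * vb); acc_grad(b, g * va) })
}

ag_scale <- function(a, s) {
  v <- vof(a) * s
  if (!tracing(a)) return(v)
  new_node(v, function(g) acc_grad(a, g * s))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-vof(a)))
  if (!tracing(a)) return(v)
  new_node(v, function(g) acc_grad(a, g * v * (1 - v)))
}

ag_swish <- function(a) {
  x <- vof(a)
  s <- 1 / (1 + exp(-x))
  v <- x * s
  if (!tracing(a)) return(v)
  new_node(v, function(g) acc_grad(a, g * (s + x * s * (1 - s))))
}

ag_gelu <- function(a) {
  x <- vof(a)
  v <- x * stats::pnorm(x)
  if (!tracing(a)) return(v)
  new_node(v, function(g) acc_grad(a, g * (stats::pnorm(x) + x * stats::dnorm(x))))
}

## ---- matrix ops (2-D) -----------------------------------------------------

ag_matmul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  v <- va %*% vb
  if (!tracing(a, b)) return(v)
  new_node(v, function(g) {
    acc_grad(a, g %*% t(vb))
    acc_grad(b, crossprod(va, g))
  })
}

ag_dense <- function(x, w, b) {
  vx <- vof(x)
  v <- vof(w) %*% vx + vof(b)
  if (!tracing(x, w, b)) return(v)
  new_node(v, function(g) {
    acc_grad(w, tcrossprod(g, vx))
    acc_grad(x, crossprod(vof(w), g))
    acc_grad(b, rowSums(g))
  })
}

## ---- batched token ops; arrays (d, C, N) ----------------------------------

## X (d, a, N) %*% W (a, b) per sample, in one GEMM via permutation.
ag_bmm3 <- function(x, w) {
  vx <- vof(x); vw <- vof(w)
  dm <- dim(vx)
  xm <- matrix(aperm(vx, c(1L, 3L, 2L)), dm[1L] * dm[3L], dm[2L])
  ym <- xm %*% vw
  v <- aperm(array(ym, c(dm[1L], dm[3L], ncol(vw))), c(1L, 3L, 2L))
  if (!tracing(x, w)) return(v)
  new_node(v, function(g) {
    gm <- matrix(aperm(g, c(1L, 3L, 2L)), dm[1L] * dm[3L], ncol(vw))
    acc_grad(w, crossprod(xm, gm))
    gx <- gm %*% t(vw)
    acc_grad(x, aperm(array(gx, c(dm[1L], dm[3L], dm[2L])), c(1L, 3L, 2L)))
  })
}

## t(A_n) %*% B_n per sample: A (d, a, N), B (d, b, N) -> (a, b, N)
ag_bmm_tA <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  da <- dim(va); db <- dim(vb)
  v <- array(0, c(da[2L], db[2L], da[3L]))
  for (n in seq_len(da[3L]))
    v[, , n] <- crossprod(va[, , n, drop = TRUE], vb[, , n, drop = TRUE])
  if (!tracing(a, b)) return(v)
  new_node(v, function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (n in seq_len(da[3L])) {
      gn <- g[, , n, drop = TRUE]
      if (is.null(dim(gn))) gn <- matrix(gn, da[2L], db[2L])
      ga[, , n] <- vb[, , n] %*% t(gn)
      gb[, , n] <- va[, , n] %*% gn
    }
    acc_grad(a, ga); acc_grad(b, gb)
  })
}

## A_n %*% t(B_n) per sample: A (d, a, N), B (m, a, N) -> (d, m, N)
ag_bmm_tB <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  da <- dim(va); db <- dim(vb)
  v <- array(0, c(da[1L], db[1L], da[3L]))
  for (n in seq_len(da[3L]))
    v[, , n] <- tcrossprod(va[, , n, drop = TRUE], vb[, , n, drop = TRUE])
  if (!tracing(a, b)) return(v)
  new_node(v, function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (n in seq_len(da[3L])) {
      gn <- g[, , n, drop = TRUE]
      if (is.null(dim(gn))) gn <- matrix(gn, da[1L], db[1L])
      ga[, , n] <- gn %*% vb[, , n]
      gb[, , n] <- crossprod(gn, va[, , n])
    }
    acc_grad(a, ga); acc_grad(b, gb)
  })
}

## columns of the 2nd axis of (d, a, N)
ag_cols3 <- function(x, cols) {
  vx <- vof(x)
  v <- vx[, cols, , drop = FALSE]
  if (!tracing(x)) return(v)
  new_node(v, function(g) {
    gx <- array(0, dim(vx))
    gx[, cols, ] <- g
    acc_grad(x, gx)
  })
}

ag_concat2_3 <- function(xs) {
  vs <- lapply(xs, vof)
  widths <- vapply(vs, function(v) dim(v)[2L], 0)
  dm <- dim(vs[[1L]])
  v <- array(0, c(dm[1L], sum(widths), dm[3L]))
  at <- 0L
  for (i in seq_along(vs)) {
    v[, at + seq_len(widths[i]), ] <- vs[[i]]
    at <- at + widths[i]
  }
  if (!isTRUE(.ag$on) || !any(vapply(xs, is_node, TRUE))) return(v)
  new_node(v, function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      acc_grad(xs[[i]], g[, at + seq_len(widths[i]), , drop = FALSE])
      at <- at + widths[i]
    }
  })
}

ag_mean_list <- function(xs) {
  k <- length(xs)
  v <- Reduce(`+`, lapply(xs, vof)) / k
  if (!isTRUE(.ag$on) || !any(vapply(xs, is_node, TRUE))) return(v)
  new_node(v, function(g) for (x in xs) acc_grad(x, g / k))
}

## whole-matrix (instance) normalization per sample of (a, b, N)
ag_instnorm3 <- function(x, eps = 1e-5) {
  vx <- vof(x)
  dm <- dim(vx)
  m <- dm[1L] * dm[2L]
  xm <- matrix(vx, m, dm[3L])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc^2)
  isd <- 1 / sqrt(va + eps)
  ym <- sweep(xc, 2L, isd, `*`)
  v <- array(ym, dm)
  if (!tracing(x)) return(v)
  new_node(v, function(g) {
    gm <- matrix(g, m, dm[3L])
    gy <- sweep(gm, 2L, colMeans(gm))
    proj <- colMeans(gm * ym)
    gx <- sweep(gy - sweep(ym, 2L, proj, `*`), 2L, isd, `*`)
    acc_grad(x, array(gx, dm))
  })
}

## row-wise layer norm over the feature (2nd) axis of (d, C, N)
ag_layernorm3 <- function(x, gamma, beta, eps = 1e-5) {
  vx <- vof(x); vg <- vof(gamma); vb <- vof(beta)
  dm <- dim(vx)
  xp <- matrix(aperm(vx, c(2L, 1L, 3L)), dm[2L], dm[1L] * dm[3L]) # C x (d*N)
  mu <- colMeans(xp)
  xc <- sweep(xp, 2L, mu)
  va <- colMeans(xc^2)
  isd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, isd, `*`)
  ym <- xh * vg + vb
  v <- aperm(array(ym, c(dm[2L], dm[1L], dm[3L])), c(2L, 1L, 3L))
  if (!tracing(x, gamma, beta)) return(v)
  new_node(v, function(g) {
    gp <- matrix(aperm(g, c(2L, 1L, 3L)), dm[2L], dm[1L] * dm[3L])
    acc_grad(gamma, rowSums(gp * xh))
    acc_grad(beta, rowSums(gp))
    gh <- gp * vg
    gc <- sweep(gh, 2L, colMeans(gh))
    proj <- colMeans(gh * xh)
    gx <- sweep(gc - sweep(xh, 2L, proj, `*`), 2L, isd, `*`)
    acc_grad(x, aperm(array(gx, c(dm[2L], dm[1L], dm[3L])), c(2L, 1L, 3L)))
  })
}

## add a length-C bias along the 2nd axis of (d, C, N)
ag_bias2_3 <- function(x, b) {
  vx <- vof(x); vb <- vof(b)
  dm <- dim(vx)
  v <- vx + rep(rep(vb, each = dm[1L]), times = dm[3L])
  dim(v) <- dm
  if (!tracing(x, b)) return(v)
  new_node(v, function(g) {
    acc_grad(x, g)
    acc_grad(b, rowSums(matrix(aperm(g, c(2L, 1L, 3L)), dm[2L], dm[1L] * dm[3L])))
  })
}

## ---- image-tensor ops; arrays (H, W, C, N) --------------------------------

ag_conv2d <- function(x, w, b = NULL, pad = 1L, groups = 1L) {
  vx <- vof(x); vw <- vof(w)
  vb <- if (is.null(b)) numeric(0) else vof(b)
  v <- conv2d_fwd_cpp(vx, dim(vx), vw, dim(vw), vb, pad, groups)
  if (!tracing(x, w, b)) return(v)
  new_node(v, function(g) {
    bw <- conv2d_bwd_cpp(vx, dim(vx), vw, dim(vw), g, pad, groups,
                         length(vb) > 0L)
    acc_grad(x, bw$gx)
    acc_grad(w, bw$gw)
    if (!is.null(b)) acc_grad(b, bw$gb)
  })
}

ag_maxpool2 <- function(x) {
  vx <- vof(x)
  fw <- maxpool2_fwd_cpp(vx, dim(vx))
  if (!tracing(x)) return(fw$y)
  new_node(fw$y, function(g) acc_grad(x, maxpool2_bwd_cpp(fw$idx, g, dim(vx))))
}

ag_upsample2 <- function(x) {
  vx <- vof(x)
  v <- upsample2_fwd_cpp(vx, dim(vx))
  if (!tracing(x)) return(v)
  new_node(v, function(g) acc_grad(x, upsample2_bwd_cpp(g, dim(vx))))
}

ag_avgpool_grid <- function(x, gh, gw) {
  vx <- vof(x)
  v <- avgpool_grid_fwd_cpp(vx, dim(vx), gh, gw)
  if (!tracing(x)) return(v)
  new_node(v, function(g) acc_grad(x, avgpool_grid_bwd_cpp(g, dim(vx), gh, gw)))
}

ag_tokens_to_map <- function(t, gh, gw, H, W) {
  vt <- vof(t)
  v <- tokens_to_map_fwd_cpp(vt, dim(vt), gh, gw, H, W)
  if (!tracing(t)) return(v)
  new_node(v, function(g) acc_grad(t, tokens_to_map_bwd_cpp(g, dim(v), gh, gw)))
}

## concat along the channel (3rd) axis
ag_concat_c <- function(xs) {
  vs <- lapply(xs, vof)
  cs <- vapply(vs, function(v) dim(v)[3L], 0)
  dm <- dim(vs[[1L]])
  v <- array(0, c(dm[1L], dm[2L], sum(cs), dm[4L]))
  at <- 0L
  for (i in seq_along(vs)) {
    v[, , at + seq_len(cs[i]), ] <- vs[[i]]
    at <- at + cs[i]
  }
  if (!isTRUE(.ag$on) || !any(vapply(xs, is_node, TRUE))) return(v)
  new_node(v, function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      acc_grad(xs[[i]], g[, , at + seq_len(cs[i]), , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

## global average pool (H, W, C, N) -> (C, N)
ag_gap <- function(x) {
  vx <- vof(x)
  dm <- dim(vx)
  hw <- dm[1L] * dm[2L]
  v <- matrix(colMeans(matrix(vx, hw, dm[3L] * dm[4L])), dm[3L], dm[4L])
  if (!tracing(x)) return(v)
  new_node(v, function(g) {
    gx <- rep(as.vector(g), each = hw) / hw
    dim(gx) <- dm
    acc_grad(x, gx)
  })
}

## multiply (H, W, C, N) by per-channel gates (C, N)
ag_scale_channels <- function(x, gates) {
  vx <- vof(x); vg <- vof(gates)
  dm <- dim(vx)
  hw <- dm[1L] * dm[2L]
  gg <- rep(as.vector(vg), each = hw)
  v <- vx * gg
  dim(v) <- dm
  if (!tracing(x, gates)) return(v)
  new_node(v, function(g) {
    acc_grad(x, array(g * gg, dm))
    gm <- colSums(matrix(g * as.vector(vx), hw, dm[3L] * dm[4L]))
    acc_grad(gates, matrix(gm, dm[3L], dm[4L]))
  })
}

## expand a (H, W, 1, N) map across C channels
expand_spatial <- function(s, C) {
  dm <- dim(s)
  sv <- array(s, c(dm[1L], dm[2L], dm[4L]))
  aperm(array(rep(sv, C), c(dm[1L], dm[2L], dm[4L], C)), c(1L, 2L, 4L, 3L))
}

## sum a (H, W, C, N) array over channels -> (H, W, 1, N)
sum_channels <- function(x) {
  dm <- dim(x)
  xp <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), dm[1L] * dm[2L] * dm[4L], dm[3L])
  s <- rowSums(xp)
  aperm(array(s, c(dm[1L], dm[2L], dm[4L], 1L)), c(1L, 2L, 4L, 3L))
}

## multiply (H, W, C, N) by a spatial map (H, W, 1, N)
ag_scale_spatial <- function(x, s) {
  vx <- vof(x); vs <- vof(s)
  dm <- dim(vx)
  sm <- expand_spatial(vs, dm[3L])
  v <- vx * sm
  if (!tracing(x, s)) return(v)
  new_node(v, function(g) {
    acc_grad(x, g * sm)
    acc_grad(s, sum_channels(g * vx))
  })
}

## mean over channels -> (H, W, 1, N)
ag_channel_mean <- function(x) {
  vx <- vof(x)
  dm <- dim(vx)
  v <- sum_channels(vx) / dm[3L]
  if (!tracing(x)) return(v)
  new_node(v, function(g) acc_grad(x, expand_spatial(g, dm[3L]) / dm[3L]))
}

## max over channels -> (H, W, 1, N); ties keep the lowest channel
ag_channel_max <- function(x) {
  vx <- vof(x)
  dm <- dim(vx)
  xp <- matrix(aperm(vx, c(1L, 2L, 4L, 3L)), dm[1L] * dm[2L] * dm[4L], dm[3L])
  am <- max.col(xp, ties.method = "first")
  vals <- xp[cbind(seq_len(nrow(xp)), am)]
  v <- array(vals, c(dm[1L], dm[2L], 1L, dm[4L]))
  if (!tracing(x)) return(v)
  new_node(v, function(g) {
    gp <- matrix(0, nrow(xp), dm[3L])
    gp[cbind(seq_len(nrow(xp)), am)] <- as.vector(g)
    gx <- aperm(array(gp, c(dm[1L], dm[2L], dm[4L], dm[3L])), c(1L, 2L, 4L, 3L))
    acc_grad(x, gx)
  })
}

## batch normalization over (H, W, N) per channel
ag_batchnorm <- function(x, gamma, beta, model, key, train, eps = 1e-5,
                         momentum = 0.1) {
  vx <- vof(x); vg <- vof(gamma); vb <- vof(beta)
  dm <- dim(vx)
  hw <- dm[1L] * dm[2L]
  C <- dm[3L]; N <- dm[4L]
  xm <- matrix(vx, hw, C * N)
  if (train) {
    pc <- matrix(colMeans(xm), C, N)
    mu <- rowMeans(pc)
    xc <- xm - rep(rep(mu, each = hw), times = N)
    va <- rowMeans(matrix(colMeans(xc^2), C, N))
    rk <- paste0(key, ".mean"); vk <- paste0(key, ".var")
    model$buffers[[rk]] <- (1 - momentum) * model$buffers[[rk]] + momentum * mu
    model$buffers[[vk]] <- (1 - momentum) * model$buffers[[vk]] + momentum * va
  } else {
    mu <- model$buffers[[paste0(key, ".mean")]]
    va <- model$buffers[[paste0(key, ".var")]]
    xc <- xm - rep(rep(mu, each = hw), times = N)
  }
  isd <- 1 / sqrt(va + eps)
  xh <- xc * rep(rep(isd, each = hw), times = N)
  v <- xh * rep(rep(vg, each = hw), times = N) +
    rep(rep(vb, each = hw), times = N)
  dim(v) <- dm
  if (!tracing(x, gamma, beta)) return(v)
  m <- hw * N
  new_node(v, function(g) {
    gm <- matrix(g, hw, C * N)
    gsum <- rowSums(matrix(colSums(gm), C, N))
    gxh_sum <- rowSums(matrix(colSums(gm * xh), C, N))
    acc_grad(gamma, gxh_sum)
    acc_grad(beta, gsum)
    gh <- gm * rep(rep(vg, each = hw), times = N)
    if (train) {
      ghs <- rowSums(matrix(colSums(gh), C, N)) / m
      ghx <- rowSums(matrix(colSums(gh * xh), C, N)) / m
      gx <- (gh - rep(rep(ghs, each = hw), times = N) -
               xh * rep(rep(ghx, each = hw), times = N)) *
        rep(rep(isd, each = hw), times = N)
    } else {
      gx <- gh * rep(rep(isd, each = hw), times = N)
    }
    acc_grad(x, array(gx, dm))
  })
}

## focal loss straight from logits (fused softmax + focal, analytic gradient)
ag_focal_from_logits <- function(logits, target, alpha_vec, gamma,
                                 eps = 1e-7) {
  vz <- vof(logits)
  dm <- dim(vz)
  C <- dm[3L]
  zp <- matrix(aperm(vz, c(1L, 2L, 4L, 3L)), dm[1L] * dm[2L] * dm[4L], C)
  tv <- as.integer(target) + 1L
  mx <- do.call(pmax, lapply(seq_len(C), function(j) zp[, j]))
  ex <- exp(zp - mx)
  Z <- rowSums(ex)
  p <- ex / Z
  M <- nrow(zp)
  pt <- p[cbind(seq_len(M), tv)]
  clamped <- pt < eps | pt > 1 - eps
  ptc <- pmin(pmax(pt, eps), 1 - eps)
  at <- alpha_vec[tv]
  omp <- 1 - ptc
  li <- -at * omp^gamma * log(ptc)
  v <- mean(li)
  if (!tracing(logits)) return(v)
  new_node(v, function(g) {
    dldpt <- if (gamma == 0) -at / ptc
             else -at * (-gamma * omp^(gamma - 1) * log(ptc) + omp^gamma / ptc)
    dldpt[clamped] <- 0
    a <- dldpt * pt
    G <- -a * p
    G[cbind(seq_len(M), tv)] <- G[cbind(seq_len(M), tv)] + a
    G <- G * (g / M)
    gz <- aperm(array(G, c(dm[1L], dm[2L], dm[4L], C)), c(1L, 2L, 4L, 3L))
    acc_grad(logits, gz)
  })
}
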