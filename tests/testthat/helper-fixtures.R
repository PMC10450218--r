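# Shared fixtures: tiny model configurations and synthetic samples sized for
# fast tests.

tiny_config <- function(input_size = 32, num_classes = 2, seed = 1,
                        heads = 2, layers = 2, token_len = 4) {
  caunet_config(num_classes = num_classes, input_size = input_size,
                widths = c(4, 8, 16, 32), groups = 2, se_reduction = 2,
                heads = heads, layers = layers, token_len = token_len,
                seed = seed)
}

desk_config <- function(num_classes = 2, seed = 1) {
  # the desk-scale study configuration: 64 px, widths 8/16/32/64,
  # d = 16 tokens, 2 heads, 2 transformer layers
  caunet_config(num_classes = num_classes, input_size = 64,
                widths = c(8, 16, 32, 64), groups = 4, se_reduction = 4,
                heads = 2, layers = 2, token_len = 16, seed = seed)
}

random_image_batch <- function(size, n = 2, seed = 1) {
  set.seed(seed)
  array(stats::runif(size * size * 3 * n), c(size, size, 3, n))
}

random_mask <- function(size, num_classes = 2, n = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(n)) matrix(sample(0:(num_classes - 1), size * size, TRUE), size)
  else array(sample(0:(num_classes - 1), size * size * n, TRUE),
             c(size, size, n))
}

# brute-force set-based metric oracle: collects pixel index sets per class
# and measures overlaps directly
oracle_report <- function(pred, true, num_classes) {
  pv <- as.vector(pred); tv <- as.vector(true)
  per <- lapply(0:(num_classes - 1), function(cl) {
    A <- which(tv == cl)   # reference pixels of the class
    B <- which(pv == cl)   # predicted pixels
    tp <- length(intersect(A, B))
    fp <- length(setdiff(B, A))
    fn <- length(setdiff(A, B))
    if (tp + fp + fn == 0)
      return(list(iou = 1, prec = 1, rec = 1, dice = 1))
    list(iou = if (tp + fp + fn > 0) tp / length(union(A, B)) else 0,
         prec = if (length(B) > 0) tp / length(B) else 0,
         rec = if (length(A) > 0) tp / length(A) else 0,
         dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
  })
  list(iou = vapply(per, `[[`, 0, "iou"),
       prec = vapply(per, `[[`, 0, "prec"),
       rec = vapply(per, `[[`, 0, "rec"),
       dice = vapply(per, `[[`, 0, "dice"))
}
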