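## Synthetic endoscopy-like scenes: reddish mucosal backgrounds carrying
## "spot" (compact blob) and "tendril" (curvilinear, optionally branching)
## lesions, with optional Gaussian blur and specular highlights. Masks are
## class-index images aligned pixel-for-pixel with the rendered lesions, so
## every other module is testable without clinical data.

#' Specification of a synthetic endoscopy-like scene
#'
#' All geometric defaults scale with `image_size` so the same spec family
#' works at full and desk scale. Counts and sizes are sampled uniformly from
#' the given `c(min, max)` ranges.
#'
#' @param image_size square canvas side in pixels.
#' @param n_spots integer range of spot lesions per image.
#' @param n_tendrils integer range of tendril lesions per image.
#' @param spot_radius pixel range of spot radii; default 4.5% to 9% of the
#'   canvas side.
#' @param tendril_length pixel range of tendril arc length; default 20% to
#'   60% of the canvas side.
#' @param tendril_width pixel range of tendril stroke width; default 1.2% to
#'   3% of the canvas side (at least 1 px).
#' @param blur_prob probability that the image (not the mask) is blurred.
#' @param reflection_prob probability of specular highlight ellipses
#'   (image only, never the mask).
#' @param label_scheme `"two_class"` (0 background, 1 lesion) or
#'   `"three_class"` (0 background, 1 spot, 2 tendril).
#' @param background_palette list with `r`, `g`, `b` ranges (0-255) for the
#'   mucosal base colour, biased to reds/pinks.
#' @param seed integer seed; all randomness in generation flows from it.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 224,
                           n_spots = c(1, 3),
                           n_tendrils = c(0, 2),
                           spot_radius = round(image_size * c(0.045, 0.09)),
                           tendril_length = round(image_size * c(0.2, 0.6)),
                           tendril_width = pmax(1, round(image_size * c(0.012, 0.03))),
                           blur_prob = 0.3,
                           reflection_prob = 0.3,
                           label_scheme = c("two_class", "three_class"),
                           background_palette = list(r = c(150, 220),
                                                     g = c(60, 120),
                                                     b = c(60, 120)),
                           seed = 1L) {
  label_scheme <- match.arg(label_scheme)
  spec <- list(image_size = as.integer(image_size), n_spots = n_spots,
               n_tendrils = n_tendrils, spot_radius = spot_radius,
               tendril_length = tendril_length, tendril_width = tendril_width,
               blur_prob = blur_prob, reflection_prob = reflection_prob,
               label_scheme = label_scheme,
               background_palette = background_palette, seed = as.integer(seed))
  for (f in c("n_spots", "n_tendrils", "spot_radius", "tendril_length",
              "tendril_width")) {
    r <- spec[[f]]
    if (length(r) != 2 || any(r < 0) || r[2] < r[1])
      stop("`", f, "` must be a nonempty nonnegative range c(min, max)")
  }
  for (f in c("blur_prob", "reflection_prob"))
    if (spec[[f]] < 0 || spec[[f]] > 1) stop("`", f, "` must lie in [0, 1]")
  if (spec$image_size < 8) stop("`image_size` too small")
  class(spec) <- "synthetic_spec"
  spec
}

runif_range <- function(r) stats::runif(1, r[1], r[2])
rint_range <- function(r) sample(seq.int(r[1], r[2]), 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## low-frequency shaded background in the red/pink palette
render_background <- function(s) {
  pal <- s$background_palette
  base <- c(runif_range(pal$r), runif_range(pal$g), runif_range(pal$b))
  n <- s$image_size
  gx <- matrix(seq(-1, 1, length.out = n), n, n)
  gy <- t(gx)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    grad <- stats::runif(1, -12, 12) * gx + stats::runif(1, -12, 12) * gy
    img[, , ch] <- base[ch] + grad + matrix(stats::rnorm(n * n, 0, 4), n, n)
  }
  clamp(img, 0, 255)
}

## disc support via pixel-centre scan over the bounding box
disc_pixels <- function(cx, cy, r, n) {
  rows <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(n, ceiling(cx + r))
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  sel <- (rr - cy)^2 + (cc - cx)^2 <= r^2
  cbind(row = rr[sel], col = cc[sel])
}

## pixels within width/2 of any segment of a polyline
polyline_pixels <- function(pts, width, n) {
  half <- width / 2
  out <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    p1 <- pts[i, ]; p2 <- pts[i + 1, ]
    lo <- pmin(p1, p2) - half; hi <- pmax(p1, p2) + half
    rows <- max(1, floor(lo[2])):min(n, ceiling(hi[2]))
    cols <- max(1, floor(lo[1])):min(n, ceiling(hi[1]))
    if (!length(rows) || !length(cols)) next
    rr <- matrix(rows, length(rows), length(cols))
    cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) 0 else clamp(((cc - p1[1]) * dx + (rr - p1[2]) * dy) / len2, 0, 1)
    d2 <- (cc - (p1[1] + t * dx))^2 + (rr - (p1[2] + t * dy))^2
    sel <- d2 <= half^2
    if (any(sel)) out <- rbind(out, cbind(row = rr[sel], col = cc[sel]))
  }
  unique(out)
}

## random-walk tendril path with an optional single branch
tendril_path <- function(start, length, n) {
  step <- 2
  ns <- max(3, round(length / step))
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, ns + 1, 2)
  pts[1, ] <- start
  for (i in seq_len(ns)) {
    theta <- theta + stats::rnorm(1, 0, 0.3)
    pts[i + 1, ] <- pts[i, ] + step * c(cos(theta), sin(theta))
  }
  pts[, 1] <- clamp(pts[, 1], 1, n)
  pts[, 2] <- clamp(pts[, 2], 1, n)
  branch <- NULL
  if (stats::runif(1) < 0.5 && ns >= 6) {
    at <- sample(seq.int(2, ns - 2), 1)
    bth <- theta + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.0)
    bn <- max(2, round(ns / 2))
    bp <- matrix(0, bn + 1, 2)
    bp[1, ] <- pts[at, ]
    for (i in seq_len(bn)) {
      bth <- bth + stats::rnorm(1, 0, 0.3)
      bp[i + 1, ] <- bp[i, ] + step * c(cos(bth), sin(bth))
    }
    bp[, 1] <- clamp(bp[, 1], 1, n)
    bp[, 2] <- clamp(bp[, 2], 1, n)
    branch <- bp
  }
  list(main = pts, branch = branch)
}

lesion_color <- function() {
  c(stats::runif(1, 90, 140), stats::runif(1, 10, 45), stats::runif(1, 10, 45))
}

paint <- function(img, mask, px, color, class) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[px] <- color[ch] + stats::rnorm(nrow(px), 0, 3)
    img[, , ch] <- pl
  }
  mask[px] <- class
  list(img = clamp(img, 0, 255), mask = mask)
}

## separable Gaussian blur, reflecting edges
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- dim(img)[1]
  idx <- function(i) clamp(i, 1, n)
  for (ch in seq_len(dim(img)[3])) {
    p <- img[, , ch]
    acc <- matrix(0, n, n)
    for (j in -r:r) acc <- acc + k[j + r + 1] * p[idx(seq_len(n) + j), , drop = FALSE]
    p <- acc
    acc <- matrix(0, n, n)
    for (j in -r:r) acc <- acc + k[j + r + 1] * p[, idx(seq_len(n) + j), drop = FALSE]
    img[, , ch] <- acc
  }
  img
}

add_reflections <- function(img) {
  n <- dim(img)[1]
  for (i in seq_len(sample(1:3, 1))) {
    cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
    ax <- stats::runif(1, 0.02, 0.08) * n; ay <- stats::runif(1, 0.02, 0.08) * n
    th <- stats::runif(1, 0, pi)
    alpha <- stats::runif(1, 0.6, 0.9)
    rows <- max(1, floor(cy - ax - ay)):min(n, ceiling(cy + ax + ay))
    cols <- max(1, floor(cx - ax - ay)):min(n, ceiling(cx + ax + ay))
    rr <- matrix(rows, length(rows), length(cols))
    cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    u <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
    v <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
    sel <- (u / ax)^2 + (v / ay)^2 <= 1
    if (!any(sel)) next
    px <- cbind(rr[sel], cc[sel])
    white <- c(252, 250, 246)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[px] <- (1 - alpha) * pl[px] + alpha * white[ch]
      img[, , ch] <- pl
    }
  }
  clamp(img, 0, 255)
}

#' Generate one synthetic image/mask pair
#'
#' Renders the background, paints spot and tendril lesions into both the
#' image and the class-index mask, then (image only) applies optional blur
#' and specular reflections. Deterministic given `spec` and `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param id sample identifier stored in the result.
#' @return an image sample: list with `id`, `image` (H x W x 3, values
#'   0-255), `mask` (H x W integer matrix of class indices) and
#'   `normalized = FALSE`.
#' @export
generate_sample <- function(spec, seed = spec$seed, id = "sample") {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- spec$image_size
  img <- render_background(spec)
  mask <- matrix(0L, n, n)
  nsp <- rint_range(spec$n_spots)
  ntd <- rint_range(spec$n_tendrils)
  spot_class <- 1L
  tendril_class <- if (spec$label_scheme == "three_class") 2L else 1L
  for (i in seq_len(nsp)) {
    r <- runif_range(spec$spot_radius)
    if (2 * r + 2 > n) stop("spot radius ", round(r), " cannot fit the canvas")
    ok <- FALSE
    for (try in 1:100) {
      cx <- stats::runif(1, r + 1, n - r)
      cy <- stats::runif(1, r + 1, n - r)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place spot lesion")
    px <- disc_pixels(cx, cy, r, n)
    res <- paint(img, mask, px, lesion_color(), spot_class)
    img <- res$img; mask <- res$mask
  }
  for (i in seq_len(ntd)) {
    len <- runif_range(spec$tendril_length)
    wid <- runif_range(spec$tendril_width)
    if (len >= 4 * n) stop("tendril length cannot fit the canvas")
    margin <- min(n / 4, len / 4)
    start <- c(stats::runif(1, 1 + margin, n - margin),
               stats::runif(1, 1 + margin, n - margin))
    path <- tendril_path(start, len, n)
    px <- polyline_pixels(path$main, wid, n)
    if (!is.null(path$branch))
      px <- unique(rbind(px, polyline_pixels(path$branch, wid, n)))
    res <- paint(img, mask, px, lesion_color(), tendril_class)
    img <- res$img; mask <- res$mask
  }
  if (stats::runif(1) < spec$blur_prob)
    img <- gaussian_blur(img, stats::runif(1, 0.5, 1.5))
  if (stats::runif(1) < spec$reflection_prob)
    img <- add_reflections(img)
  list(id = id, image = round(img), mask = mask, normalized = FALSE)
}

#' Generate a dataset of synthetic samples on disk
#'
#' Writes `n` image PNGs, `n` single-channel mask PNGs (pixel value = class
#' index) and a `manifest.csv` with columns `id`, `image_path`, `mask_path`
#' (paths relative to `out_dir`). Filenames are deterministic in the index
#' and sample `i` is generated with seed `spec$seed + i`, so two runs with
#' the same spec produce identical bytes.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of samples.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) the manifest data frame.
#' @export
generate_dataset <- function(spec, n, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("`out_dir` exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("sample_%04d", i)
    s <- generate_sample(spec, seed = spec$seed + i, id = id)
    ip <- sprintf("img_%04d.png", i)
    mp <- sprintf("mask_%04d.png", i)
    write_image_png(s$image, file.path(out_dir, ip))
    write_mask_png(s$mask, file.path(out_dir, mp))
    rows[[i]] <- data.frame(id = id, image_path = ip, mask_path = mp)
  }
  manifest <- if (n > 0) do.call(rbind, rows)
    else data.frame(id = character(), image_path = character(),
                    mask_path = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
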