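## Image/mask IO, min-max normalization, polygon-annotation rasterization,
## augmentation and dataset splitting.

#' Min-max normalize an image to [0, 1]
#'
#' `y = (x - min(x)) / (max(x) - min(x))` over all pixels (and channels).
#' A constant image maps to all zeros rather than dividing by zero. The map
#' is idempotent: normalizing a normalized image changes nothing.
#'
#' @param x numeric array; all values must be finite.
#' @return an array of the same shape with values in `[0, 1]`.
#' @examples
#' normalize_minmax(c(0, 127.5, 255))
#' @export
normalize_minmax <- function(x) {
  if (!all(is.finite(x))) stop("`x` must be finite")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Rasterize polygon annotations (Labelme dialect) into a class-index mask
#'
#' Reads a Labelme-style annotation (a file path or an already-parsed list
#' with a `shapes` list of `{label, points}` entries) and fills each polygon
#' with its label's class index. Rasterization uses the even-odd rule with
#' pixel-centre sampling at 0-based coordinates (point `(x, y)` = column `x`,
#' row `y`). Later-listed shapes overwrite earlier ones where they overlap.
#'
#' @param annotation path to a Labelme JSON file, or an equivalent list.
#' @param class_map named integer vector mapping labels to class indices
#'   (>= 1; 0 is background).
#' @param size `c(H, W)` of the output mask.
#' @return an `H x W` integer matrix of class indices.
#' @export
labelme_to_mask <- function(annotation, class_map, size) {
  if (is.character(annotation)) {
    annotation <- tryCatch(
      jsonlite::read_json(annotation, simplifyVector = FALSE),
      error = function(e) stop("malformed annotation JSON: ", conditionMessage(e)))
  }
  shapes <- annotation$shapes
  H <- size[1]; W <- size[2]
  mask <- matrix(0L, H, W)
  for (sh in shapes) {
    lab <- sh$label
    if (is.null(lab) || !lab %in% names(class_map))
      stop("unknown label in annotation: '", lab, "'")
    pts <- sh$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
    pts <- matrix(as.numeric(pts), ncol = 2)
    inside <- polygon_fill(pts, H, W)
    mask[inside] <- as.integer(class_map[[lab]])
  }
  mask
}

## Even-odd scanline fill; returns a logical H x W matrix of pixel centres
## inside the polygon. Vertices are (x = col, y = row), 0-based.
polygon_fill <- function(pts, H, W) {
  inside <- matrix(FALSE, H, W)
  if (nrow(pts) < 3) return(inside)
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (r in 0:(H - 1)) {
    crosses <- (y > r) != (y2 > r)
    if (!any(crosses)) next
    xc <- x[crosses] + (r - y[crosses]) * (x2[crosses] - x[crosses]) /
      (y2[crosses] - y[crosses])
    xc <- sort(xc)
    cols <- 0:(W - 1)
    cnt_right <- length(xc) - findInterval(cols, xc)
    inside[r + 1, cnt_right %% 2 == 1] <- TRUE
  }
  inside
}

#' Augmentation settings
#'
#' Geometric transforms (rotation, mirror flip) are applied identically to
#' image and mask (nearest-neighbour for the mask, since class indices are
#' categorical); photometric transforms (brightness, contrast, sharpness,
#' chroma) touch the image only. Factor ranges default to `[0.7, 1.3]`.
#'
#' @param rotation degree range for random rotation.
#' @param brightness,contrast,sharpness,chroma multiplicative factor ranges.
#' @param mirror_flip probability of a horizontal mirror flip.
#' @param multiplier expansion factor (>= 1, real); each call produces
#'   `floor(multiplier)` or `ceiling(multiplier)` variants with the
#'   fractional part as the probability of the extra one, so the expected
#'   dataset expansion matches a non-integer target.
#' @param seed integer seed.
#' @return a list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation = c(-25, 25), brightness = c(0.7, 1.3),
                              contrast = c(0.7, 1.3), sharpness = c(0.7, 1.3),
                              chroma = c(0.7, 1.3), mirror_flip = 0.5,
                              multiplier = 1, seed = 1L) {
  for (r in list(brightness, contrast, sharpness, chroma))
    if (any(r <= 0) || r[2] < r[1]) stop("factor ranges must be positive")
  if (multiplier <= 0) stop("`multiplier` must be positive")
  if (multiplier < 1) stop("`multiplier` must be at least 1")
  structure(list(rotation = rotation, brightness = brightness,
                 contrast = contrast, sharpness = sharpness, chroma = chroma,
                 mirror_flip = mirror_flip, multiplier = multiplier,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

flip_h <- function(x) {
  if (length(dim(x)) == 3) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

## rotate around the image centre by `angle` degrees; inverse mapping with
## bilinear (image) or nearest-neighbour (mask) sampling, fill = 0
rotate_plane <- function(p, angle, nearest) {
  H <- nrow(p); W <- ncol(p)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  sy <- cy + (r - cy) * cos(th) - (c - cx) * sin(th)
  sx <- cx + (r - cy) * sin(th) + (c - cx) * cos(th)
  if (nearest) {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(0, H, W)
    out[ok] <- p[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sy); c0 <- floor(sx)
  fr <- sy - r0; fc <- sx - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- matrix(0, H, W)
    v[ok] <- p[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
}

rotate_sample <- function(img, mask, angle) {
  if (angle == 0) return(list(image = img, mask = mask))
  out <- img
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- rotate_plane(img[, , ch], angle, nearest = FALSE)
  m <- rotate_plane(mask, angle, nearest = TRUE)
  list(image = out, mask = matrix(as.integer(m), nrow(mask)))
}

photometric <- function(img, f_bright, f_contrast, f_sharp, f_chroma, top) {
  if (f_bright != 1) img <- pmin(pmax(img * f_bright, 0), top)
  if (f_contrast != 1) {
    m <- mean(img)
    img <- pmin(pmax((img - m) * f_contrast + m, 0), top)
  }
  if (f_sharp != 1) {
    blur <- img
    for (ch in seq_len(dim(img)[3]))
      blur[, , ch] <- box_blur3(img[, , ch])
    img <- pmin(pmax(img + (f_sharp - 1) * (img - blur), 0), top)
  }
  if (f_chroma != 1) {
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    for (ch in 1:3)
      img[, , ch] <- pmin(pmax(g + f_chroma * (img[, , ch] - g), 0), top)
  }
  img
}

box_blur3 <- function(p) {
  H <- nrow(p); W <- ncol(p)
  up <- p[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- p[c(seq_len(H)[-1], H), , drop = FALSE]
  v <- (up + p + dn) / 3
  lf <- v[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- v[, c(seq_len(W)[-1], W), drop = FALSE]
  (lf + v + rt) / 3
}

#' Augment one sample into several variants
#'
#' Per variant: a Bernoulli mirror flip and a uniform rotation are applied to
#' image and mask together (mask via nearest neighbour, out-of-canvas filled
#' with background class 0), then brightness/contrast/sharpness/chroma
#' factors to the image only. The mask of a photometric-only variant is
#' bit-identical to the input mask.
#'
#' @param sample an image sample (list with `image`, `mask`, `normalized`).
#' @param spec an [augmentation_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a list of image samples.
#' @export
augment_sample <- function(sample, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  m <- spec$multiplier
  k <- floor(m) + (stats::runif(1) < m - floor(m))
  top <- if (isTRUE(sample$normalized)) 1 else 255
  out <- vector("list", k)
  for (i in seq_len(k)) {
    img <- sample$image; msk <- sample$mask
    if (stats::runif(1) < spec$mirror_flip) {
      img <- flip_h(img); msk <- flip_h(msk)
    }
    angle <- runif_range(spec$rotation)
    rs <- rotate_sample(img, msk, angle)
    img <- photometric(rs$image, runif_range(spec$brightness),
                       runif_range(spec$contrast), runif_range(spec$sharpness),
                       runif_range(spec$chroma), top)
    out[[i]] <- list(id = paste0(sample$id, "_aug", i), image = img,
                     mask = rs$mask, normalized = sample$normalized)
  }
  out
}

#' Split sample ids into train and test sets
#'
#' Random partition with `round(train_fraction * n)` training ids (clamped so
#' both sides are nonempty), deterministic given `seed`.
#'
#' @param ids character or integer vector of unique ids, length >= 2.
#' @param train_fraction fraction in (0, 1); default 0.8 for the 8:2 split.
#' @param seed integer seed.
#' @return a list with elements `train` and `test`.
#' @export
split_dataset <- function(ids, train_fraction = 0.8, seed = 1L) {
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample(n)
  ntr <- min(max(round(train_fraction * n), 1), n - 1)
  list(train = ids[sort(perm[seq_len(ntr)])],
       test = ids[sort(perm[-seq_len(ntr)])])
}

## ---- IO -------------------------------------------------------------------

#' Write an RGB image as an 8-bit PNG
#' @param image `H x W x 3` array with values in 0-255 (or 0-1 if normalized).
#' @param path output path.
#' @export
write_image_png <- function(image, path) {
  if (max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}

#' Read an image file into an H x W x 3 array (values 0-255)
#'
#' PNG is read natively; JPG/JPEG requires the EBImage package.
#' @param path image path.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPG requires the EBImage package")
    a <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else stop("unsupported image format: ", ext)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write a class-index mask as a single-channel 8-bit PNG
#' @param mask integer matrix of class indices (0-255).
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a single-channel mask PNG back into an integer matrix
#' @param path mask path.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a))
}

#' Read a dataset manifest (id, image_path, mask_path) into samples
#'
#' Paths in the manifest are resolved relative to the manifest's directory.
#' @param path path to a manifest CSV.
#' @return a list of image samples.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    list(id = man$id[i],
         image = read_image(file.path(base, man$image_path[i])),
         mask = read_mask_png(file.path(base, man$mask_path[i])),
         normalized = FALSE)
  })
}
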