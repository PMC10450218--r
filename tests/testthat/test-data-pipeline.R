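# Normalization, polygon rasterization, augmentation, splitting, IO.

test_that("min-max normalization maps endpoints and is idempotent", {
  expect_equal(normalize_minmax(c(0, 127.5, 255)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(1)
  x <- array(runif(48, -3, 7), c(4, 4, 3))
  y <- normalize_minmax(x)
  expect_true(all(y >= 0 & y <= 1))
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_equal(normalize_minmax(y), y, tolerance = 1e-12)
  expect_error(normalize_minmax(c(1, NA)), "finite")
})

test_that("polygon rasterization matches a brute-force even-odd scan", {
  ann <- list(shapes = list(list(
    label = "spot",
    points = list(c(10, 10), c(20, 10), c(20, 20), c(10, 20)))))
  mask <- labelme_to_mask(ann, c(spot = 1L), c(32, 32))
  # independent per-pixel ray cast (even-odd rule, centre sampling)
  poly <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  brute <- matrix(0L, 32, 32)
  for (r in 0:31) for (cc in 0:31) {
    n <- nrow(poly); cross <- 0
    for (k in seq_len(n)) {
      p1 <- poly[k, ]; p2 <- poly[k %% n + 1, ]
      if ((p1[2] > r) != (p2[2] > r)) {
        xc <- p1[1] + (r - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
        if (xc > cc) cross <- cross + 1
      }
    }
    if (cross %% 2 == 1) brute[r + 1, cc + 1] <- 1L
  }
  expect_identical(mask, brute)
  expect_equal(sum(mask), 100)  # 10 x 10 interior pixel centres

  # empty annotation and error contracts
  expect_true(all(labelme_to_mask(list(shapes = list()), c(a = 1L),
                                  c(8, 8)) == 0))
  expect_error(labelme_to_mask(ann, c(other = 1L), c(32, 32)), "spot")
})

test_that("later-listed polygons win on overlap and JSON files load", {
  ann <- list(shapes = list(
    list(label = "a", points = list(c(2, 2), c(12, 2), c(12, 12), c(2, 12))),
    list(label = "b", points = list(c(8, 8), c(18, 8), c(18, 18), c(8, 18)))))
  mask <- labelme_to_mask(ann, c(a = 1L, b = 2L), c(24, 24))
  expect_equal(mask[10 + 1, 10 + 1], 2L)  # overlap pixel takes the later label
  expect_equal(mask[4 + 1, 4 + 1], 1L)
  expect_equal(mask[16 + 1, 16 + 1], 2L)

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(ann, f, auto_unbox = TRUE)
  expect_identical(labelme_to_mask(f, c(a = 1L, b = 2L), c(24, 24)), mask)
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(labelme_to_mask(bad, c(a = 1L), c(8, 8)), "malformed")
  unlink(c(f, bad))
})

make_sample <- function(size = 32, seed = 8) {
  spec <- synthetic_spec(image_size = size, seed = seed)
  generate_sample(spec)
}

test_that("mirror flip is an involution and preserves foreground count", {
  s <- make_sample()
  spec <- augmentation_spec(rotation = c(0, 0), brightness = c(1, 1),
                            contrast = c(1, 1), sharpness = c(1, 1),
                            chroma = c(1, 1), mirror_flip = 1, seed = 1)
  v1 <- augment_sample(s, spec)[[1]]
  expect_equal(sum(v1$mask > 0), sum(s$mask > 0))  # flip preserves count
  v2 <- augment_sample(v1, spec)[[1]]
  expect_identical(v2$image, s$image)
  expect_identical(v2$mask, s$mask)
})

test_that("identity augmentation returns the sample unchanged", {
  s <- make_sample()
  spec <- augmentation_spec(rotation = c(0, 0), brightness = c(1, 1),
                            contrast = c(1, 1), sharpness = c(1, 1),
                            chroma = c(1, 1), mirror_flip = 0, seed = 2)
  v <- augment_sample(s, spec)[[1]]
  expect_identical(v$image, s$image)
  expect_identical(v$mask, s$mask)
})

test_that("photometric-only variants leave the mask bit-identical", {
  s <- make_sample()
  spec <- augmentation_spec(rotation = c(0, 0), mirror_flip = 0,
                            multiplier = 3, seed = 3)
  vs <- augment_sample(s, spec)
  expect_length(vs, 3)
  for (v in vs) {
    expect_identical(v$mask, s$mask)
    expect_true(all(v$image >= 0 & v$image <= 255))
  }
})

test_that("rotation moves image and mask together", {
  s <- make_sample(seed = 12)
  spec <- augmentation_spec(rotation = c(30, 30), brightness = c(1, 1),
                            contrast = c(1, 1), sharpness = c(1, 1),
                            chroma = c(1, 1), mirror_flip = 0, seed = 4)
  v <- augment_sample(s, spec)[[1]]
  expect_false(identical(v$mask, s$mask))
  expect_true(all(v$mask %in% sort(unique(as.vector(s$mask)))))
  # area approximately preserved under nearest-neighbour rotation
  expect_lt(abs(sum(v$mask > 0) - sum(s$mask > 0)) / max(sum(s$mask > 0), 1),
            0.25)
  # same seed reproduces the same variants
  v2 <- augment_sample(s, spec)[[1]]
  expect_identical(v$image, v2$image)
})

test_that("multiplier realizes floor/ceil sampling with the right mean", {
  s <- make_sample()
  spec <- augmentation_spec(multiplier = 2.5, seed = 1)
  ks <- vapply(1:40, function(i) length(augment_sample(s, spec, seed = i)), 0L)
  expect_true(all(ks %in% c(2L, 3L)))
  expect_gt(mean(ks), 2.2)
  expect_lt(mean(ks), 2.8)
  expect_error(augmentation_spec(multiplier = 0), "multiplier")
})

test_that("dataset splitting is a deterministic partition", {
  ids <- paste0("s", 1:10)
  sp <- split_dataset(ids, 0.8, seed = 5)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_dataset(ids, 0.8, seed = 5))
  expect_false(identical(sp, split_dataset(ids, 0.8, seed = 6)))

  sp5 <- split_dataset(paste0("t", 1:5), 0.8, seed = 1)
  expect_length(sp5$train, 4)
  expect_length(sp5$test, 1)
  expect_error(split_dataset("only", 0.8), "at least 2")
  expect_error(split_dataset(ids, 1.2), "train_fraction")
})

test_that("mask PNG round trip is exact", {
  m <- random_mask(16, 3, seed = 6)
  f <- tempfile(fileext = ".png")
  write_mask_png(m, f)
  expect_identical(read_mask_png(f), matrix(as.integer(m), 16))
  unlink(f)
})
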