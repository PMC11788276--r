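# YOLO label I/O, deterministic splits, letterboxing, mosaic.

test_that("label files round-trip to 6 decimals and handle edge cases", {
  f <- tempfile(fileext = ".txt")
  ann <- data.frame(class = c(3L, 0L), cx = c(0.5, 0.25), cy = c(0.5, 0.75),
                    w = c(0.2, 0.1), h = c(0.1, 0.3))
  write_yolo_labels(ann, f)
  back <- read_yolo_labels(f)
  expect_equal(back, ann, tolerance = 1e-6)

  writeLines(character(0), f)
  expect_equal(nrow(read_yolo_labels(f)), 0)

  writeLines("3 0.5 0.5 0.2 0.1", f)
  one <- read_yolo_labels(f)
  expect_equal(one$class, 3L)

  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 bad 0.1"), f)
  expect_error(read_yolo_labels(f), "line 2")
})

test_that("out-of-range labels are clipped with a warning", {
  f <- tempfile(fileext = ".txt")
  writeLines("0 0.95 0.5 0.3 0.2", f)
  expect_warning(a <- read_yolo_labels(f), "clipped")
  expect_lte(a$cx + a$w / 2, 1)
})

test_that("splits are deterministic, disjoint, exhaustive, with val taking the odd item", {
  s <- split_dataset(1:10, seed = 3)
  expect_equal(lengths(s), c(train = 8L, val = 1L, test = 1L))
  s2 <- split_dataset(1:2569, seed = 1)
  expect_equal(lengths(s2), c(train = 2055L, val = 257L, test = 257L))
  for (seed in c(0, 7, 123)) {
    n <- sample(10:200, 1)
    a <- split_dataset(seq_len(n), seed = seed)
    b <- split_dataset(seq_len(n), seed = seed)
    expect_identical(a, b)
    all_items <- c(a$train, a$val, a$test)
    expect_equal(sort(all_items), seq_len(n))
    expect_equal(length(all_items), length(unique(all_items)))
  }
  expect_error(split_dataset(1:2), "split error")
})

test_that("letterbox geometry: identity, symmetric pad, exact box round-trip", {
  img <- array(runif(640 * 640 * 3), dim = c(640, 640, 3))
  lb <- letterbox(img, 640)
  expect_equal(lb$transform$scale, 1)
  expect_equal(lb$transform$pad_x, 0)
  expect_identical(lb$image, img)

  img2 <- array(runif(320 * 640 * 3), dim = c(320, 640, 3))
  lb2 <- letterbox(img2, 640)
  expect_equal(lb2$transform$scale, 1)
  expect_equal(lb2$transform$pad_y, 160)
  expect_equal(lb2$transform$pad_x, 0)

  ann <- data.frame(class = 0L, cx = 0.3, cy = 0.6, w = 0.2, h = 0.25)
  fwd <- apply_letterbox(ann, lb2$transform)
  back <- apply_letterbox(fwd, lb2$transform, inverse = TRUE)
  expect_equal(back, ann, tolerance = 1e-9)
})

test_that("mosaic disabled returns the letterboxed first sample; enabled output stays in bounds", {
  set.seed(2)
  mk <- function() {
    img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
    ann <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.4, h = 0.4)
    list(image = img, ann = ann)
  }
  samples <- list(mk(), mk(), mk(), mk())
  off <- mosaic_augment(samples, seed = 5, enabled = FALSE, target = 64)
  expect_equal(off$image, samples[[1]]$image, tolerance = 1e-12)
  expect_equal(off$ann$cx, 0.5, tolerance = 1e-9)

  on1 <- mosaic_augment(samples, seed = 5, enabled = TRUE, target = 64)
  on2 <- mosaic_augment(samples, seed = 5, enabled = TRUE, target = 64)
  expect_identical(on1$image, on2$image)
  expect_identical(on1$ann, on2$ann)
  if (nrow(on1$ann)) {
    expect_true(all(on1$ann$cx - on1$ann$w / 2 >= -1e-9))
    expect_true(all(on1$ann$cx + on1$ann$w / 2 <= 1 + 1e-9))
    expect_true(all(on1$ann$cy + on1$ann$h / 2 <= 1 + 1e-9))
  }
  # identical single-box samples: remapped boxes from all four tiles
  on_many <- lapply(1:25, function(s)
    mosaic_augment(samples, seed = s, enabled = TRUE, target = 64))
  counts <- vapply(on_many, function(o) nrow(o$ann), numeric(1))
  expect_true(any(counts >= 3))
  for (o in on_many)
    if (nrow(o$ann))
      expect_true(all(o$ann$w > 0 & o$ann$h > 0))
})

test_that("image files round-trip through the png path", {
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(dim(back), c(16, 16, 3))
  expect_equal(back, img, tolerance = 1 / 255)
})
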