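# YOLO-format dataset reading/writing, deterministic splitting, letterboxing
# and mosaic augmentation.
#
# Images are arrays dim c(H, W, 3) with values in [0, 1]. Labels are one
# "class cx cy w h" line per object, coordinates normalized to [0, 1].

#' Read a YOLO label file
#'
#' @param path Label file; one `class cx cy w h` line per object.
#' @return Data frame with columns `class`, `cx`, `cy`, `w`, `h`.
#'   Out-of-range boxes are clipped (with a warning); malformed lines raise
#'   an error naming the line.
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || any(is.na(v)))
      stop(sprintf("parse error in %s line %d: expected 5 numeric fields", path, i))
    out[i, ] <- list(as.integer(v[1]), v[2], v[3], v[4], v[5])
  }
  clipped <- clip_annotations(out)
  # warn only for substantive violations, not 1e-6-level rounding from the
  # fixed-precision label format
  if (nrow(clipped) < nrow(out) ||
      (nrow(out) && max(abs(as.matrix(clipped[-1]) - as.matrix(out[-1]))) > 1e-4))
    warning("out-of-range boxes clipped in ", path)
  clipped
}

# clip normalized boxes so that cx +/- w/2 stays inside [0, 1]
clip_annotations <- function(ann) {
  if (!nrow(ann)) return(ann)
  x1 <- pmax(ann$cx - ann$w / 2, 0); x2 <- pmin(ann$cx + ann$w / 2, 1)
  y1 <- pmax(ann$cy - ann$h / 2, 0); y2 <- pmin(ann$cy + ann$h / 2, 1)
  keep <- x2 - x1 > 1e-6 & y2 - y1 > 1e-6
  data.frame(class = ann$class[keep],
             cx = (x1 + x2)[keep] / 2, cy = (y1 + y2)[keep] / 2,
             w = (x2 - x1)[keep], h = (y2 - y1)[keep])
}

#' Write YOLO labels
#'
#' @param ann Annotation data frame (`class`, `cx`, `cy`, `w`, `h`).
#' @param path Output path.
#' @export
write_yolo_labels <- function(ann, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", ann$class, ann$cx, ann$cy,
                   ann$w, ann$h)
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic train/val/test split
#'
#' Shuffles by seed, takes `floor(0.8 n)` for training and splits the
#' remainder as evenly as possible, validation receiving the extra item when
#' the remainder is odd (so n = 2569 gives 2055/257/257).
#'
#' @param items Vector or list of items (e.g. image paths).
#' @param ratios Positive split weights; only 8:1:1 semantics are defined.
#' @param seed Shuffle seed.
#' @return List with `train`, `val`, `test` (disjoint, covering all items).
#' @export
split_dataset <- function(items, ratios = c(8, 1, 1), seed = 0L) {
  n <- length(items)
  if (n < 3) stop("split error: need at least 3 items")
  if (any(ratios <= 0)) stop("split error: ratios must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(n * ratios[1] / sum(ratios))
  rem <- n - n_train
  n_val <- ceiling(rem / 2)
  list(train = items[ord[seq_len(n_train)]],
       val = items[ord[n_train + seq_len(n_val)]],
       test = items[ord[(n_train + n_val + 1):n]])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read / write an image as an `[0, 1]` array
#'
#' @param path PNG file path.
#' @return `read_image` returns an `H x W x 3` array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @param img `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# bilinear resize of an H x W x C image to h2 x w2
resize_image <- function(img, h2, w2) {
  d <- dim(img)
  sy <- d[1] / h2; sx <- d[2] / w2
  yy <- pmin(pmax((seq_len(h2) - 0.5) * sy - 0.5, 0), d[1] - 1)
  xx <- pmin(pmax((seq_len(w2) - 0.5) * sx - 0.5, 0), d[2] - 1)
  ys <- matrix(rep(yy, times = w2), ncol = 1)
  xs <- matrix(rep(xx, each = h2), ncol = 1)
  x4 <- array(img, dim = c(d[1], d[2], d[3], 1))
  out <- cpp_bilinear_gather(x4, d[1], d[2], d[3], 1L, ys, xs)
  array(out, dim = c(h2, w2, d[3]))
}

#' Letterbox an image to a square canvas
#'
#' Aspect-preserving resize followed by symmetric gray padding (value
#' 114/255). The returned transform maps normalized source boxes to
#' normalized canvas boxes exactly (and back).
#'
#' @param img `H x W x 3` array.
#' @param target Canvas side (640 for the full-scale input standard).
#' @return List `image` (target x target x 3) and `transform`
#'   (`scale`, `pad_x`, `pad_y`, `src_h`, `src_w`, all in pixels).
#' @export
letterbox <- function(img, target = 640L) {
  d <- dim(img)
  sc <- min(target / d[1], target / d[2])
  nh <- round(d[1] * sc); nw <- round(d[2] * sc)
  resized <- if (nh == d[1] && nw == d[2]) img else resize_image(img, nh, nw)
  canvas <- array(114 / 255, dim = c(target, target, 3))
  py <- (target - nh) %/% 2
  px <- (target - nw) %/% 2
  canvas[py + seq_len(nh), px + seq_len(nw), ] <- resized
  list(image = canvas,
       transform = list(scale = sc, pad_x = px, pad_y = py,
                        src_h = d[1], src_w = d[2], target = target))
}

#' Map normalized boxes through (or back through) a letterbox transform
#'
#' @param ann Annotations normalized to the source image.
#' @param tr A transform from [letterbox()].
#' @param inverse Map canvas-normalized boxes back to the source frame.
#' @return Annotations normalized to the other frame.
#' @export
apply_letterbox <- function(ann, tr, inverse = FALSE) {
  t <- tr$target
  if (!inverse) {
    data.frame(class = ann$class,
               cx = (ann$cx * tr$src_w * tr$scale + tr$pad_x) / t,
               cy = (ann$cy * tr$src_h * tr$scale + tr$pad_y) / t,
               w = ann$w * tr$src_w * tr$scale / t,
               h = ann$h * tr$src_h * tr$scale / t)
  } else {
    data.frame(class = ann$class,
               cx = (ann$cx * t - tr$pad_x) / (tr$src_w * tr$scale),
               cy = (ann$cy * t - tr$pad_y) / (tr$src_h * tr$scale),
               w = ann$w * t / (tr$src_w * tr$scale),
               h = ann$h * t / (tr$src_h * tr$scale))
  }
}

#' Mosaic augmentation
#'
#' Standard 2x2 mosaic: four samples letterboxed to the target size are laid
#' out on a double-size canvas around a random center, followed by random
#' horizontal flip (p = 0.5), translation (fraction 0.1) and scale jitter
#' (fraction 0.5), then center-cropped back to the target. Labels are
#' remapped and clipped. When `enabled = FALSE` (the mosaic-off phase of the
#' final training epochs) the first sample is returned letterboxed with its
#' labels.
#'
#' @param samples List of 4 `list(image =, ann =)` pairs (normalized
#'   annotations).
#' @param seed Seed making the layout reproducible.
#' @param enabled Mosaic on/off switch.
#' @param target Output canvas side.
#' @param flip_p,translate,scale_jitter Augmentation strengths.
#' @return `list(image =, ann =)` with annotations normalized to the output.
#' @export
mosaic_augment <- function(samples, seed, enabled = TRUE, target = 640L,
                           flip_p = 0.5, translate = 0.1, scale_jitter = 0.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!enabled) {
    lb <- letterbox(samples[[1]]$image, target)
    return(list(image = lb$image,
                ann = clip_annotations(apply_letterbox(samples[[1]]$ann, lb$transform))))
  }
  stopifnot(length(samples) >= 4)
  big <- array(114 / 255, dim = c(2 * target, 2 * target, 3))
  cx <- round(runif(1, 0.5, 1.5) * target)
  cy <- round(runif(1, 0.5, 1.5) * target)
  anns <- list()
  quads <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (q in 1:4) {
    lb <- letterbox(samples[[q]]$image, target)
    a <- apply_letterbox(samples[[q]]$ann, lb$transform)
    qy <- if (quads[[q]][1] == 1) cy - target else cy
    qx <- if (quads[[q]][2] == 1) cx - target else cx
    ys <- max(qy + 1, 1):min(qy + target, 2 * target)
    xs <- max(qx + 1, 1):min(qx + target, 2 * target)
    big[ys, xs, ] <- lb$image[ys - qy, xs - qx, , drop = FALSE]
    if (nrow(a)) {
      a$cx <- (a$cx * target + qx) / (2 * target)
      a$cy <- (a$cy * target + qy) / (2 * target)
      a$w <- a$w / 2; a$h <- a$h / 2
      anns[[length(anns) + 1]] <- a
    }
  }
  ann <- if (length(anns)) do.call(rbind, anns) else
    data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0))
  # random affine: scale + translate around the canvas center, then crop
  sc <- runif(1, 1 - scale_jitter, 1 + scale_jitter)
  tx <- runif(1, -translate, translate) * 2 * target
  ty <- runif(1, -translate, translate) * 2 * target
  # sample the affine-transformed big canvas on the target grid
  ctr <- target                       # center of the big canvas
  yy <- ((seq_len(target) - 0.5) - target / 2) / sc + ctr + ty - 0.5
  xx <- ((seq_len(target) - 0.5) - target / 2) / sc + ctr + tx - 0.5
  ys <- matrix(rep(pmin(pmax(yy, 0), 2 * target - 1), times = target), ncol = 1)
  xs <- matrix(rep(pmin(pmax(xx, 0), 2 * target - 1), each = target), ncol = 1)
  out <- cpp_bilinear_gather(array(big, dim = c(dim(big), 1)),
                             2L * target, 2L * target, 3L, 1L, ys, xs)
  img <- array(out, dim = c(target, target, 3))
  if (nrow(ann)) {
    # same affine on the normalized coordinates
    ann$cx <- ((ann$cx * 2 * target - ctr - tx) * sc + target / 2) / target
    ann$cy <- ((ann$cy * 2 * target - ctr - ty) * sc + target / 2) / target
    ann$w <- ann$w * 2 * sc
    ann$h <- ann$h * 2 * sc
  }
  if (runif(1) < flip_p) {
    img <- img[, rev(seq_len(target)), , drop = FALSE]
    if (nrow(ann)) ann$cx <- 1 - ann$cx
  }
  list(image = img, ann = clip_annotations(ann))
}

#' Read a dataset index from a data.yaml layout
#'
#' Expects the YOLO layout: `images/` and `labels/` directories beside a
#' `data.yaml` holding `names:` (class list) and `nc:`.
#'
#' @param dir Dataset directory.
#' @return List: `items` (data frame of image/label paths), `class_names`,
#'   `nc`.
#' @export
read_dataset_index <- function(dir) {
  yml <- yaml::read_yaml(file.path(dir, "data.yaml"))
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE,
                          pattern = "\\.(png|jpg|jpeg)$"))
  labs <- file.path(dir, "labels",
                    paste0(tools::file_path_sans_ext(basename(imgs)), ".txt"))
  list(items = data.frame(image = imgs, label = labs,
                          stringsAsFactors = FALSE),
       class_names = unlist(yml$names), nc = yml$nc)
}
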