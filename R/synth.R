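# Deterministic synthetic leaf/lesion detection scenes.
#
# The generator emulates the traits that make field imagery of diseased
# plants hard: multiple objects per scene, elongated and twisted lesion
# shapes, cluttered textured backgrounds, global lighting variation, and
# partial occlusion by foreground strips. It makes no attempt at
# photorealism or biological accuracy; its purpose is to exercise every
# stage of the detection stack (including the curved structures the snake
# convolution targets) without any external download.
#
# Class palette (6): three lesion types drawn on a host leaf -- 0 a long
# curved brown streak, 1 a dark blotch cluster, 2 a yellow ring spot -- and
# three whole-leaf types annotated as objects -- 3 a broad green leaf, 4 a
# narrow blue-green leaf, 5 a lobed yellow-green leaf. Colors and shapes are
# deliberately separable so a small detector trained briefly on a CPU can
# learn them.

.synth_default_params <- function(size = 640L) {
  list(size = as.integer(size), n_classes = 6L, objects = c(1L, 4L),
       class_mix = rep(1 / 6, 6), occlusion_p = 0.3, lighting = c(0.75, 1.25))
}

#' Default synthetic scene configuration
#'
#' @param profile `"full"` (640 px canvas, the standard input size) or
#'   `"desk"` (256 px, for fast CPU training).
#' @return Parameter list for [generate_leaf_scene()].
#' @export
synth_profile <- function(profile = c("full", "desk")) {
  profile <- match.arg(profile)
  .synth_default_params(if (profile == "full") 640L else 256L)
}

# Painters draw onto cv$img, where cv is an environment holding the canvas
# (avoids copying the full image on every stamp). Each returns the painted
# bounding box, or NULL when nothing landed on the canvas.

.paint_disk <- function(cv, cy, cx, r, col) {
  S <- dim(cv$img)[1]
  ys <- max(1, floor(cy - r)):min(S, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(S, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(NULL)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  mask <- dy^2 + dx^2 <= r^2
  if (!any(mask)) return(NULL)
  for (ch in 1:3) {
    sl <- cv$img[ys, xs, ch]
    sl[mask] <- col[ch]
    cv$img[ys, xs, ch] <- sl
  }
  list(ys = range(ys[rowSums(mask) > 0]), xs = range(xs[colSums(mask) > 0]))
}

# smooth low-frequency noise field via coarse grid + bilinear upsampling
.noise_field <- function(S, cells = 8) {
  g <- matrix(runif(cells^2), cells, cells)
  resize_image(array(g, dim = c(cells, cells, 1)), S, S)[, , 1]
}

.textured_background <- function(cv, S) {
  base <- c(runif(1, 0.25, 0.5), runif(1, 0.2, 0.4), runif(1, 0.1, 0.3))
  f1 <- .noise_field(S, 6); f2 <- .noise_field(S, 24)
  cv$img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3)
    cv$img[, , ch] <- pmin(pmax(base[ch] * (0.6 + 0.6 * f1) +
                                  0.12 * (f2 - 0.5), 0), 1)
  # clutter: a few random dull strips
  for (i in seq_len(sample(2:5, 1))) {
    y0 <- runif(1, 1, S); x0 <- runif(1, 1, S)
    ang <- runif(1, 0, pi); len <- runif(1, 0.3, 0.9) * S
    col <- runif(3, 0.1, 0.45)
    tt <- seq(0, 1, length.out = ceiling(len))
    yy <- y0 + tt * len * sin(ang); xx <- x0 + tt * len * cos(ang)
    ok <- yy >= 2 & yy <= S - 1 & xx >= 2 & xx <= S - 1
    for (j in which(ok)) .paint_disk(cv, yy[j], xx[j], runif(1, 1, 2.5), col)
  }
  invisible(cv)
}

# radial leaf blob: ellipse with angular wobble; returns bbox of painting
.paint_leaf <- function(cv, cy, cx, ry, rx, col, wobble = 0.25, lobes = 2) {
  S <- dim(cv$img)[1]
  ys <- max(1, floor(cy - ry * 1.4)):min(S, ceiling(cy + ry * 1.4))
  xs <- max(1, floor(cx - rx * 1.4)):min(S, ceiling(cx + rx * 1.4))
  dy <- outer((ys - cy) / ry, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), (xs - cx) / rx)
  th <- atan2(dy, dx)
  phase <- runif(1, 0, 2 * pi)
  rad <- 1 + wobble * sin(lobes * th + phase)
  mask <- sqrt(dy^2 + dx^2) <= rad
  if (!any(mask)) return(NULL)
  shade <- 1 - 0.25 * sqrt(pmin(dy^2 + dx^2, 1))
  for (ch in 1:3) {
    sl <- cv$img[ys, xs, ch]
    sl[mask] <- (col[ch] * shade)[mask]
    cv$img[ys, xs, ch] <- sl
  }
  list(y1 = min(ys[rowSums(mask) > 0]), y2 = max(ys[rowSums(mask) > 0]),
       x1 = min(xs[colSums(mask) > 0]), x2 = max(xs[colSums(mask) > 0]))
}

# thick S-shaped Bezier streak; returns bbox and the arc/chord ratio
.paint_streak <- function(cv, cy, cx, len, thick, col) {
  ang <- runif(1, 0, 2 * pi)
  ux <- cos(ang); uy <- sin(ang)
  px <- -uy; py <- ux
  amp <- runif(1, 0.55, 0.85) * len
  p0 <- c(cy - uy * len / 2, cx - ux * len / 2)
  p3 <- c(cy + uy * len / 2, cx + ux * len / 2)
  p1 <- c(cy - uy * len / 6 + py * amp, cx - ux * len / 6 + px * amp)
  p2 <- c(cy + uy * len / 6 - py * amp, cx + ux * len / 6 - px * amp)
  tt <- seq(0, 1, length.out = max(24, ceiling(len)))
  b <- function(i) (1 - tt)^3 * p0[i] + 3 * (1 - tt)^2 * tt * p1[i] +
    3 * (1 - tt) * tt^2 * p2[i] + tt^3 * p3[i]
  yy <- b(1); xx <- b(2)
  arc <- sum(sqrt(diff(yy)^2 + diff(xx)^2))
  chord <- sqrt((yy[length(yy)] - yy[1])^2 + (xx[length(xx)] - xx[1])^2)
  S <- dim(cv$img)[1]
  y1 <- S; y2 <- 1; x1 <- S; x2 <- 1
  for (j in seq_along(tt)) {
    if (yy[j] < 2 || yy[j] > S - 1 || xx[j] < 2 || xx[j] > S - 1) next
    r <- thick * (0.7 + 0.3 * sin(pi * tt[j]))
    bb <- .paint_disk(cv, yy[j], xx[j], r, col)
    if (!is.null(bb)) {
      y1 <- min(y1, bb$ys[1]); y2 <- max(y2, bb$ys[2])
      x1 <- min(x1, bb$xs[1]); x2 <- max(x2, bb$xs[2])
    }
  }
  if (y2 < y1) return(NULL)
  list(y1 = y1, y2 = y2, x1 = x1, x2 = x2, arc_chord = arc / max(chord, 1e-9))
}

.paint_blotch <- function(cv, cy, cx, r, col) {
  n <- sample(3:6, 1)
  y1 <- Inf; y2 <- -Inf; x1 <- Inf; x2 <- -Inf
  for (i in seq_len(n)) {
    oy <- cy + runif(1, -r, r) * 0.8
    ox <- cx + runif(1, -r, r) * 0.8
    rr <- runif(1, 0.3, 0.55) * r
    bb <- .paint_disk(cv, oy, ox, rr, col * runif(1, 0.8, 1.2))
    if (!is.null(bb)) {
      y1 <- min(y1, bb$ys[1]); y2 <- max(y2, bb$ys[2])
      x1 <- min(x1, bb$xs[1]); x2 <- max(x2, bb$xs[2])
    }
  }
  if (!is.finite(y1)) return(NULL)
  list(y1 = y1, y2 = y2, x1 = x1, x2 = x2)
}

.paint_ring <- function(cv, cy, cx, r, col) {
  S <- dim(cv$img)[1]
  ys <- max(1, floor(cy - r)):min(S, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(S, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dist <- sqrt(dy^2 + dx^2)
  mask <- dist <= r & dist >= 0.55 * r
  core <- dist < 0.55 * r
  if (!any(mask | core)) return(NULL)
  for (ch in 1:3) {
    sl <- cv$img[ys, xs, ch]
    sl[mask] <- col[ch]
    sl[core] <- c(0.35, 0.2, 0.1)[ch]
    cv$img[ys, xs, ch] <- sl
  }
  list(y1 = min(ys[rowSums(mask | core) > 0]), y2 = max(ys[rowSums(mask | core) > 0]),
       x1 = min(xs[colSums(mask | core) > 0]), x2 = max(xs[colSums(mask | core) > 0]))
}

#' Generate one synthetic leaf/lesion scene
#'
#' Deterministic in `seed`: the same seed reproduces the scene bit-exactly.
#' Every annotation is the tight bound of its rendered object before any
#' occluding strip is drawn.
#'
#' @param seed Scene seed.
#' @param params Configuration from [synth_profile()]; fields `size`,
#'   `n_classes`, `objects` (count range), `class_mix`, `occlusion_p`,
#'   `lighting` (gain range).
#' @return List `image` (S x S x 3), `ann` (normalized YOLO annotations) and
#'   `provenance` (seed and per-object generation parameters).
#' @export
generate_leaf_scene <- function(seed, params = synth_profile("full")) {
  S <- params$size
  if (S < 32) stop("generation error: canvas too small")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cv <- new.env(parent = emptyenv())
  .textured_background(cv, S)
  n_obj <- if (params$objects[1] >= params$objects[2]) params$objects[1] else
    sample(params$objects[1]:params$objects[2], 1)
  ann <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                    w = numeric(0), h = numeric(0))
  prov <- list(seed = seed, objects = list())
  leaf_cols <- list(c(0.20, 0.55, 0.18), c(0.15, 0.45, 0.40), c(0.55, 0.65, 0.15))
  lesion_cols <- list(c(0.45, 0.25, 0.08), c(0.12, 0.08, 0.05), c(0.92, 0.85, 0.15))
  for (ob in seq_len(n_obj)) {
    cls <- sample(params$n_classes, 1, prob = params$class_mix) - 1L
    cy <- runif(1, 0.2, 0.8) * S
    cx <- runif(1, 0.2, 0.8) * S
    rec <- list(class = cls, cy = cy, cx = cx)
    if (cls >= 3) {
      # healthy leaf object
      base_r <- runif(1, 0.10, 0.20) * S
      asp <- switch(as.character(cls), "3" = runif(1, 0.8, 1.2),
                    "4" = runif(1, 2.2, 3.2), "5" = runif(1, 0.9, 1.4))
      lobes <- if (cls == 5L) 5 else 2
      wob <- if (cls == 5L) 0.35 else 0.2
      bb <- .paint_leaf(cv, cy, cx, base_r, base_r * asp,
                        leaf_cols[[cls - 2L]] * runif(1, 0.85, 1.15), wob, lobes)
      rec$size <- base_r
    } else {
      # host leaf (context, unannotated), then the lesion on it
      host_r <- runif(1, 0.14, 0.22) * S
      .paint_leaf(cv, cy, cx, host_r, host_r * runif(1, 1.0, 1.6),
                  c(0.2, 0.5, 0.17) * runif(1, 0.8, 1.2), 0.2, 2)
      col <- lesion_cols[[cls + 1L]]
      bb <- switch(as.character(cls),
        "0" = .paint_streak(cv, cy, cx, runif(1, 0.5, 0.8) * host_r * 2,
                            max(2, 0.012 * S), col),
        "1" = .paint_blotch(cv, cy, cx, runif(1, 0.35, 0.6) * host_r, col),
        "2" = .paint_ring(cv, cy, cx, runif(1, 0.3, 0.5) * host_r, col))
      rec$size <- host_r
      if (!is.null(bb$arc_chord)) rec$arc_chord <- bb$arc_chord
    }
    if (is.null(bb)) next
    w <- (bb$x2 - bb$x1 + 1) / S
    h <- (bb$y2 - bb$y1 + 1) / S
    if (w * S < 4 || h * S < 4) next
    ann <- rbind(ann, data.frame(class = cls,
                                 cx = (bb$x1 + bb$x2) / 2 / S,
                                 cy = (bb$y1 + bb$y2) / 2 / S,
                                 w = w, h = h))
    prov$objects[[length(prov$objects) + 1]] <- rec
  }
  # global illumination jitter
  gain <- runif(1, params$lighting[1], params$lighting[2])
  cast <- runif(3, 0.95, 1.05)
  for (ch in 1:3) cv$img[, , ch] <- pmin(cv$img[, , ch] * gain * cast[ch], 1)
  prov$lighting_gain <- gain
  # occasional occluding foreground strip (after the boxes are recorded)
  if (runif(1) < params$occlusion_p) {
    y0 <- runif(1, 0.2, 0.8) * S
    ang <- runif(1, -0.3, 0.3)
    thick <- runif(1, 0.02, 0.05) * S
    col <- runif(3, 0.2, 0.5)
    for (x in seq_len(S)) {
      yc <- y0 + (x - S / 2) * tan(ang)
      ys <- max(1, floor(yc - thick)):min(S, ceiling(yc + thick))
      if (ys[1] <= ys[length(ys)])
        for (ch in 1:3) cv$img[ys, x, ch] <- col[ch]
    }
    prov$occluded <- TRUE
  }
  ann <- clip_annotations(ann)
  list(image = cv$img, ann = ann, provenance = prov)
}

#' Generate a synthetic dataset on disk
#'
#' Writes the YOLO layout (`images/`, `labels/`, `data.yaml`) and returns
#' the index. Scene `i` uses seed `seed + i`, so the whole directory is a
#' pure function of `seed`.
#'
#' @param n Number of scenes.
#' @param out Output directory (created if needed).
#' @param seed Base seed.
#' @param params Scene configuration from [synth_profile()].
#' @return The [read_dataset_index()] of the written dataset.
#' @export
generate_dataset <- function(n, out, seed = 0L, params = synth_profile("full")) {
  dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "labels"), recursive = TRUE, showWarnings = FALSE)
  names6 <- c("streak_lesion", "blotch_lesion", "ring_spot",
              "healthy_broad", "healthy_narrow", "healthy_lobed")
  for (i in seq_len(n)) {
    sc <- generate_leaf_scene(seed + i, params)
    stem <- sprintf("scene_%05d", i)
    write_image(sc$image, file.path(out, "images", paste0(stem, ".png")))
    write_yolo_labels(sc$ann, file.path(out, "labels", paste0(stem, ".txt")))
  }
  yaml::write_yaml(list(nc = params$n_classes,
                        names = as.list(names6[seq_len(params$n_classes)])),
                   file.path(out, "data.yaml"))
  read_dataset_index(out)
}

#' Oracle detections from ground-truth labels
#'
#' Turns a ground-truth table into perfect unit-confidence detections; a
#' detector with oracle access to the generation provenance must reach
#' mAP@0.5 = 1 on consistent labels.
#'
#' @param ground_truths Data frame with `image`, `class`, `x1`, `y1`, `x2`,
#'   `y2`.
#' @return Detection data frame with `score = 1`.
#' @export
oracle_detector <- function(ground_truths) {
  out <- ground_truths
  out$score <- 1
  out
}
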