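# Synthetic berry-scene generator: dense red umbels on green canopy with
# brown soil, stems, leaf occlusion, scale and illumination variation, plus
# the training-set augmentations and YOLO dataset layout helpers.

#' Scene specification for the synthetic berry generator.
#'
#' Geometry is given at a 640-pixel reference resolution and scaled with
#' `img_size`. Every scene is a pure function of the spec (including its
#' seed). Emitted labels obey the annotation rule that fruits with less
#' than 10% visible area carry no box.
#'
#' @param img_size square image side in pixels
#' @param n_umbels number of berry umbels (the labelled objects)
#' @param berries_range min/max berries per umbel
#' @param berry_radius min/max berry radius in pixels at 640
#' @param umbel_scale min/max umbel scale factor (scale variation)
#' @param occlusion mean fraction of each umbel hidden by foliage, in `[0, 1)`
#' @param illum min/max global illumination gain
#' @param seed integer seed
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(img_size = 640L, n_umbels = 6L,
                       berries_range = c(15L, 40L), berry_radius = c(2, 6),
                       umbel_scale = c(0.6, 1.4), occlusion = 0.3,
                       illum = c(0.7, 1.3), seed = 0L) {
  if (occlusion < 0 || occlusion >= 1) stop("scene_spec: occlusion must be in [0, 1)")
  structure(list(img_size = as.integer(img_size), n_umbels = as.integer(n_umbels),
                 berries_range = berries_range, berry_radius = berry_radius,
                 umbel_scale = umbel_scale, occlusion = occlusion,
                 illum = illum, seed = as.integer(seed)),
            class = "scene_spec")
}

# paint a filled ellipse into channel matrices; returns affected logical mask
fill_ellipse <- function(mask, cx, cy, rx, ry, H, W) {
  x0 <- max(1L, floor(cx - rx)); x1 <- min(W, ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(H, ceiling(cy + ry))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- ((xs - cx) / rx)^2; dy2 <- ((ys - cy) / ry)^2
  sub <- outer(dy2, dx2, `+`) <= 1
  sub[is.na(sub)] <- FALSE          # degenerate radii
  mask[ys, xs] <- mask[ys, xs] | sub
  mask
}

smooth_noise <- function(H, W, cells = 8L, amp = 1) {
  coarse <- matrix(stats::runif(cells * cells), cells, cells)
  yi <- pmin(cells, pmax(1, ceiling(seq_len(H) / H * cells)))
  xi <- pmin(cells, pmax(1, ceiling(seq_len(W) / W * cells)))
  amp * coarse[yi, xi]
}

#' Render one synthetic berry scene with YOLO labels.
#'
#' Draws canopy and soil background, stems, red berry umbels and green leaf
#' occluders, then applies a global illumination gain. One box is emitted
#' per umbel whose visible area is at least 10% of its unoccluded area.
#'
#' @param spec a [scene_spec()]
#' @return a `labeled_image`: list with `image` (array `H x W x 3` in `[0,1]`)
#'   and `labels` (data.frame `class, cx, cy, w, h`, normalised to `[0, 1]`)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  S <- spec$img_size; H <- S; W <- S
  sc <- S / 640
  # canopy background with soil patches
  g <- 0.28 + 0.25 * smooth_noise(H, W, 10)
  r <- 0.10 + 0.10 * smooth_noise(H, W, 12)
  b <- 0.06 + 0.08 * smooth_noise(H, W, 9)
  soil <- smooth_noise(H, W, 5) > 0.72
  r[soil] <- 0.35 + 0.1 * r[soil]; g[soil] <- 0.25 + 0.1 * g[soil]; b[soil] <- 0.12
  umbels <- list()
  margin <- 0.08 * S
  for (k in seq_len(spec$n_umbels)) {
    scale <- stats::runif(1, spec$umbel_scale[1], spec$umbel_scale[2])
    cx <- stats::runif(1, margin, W - margin)
    cy <- stats::runif(1, margin, H - margin)
    nb <- sample(spec$berries_range[1]:spec$berries_range[2], 1)
    rad <- stats::runif(nb, spec$berry_radius[1], spec$berry_radius[2]) * sc * scale
    clus <- (1.25 + 0.065 * nb) * mean(rad)         # compact cluster extent
    ang <- stats::runif(nb, 0, 2 * pi)
    rr <- stats::runif(nb)^0.85 * pmax(clus - rad, 0.3 * clus)  # berries stay on the body
    bx <- cx + rr * cos(ang); by <- cy + rr * sin(ang) * 0.8
    # umbels are densely packed: a filled body with berries texturing the rim
    mask <- fill_ellipse(matrix(FALSE, H, W), cx, cy, clus, clus * 0.85, H, W)
    for (i in seq_len(nb))
      mask <- fill_ellipse(mask, bx[i], by[i], rad[i], rad[i] * stats::runif(1, 0.75, 1), H, W)
    if (!any(mask)) next
    umbels[[length(umbels) + 1L]] <- list(
      mask = mask, shade = 0.75 + 0.25 * stats::runif(1),
      stem = c(round(cx), min(H, round(cy + clus)),
               min(H, round(cy + clus + 30 * sc * scale))))
  }
  # stems first (behind the fruit), then the umbels over them
  for (u in umbels) {
    sx <- u$stem[1]; sy0 <- u$stem[2]; sy1 <- u$stem[3]
    if (sy1 > sy0 && sx >= 1 && sx <= W) {
      cols <- max(1, sx - 1):min(W, sx + 1)
      r[sy0:sy1, cols] <- 0.25; g[sy0:sy1, cols] <- 0.18; b[sy0:sy1, cols] <- 0.08
    }
  }
  for (u in umbels) {
    mask <- u$mask
    r[mask] <- (0.75 + 0.2 * stats::runif(sum(mask))) * u$shade
    g[mask] <- 0.08 + 0.08 * stats::runif(sum(mask))
    b[mask] <- 0.05 + 0.05 * stats::runif(sum(mask))
  }
  # leaf occluders drawn after the fruit: each leaf sweeps in from one side
  # and covers the fraction of the umbel's pixels set by the per-umbel draw
  occ_masks <- matrix(FALSE, H, W)
  for (u in umbels) {
    f <- min(0.99, max(0, stats::rnorm(1, spec$occlusion, 0.12 * spec$occlusion + 0.02)))
    if (spec$occlusion <= 0) f <- 0
    if (f <= 0.02) next
    idx <- which(u$mask, arr.ind = TRUE)
    xs <- idx[, 2]
    tx <- stats::quantile(xs, f, names = FALSE)       # cover pixels left of tx
    uy <- range(idx[, 1]); ux <- range(xs)
    covered <- u$mask & (col(u$mask) <= tx)
    # dress the straight sweep edge as a leaf-shaped ellipse around it
    leaf <- fill_ellipse(matrix(FALSE, H, W),
                         (ux[1] + tx) / 2, mean(uy),
                         max((tx - ux[1]) / 2, 1.5),
                         max((uy[2] - uy[1]) / 2 * 1.3, 1.5), H, W)
    occ_masks <- occ_masks | covered | leaf
  }
  if (any(occ_masks)) {
    r[occ_masks] <- 0.10 + 0.06 * stats::runif(sum(occ_masks))
    g[occ_masks] <- 0.35 + 0.15 * stats::runif(sum(occ_masks))
    b[occ_masks] <- 0.08
  }
  labels <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                       w = numeric(0), h = numeric(0))
  for (u in umbels) {
    vis <- u$mask & !occ_masks
    frac <- sum(vis) / sum(u$mask)
    if (frac < 0.1) next
    idx <- which(vis, arr.ind = TRUE)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1]); x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    # discernibility rule: fragmented slivers whose visible pixels fill less
    # than half of their own box are not annotatable objects
    if (sum(vis) < 0.5 * (y1 - y0 + 1) * (x1 - x0 + 1)) next
    labels <- rbind(labels, data.frame(
      class = 0L, cx = (x0 + x1) / 2 / W, cy = (y0 + y1) / 2 / H,
      w = (x1 - x0 + 1) / W, h = (y1 - y0 + 1) / H))
  }
  if (!nrow(labels)) warning("generate_scene: spec produced no visible fruit labels")
  gain <- stats::runif(1, spec$illum[1], spec$illum[2])
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- pmin(1, pmax(0, r * gain))
  img[, , 2] <- pmin(1, pmax(0, g * gain))
  img[, , 3] <- pmin(1, pmax(0, b * gain))
  structure(list(image = img, labels = labels), class = "labeled_image")
}

#' Generate a deterministic set of scenes.
#' @param n number of scenes
#' @param spec base [scene_spec()]; scene `i` uses seed `spec$seed + i`
#' @return list of `labeled_image`
#' @export
generate_scenes <- function(n, spec = scene_spec()) {
  lapply(seq_len(n), function(i) {
    s <- spec; s$seed <- spec$seed + i
    generate_scene(s)
  })
}

# ---- augmentations ---------------------------------------------------------

labels_to_px <- function(labels, W, H) {
  cbind(x0 = (labels$cx - labels$w / 2) * W, y0 = (labels$cy - labels$h / 2) * H,
        x1 = (labels$cx + labels$w / 2) * W, y1 = (labels$cy + labels$h / 2) * H)
}

px_to_labels <- function(px, W, H, class = 0L) {
  data.frame(class = class,
             cx = (px[, 1] + px[, 3]) / 2 / W, cy = (px[, 2] + px[, 4]) / 2 / H,
             w = (px[, 3] - px[, 1]) / W, h = (px[, 4] - px[, 2]) / H)
}

#' Apply one training augmentation to a labelled scene.
#'
#' Operations: `rotate` (random small rotation), `translate`, `brightness`
#' (multiplicative gain in linear intensity), `occlude` (pasted foliage
#' patches), `concat4` (2x2 mosaic of four scenes rescaled to the original
#' size). Labels are transformed consistently, clipped to the frame, and
#' dropped when the remaining area falls below 10% of the original box.
#'
#' @param item a `labeled_image`
#' @param op one of `"rotate"`, `"translate"`, `"brightness"`, `"occlude"`,
#'   `"concat4"`
#' @param seed integer seed for the operation's randomness
#' @param others list of exactly three further `labeled_image`s for `concat4`
#' @param params optional explicit parameters: `angle` (degrees), `dx`, `dy`
#'   (pixels), `gain`
#' @return a transformed `labeled_image`
#' @export
augment_scene <- function(item, op, seed = 0L, others = NULL, params = list()) {
  op <- match.arg(op, c("rotate", "translate", "brightness", "occlude", "concat4"))
  set.seed(seed)
  img <- item$image; H <- dim(img)[1]; W <- dim(img)[2]
  labels <- item$labels
  drop_small <- function(px_new, px_old) {
    a_new <- pmax(0, px_new[, 3] - px_new[, 1]) * pmax(0, px_new[, 4] - px_new[, 2])
    a_old <- pmax(0, px_old[, 3] - px_old[, 1]) * pmax(0, px_old[, 4] - px_old[, 2])
    a_new >= 0.1 * a_old & a_new > 0
  }
  clipf <- function(px) cbind(pmax(px[, 1], 0), pmax(px[, 2], 0),
                              pmin(px[, 3], W), pmin(px[, 4], H))
  if (op == "rotate") {
    ang <- (params$angle %||% stats::runif(1, -15, 15)) * pi / 180
    if (abs(ang) < 1e-12) return(item)
    cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
    co <- cos(ang); si <- sin(ang)
    # inverse map for nearest-neighbour sampling
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    xr <- co * (xs - cx0) + si * (ys - cy0) + cx0
    yr <- -si * (xs - cx0) + co * (ys - cy0) + cy0
    xi <- round(xr); yi <- round(yr)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    fill <- apply(img, 3, stats::median)
    out <- array(0, dim(img))
    for (ch in 1:3) {
      m <- matrix(fill[ch], H, W)
      src <- img[, , ch]
      m[ok] <- src[cbind(yi[ok], xi[ok])]
      out[, , ch] <- m
    }
    if (nrow(labels)) {
      px <- labels_to_px(labels, W, H)
      newpx <- t(apply(px, 1, function(bb) {
        cs <- rbind(c(bb[1], bb[2]), c(bb[3], bb[2]), c(bb[1], bb[4]), c(bb[3], bb[4]))
        xr2 <- co * (cs[, 1] - cx0) - si * (cs[, 2] - cy0) + cx0
        yr2 <- si * (cs[, 1] - cx0) + co * (cs[, 2] - cy0) + cy0
        c(min(xr2), min(yr2), max(xr2), max(yr2))
      }))
      clipped <- clipf(newpx)
      keep <- drop_small(clipped, newpx)
      labels <- px_to_labels(clipped[keep, , drop = FALSE], W, H)
    }
    return(structure(list(image = out, labels = labels), class = "labeled_image"))
  }
  if (op == "translate") {
    dx <- round(params$dx %||% (stats::runif(1, -0.12, 0.12) * W))
    dy <- round(params$dy %||% (stats::runif(1, -0.12, 0.12) * H))
    out <- array(apply(img, 3, stats::median)[rep(1:3, each = H * W)], dim(img))
    sx <- max(1, 1 - dx):min(W, W - dx); tx <- sx + dx
    sy <- max(1, 1 - dy):min(H, H - dy); ty <- sy + dy
    out[ty, tx, ] <- img[sy, sx, ]
    if (nrow(labels)) {
      px <- labels_to_px(labels, W, H)
      moved <- cbind(px[, 1] + dx, px[, 2] + dy, px[, 3] + dx, px[, 4] + dy)
      clipped <- clipf(moved)
      keep <- drop_small(clipped, moved)
      labels <- px_to_labels(clipped[keep, , drop = FALSE], W, H)
    }
    return(structure(list(image = out, labels = labels), class = "labeled_image"))
  }
  if (op == "brightness") {
    gain <- params$gain %||% stats::runif(1, 0.5, 1.5)
    out <- pmin(1, pmax(0, img * gain))
    return(structure(list(image = out, labels = labels), class = "labeled_image"))
  }
  if (op == "occlude") {
    out <- img
    if (nrow(labels)) {
      px <- labels_to_px(labels, W, H)
      covered <- numeric(nrow(labels))
      for (i in seq_len(nrow(labels))) {
        if (stats::runif(1) > 0.7) next
        bw <- px[i, 3] - px[i, 1]; bh <- px[i, 4] - px[i, 2]
        f <- stats::runif(1, 0.2, 0.6)
        ox0 <- max(1, round(px[i, 1])); ox1 <- min(W, round(px[i, 1] + f * bw))
        oy0 <- max(1, round(px[i, 2])); oy1 <- min(H, round(px[i, 4]))
        if (ox1 > ox0 && oy1 > oy0) {
          out[oy0:oy1, ox0:ox1, 1] <- 0.12
          out[oy0:oy1, ox0:ox1, 2] <- 0.4 + 0.1 * stats::runif(1)
          out[oy0:oy1, ox0:ox1, 3] <- 0.1
          covered[i] <- f
        }
      }
      labels <- labels[covered <= 0.9, , drop = FALSE]
    }
    return(structure(list(image = out, labels = labels), class = "labeled_image"))
  }
  # concat4: 2x2 mosaic, rescaled back to the original size
  if (length(others) != 3L) stop("augment_scene: concat4 needs exactly 3 further items")
  items <- c(list(item), others)
  half <- function(im) im[seq(1, dim(im)[1], by = 2), seq(1, dim(im)[2], by = 2), , drop = FALSE]
  out <- array(0, dim(img))
  h2 <- H %/% 2L; w2 <- W %/% 2L
  offs <- list(c(0, 0), c(0, w2), c(h2, 0), c(h2, w2))
  newlab <- list()
  for (k in 1:4) {
    hi <- half(items[[k]]$image)[seq_len(h2), seq_len(w2), , drop = FALSE]
    out[offs[[k]][1] + seq_len(h2), offs[[k]][2] + seq_len(w2), ] <- hi
    lb <- items[[k]]$labels
    if (nrow(lb)) {
      newlab[[k]] <- data.frame(class = lb$class,
                                cx = lb$cx / 2 + offs[[k]][2] / W,
                                cy = lb$cy / 2 + offs[[k]][1] / H,
                                w = lb$w / 2, h = lb$h / 2)
    }
  }
  labels <- do.call(rbind, newlab[!vapply(newlab, is.null, logical(1))])
  if (is.null(labels)) labels <- item$labels[0, ]
  structure(list(image = out, labels = labels), class = "labeled_image")
}

# ---- dataset split and YOLO layout ----------------------------------------

#' Randomly partition items into train/val/test with largest-remainder sizes.
#'
#' @param items a list of items or a single integer count
#' @param ratios positive weights, default `c(7, 2, 1)`
#' @param seed shuffle seed
#' @return list with `train`, `val`, `test` (items, or 1-based indices when
#'   `items` is a count)
#' @examples
#' lengths(split_dataset(1519L))  # 1063 / 304 / 152
#' @export
split_dataset <- function(items, ratios = c(7, 2, 1), seed = 0L) {
  n <- if (is.numeric(items) && length(items) == 1L) as.integer(items) else length(items)
  if (sum(ratios) <= 0) stop("split_dataset: ratios must sum to a positive number")
  if (n < length(ratios)) stop("split_dataset: fewer items than partitions")
  set.seed(seed)
  ord <- sample.int(n)
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  take <- function(k) if (sizes[k] > 0) ord[starts[k]:ends[k]] else integer(0)
  idx <- list(train = sort(take(1)), val = sort(take(2)), test = sort(take(3)))
  if (is.numeric(items) && length(items) == 1L) idx
  else lapply(idx, function(i) items[i])
}

#' Write a dataset in the standard YOLO layout.
#'
#' Creates `images/<split>/` and `labels/<split>/` plus a `dataset.yaml`
#' (`nc: 1`, `names: [RSZ]`). Images are PNG; labels are one
#' `class cx cy w h` line per object with 6 decimals; images without objects
#' get an empty label file (negative samples).
#'
#' @param splits named list (`train`, `val`, `test`) of `labeled_image` lists
#' @param root output directory (created if needed)
#' @return `root`, invisibly
#' @export
write_yolo_dataset <- function(splits, root) {
  for (sp in names(splits)) {
    dir.create(file.path(root, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "labels", sp), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(splits[[sp]])) {
      it <- splits[[sp]][[i]]
      stem <- sprintf("img_%04d", i)
      png::writePNG(it$image, file.path(root, "images", sp, paste0(stem, ".png")))
      lb <- it$labels
      lines <- if (nrow(lb))
        sprintf("%d %.6f %.6f %.6f %.6f", lb$class, lb$cx, lb$cy, lb$w, lb$h)
      else character(0)
      writeLines(lines, file.path(root, "labels", sp, paste0(stem, ".txt")))
    }
  }
  yaml::write_yaml(list(path = normalizePath(root), train = "images/train",
                        val = "images/val", test = "images/test",
                        nc = 1L, names = list("RSZ")),
                   file.path(root, "dataset.yaml"))
  invisible(root)
}

#' Read a dataset in YOLO layout.
#'
#' @param root dataset directory containing `dataset.yaml`
#' @param splits which splits to read
#' @return named list of `labeled_image` lists; orphan image/label stems are
#'   reported in the `integrity` attribute and trigger a warning
#' @export
read_yolo_dataset <- function(root, splits = c("train", "val", "test")) {
  out <- list(); orphans <- character(0)
  for (sp in splits) {
    idir <- file.path(root, "images", sp); ldir <- file.path(root, "labels", sp)
    if (!dir.exists(idir)) next
    imgs <- sort(list.files(idir, pattern = "\\.png$"))
    items <- list()
    for (f in imgs) {
      stem <- sub("\\.png$", "", f)
      lf <- file.path(ldir, paste0(stem, ".txt"))
      if (!file.exists(lf)) { orphans <- c(orphans, paste0(sp, "/", stem)); next }
      img <- png::readPNG(file.path(idir, f))
      lines <- readLines(lf)
      lines <- lines[nzchar(lines)]
      lb <- if (length(lines)) {
        m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
        data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5])
      } else data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                        w = numeric(0), h = numeric(0))
      items[[length(items) + 1L]] <- structure(list(image = img, labels = lb),
                                               class = "labeled_image")
    }
    lbs <- sort(list.files(ldir, pattern = "\\.txt$"))
    extra <- setdiff(sub("\\.txt$", "", lbs), sub("\\.png$", "", imgs))
    if (length(extra)) orphans <- c(orphans, paste0(sp, "/", extra))
    out[[sp]] <- items
  }
  if (length(orphans))
    warning("read_yolo_dataset: orphan stems: ", paste(orphans, collapse = ", "))
  attr(out, "integrity") <- orphans
  out
}
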