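# Scene generator determinism and geometry, augmentations, splitting,
# YOLO layout round-trips.

test_that("scene generation is a pure function of the spec", {
  sp <- scene_spec(img_size = 96L, n_umbels = 3L, seed = 7L)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a, b)
  sp2 <- sp; sp2$seed <- 8L
  expect_false(identical(generate_scene(sp2)$image, a$image))
})

test_that("labels respect the visibility rule and coordinate bounds", {
  sp <- scene_spec(img_size = 96L, n_umbels = 4L, occlusion = 0, seed = 3L)
  it <- generate_scene(sp)
  expect_identical(nrow(it$labels), 4L)   # no occlusion: every umbel labelled
  expect_true(all(it$labels$class == 0L))
  with(it$labels, {
    expect_true(all(cx >= 0 & cx <= 1 & cy >= 0 & cy <= 1))
    expect_true(all(w > 0 & h > 0 & w <= 1 & h <= 1))
  })
  # near-total occlusion suppresses all labels
  sp2 <- scene_spec(img_size = 96L, n_umbels = 3L, occlusion = 0.97, seed = 3L)
  expect_warning(it2 <- generate_scene(sp2), "no visible")
  expect_identical(nrow(it2$labels), 0L)
})

test_that("emitted boxes sit on red fruit pixels", {
  items <- tiny_scene_set(6, img = 128L, seed = 21L)
  frac_red <- function(it) {
    W <- dim(it$image)[2]; H <- dim(it$image)[1]
    px <- yologinseng:::labels_to_px(it$labels, W, H)
    vapply(seq_len(nrow(px)), function(i) {
      # pixels whose centres fall inside the box
      ys <- max(1, ceiling(px[i, 2])):min(H, floor(px[i, 4]))
      xs <- max(1, ceiling(px[i, 1])):min(W, floor(px[i, 3]))
      red <- it$image[ys, xs, 1] > it$image[ys, xs, 2] + 0.15
      mean(red)
    }, numeric(1))
  }
  fr <- unlist(lapply(items, frac_red))
  expect_gt(mean(fr > 0.5), 0.9)  # boxes are predominantly fruit-coloured
})

test_that("augmentations transform labels consistently", {
  it <- tiny_scene_set(1, img = 96L, seed = 11L)[[1]]
  # zero rotation is the identity
  expect_identical(augment_scene(it, "rotate", seed = 1, params = list(angle = 0)), it)
  # pure translation shifts every centre by dx/W
  tr <- augment_scene(it, "translate", seed = 1, params = list(dx = 10, dy = 0))
  common <- seq_len(min(nrow(tr$labels), nrow(it$labels)))
  if (length(common))
    expect_equal(tr$labels$cx[common], it$labels$cx[common] + 10 / 96, tolerance = 1e-9)
  # brightness changes pixels, never labels
  br <- augment_scene(it, "brightness", seed = 2, params = list(gain = 1.3))
  expect_identical(br$labels, it$labels)
  expect_equal(br$image, pmin(1, it$image * 1.3), tolerance = 1e-12)
  # rotation keeps labels inside the frame
  ro <- augment_scene(it, "rotate", seed = 3)
  if (nrow(ro$labels))
    expect_true(all(ro$labels$cx >= 0 & ro$labels$cx <= 1))
  # occlusion never invents labels
  oc <- augment_scene(it, "occlude", seed = 4)
  expect_lte(nrow(oc$labels), nrow(it$labels))
})

test_that("concat4 builds a mosaic conserving surviving labels", {
  items <- tiny_scene_set(4, img = 64L, seed = 31L)
  mo <- augment_scene(items[[1]], "concat4", seed = 5, others = items[2:4])
  expect_identical(dim(mo$image), dim(items[[1]]$image))
  expect_identical(nrow(mo$labels), sum(vapply(items, function(i) nrow(i$labels), integer(1))))
  expect_true(all(mo$labels$w <= 0.5 & mo$labels$h <= 0.5))
  expect_error(augment_scene(items[[1]], "concat4", others = items[2:3]), "exactly 3")
})

test_that("split_dataset reproduces the printed 7:2:1 partition sizes", {
  s <- split_dataset(1519L, c(7, 2, 1), seed = 4)
  expect_identical(lengths(s), c(train = 1063L, val = 304L, test = 152L))
  s10 <- split_dataset(10L, c(7, 2, 1), seed = 1)
  expect_identical(lengths(s10), c(train = 7L, val = 2L, test = 1L))
  # partition law: disjoint and exhaustive
  all_idx <- sort(c(s$train, s$val, s$test))
  expect_identical(all_idx, 1:1519)
  expect_error(split_dataset(2L, c(7, 2, 1)), "fewer items")
  # deterministic per seed
  expect_identical(split_dataset(100L, seed = 9), split_dataset(100L, seed = 9))
})

test_that("YOLO dataset layout round-trips labels exactly", {
  root <- tempfile("yolo_ds_")
  items <- tiny_scene_set(5, img = 48L, seed = 41L)
  empty <- structure(list(image = array(0.5, c(48, 48, 3)),
                          labels = items[[1]]$labels[0, ]), class = "labeled_image")
  splits <- list(train = items[1:3], val = items[4:5], test = list(empty))
  write_yolo_dataset(splits, root)
  expect_true(file.exists(file.path(root, "dataset.yaml")))
  y <- yaml::read_yaml(file.path(root, "dataset.yaml"))
  expect_identical(y$nc, 1L)
  expect_identical(unlist(y$names), "RSZ")
  rd <- read_yolo_dataset(root)
  for (sp in c("train", "val")) {
    for (i in seq_along(rd[[sp]])) {
      a <- splits[[sp]][[i]]$labels; b <- rd[[sp]][[i]]$labels
      expect_lt(max(abs(as.matrix(b[, c("cx", "cy", "w", "h")]) -
                        as.matrix(a[, c("cx", "cy", "w", "h")]))), 5e-7)
    }
  }
  # negative sample: empty label file present, not missing
  expect_true(file.exists(file.path(root, "labels", "test", "img_0001.txt")))
  expect_identical(nrow(rd$test[[1]]$labels), 0L)
  # the exact printed line format parses back to the exact tuple
  lf <- file.path(root, "labels", "probe.txt")
  writeLines("0 0.500000 0.500000 0.100000 0.200000", lf)
  v <- as.numeric(strsplit(readLines(lf), " ")[[1]])
  expect_identical(v, c(0, 0.5, 0.5, 0.1, 0.2))
  unlink(root, recursive = TRUE)
})

test_that("generated sets hit their occupancy statistics", {
  sp <- scene_spec(img_size = 64L, n_umbels = 4L, occlusion = 0.2,
                   berry_radius = c(8, 14), seed = 60L)
  items <- generate_scenes(60, sp)
  counts <- vapply(items, function(i) nrow(i$labels), integer(1))
  # visibility rule removes a small fraction; the mean stays near the spec
  expect_gt(mean(counts), 4 * 0.8)
  expect_lte(max(counts), 4L)
})
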