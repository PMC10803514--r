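test_that("label tables parse +/- and 1/0 coding and reject bad values", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id,image_id,ER,PR,HER2,KI67",
               "p1,i1,+,-,1,0",
               "p2,i2,1,+,-,+"),
             file.path(dir, "labels.csv"))
  df <- read_label_table(file.path(dir, "labels.csv"))
  expect_equal(df$ER, c(1L, 1L))
  expect_equal(df$PR, c(0L, 1L))
  expect_equal(df$HER2, c(1L, 0L))
  expect_equal(df$KI67, c(0L, 1L))

  writeLines(c("patient_id,image_id,ER,PR,HER2,KI67", "p1,i1,?,-,1,0"),
             file.path(dir, "bad.csv"))
  expect_error(read_label_table(file.path(dir, "bad.csv")),
               "row 1")
  writeLines(c("patient_id,image_id,ER,PR,HER2", "p1,i1,+,-,1"),
             file.path(dir, "missing.csv"))
  expect_error(read_label_table(file.path(dir, "missing.csv")), "KI67")
})

test_that("load_manifest builds one record per row with parsed boxes", {
  dir <- make_tiny_manifest_dir(withr::local_tempdir(), n = 3L)
  man <- load_manifest(file.path(dir, "labels.csv"), dir)
  expect_length(man$records, 3L)
  for (r in man$records) {
    expect_false(r$pre_cropped)
    expect_equal(nrow(r$boxes), 1L)
    expect_equal(r$boxes$cx, 0.5)
    expect_true(file.exists(r$image_path))
  }
  # empty label table -> empty manifest, no error
  writeLines("patient_id,image_id,ER,PR,HER2,KI67", file.path(dir, "empty.csv"))
  man0 <- load_manifest(file.path(dir, "empty.csv"), dir)
  expect_length(man0$records, 0L)
  # missing box file -> pre-cropped flag
  file.remove(file.path(dir, "t01.txt"))
  man2 <- load_manifest(file.path(dir, "labels.csv"), dir)
  expect_true(man2$records[[1]]$pre_cropped)
  expect_null(man2$records[[1]]$boxes)
})

test_that("manifest JSON round-trip reproduces records", {
  dir <- make_tiny_manifest_dir(withr::local_tempdir(), n = 3L)
  man <- load_manifest(file.path(dir, "labels.csv"), dir)
  jp <- file.path(dir, "manifest.json")
  write_manifest(man, jp)
  man2 <- read_manifest(jp)
  expect_length(man2$records, 3L)
  for (i in 1:3) {
    expect_equal(man2$records[[i]]$label$ER, man$records[[i]]$label$ER)
    expect_equal(man2$records[[i]]$boxes$cx, man$records[[i]]$boxes$cx)
    expect_equal(man2$records[[i]]$image_path, man$records[[i]]$image_path)
  }
})

test_that("crop_roi matches naive index slicing and clamps at edges", {
  set.seed(3)
  img <- matrix(runif(640 * 640), 640, 640)
  # identity crop
  expect_identical(crop_roi(img, data.frame(cx = .5, cy = .5, w = 1, h = 1)), img)
  # forced arithmetic: quarter box in a 640x640 image
  cr <- crop_roi(img, data.frame(cx = .25, cy = .25, w = .25, h = .25))
  expect_identical(dim(cr), c(160L, 160L))
  expect_identical(cr, img[81:240, 81:240])
  # random boxes on small images vs slicing oracle
  for (i in 1:25) {
    H <- sample(8:20, 1); W <- sample(8:20, 1)
    im <- matrix(runif(H * W), H, W)
    b <- data.frame(cx = runif(1, .2, .9), cy = runif(1, .2, .9),
                    w = runif(1, .2, .8), h = runif(1, .2, .8))
    rr <- function(v) sign(v) * floor(abs(v) + 0.5)
    r0 <- max(0, rr((b$cy - b$h / 2) * H)); r1 <- min(H, rr((b$cy + b$h / 2) * H))
    c0 <- max(0, rr((b$cx - b$w / 2) * W)); c1 <- min(W, rr((b$cx + b$w / 2) * W))
    if (r1 <= r0 || c1 <= c0) {
      expect_error(crop_roi(im, b), "degenerate")
    } else {
      expect_identical(crop_roi(im, b), im[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE])
    }
  }
  # box past the right edge: clamped, no padding
  b <- data.frame(cx = 0.9, cy = 0.5, w = 0.4, h = 0.4)
  cr <- crop_roi(img, b)
  expect_lte(ncol(cr), 640L - 448L + 1L)
  expect_true(all(cr %in% img))
  # degenerate box errors
  expect_error(crop_roi(img, data.frame(cx = 1.2, cy = .5, w = 0.001, h = .2)),
               "degenerate")
})

test_that("split_dataset partitions at the 70/30 proportion, deterministically", {
  dir <- make_tiny_manifest_dir(withr::local_tempdir(), n = 10L)
  man <- load_manifest(file.path(dir, "labels.csv"), dir)
  sp <- split_spec(0.70, seed = 11L)
  parts <- split_dataset(man, sp)
  expect_length(parts$train$records, 7L)
  expect_length(parts$test$records, 3L)
  ids <- function(m) vapply(m$records, function(r) r$label$image_id, "")
  # identical membership on a second call with the same seed
  parts2 <- split_dataset(man, sp)
  expect_identical(ids(parts$train), ids(parts2$train))
  expect_identical(ids(parts$test), ids(parts2$test))
  # partition property over many seeds
  all_ids <- sort(ids(man))
  for (s in 1:100) {
    p <- split_dataset(man, split_spec(0.70, seed = s))
    expect_identical(sort(c(ids(p$train), ids(p$test))), all_ids)
    expect_length(intersect(ids(p$train), ids(p$test)), 0L)
  }
  expect_error(split_dataset(structure(list(records = man$records[1], root = dir),
                                       class = "dataset_manifest"), sp),
               "at least 2")
})

test_that("patient-grouped split keeps each patient on one side", {
  dir <- withr::local_tempdir()
  rows <- lapply(1:10, function(i) {
    img <- matrix(runif(64), 8, 8)
    iid <- sprintf("g%02d", i)
    save_gray_image(img, file.path(dir, paste0(iid, ".png")))
    # patient A owns 4 of the 10 images
    data.frame(patient_id = if (i <= 4) "A" else sprintf("B%d", i),
               image_id = iid, ER = 1L, PR = 0L, HER2 = 1L, KI67 = 0L,
               stringsAsFactors = FALSE)
  })
  write_label_table(do.call(rbind, rows), file.path(dir, "labels.csv"))
  man <- load_manifest(file.path(dir, "labels.csv"), dir)
  for (s in 1:20) {
    p <- split_dataset(man, split_spec(0.70, seed = s, group_by_patient = TRUE))
    pid <- function(m) unique(vapply(m$records, function(r) r$label$patient_id, ""))
    expect_length(intersect(pid(p$train), pid(p$test)), 0L)
  }
})

test_that("images round-trip through PNG within 8-bit quantisation", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(300), 15, 20)
  p <- file.path(dir, "x.png")
  save_gray_image(img, p)
  back <- load_gray_image(p)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  # YOLO box files round-trip
  b <- data.frame(class_id = 0L, cx = .25, cy = .75, w = .5, h = .25)
  bp <- file.path(dir, "x.txt")
  write_yolo_boxes(b, bp)
  b2 <- read_yolo_boxes(bp)
  expect_equal(b2$cx, b$cx, tolerance = 1e-6)
  expect_equal(b2$class_id, 0L)
})
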