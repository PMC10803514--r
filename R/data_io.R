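# Reading and writing images, YOLO-format detection boxes, label tables and
# dataset manifests; ROI cropping; reproducible train/test splits.
#
# Conventions fixed here because upstream formats leave them open: pixel
# coordinates are 0-based, rows first, half-open intervals; YOLO boxes are
# centre-normalised fractions of width/height; images become single-channel
# float in [0, 1] on load whatever the source bit depth.

LABEL_COLUMNS <- c("ER", "PR", "HER2", "KI67")

#' Read a grayscale image as a `[0, 1]` intensity matrix
#'
#' PNG and JPEG are supported; multi-channel sources are averaged to one
#' channel.
#'
#' @param path image file path.
#' @return numeric matrix (rows = image rows) with intensities in `[0, 1]`.
#' @export
load_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format '%s' (PNG and JPEG are supported)", ext))
  )
  if (length(dim(px)) == 3L) px <- apply(px[, , seq_len(min(3L, dim(px)[3])), drop = FALSE],
                                         c(1, 2), mean)
  pmin(pmax(px, 0), 1)
}

#' Write a `[0, 1]` intensity matrix as a grayscale PNG
#'
#' @param image numeric matrix with intensities in `[0, 1]`.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_gray_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read / write detection boxes in YOLO text format
#'
#' One `class cx cy w h` line per box, whitespace-separated, centre and size
#' normalised to `(0, 1]` fractions of image width/height.
#'
#' @param path text file path.
#' @return data frame with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_boxes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0)))
  parts <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  bad <- vapply(parts, function(p) length(p) != 5L || anyNA(p), logical(1))
  if (any(bad))
    stop(sprintf("malformed YOLO box line %d in %s", which(bad)[1], path))
  m <- do.call(rbind, parts)
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' @rdname read_yolo_boxes
#' @param boxes data frame as returned by `read_yolo_boxes`.
#' @export
write_yolo_boxes <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                   boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

parse_label_value <- function(v, row, column) {
  v <- trimws(as.character(v))
  # tolerate the ASCII and the typographic minus
  if (v %in% c("+", "1")) return(1L)
  if (v %in% c("-", "−", "0")) return(0L)
  stop(sprintf("invalid label '%s' in column %s, data row %d (expected +, -, 1 or 0)",
               v, column, row), call. = FALSE)
}

#' Read a label table
#'
#' The CSV must have header `patient_id,image_id,ER,PR,HER2,KI67`; label
#' values may be `+`/`-` or `1`/`0` (severe/positive = 1, mild/negative = 0).
#'
#' @param path CSV path.
#' @return data frame with character ids and integer 0/1 label columns.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  needed <- c("patient_id", "image_id", LABEL_COLUMNS)
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop(sprintf("label table %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$patient_id)) || any(!nzchar(df$image_id)))
      stop("label table has empty patient_id or image_id values")
    for (cl in LABEL_COLUMNS)
      df[[cl]] <- vapply(seq_len(nrow(df)),
                         function(i) parse_label_value(df[[cl]][i], i, cl),
                         integer(1))
  } else {
    for (cl in LABEL_COLUMNS) df[[cl]] <- integer(0)
  }
  df[needed]
}

#' @rdname read_label_table
#' @param labels data frame with the manifest label columns.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels[c("patient_id", "image_id", LABEL_COLUMNS)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a dataset manifest
#'
#' One record per label-table row.  Detection boxes are read from
#' `<box_dir>/<image_id>.txt`; a missing box file flags the record as
#' pre-cropped.  Image files are `<image_dir>/<image_id>.png` (or `.jpg`).
#'
#' @param label_csv_path label CSV (see [read_label_table()]).
#' @param image_dir directory holding the images.
#' @param box_dir directory holding the YOLO box files (defaults to
#'   `image_dir`).
#' @return a `dataset_manifest`: list with `records` (each holding
#'   `image_path`, `boxes`, `label`, `pre_cropped`) and `root`.
#' @export
load_manifest <- function(label_csv_path, image_dir, box_dir = image_dir) {
  labels <- read_label_table(label_csv_path)
  records <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    iid <- labels$image_id[i]
    img <- file.path(image_dir, paste0(iid, ".png"))
    if (!file.exists(img)) {
      alt <- file.path(image_dir, paste0(iid, c(".jpg", ".jpeg")))
      alt <- alt[file.exists(alt)]
      if (length(alt) == 0)
        stop(sprintf("image file for image_id '%s' not found under %s", iid, image_dir))
      img <- alt[1]
    }
    bpath <- file.path(box_dir, paste0(iid, ".txt"))
    pre_cropped <- !file.exists(bpath)
    boxes <- if (pre_cropped) NULL else read_yolo_boxes(bpath)
    records[[i]] <- list(image_path = img, boxes = boxes,
                         label = labels[i, , drop = FALSE],
                         pre_cropped = pre_cropped)
  }
  structure(list(records = records, root = image_dir), class = "dataset_manifest")
}

manifest_labels <- function(manifest) {
  if (length(manifest$records) == 0L)
    return(read_label_table(textConnection("patient_id,image_id,ER,PR,HER2,KI67")))
  do.call(rbind, lapply(manifest$records, function(r) r$label))
}

#' Write / read a manifest as JSON
#'
#' Stores image paths, boxes and labels; pixels stay in the image files.
#'
#' @param manifest a `dataset_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  recs <- lapply(manifest$records, function(r) {
    list(image_path = r$image_path,
         boxes = if (is.null(r$boxes)) NULL else r$boxes,
         label = as.list(r$label),
         pre_cropped = r$pre_cropped)
  })
  jsonlite::write_json(list(root = manifest$root, records = recs), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(j$records, function(r) {
    boxes <- if (is.null(r$boxes)) NULL else
      do.call(rbind.data.frame, lapply(r$boxes, as.data.frame))
    lab <- as.data.frame(r$label, stringsAsFactors = FALSE)
    for (cl in LABEL_COLUMNS) lab[[cl]] <- as.integer(lab[[cl]])
    list(image_path = r$image_path, boxes = boxes, label = lab,
         pre_cropped = isTRUE(r$pre_cropped))
  })
  structure(list(records = records, root = j$root), class = "dataset_manifest")
}

#' Crop a nodule ROI from a detection box
#'
#' The centre-normalised box is denormalised against the image size, its
#' edges rounded half-away-from-zero, clamped to the image bounds, and the
#' half-open pixel rectangle is sliced out; no padding is added for boxes
#' that extend past an edge.
#'
#' @param image `[0, 1]` intensity matrix.
#' @param box single-row data frame (or list) with `cx`, `cy`, `w`, `h`
#'   normalised to the image size.
#' @return the cropped intensity matrix.
#' @export
crop_roi <- function(image, box) {
  H <- nrow(image); W <- ncol(image)
  r0 <- max(0, round_half_up((box$cy - box$h / 2) * H))
  r1 <- min(H, round_half_up((box$cy + box$h / 2) * H))
  c0 <- max(0, round_half_up((box$cx - box$w / 2) * W))
  c1 <- min(W, round_half_up((box$cx + box$w / 2) * W))
  if (r1 <= r0 || c1 <= c0)
    stop(sprintf("degenerate box (cx=%g, cy=%g, w=%g, h=%g): zero area after clamping",
                 box$cx, box$cy, box$w, box$h), call. = FALSE)
  image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
}

#' Train/test split specification
#'
#' @param train_fraction fraction of records assigned to training (default
#'   0.70).
#' @param seed split seed.
#' @param group_by_patient keep all images of a patient on one side
#'   (default `FALSE`: image-level split).
#' @return a `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.70, seed = 1L,
                       group_by_patient = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 group_by_patient = isTRUE(group_by_patient)),
            class = "split_spec")
}

subset_manifest <- function(manifest, idx) {
  structure(list(records = manifest$records[idx], root = manifest$root),
            class = "dataset_manifest")
}

#' Split a manifest into train and test manifests
#'
#' Image-level by default: `round(train_fraction * N)` records are sampled
#' into the training side.  With `group_by_patient`, whole patients are
#' assigned greedily (in seeded random order) until the training side
#' reaches the target count, so no patient spans both sides.  Identical
#' seeds give identical splits.
#'
#' @param manifest a `dataset_manifest`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` manifests (a partition of the
#'   records).
#' @export
split_dataset <- function(manifest, spec) {
  N <- length(manifest$records)
  if (N < 2L) stop("split_dataset: need at least 2 records to partition")
  n_train <- as.integer(round(spec$train_fraction * N))
  n_train <- min(max(n_train, 1L), N - 1L)
  idx_train <- with_local_seed(spec$seed, {
    if (spec$group_by_patient) {
      pid <- vapply(manifest$records, function(r) r$label$patient_id, "")
      ord <- sample(unique(pid))
      take <- integer(0)
      for (p in ord) {
        if (length(take) >= n_train) break
        take <- c(take, which(pid == p))
      }
      sort(take)
    } else {
      sort(sample.int(N, n_train))
    }
  })
  list(train = subset_manifest(manifest, idx_train),
       test = subset_manifest(manifest, setdiff(seq_len(N), idx_train)))
}
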