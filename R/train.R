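# Training, evaluation and prediction tying all modules together.

#' Run configuration
#'
#' @param model an [mfdnet_config()].
#' @param batch_size SGD batch size (default 8).
#' @param epochs training epochs (default 200; the desk preset uses 20).
#' @param lr SGD learning rate; decayed by x0.1 at 50% and 75% of the
#'   epochs.
#' @param objective `"per_head_ce"` (default; sum of the four per-head
#'   cross-entropies) or `"concurrent"` (concurrent soft-max over the 4-tag
#'   positive-label vocabulary with the training-set co-occurrence matrix).
#' @param split a [split_spec()].
#' @param roi_mode how images are prepared: `"window"` (default; fixed-size
#'   square window centred on the detection box, preserving absolute nodule
#'   scale), `"tight"` (crop exactly to the box), `"full"` (whole image).
#' @param window_frac window edge as a fraction of the image edge
#'   (`roi_mode = "window"`).
#' @param expand_factor augmentation expansion applied to the training side
#'   after the split (1 = none).
#' @param seed run seed; every stochastic step derives from it.
#' @param preset `"custom"` (use arguments as given), `"paper"` (input 224,
#'   stem 32, 200 epochs, batch 8) or `"desk"` (input 32, stem 8, 12 epochs,
#'   training side expanded x5 -- small enough to train on one CPU in
#'   minutes).
#' @return a `run_config` list.
#' @export
run_config <- function(model = mfdnet_config(), batch_size = 8L,
                       epochs = 200L, lr = 0.01,
                       objective = c("per_head_ce", "concurrent"),
                       split = split_spec(), roi_mode = c("window", "tight", "full"),
                       window_frac = 0.75, expand_factor = 1L, seed = 1L,
                       preset = c("custom", "paper", "desk")) {
  preset <- match.arg(preset)
  objective <- match.arg(objective)
  roi_mode <- match.arg(roi_mode)
  if (preset == "paper") {
    model <- mfdnet_config(input_size = 224L, stem_channels = 32L, seed = seed)
    epochs <- 200L; batch_size <- 8L
  } else if (preset == "desk") {
    model <- mfdnet_config(input_size = 32L, stem_channels = 8L,
                           fused_width = 32L, fc_dim = 64L, seed = seed)
    epochs <- 12L; batch_size <- 8L; lr <- 0.05; expand_factor <- 5L
  }
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0, expand_factor >= 1L)
  structure(list(model = model, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, objective = objective,
                 split = split, roi_mode = roi_mode, window_frac = window_frac,
                 expand_factor = as.integer(expand_factor),
                 seed = as.integer(seed)),
            class = "run_config")
}

# square window of fixed size centred on the box (absolute scale preserved)
window_crop <- function(image, box, frac) {
  H <- nrow(image); W <- ncol(image)
  side <- round_half_up(frac * min(H, W))
  r0 <- round_half_up(box$cy * H - side / 2)
  c0 <- round_half_up(box$cx * W - side / 2)
  r0 <- min(max(r0, 0), H - side)
  c0 <- min(max(c0, 0), W - side)
  image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
}

resize_image <- function(image, size) {
  if (nrow(image) == size && ncol(image) == size) return(image)
  matrix(bilinear_resize_fwd_cpp(array(image, c(dim(image), 1L, 1L)),
                                 as.integer(size), as.integer(size)),
         size, size)
}

#' Prepare one record's pixels for the network
#'
#' @param image `[0, 1]` intensity matrix.
#' @param box single-row box data frame or `NULL` (pre-cropped records).
#' @param input_size target square edge.
#' @param roi_mode,window_frac see [run_config()].
#' @return `input_size` x `input_size` matrix.
#' @export
prepare_input <- function(image, box, input_size,
                          roi_mode = "window", window_frac = 0.75) {
  if (!is.null(box) && nrow(box) > 0) {
    box <- box[1, , drop = FALSE]
    if (roi_mode == "tight") image <- crop_roi(image, box)
    else if (roi_mode == "window") image <- window_crop(image, box, window_frac)
  }
  resize_image(image, input_size)
}

# load a manifest into arrays ready for the model
load_dataset <- function(manifest, input_size, roi_mode = "window",
                         window_frac = 0.75) {
  n <- length(manifest$records)
  x <- array(0, c(input_size, input_size, n))
  y <- matrix(0L, n, 4L, dimnames = list(NULL, LABEL_COLUMNS))
  pid <- character(n)
  for (i in seq_len(n)) {
    r <- manifest$records[[i]]
    img <- r[["image"]] %||% load_gray_image(r$image_path)
    x[, , i] <- prepare_input(img, r$boxes, input_size, roi_mode, window_frac)
    y[i, ] <- as.integer(r$label[1, LABEL_COLUMNS])
    pid[i] <- r$label$patient_id
  }
  list(x = x, y = y, patient_id = pid)
}

# loss and logit gradients for one batch; y is 0/1 matrix [B, 4]
batch_loss_grad <- function(logits, y, objective, r = NULL) {
  B <- ncol(logits[[1]])
  if (objective == "per_head_ce") {
    loss <- 0
    glog <- list()
    for (k in seq_along(INDEX_NAMES)) {
      z <- logits[[k]]
      zm <- sweep(z, 2L, apply(z, 2L, max), "-")
      e <- exp(zm)
      sig <- sweep(e, 2L, colSums(e), "/")
      yk <- y[, k]
      tr <- rbind(1 - yk, yk)
      loss <- loss - mean(log(pmax(sig[cbind(yk + 1L, seq_len(B))], 1e-12)))
      glog[[INDEX_NAMES[k]]] <- (sig - tr) / B
    }
    return(list(loss = loss, glogits = glog))
  }
  # concurrent soft-max over the 4 positive-tag scores z_i = z_pos - z_neg
  s <- do.call(rbind, lapply(logits, function(z) z[2, ] - z[1, ]))
  loss <- 0
  gs <- matrix(0, 4L, B)
  for (b in seq_len(B)) {
    yb <- y[b, ]
    if (sum(yb) == 0) next
    sig <- concurrent_softmax_probs(s[, b], yb, r)
    loss <- loss - sum(yb * log(pmax(sig, 1e-12)))
    gs[, b] <- concurrent_softmax_grad(s[, b], yb, r)
  }
  loss <- loss / B
  gs <- gs / B
  glog <- list()
  for (k in seq_along(INDEX_NAMES))
    glog[[INDEX_NAMES[k]]] <- rbind(-gs[k, ], gs[k, ])
  list(loss = loss, glogits = glog)
}

lr_at <- function(base_lr, epoch, epochs) {
  f <- epoch / epochs
  if (f > 0.75) base_lr * 0.01 else if (f > 0.5) base_lr * 0.1 else base_lr
}

predictions_from_logits <- function(logits_t) {
  # logits_t: named list of [2, B]; returns [B, 4] 0/1 matrix
  out <- sapply(logits_t, function(z) as.integer(z[2, ] > z[1, ]))
  matrix(out, ncol = 4L, dimnames = list(NULL, names(logits_t)))
}

eval_arrays <- function(model, x, y, batch = 32L) {
  n <- dim(x)[3]
  preds <- matrix(0L, n, 4L, dimnames = list(NULL, INDEX_NAMES))
  for (i0 in seq(1L, n, by = batch)) {
    idx <- i0:min(i0 + batch - 1L, n)
    xb <- array(x[, , idx], c(dim(x)[1], dim(x)[2], 1L, length(idx)))
    r <- .model_fwd(model, xb)
    preds[idx, ] <- predictions_from_logits(r$logits)
  }
  metrics <- lapply(INDEX_NAMES, function(nm)
    confusion_and_metrics(preds[, nm], y[, nm]))
  names(metrics) <- INDEX_NAMES
  list(metrics = metrics, predictions = preds)
}

#' Train an MFD-Net model
#'
#' Splits the manifest, optionally expands the training side, runs plain
#' SGD over shuffled batches with per-epoch evaluation on the held-out
#' split, and keeps the best checkpoint by mean four-index accuracy.  Fully
#' reproducible under `cfg$seed`.  A non-finite loss aborts training and
#' the last finite model is returned.
#'
#' @param cfg a [run_config()].
#' @param manifest a `dataset_manifest` (e.g. from [generate_cohort()] or
#'   [load_manifest()]).
#' @return list with `model` (best checkpoint), `final_model`, `records`
#'   (one row per epoch: loss, per-index test accuracy, wall time), `split`
#'   (the train/test manifests), and `cooccurrence` (the training-set
#'   matrix).
#' @export
train_mfdnet <- function(cfg, manifest) {
  stopifnot(inherits(cfg, "run_config"))
  sp <- cfg$split
  sp$seed <- cfg$seed
  parts <- split_dataset(manifest, sp)
  train_m <- parts$train
  if (cfg$expand_factor > 1L)
    train_m <- expand_dataset(train_m,
                              default_expansion_plan(cfg$expand_factor,
                                                     seed = cfg$seed))
  tr <- load_dataset(train_m, cfg$model$input_size, cfg$roi_mode, cfg$window_frac)
  te <- load_dataset(parts$test, cfg$model$input_size, cfg$roi_mode, cfg$window_frac)
  r_mat <- estimate_cooccurrence(tr$y)
  mcfg <- cfg$model
  mcfg$seed <- cfg$seed
  model <- build_model(mcfg)
  n <- dim(tr$x)[3]
  records <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, model = model)
  for (ep in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_at(cfg$lr, ep, cfg$epochs)
    ord <- with_local_seed(cfg$seed + 7919L * ep, sample.int(n))
    ep_loss <- 0; nb <- 0L
    aborted <- FALSE
    for (i0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[i0:min(i0 + cfg$batch_size - 1L, n)]
      xb <- array(tr$x[, , idx], c(dim(tr$x)[1], dim(tr$x)[2], 1L, length(idx)))
      fw <- .model_fwd(model, xb)
      lg <- batch_loss_grad(fw$logits, tr$y[idx, , drop = FALSE],
                            cfg$objective, r_mat)
      if (!is.finite(lg$loss)) { aborted <- TRUE; break }
      grads <- .model_bwd(model, fw$cache, lg$glogits)
      model$blocks <- sgd_update(model$blocks, grads, lr)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    if (aborted) {
      warning(sprintf("non-finite loss at epoch %d: aborting, keeping last good checkpoint", ep))
      records <- records[seq_len(ep - 1L)]
      break
    }
    ev <- eval_arrays(model, te$x, te$y)
    accs <- vapply(ev$metrics, function(m) m$accuracy, numeric(1))
    records[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / max(nb, 1L),
                                acc_ER = accs[["ER"]], acc_PR = accs[["PR"]],
                                acc_HER2 = accs[["HER2"]], acc_KI67 = accs[["KI67"]],
                                wall_time = proc.time()[["elapsed"]] - t0)
    if (mean(accs) > best$acc) best <- list(acc = mean(accs), model = model)
  }
  list(model = best$model, final_model = model,
       records = do.call(rbind, records),
       split = parts, cooccurrence = r_mat)
}

#' Evaluate a model on a manifest
#'
#' Deterministic forward pass; returns confusion counts and the four
#' metrics for each of ER, PR, HER-2 and Ki-67 simultaneously.
#'
#' @param model an `mfdnet_model`.
#' @param manifest a `dataset_manifest`.
#' @param roi_mode,window_frac input preparation, as in [run_config()].
#' @return list with `metrics` (per-index list with tp/fp/tn/fn, precision,
#'   recall, accuracy, f1) and `predictions` (`[N, 4]` 0/1 matrix).
#' @export
evaluate_mfdnet <- function(model, manifest, roi_mode = "window",
                            window_frac = 0.75) {
  ds <- load_dataset(manifest, model$cfg$input_size, roi_mode, window_frac)
  eval_arrays(model, ds$x, ds$y)
}

#' Write per-index metrics as JSON
#'
#' Schema: `{index: {precision, recall, accuracy, f1, tp, fp, tn, fn}}`.
#'
#' @param metrics `$metrics` from [evaluate_mfdnet()].
#' @param path output path.
#' @export
write_metrics_json <- function(metrics, path) {
  out <- lapply(metrics, function(m)
    m[c("precision", "recall", "accuracy", "f1", "tp", "fp", "tn", "fn")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predict the four immunomarker calls for images
#'
#' @param model an `mfdnet_model`.
#' @param images list of intensity matrices, or character vector of image
#'   paths; unreadable files are skipped with a warning.
#' @param boxes optional list of box data frames aligned with `images`.
#' @param roi_mode,window_frac input preparation, as in [run_config()].
#' @return data frame with one row per image: id, then for each index the
#'   0/1 call and the positive-class probability (each head's probability
#'   pair sums to 1).
#' @export
predict_mfdnet <- function(model, images, boxes = NULL,
                           roi_mode = "window", window_frac = 0.75) {
  if (is.character(images)) {
    paths <- images
    images <- list(); keep <- character(0)
    for (p in paths) {
      im <- tryCatch(load_gray_image(p), error = function(e) {
        warning(sprintf("skipping unreadable image %s: %s", p, conditionMessage(e)))
        NULL
      })
      if (!is.null(im)) { images[[length(images) + 1L]] <- im; keep <- c(keep, p) }
    }
    if (length(images) == 0L) stop("predict_mfdnet: no readable images")
    ids <- basename(keep)
  } else ids <- paste0("image", seq_along(images))
  n <- length(images)
  S <- model$cfg$input_size
  x <- array(0, c(S, S, 1L, n))
  for (i in seq_len(n))
    x[, , 1L, i] <- prepare_input(images[[i]],
                                  if (is.null(boxes)) NULL else boxes[[i]],
                                  S, roi_mode, window_frac)
  out <- model_forward(model, array(x, c(S, S, n)))
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in INDEX_NAMES) {
    df[[paste0(nm, "_call")]] <- as.integer(out$probs[[nm]][, 2] > 0.5)
    df[[paste0(nm, "_prob_pos")]] <- out$probs[[nm]][, 2]
  }
  df
}

#' Majority-class baseline accuracies
#'
#' Predicts every test record as the training-side majority class of each
#' index.
#'
#' @param train_y,test_y 0/1 label matrices with the four index columns.
#' @return named numeric vector of baseline accuracies.
#' @export
majority_baseline <- function(train_y, test_y) {
  vapply(colnames(train_y), function(nm) {
    maj <- as.integer(mean(train_y[, nm]) >= 0.5)
    mean(test_y[, nm] == maj)
  }, numeric(1))
}
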