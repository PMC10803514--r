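# MFD-Net assembly: stem, staged feature distillation, channel fusion,
# ESCA attention, global max pooling and four simultaneous two-way heads.

INDEX_NAMES <- c("ER", "PR", "HER2", "KI67")

#' MFD-Net configuration
#'
#' @param input_size square input edge in pixels; must be divisible by
#'   `2^(num_stages - 1)` (the depth branch halves resolution once per stage
#'   after the first).
#' @param stem_channels channels after the stem 1x1 convolution.
#' @param num_stages number of distillation stages (default 3).
#' @param compression_ratio fraction of a stage's input channels kept by its
#'   distillation branch (default 0.5).
#' @param kernel_sizes depthwise kernel sizes used by every block.
#' @param mu low-rank subspace fraction of the blueprint-separable pointwise
#'   factorisation.
#' @param sam_reduction channel reduction ratio of the spatial gate.
#' @param fused_width channels after the fusion 1x1 compression (default
#'   `4 * stem_channels`).
#' @param fc_dim width of the shared fully connected trunk (default
#'   `2 * fused_width`).
#' @param use_distill keep the depthwise distillation branches (disable for
#'   the depth-branch-only ablation).
#' @param use_esca keep the attention block (disable for the no-attention
#'   ablation).
#' @param esca_channel_attention keep the channel gate inside ESCA (disable
#'   for the spatial-only ablation).
#' @param bias give convolutions bias terms (default `TRUE`).
#' @param seed initialization seed.
#' @return an `mfdnet_config` list, validated.
#' @export
mfdnet_config <- function(input_size = 224L, stem_channels = 32L,
                          num_stages = 3L, compression_ratio = 0.5,
                          kernel_sizes = c(3L, 4L, 6L), mu = 0.5,
                          sam_reduction = 8L, fused_width = 4L * stem_channels,
                          fc_dim = 2L * fused_width, use_distill = TRUE,
                          use_esca = TRUE, esca_channel_attention = TRUE,
                          bias = TRUE, seed = 1L) {
  cfg <- list(input_size = as.integer(input_size),
              stem_channels = as.integer(stem_channels),
              num_stages = as.integer(num_stages),
              compression_ratio = compression_ratio,
              kernel_sizes = as.integer(kernel_sizes), mu = mu,
              sam_reduction = as.integer(sam_reduction),
              fused_width = as.integer(fused_width),
              fc_dim = as.integer(fc_dim),
              use_distill = isTRUE(use_distill),
              use_esca = isTRUE(use_esca),
              esca_channel_attention = isTRUE(esca_channel_attention),
              bias = isTRUE(bias), seed = as.integer(seed))
  if (cfg$num_stages < 1L) stop("config error: num_stages must be >= 1")
  if (!(cfg$compression_ratio > 0 && cfg$compression_ratio < 1))
    stop("config error: compression_ratio must be in (0, 1)")
  if (!(cfg$mu > 0 && cfg$mu < 1)) stop("config error: mu must be in (0, 1)")
  down <- 2L^(cfg$num_stages - 1L)
  if (cfg$input_size %% down != 0L)
    stop(sprintf("config error: input_size must be divisible by %d", down))
  if (cfg$input_size %/% down < 2L)
    stop("config error: final resolution below 2x2; enlarge input_size")
  if (cfg$fused_width < 1L) stop("config error: fused_width must be >= 1")
  class(cfg) <- "mfdnet_config"
  cfg
}

stage_plan <- function(cfg) {
  cin <- cfg$stem_channels
  plan <- vector("list", cfg$num_stages)
  for (s in seq_len(cfg$num_stages)) {
    plan[[s]] <- list(cin = cin, cout = 2L * cin,
                      cd = max(1L, as.integer(round(cfg$compression_ratio * cin))),
                      stride = if (s == 1L) 1L else 2L)
    cin <- 2L * cin
  }
  plan
}

fused_concat_width <- function(cfg) {
  plan <- stage_plan(cfg)
  w <- plan[[cfg$num_stages]]$cout
  if (cfg$use_distill) w <- w + sum(vapply(plan, function(p) p$cd, integer(1)))
  w
}

#' Build an MFD-Net model
#'
#' Assembles stem, `num_stages` distillation stages (each a multi-kernel
#' depthwise distillation branch plus a blueprint-separable depth branch),
#' the fusion 1x1 compression, the ESCA attention block, and the shared
#' trunk with four simultaneous two-way heads (ER, PR, HER-2, Ki-67).
#' Initialization is deterministic under `cfg$seed`.
#'
#' @param cfg an [mfdnet_config()].
#' @return an `mfdnet_model` object.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "mfdnet_config"))
  plan <- stage_plan(cfg)
  with_local_seed(cfg$seed, {
    blocks <- list(stem = pw_weights(1L, cfg$stem_channels, bias = cfg$bias))
    blocks$stages <- lapply(plan, function(p) {
      st <- list()
      if (cfg$use_distill) {
        st$dw <- multikernel_dw_weights(p$cin, cfg$kernel_sizes, bias = cfg$bias)
        st$dpw1 <- pw_weights(p$cin, p$cd, bias = cfg$bias)
        st$dpw2 <- pw_weights(p$cd, p$cd, bias = cfg$bias)
      }
      st$bs <- bsconv_weights(p$cin, p$cout, cfg$kernel_sizes, mu = cfg$mu,
                              stride = p$stride, bias = cfg$bias)
      st
    })
    blocks$fuse <- pw_weights(fused_concat_width(cfg), cfg$fused_width,
                              bias = cfg$bias)
    if (cfg$use_esca)
      blocks$esca <- esca_weights(cfg$fused_width, cfg$sam_reduction,
                                  channel_attention = cfg$esca_channel_attention)
    fc_params <- list(
      W1 = matrix(he_init(c(cfg$fc_dim, cfg$fused_width), cfg$fused_width),
                  cfg$fc_dim, cfg$fused_width),
      b1 = numeric(cfg$fc_dim))
    for (nm in INDEX_NAMES) {
      fc_params[[paste0("head_", nm)]] <-
        matrix(he_init(c(2L, cfg$fc_dim), cfg$fc_dim, gain = 0.1), 2L, cfg$fc_dim)
      fc_params[[paste0("headb_", nm)]] <- numeric(2L)
    }
    blocks$fc <- new_block_weights(
      list(in_dim = cfg$fused_width, fc_dim = cfg$fc_dim),
      fc_params, "fc_weights")
    structure(list(cfg = cfg, blocks = blocks), class = "mfdnet_model")
  })
}

## ---- stage forward / backward ----

.stage_fwd <- function(st, x) {
  cache <- list(x = x)
  distilled <- NULL
  if (!is.null(st$dw)) {
    mk <- .mk_dw_fwd(x, st$dw)
    fdm <- pw_fwd(mk$y, st$dpw1$params$W, st$dpw1$params$b)
    fd <- pw_fwd(fdm, st$dpw2$params$W, st$dpw2$params$b)
    cache$mk <- mk$cache; cache$mky <- mk$y; cache$fdm <- fdm
    distilled <- fd
  }
  bs <- .bsconv_fwd(x, st$bs)
  cache$bs <- bs$cache
  list(distilled = distilled, depth = bs$y, cache = cache)
}

.stage_bwd <- function(st, cache, g_fd, g_depth) {
  grads <- list()
  gx <- NULL
  if (!is.null(st$dw)) {
    if (is.null(g_fd)) g_fd <- array(0, dim(cache$fdm))
    p2 <- pw_bwd(cache$fdm, st$dpw2$params$W, g_fd)
    p1 <- pw_bwd(cache$mky, st$dpw1$params$W, p2$gx)
    mk <- .mk_dw_bwd(st$dw, cache$mk, p1$gx)
    grads$dw <- mk$grads
    grads$dpw1 <- list(W = p1$gW, b = p1$gb)[names(st$dpw1$params)]
    grads$dpw2 <- list(W = p2$gW, b = p2$gb)[names(st$dpw2$params)]
    gx <- mk$gx
  }
  bs <- .bsconv_bwd(st$bs, cache$bs, g_depth)
  grads$bs <- bs$grads
  gx <- if (is.null(gx)) bs$gx else gx + bs$gx
  list(gx = gx, grads = grads[names(st)])
}

#' Run one distillation stage
#'
#' The distillation branch applies the multi-kernel depthwise block, a 1x1
#' compression to `compression_ratio` of the stage input channels, and a
#' second 1x1 distillation; the depth branch applies the blueprint-separable
#' block (stride 2 after the first stage).
#'
#' @param stage one element of `model$blocks$stages`.
#' @param input stage input feature map `[H, W, C, B]`.
#' @return list with `distilled` (`NULL` when the branch is disabled) and
#'   `depth` feature maps.
#' @export
distill_stage_forward <- function(stage, input) {
  input <- as_feature_map(input)
  check_channels(input, stage$bs$meta$cin, "distill_stage_forward")
  r <- .stage_fwd(stage, input)
  list(distilled = r$distilled, depth = r$depth)
}

## ---- fusion ----

concat_channels <- function(parts) {
  d1 <- dim(parts[[1]])
  Cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  at <- 0L
  for (p in parts) {
    C <- dim(p)[3]
    out[, , at + seq_len(C), ] <- p
    at <- at + C
  }
  out
}

.fuse_fwd <- function(parts, w) {
  target <- dim(parts[[length(parts)]])[1:2]
  pooled <- vector("list", length(parts))
  pools <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- dim(parts[[i]])
    if (d[1] %% target[1] != 0L || d[2] %% target[2] != 0L)
      stop("fuse_features: spatial sizes are not integer multiples of the target")
    f <- d[1] %/% target[1]
    if (d[2] %/% target[2] != f)
      stop("fuse_features: mismatched H,W pooling factors")
    if (f == 1L) {
      pooled[[i]] <- parts[[i]]
    } else {
      mp <- maxpool_fwd_cpp(parts[[i]], f, f, FALSE)
      pooled[[i]] <- mp$y
      pools[[i]] <- list(idx = mp$idx, xdim = d)
    }
  }
  cat_ <- concat_channels(pooled)
  y <- pw_fwd(cat_, w$params$W, w$params$b)
  list(y = y, cache = list(cat = cat_, pools = pools,
                           Cs = vapply(pooled, function(p) dim(p)[3], integer(1))))
}

.fuse_bwd <- function(w, cache, gy) {
  pb <- pw_bwd(cache$cat, w$params$W, gy)
  grads <- list(W = pb$gW, b = pb$gb)[names(w$params)]
  gparts <- vector("list", length(cache$Cs))
  at <- 0L
  for (i in seq_along(cache$Cs)) {
    g <- pb$gx[, , at + seq_len(cache$Cs[i]), , drop = FALSE]
    at <- at + cache$Cs[i]
    if (!is.null(cache$pools[[i]]))
      g <- maxpool_bwd_cpp(cache$pools[[i]]$idx, g, cache$pools[[i]]$xdim)
    gparts[[i]] <- g
  }
  list(gparts = gparts, grads = grads)
}

#' Fuse distilled and depth features along the channel axis
#'
#' Earlier-stage distilled maps are max-pooled down to the final depth
#' resolution, everything is concatenated along channels, and a 1x1
#' convolution compresses to the configured fused width.
#'
#' @param distilled list of per-stage distilled feature maps (may be empty).
#' @param depth final depth-branch feature map (sets the target resolution).
#' @param w fusion pointwise weights (`model$blocks$fuse`).
#' @return fused feature map `[H, W, fused_width, B]`.
#' @export
fuse_features <- function(distilled, depth, w) {
  parts <- c(distilled, list(depth))
  .fuse_fwd(parts, w)$y
}

## ---- full model forward / backward ----

batchify_images <- function(images, input_size) {
  if (is.list(images)) {
    stopifnot(all(vapply(images, is.matrix, logical(1))))
    arr <- array(0, c(dim(images[[1]]), length(images)))
    for (i in seq_along(images)) arr[, , i] <- images[[i]]
    images <- arr
  }
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  if (length(dim(images)) == 3L)
    images <- array(images, c(dim(images)[1:2], 1L, dim(images)[3]))
  d <- dim(images)
  if (d[1] != input_size || d[2] != input_size)
    stop(sprintf("model_forward: expected %dx%d input images, got %dx%d",
                 input_size, input_size, d[1], d[2]), call. = FALSE)
  images
}

.model_fwd <- function(model, x) {
  cfg <- model$cfg
  xn <- (x - 0.5) * 2          # centre intensities; fixed affine, no stats
  cache <- list(xn = xn)
  cur <- pw_fwd(xn, model$blocks$stem$params$W, model$blocks$stem$params$b)
  cache$stem_out <- cur
  fds <- list()
  cache$stages <- vector("list", cfg$num_stages)
  for (s in seq_len(cfg$num_stages)) {
    r <- .stage_fwd(model$blocks$stages[[s]], cur)
    cache$stages[[s]] <- r$cache
    if (!is.null(r$distilled)) fds[[length(fds) + 1L]] <- r$distilled
    cur <- r$depth
  }
  fu <- .fuse_fwd(c(fds, list(cur)), model$blocks$fuse)
  cache$fuse <- fu$cache
  feat <- fu$y
  if (cfg$use_esca) {
    es <- .esca_fwd(feat, model$blocks$esca)
    cache$esca <- es$cache
    feat <- es$y
  }
  gm <- gmp_fwd(feat)
  cache$gmp <- gm
  fc <- model$blocks$fc$params
  pre <- fc$W1 %*% gm$v + fc$b1
  trunk <- gelu(pre)
  cache$v <- gm$v; cache$pre <- pre; cache$trunk <- trunk
  logits <- lapply(INDEX_NAMES, function(nm)
    fc[[paste0("head_", nm)]] %*% trunk + fc[[paste0("headb_", nm)]])
  names(logits) <- INDEX_NAMES
  list(logits = logits, cache = cache)
}

.model_bwd <- function(model, cache, glogits) {
  cfg <- model$cfg
  fc <- model$blocks$fc$params
  gtrunk <- matrix(0, nrow(fc$W1), ncol(cache$trunk))
  fc_grads <- list(W1 = NULL, b1 = NULL)
  for (nm in INDEX_NAMES) {
    gz <- glogits[[nm]]
    fc_grads[[paste0("head_", nm)]] <- gz %*% t(cache$trunk)
    fc_grads[[paste0("headb_", nm)]] <- rowSums(gz)
    gtrunk <- gtrunk + t(fc[[paste0("head_", nm)]]) %*% gz
  }
  gpre <- gtrunk * gelu_grad(cache$pre)
  fc_grads$W1 <- gpre %*% t(cache$v)
  fc_grads$b1 <- rowSums(gpre)
  gv <- t(fc$W1) %*% gpre
  gfeat <- gmp_bwd(cache$gmp, gv)
  grads <- list()
  if (cfg$use_esca) {
    eb <- .esca_bwd(model$blocks$esca, cache$esca, gfeat)
    grads$esca <- eb$grads
    gfeat <- eb$gx
  }
  fb <- .fuse_bwd(model$blocks$fuse, cache$fuse, gfeat)
  grads$fuse <- fb$grads
  nparts <- length(fb$gparts)
  g_depth <- fb$gparts[[nparts]]
  stage_grads <- vector("list", cfg$num_stages)
  for (s in rev(seq_len(cfg$num_stages))) {
    g_fd <- if (cfg$use_distill) fb$gparts[[s]] else NULL
    sb <- .stage_bwd(model$blocks$stages[[s]], cache$stages[[s]], g_fd, g_depth)
    stage_grads[[s]] <- sb$grads
    g_depth <- sb$gx          # gradient w.r.t. this stage's input
  }
  sb_stem <- pw_bwd(cache$xn, model$blocks$stem$params$W, g_depth)
  out <- list(stem = list(W = sb_stem$gW, b = sb_stem$gb)[names(model$blocks$stem$params)],
              stages = stage_grads, fuse = grads$fuse)
  if (cfg$use_esca) out$esca <- grads$esca
  out$fc <- fc_grads[names(model$blocks$fc$params)]
  out[names(model$blocks)]
}

#' Full MFD-Net forward pass
#'
#' Runs stem, stages, fusion, attention, global max pooling, the shared
#' trunk and the four heads on a batch of grayscale images in `[0, 1]`.
#'
#' @param model an `mfdnet_model` from [build_model()].
#' @param images `[H, W, B]` or `[H, W, 1, B]` array, a matrix, or a list of
#'   matrices, each `input_size` square.
#' @return a `mfd_head_output` list: `logits` and `probs`, each a named list
#'   (ER, PR, HER2, KI67) of `[B, 2]` matrices with columns
#'   (negative, positive); probability rows sum to 1.
#' @export
model_forward <- function(model, images) {
  x <- batchify_images(images, model$cfg$input_size)
  r <- .model_fwd(model, x)
  logits <- lapply(r$logits, t)
  probs <- lapply(logits, function(z) t(apply(z, 1L, softmax_probs)))
  structure(list(logits = logits, probs = probs), class = "mfd_head_output")
}

#' Per-block parameter summary of a model
#'
#' @param model an `mfdnet_model`.
#' @return data frame with one row per block: name and parameter count.
#' @export
model_summary <- function(model) {
  rows <- list(c("stem", count_block_params(model$blocks$stem)))
  for (s in seq_along(model$blocks$stages)) {
    st <- model$blocks$stages[[s]]
    if (!is.null(st$dw)) {
      rows[[length(rows) + 1L]] <- c(sprintf("stage%d/distill", s),
                                     count_block_params(st$dw) +
                                       count_block_params(st$dpw1) +
                                       count_block_params(st$dpw2))
    }
    rows[[length(rows) + 1L]] <- c(sprintf("stage%d/depth", s),
                                   count_block_params(st$bs))
  }
  rows[[length(rows) + 1L]] <- c("fuse", count_block_params(model$blocks$fuse))
  if (!is.null(model$blocks$esca))
    rows[[length(rows) + 1L]] <- c("esca", count_block_params(model$blocks$esca))
  rows[[length(rows) + 1L]] <- c("fc+heads", count_block_params(model$blocks$fc))
  df <- data.frame(block = vapply(rows, `[`, "", 1L),
                   params = as.integer(vapply(rows, `[`, "", 2L)))
  df
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a pair of files: `<prefix>.rds` holding the parameter
#' arrays and `<prefix>.json` holding the configuration.
#'
#' @param model an `mfdnet_model`.
#' @param prefix path prefix (no extension).
#' @return `save_checkpoint` returns `prefix` invisibly; `load_checkpoint`
#'   returns the rebuilt model.
#' @export
save_checkpoint <- function(model, prefix) {
  saveRDS(get_params(model$blocks), paste0(prefix, ".rds"))
  jsonlite::write_json(unclass(model$cfg), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(prefix) {
  cfg_l <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  cfg <- do.call(mfdnet_config, cfg_l[setdiff(names(cfg_l), c())])
  model <- build_model(cfg)
  model$blocks <- set_params(model$blocks, readRDS(paste0(prefix, ".rds")))
  model
}
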