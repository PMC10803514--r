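# The three bespoke layer types.  Exported *_forward functions take a
# feature map [H,W,C,B] (R dim order; batch last) plus a weight container and
# return the transformed map.  Internal .*_fwd/.*_bwd pairs carry caches for
# hand-derived reverse-mode gradients.

check_channels <- function(x, expected, what) {
  C <- dim(x)[3]
  if (C != expected)
    stop(sprintf("%s: channel mismatch, expected C=%d but got C=%d",
                 what, expected, C), call. = FALSE)
}

# replicate a [H,W,1,B] spatial gate or [C,B] channel gate over a map
spatial_gate_full <- function(g, C) g[, , rep(1L, C), , drop = FALSE]
channel_gate_full <- function(g, H, W) array(rep(g, each = H * W),
                                             c(H, W, nrow(g), ncol(g)))

## ---- multi-kernel depthwise block: y = x + PW(GELU(sum_m DW_km(x))) ----

.mk_dw_fwd <- function(x, w) {
  m <- w$meta
  s <- NULL
  for (k in m$kernel_sizes) {
    r <- dw_fwd(x, w$params[[paste0("dw_k", k)]],
                w$params[[paste0("dwb_k", k)]])
    s <- if (is.null(s)) r else s + r
  }
  a <- gelu(s)
  p <- pw_fwd(a, w$params$pw, w$params$pwb)
  y <- if (m$pointwise_out == m$channels) x + p else p
  list(y = y, cache = list(x = x, s = s, a = a))
}

.mk_dw_bwd <- function(w, cache, gy) {
  m <- w$meta
  grads <- list()
  pb <- pw_bwd(cache$a, w$params$pw, gy)
  grads$pw <- pb$gW
  if (m$bias) grads$pwb <- pb$gb
  gs <- pb$gx * gelu_grad(cache$s)
  gx <- if (m$pointwise_out == m$channels) gy else array(0, dim(cache$x))
  for (k in m$kernel_sizes) {
    r <- dw_bwd(cache$x, w$params[[paste0("dw_k", k)]], gs)
    gx <- gx + r$gx
    grads[[paste0("dw_k", k)]] <- r$gw
    if (m$bias) grads[[paste0("dwb_k", k)]] <- r$gb
  }
  list(gx = gx, grads = grads[names(w$params)])
}

#' Forward pass of the multi-kernel depthwise convolution block
#'
#' Computes `y = x + PW(GELU(sum_m DW_km(x)))`: one depthwise convolution per
#' kernel size, additive combination, GELU, pointwise channel mixing, and a
#' residual connection.  Spatial size is preserved for every kernel size via
#' asymmetric same-size padding.
#'
#' @param x feature map, array `[H, W, C, B]` (a plain `H x W` matrix is
#'   promoted to `[H, W, 1, 1]`).
#' @param w weights from [multikernel_dw_weights()].
#' @return feature map of shape `[H, W, pointwise_out, B]`.
#' @export
multilayer_dwconv_forward <- function(x, w) {
  x <- as_feature_map(x)
  check_channels(x, w$meta$channels, "multilayer_dwconv_forward")
  .mk_dw_fwd(x, w)$y
}

## ---- multi-kernel blueprint-separable block ----
## y = residual(x) + sum_m DW_km(PW_2(PW_1(x))), pointwise pair low-rank

.bsconv_fwd <- function(x, w) {
  m <- w$meta
  t1 <- pw_fwd(x, w$params$pw1, w$params$pw1b)
  t2 <- pw_fwd(t1, w$params$pw2, w$params$pw2b)
  d <- NULL
  for (k in m$kernel_sizes) {
    r <- dw_fwd(t2, w$params[[paste0("dw_k", k)]],
                w$params[[paste0("dwb_k", k)]], stride = m$stride)
    d <- if (is.null(d)) r else d + r
  }
  if (m$has_proj) {
    xs <- subsample_fwd(x, m$stride)
    res <- pw_fwd(xs, w$params$proj, w$params$projb)
  } else {
    xs <- NULL
    res <- x
  }
  list(y = res + d, cache = list(x = x, t1 = t1, t2 = t2, xs = xs))
}

.bsconv_bwd <- function(w, cache, gy) {
  m <- w$meta
  grads <- list()
  gt2 <- array(0, dim(cache$t2))
  for (k in m$kernel_sizes) {
    r <- dw_bwd(cache$t2, w$params[[paste0("dw_k", k)]], gy, stride = m$stride)
    gt2 <- gt2 + r$gx
    grads[[paste0("dw_k", k)]] <- r$gw
    if (m$bias) grads[[paste0("dwb_k", k)]] <- r$gb
  }
  p2 <- pw_bwd(cache$t1, w$params$pw2, gt2)
  grads$pw2 <- p2$gW
  if (m$bias) grads$pw2b <- p2$gb
  p1 <- pw_bwd(cache$x, w$params$pw1, p2$gx)
  grads$pw1 <- p1$gW
  if (m$bias) grads$pw1b <- p1$gb
  gx <- p1$gx
  if (m$has_proj) {
    pr <- pw_bwd(cache$xs, w$params$proj, gy)
    grads$proj <- pr$gW
    if (m$bias) grads$projb <- pr$gb
    gx <- gx + subsample_bwd(pr$gx, dim(cache$x), m$stride)
  } else {
    gx <- gx + gy
  }
  list(gx = gx, grads = grads[names(w$params)])
}

#' Forward pass of the multi-kernel blueprint-separable convolution block
#'
#' Computes `y = residual(x) + sum_m DW_km(PW_KA(PW_KB(x)))`: the pointwise
#' channel mix comes first and is factorised through a subspace of size
#' `ceiling(mu * C_in)`, then one depthwise convolution per kernel size
#' filters spatially and the responses are summed.  The residual is the
#' identity when input and output shapes agree, otherwise a (strided)
#' pointwise projection.
#'
#' @inheritParams multilayer_dwconv_forward
#' @param w weights from [bsconv_weights()].
#' @return feature map `[H/stride, W/stride, out_channels, B]`.
#' @export
multilayer_bsconv_forward <- function(x, w) {
  x <- as_feature_map(x)
  check_channels(x, w$meta$cin, "multilayer_bsconv_forward")
  .bsconv_fwd(x, w)$y
}

## ---- ESCA attention: spatial gate, then channel gate, in series ----

.sam_fwd <- function(x, w) {
  d <- dim(x)
  r <- pw_fwd(x, w$params$sam_reduce, w$params$sam_reduce_b)
  mp <- maxpool_fwd_cpp(r, 2L, 2L, TRUE)
  cv <- dense_conv_fwd(mp$y, w$params$sam_conv, w$params$sam_conv_b)
  u <- bilinear_resize_fwd_cpp(cv, d[1], d[2])
  srl <- u + r
  l <- pw_fwd(srl, w$params$sam_out, w$params$sam_out_b)
  g <- sigmoid(l)
  y <- x * spatial_gate_full(g, d[3])
  list(y = y, cache = list(x = x, r = r, mp = mp, p = mp$y, srl = srl, g = g))
}

.sam_bwd <- function(w, cache, gy) {
  d <- dim(cache$x)
  grads <- list()
  gfull <- spatial_gate_full(cache$g, d[3])
  gx <- gy * gfull
  gg <- array(apply(gy * cache$x, c(1, 2, 4), sum), c(d[1], d[2], 1L, d[4]))
  gl <- gg * cache$g * (1 - cache$g)
  po <- pw_bwd(cache$srl, w$params$sam_out, gl)
  grads$sam_out <- po$gW
  grads$sam_out_b <- po$gb
  gcv <- bilinear_resize_bwd_cpp(po$gx, dim(cache$p)[1], dim(cache$p)[2])
  # gsrl feeds both the upsample branch and the reduced map directly
  cb <- dense_conv_bwd(cache$p, w$params$sam_conv, gcv)
  grads$sam_conv <- cb$gw
  grads$sam_conv_b <- cb$gb
  gr <- po$gx + maxpool_bwd_cpp(cache$mp$idx, cb$gx, dim(cache$r))
  pr <- pw_bwd(cache$x, w$params$sam_reduce, gr)
  grads$sam_reduce <- pr$gW
  grads$sam_reduce_b <- pr$gb
  list(gx = gx + pr$gx, grads = grads)
}

.cam_fwd <- function(x, w) {
  d <- dim(x)
  v <- gap_fwd(x)
  l <- w$params$cam_mix %*% v + w$params$cam_mix_b
  g <- sigmoid(l)
  y <- x * channel_gate_full(g, d[1], d[2])
  list(y = y, cache = list(x = x, v = v, g = g))
}

.cam_bwd <- function(w, cache, gy) {
  d <- dim(cache$x)
  gfull <- channel_gate_full(cache$g, d[1], d[2])
  gx <- gy * gfull
  gg <- matrix(apply(gy * cache$x, c(3, 4), sum), d[3], d[4])
  gl <- gg * cache$g * (1 - cache$g)
  grads <- list(cam_mix = gl %*% t(cache$v), cam_mix_b = rowSums(gl))
  gv <- t(w$params$cam_mix) %*% gl
  gx <- gx + gap_bwd(gv, d)
  list(gx = gx, grads = grads)
}

.esca_fwd <- function(x, w) {
  s <- .sam_fwd(x, w)
  if (!w$meta$channel_attention)
    return(list(y = s$y, cache = list(sam = s$cache, cam = NULL)))
  cc <- .cam_fwd(s$y, w)
  list(y = cc$y, cache = list(sam = s$cache, cam = cc$cache))
}

.esca_bwd <- function(w, cache, gy) {
  grads <- list()
  if (w$meta$channel_attention) {
    cb <- .cam_bwd(w, cache$cam, gy)
    gy <- cb$gx
    grads <- cb$grads
  }
  sb <- .sam_bwd(w, cache$sam, gy)
  grads <- c(sb$grads, grads)
  list(gx = sb$gx, grads = grads[names(w$params)])
}

#' Spatial attention gate (SAM) forward pass
#'
#' The gate is `sigmoid(PW_out(upsample(conv(maxpool2x2(PW_reduce(x)))) +
#' PW_reduce(x)))`, a single-channel map in (0,1) multiplied into every
#' channel of `x`, so the output magnitude never exceeds the input magnitude.
#'
#' @inheritParams multilayer_dwconv_forward
#' @param w weights from [esca_weights()].
#' @return gated feature map, same shape as `x`.
#' @export
sam_forward <- function(x, w) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2)
    stop("sam_forward: spatial size must be at least 2x2 for the 2x2 max pool",
         call. = FALSE)
  check_channels(x, w$meta$channels, "sam_forward")
  .sam_fwd(x, w)$y
}

#' Channel attention gate (CAM) forward pass
#'
#' Global average pooling compresses space, a 1x1 channel mix and a sigmoid
#' produce one gate value per channel, and the input is multiplied channel by
#' channel.
#'
#' @inheritParams sam_forward
#' @return gated feature map, same shape as `x`.
#' @export
cam_forward <- function(x, w) {
  x <- as_feature_map(x)
  check_channels(x, w$meta$channels, "cam_forward")
  if (!w$meta$channel_attention)
    stop("cam_forward: weights built without the channel gate", call. = FALSE)
  .cam_fwd(x, w)$y
}

#' ESCA attention block forward pass
#'
#' Applies the spatial gate first and the channel gate second, in series:
#' `y = cam_forward(sam_forward(x))`.
#'
#' @inheritParams sam_forward
#' @return gated feature map, same shape as `x`.
#' @export
esca_forward <- function(x, w) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] < 2 || d[2] < 2)
    stop("esca_forward: spatial size must be at least 2x2 for the 2x2 max pool",
         call. = FALSE)
  check_channels(x, w$meta$channels, "esca_forward")
  .esca_fwd(x, w)$y
}
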