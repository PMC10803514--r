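# Internal tensor primitives over feature maps stored as arrays with
# dim = c(H, W, C, B).  Forward functions return the output (and whatever
# the matching backward needs); backwards are hand-derived reverse-mode.

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a private RNG stream, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

# asymmetric same-size padding: left/top floor((k-1)/2), right/bottom ceil
same_pads <- function(k) {
  lo <- (k - 1L) %/% 2L
  hi <- k - 1L - lo
  c(padT = lo, padB = hi, padL = lo, padR = hi)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
sigmoid <- function(x) 1 / (1 + exp(-x))

# pointwise (1x1) convolution: channel mixing only.  W: [Cout, Cin]
pw_fwd <- function(x, W, b = NULL) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  cout <- nrow(W)
  y <- array(0, c(H, Wd, cout, B))
  for (bb in seq_len(B)) {
    xm <- matrix(x[, , , bb], H * Wd, C)
    ym <- xm %*% t(W)
    if (!is.null(b)) ym <- sweep(ym, 2L, b, "+")
    y[, , , bb] <- ym
  }
  y
}

pw_bwd <- function(x, W, gy) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  gx <- array(0, d)
  gW <- matrix(0, nrow(W), ncol(W))
  gb <- numeric(nrow(W))
  for (bb in seq_len(B)) {
    xm <- matrix(x[, , , bb], H * Wd, C)
    gm <- matrix(gy[, , , bb], H * Wd, nrow(W))
    gx[, , , bb] <- gm %*% W
    gW <- gW + t(gm) %*% xm
    gb <- gb + colSums(gm)
  }
  list(gx = gx, gW = gW, gb = gb)
}

# spatial subsampling (stride without a kernel), used by 1x1 stride-2
# residual projections
subsample_fwd <- function(x, stride) {
  if (stride == 1L) return(x)
  d <- dim(x)
  x[seq(1L, d[1], by = stride), seq(1L, d[2], by = stride), , , drop = FALSE]
}

subsample_bwd <- function(gy, xdim, stride) {
  if (stride == 1L) return(gy)
  gx <- array(0, xdim)
  gx[seq(1L, xdim[1], by = stride), seq(1L, xdim[2], by = stride), , ] <- gy
  gx
}

dw_fwd <- function(x, w, b, stride = 1L) {
  k <- dim(w)[1]
  p <- same_pads(k)
  dwconv_fwd_cpp(x, w, b %||% numeric(dim(w)[3]), as.integer(stride),
                 p[["padT"]], p[["padB"]], p[["padL"]], p[["padR"]])
}

dw_bwd <- function(x, w, gy, stride = 1L) {
  k <- dim(w)[1]
  p <- same_pads(k)
  dwconv_bwd_cpp(x, w, gy, as.integer(stride),
                 p[["padT"]], p[["padB"]], p[["padL"]], p[["padR"]])
}

dense_conv_fwd <- function(x, w, b, stride = 1L) {
  k <- dim(w)[1]
  p <- same_pads(k)
  conv2d_fwd_cpp(x, w, b %||% numeric(dim(w)[4]), as.integer(stride),
                 p[["padT"]], p[["padB"]], p[["padL"]], p[["padR"]])
}

dense_conv_bwd <- function(x, w, gy, stride = 1L) {
  k <- dim(w)[1]
  p <- same_pads(k)
  conv2d_bwd_cpp(x, w, gy, as.integer(stride),
                 p[["padT"]], p[["padB"]], p[["padL"]], p[["padR"]])
}

# global max pool: [H,W,C,B] -> value matrix [C,B] plus argmax indices
gmp_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  v <- m[cbind(idx, seq_along(idx))]
  list(v = matrix(v, d[3], d[4]), idx = idx, xdim = d)
}

gmp_bwd <- function(cache, gv) {
  d <- cache$xdim
  gm <- matrix(0, d[1] * d[2], d[3] * d[4])
  gm[cbind(cache$idx, seq_along(cache$idx))] <- as.numeric(gv)
  array(gm, d)
}

# spatial global average pool: [H,W,C,B] -> [C,B]
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

gap_bwd <- function(gv, xdim) {
  n <- xdim[1] * xdim[2]
  gm <- matrix(rep(as.numeric(gv), each = n) / n, n, xdim[3] * xdim[4])
  array(gm, xdim)
}
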