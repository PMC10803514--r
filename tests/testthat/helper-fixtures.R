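# Shared helpers: brute-force convolution oracles, finite-difference
# utilities and small fixture builders.  Everything is generated in code.

ns <- asNamespace("mfdnet")

# nested-loop direct convolution (dense); the independent oracle for the
# Rcpp kernels and for the block forwards
oracle_conv2d <- function(x, w, bias, stride = 1L, pads = NULL) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  if (is.null(pads)) {
    lo <- (kh - 1L) %/% 2L
    pads <- c(lo, kh - 1L - lo, lo, kh - 1L - lo)
  }
  Ho <- (H + pads[1] + pads[2] - kh) %/% stride + 1L
  Wo <- (W + pads[3] + pads[4] - kw) %/% stride + 1L
  y <- array(0, c(Ho, Wo, Cout, B))
  for (b in 1:B) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- bias[co]
    for (ci in 1:Cin) for (ki in 1:kh) for (kj in 1:kw) {
      hi <- (ho - 1L) * stride - pads[1] + ki
      wi <- (wo - 1L) * stride - pads[3] + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci, b] * w[ki, kj, ci, co]
    }
    y[ho, wo, co, b] <- acc
  }
  y
}

# depthwise convolution expressed through the dense oracle via a
# channel-diagonal kernel
oracle_dwconv <- function(x, w, bias, stride = 1L) {
  C <- dim(x)[3]
  k <- dim(w)[1]
  wd <- array(0, c(k, k, C, C))
  for (c in 1:C) wd[, , c, c] <- w[, , c]
  oracle_conv2d(x, wd, bias, stride)
}

# brute-force forward of the multi-kernel depthwise block
oracle_mk_dw_forward <- function(x, w) {
  m <- w$meta
  s <- 0
  for (k in m$kernel_sizes)
    s <- s + oracle_dwconv(x, w$params[[paste0("dw_k", k)]],
                           w$params[[paste0("dwb_k", k)]] %||0% m$channels)
  a <- s * stats::pnorm(s)
  d <- dim(a)
  p <- array(0, c(d[1], d[2], m$pointwise_out, d[4]))
  for (b in 1:d[4]) {
    am <- matrix(a[, , , b], d[1] * d[2], d[3])
    pm <- am %*% t(w$params$pw)
    if (!is.null(w$params$pwb)) pm <- sweep(pm, 2, w$params$pwb, "+")
    p[, , , b] <- pm
  }
  if (m$pointwise_out == m$channels) x + p else p
}

`%||0%` <- function(a, n) if (is.null(a)) numeric(n) else a

# brute-force forward of the blueprint-separable block
oracle_bsconv_forward <- function(x, w) {
  m <- w$meta
  pw_apply <- function(z, W, b) {
    d <- dim(z)
    out <- array(0, c(d[1], d[2], nrow(W), d[4]))
    for (bb in 1:d[4]) {
      zm <- matrix(z[, , , bb], d[1] * d[2], d[3])
      ym <- zm %*% t(W)
      if (!is.null(b)) ym <- sweep(ym, 2, b, "+")
      out[, , , bb] <- ym
    }
    out
  }
  t1 <- pw_apply(x, w$params$pw1, w$params$pw1b)
  t2 <- pw_apply(t1, w$params$pw2, w$params$pw2b)
  d <- 0
  for (k in m$kernel_sizes)
    d <- d + oracle_dwconv(t2, w$params[[paste0("dw_k", k)]],
                           w$params[[paste0("dwb_k", k)]] %||0% m$cout,
                           stride = m$stride)
  if (m$has_proj) {
    xs <- x[seq(1, dim(x)[1], by = m$stride), seq(1, dim(x)[2], by = m$stride), , ,
            drop = FALSE]
    res <- pw_apply(xs, w$params$proj, w$params$projb)
  } else res <- x
  res + d
}

# central finite differences of a scalar function at sampled coordinates
fd_gradient <- function(f, x, idx, eps = 1e-4) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

max_rel_err <- function(a, b, floor = 1e-4) max(abs(a - b) / pmax(floor, abs(a) + abs(b)))

# write a small synthetic manifest (images + boxes + labels) to dir
make_tiny_manifest_dir <- function(dir, n = 3L, size = 32L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    img <- matrix(runif(size * size), size, size)
    iid <- sprintf("t%02d", i)
    save_gray_image(img, file.path(dir, paste0(iid, ".png")))
    write_yolo_boxes(data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                                w = 0.5, h = 0.5),
                     file.path(dir, paste0(iid, ".txt")))
    data.frame(patient_id = sprintf("p%02d", (i + 1L) %/% 2L), image_id = iid,
               ER = i %% 2L, PR = 1L, HER2 = 0L, KI67 = (i > 1L) * 1L,
               stringsAsFactors = FALSE)
  })
  write_label_table(do.call(rbind, rows), file.path(dir, "labels.csv"))
  dir
}

label_matrix <- function(manifest) {
  do.call(rbind, lapply(manifest$records, function(r)
    as.matrix(r$label[, c("ER", "PR", "HER2", "KI67")])))
}
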