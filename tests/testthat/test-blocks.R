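test_that("multi-kernel depthwise block matches the nested-loop oracle", {
  set.seed(11)
  for (rep in 1:4) {
    C <- sample(2:4, 1); B <- sample(1:3, 1)
    H <- sample(7:9, 1); W <- sample(7:9, 1)
    w <- multikernel_dw_weights(C, c(3L, 4L, 6L))
    x <- array(rnorm(H * W * C * B), c(H, W, C, B))
    expect_lt(max(abs(multilayer_dwconv_forward(x, w) -
                        oracle_mk_dw_forward(x, w))), 1e-5)
  }
  # zero weights, zero bias -> exact identity (GELU(0)=0, residual passes)
  wz <- multikernel_dw_weights(3L, init = "zero")
  x <- array(rnorm(7 * 7 * 3 * 2), c(7, 7, 3, 2))
  expect_identical(multilayer_dwconv_forward(x, wz), x)
  # single 1x1 kernel = 1, pointwise = identity -> y = x + GELU(x)
  w1 <- multikernel_dw_weights(2L, kernel_sizes = 1L, init = "zero")
  w1$params$dw_k1[] <- 1
  w1$params$pw <- diag(2)
  x2 <- array(rnorm(5 * 5 * 2 * 1), c(5, 5, 2, 1))
  expect_equal(multilayer_dwconv_forward(x2, w1), x2 + x2 * pnorm(x2),
               tolerance = 1e-12)
  # channel mismatch raises a shape error naming the counts
  expect_error(multilayer_dwconv_forward(x2, multikernel_dw_weights(5L)),
               "expected C=5.*got C=2")
})

test_that("blueprint-separable block matches the oracle and its pointwise pair composes", {
  set.seed(12)
  for (stride in c(1L, 2L)) for (rep in 1:3) {
    cin <- sample(2:4, 1); cout <- sample(2:4, 1)
    w <- bsconv_weights(cin, cout, stride = stride)
    x <- array(rnorm(8 * 8 * cin * 2), c(8, 8, cin, 2))
    expect_lt(max(abs(multilayer_bsconv_forward(x, w) -
                        oracle_bsconv_forward(x, w))), 1e-5)
  }
  # identity pointwise factors + zero depthwise -> y = x
  wz <- bsconv_weights(4L, 4L, mu = 0.9, init = "zero")
  expect_identical(wz$meta$qprime, 4L)
  wz$params$pw1 <- diag(4); wz$params$pw2 <- diag(4)
  x <- array(rnorm(7 * 7 * 4 * 2), c(7, 7, 4, 2))
  expect_identical(multilayer_bsconv_forward(x, wz), x)
  # composing PW_A then PW_B equals one pointwise conv with the product matrix
  w <- bsconv_weights(3L, 5L, mu = 0.5)
  t1 <- ns$pw_fwd(x[, , 1:3, , drop = FALSE], w$params$pw1, NULL)
  t2 <- ns$pw_fwd(t1, w$params$pw2, NULL)
  direct <- ns$pw_fwd(x[, , 1:3, , drop = FALSE],
                      w$params$pw2 %*% w$params$pw1, NULL)
  expect_equal(t2, direct, tolerance = 1e-12)
})

test_that("the composed pointwise map of BSConv has rank at most Q'", {
  set.seed(13)
  for (cin in c(4L, 8L)) for (mu in c(0.25, 0.5)) {
    w <- bsconv_weights(cin, 2L * cin, mu = mu)
    K <- w$params$pw2 %*% w$params$pw1
    expect_lte(qr(K)$rank, ceiling(mu * cin))
  }
})

test_that("spatial gate bounds, restores odd sizes, and zero input gives half gate", {
  set.seed(14)
  w <- esca_weights(8L, reduction = 4L)
  # zero input -> all layer outputs zero (biases start at 0) -> gate 0.5, y = 0
  x0 <- array(0, c(6, 6, 8, 2))
  expect_identical(sam_forward(x0, w), x0)
  # strict contraction wherever x != 0
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  y <- sam_forward(x, w)
  expect_true(all(abs(y) < abs(x) | x == 0))
  # size-matching across odd and even spatial sizes
  for (H in 2:9) for (W in c(2L, 5L, 9L)) {
    xs <- array(rnorm(H * W * 8), c(H, W, 8, 1))
    expect_identical(dim(sam_forward(xs, w)), c(H, W, 8L, 1L))
  }
  expect_error(sam_forward(array(0, c(1, 4, 8, 1)), w), "2x2")
})

test_that("channel gate averages exactly and scales per channel", {
  set.seed(15)
  w <- esca_weights(4L, reduction = 2L)
  # constant channels: GAP returns the constants exactly
  x <- array(0, c(5, 5, 4, 2))
  for (c in 1:4) for (b in 1:2) x[, , c, b] <- c + 10 * b
  expect_equal(ns$gap_fwd(x), matrix(c(11:14, 21:24), 4, 2), tolerance = 1e-12)
  # zero mixing weight -> gate exactly 0.5 -> y = x/2
  wz <- esca_weights(4L, reduction = 2L, init = "zero")
  xr <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  expect_equal(cam_forward(xr, wz), xr / 2, tolerance = 1e-12)
  # y/x ratio is constant within each (channel, batch) slice
  y <- cam_forward(xr, w)
  for (c in 1:4) for (b in 1:2) {
    ratio <- y[, , c, b] / xr[, , c, b]
    expect_lt(diff(range(ratio)), 1e-10)
    expect_gt(min(ratio), 0)
    expect_lt(max(ratio), 1)
  }
})

test_that("ESCA is the series composition of the two gates and contracts", {
  set.seed(16)
  w <- esca_weights(8L, reduction = 4L)
  x <- array(rnorm(2 * 8 * 16 * 16), c(16, 16, 8, 2))
  y <- esca_forward(x, w)
  expect_identical(dim(y), dim(x))
  expect_equal(y, cam_forward(sam_forward(x, w), w), tolerance = 1e-12)
  expect_true(all(abs(y) <= abs(x)))
  expect_identical(esca_forward(array(0, c(4, 4, 8, 1)), w),
                   array(0, c(4, 4, 8, 1)))
})

test_that("analytic block gradients match central finite differences", {
  set.seed(17)
  checks <- list(
    list(w = multikernel_dw_weights(3L), fwd = ns$.mk_dw_fwd, bwd = ns$.mk_dw_bwd,
         dim = c(7, 7, 3, 2)),
    list(w = bsconv_weights(3L, 6L, stride = 2L), fwd = ns$.bsconv_fwd,
         bwd = ns$.bsconv_bwd, dim = c(8, 8, 3, 2)),
    list(w = esca_weights(8L, reduction = 4L), fwd = ns$.esca_fwd,
         bwd = ns$.esca_bwd, dim = c(6, 6, 8, 2))
  )
  for (ck in checks) {
    x <- array(rnorm(prod(ck$dim)), ck$dim)
    r <- ck$fwd(x, ck$w)
    tm <- array(rnorm(length(r$y)), dim(r$y))
    bw <- ck$bwd(ck$w, r$cache, tm)
    f <- function(xx) sum(ck$fwd(xx, ck$w)$y * tm)
    idx <- sample(length(x), 20)
    expect_lt(max_rel_err(fd_gradient(f, x, idx), bw$gx[idx]), 1e-3)
    for (nm in names(ck$w$params)) {
      pv <- ck$w$params[[nm]]
      pidx <- sample(length(pv), min(6, length(pv)))
      fp <- function(vv) {
        wp <- ck$w; wp$params[[nm]] <- vv
        sum(ck$fwd(x, wp)$y * tm)
      }
      num <- vapply(pidx, function(i) {
        vp <- pv; vp[i] <- vp[i] + 1e-4
        vm <- pv; vm[i] <- vm[i] - 1e-4
        (fp(vp) - fp(vm)) / 2e-4
      }, numeric(1))
      expect_lt(max_rel_err(num, bw$grads[[nm]][pidx]), 1e-3)
    }
  }
})

test_that("parameter counting enumerates stored arrays exactly", {
  # worked closed form: C=8, sizes {3,4,6}, pointwise 8->8, no bias
  w <- multikernel_dw_weights(8L, c(3L, 4L, 6L), bias = FALSE)
  expect_identical(count_block_params(w), 8L * (9L + 16L + 36L) + 64L)  # 552
  expect_identical(count_block_params(w), 552L)
  # minimal case: sizes {3}, C=1, pointwise 1->1
  expect_identical(count_block_params(multikernel_dw_weights(1L, 3L, bias = FALSE)),
                   10L)
  # random configurations vs direct enumeration
  set.seed(18)
  for (rep in 1:8) {
    C <- sample(1:9, 1)
    ks <- sort(sample(2:6, sample(1:3, 1)))
    bias <- sample(c(TRUE, FALSE), 1)
    w <- multikernel_dw_weights(C, ks, bias = bias)
    expect_identical(count_block_params(w),
                     sum(vapply(w$params, length, integer(1))))
    expected <- C * sum(ks^2) + C * C + if (bias) C * length(ks) + C else 0L
    expect_identical(count_block_params(w), as.integer(expected))
    wb <- bsconv_weights(C, 2L * C, ks, bias = bias)
    expect_identical(count_block_params(wb),
                     sum(vapply(wb$params, length, integer(1))))
  }
  # multilayer variant beats a dense 6x6 conv for all C >= 2:
  # C*(9+16+36) + C^2 < 36*C^2
  for (C in 2:32) {
    ml <- C * 61 + C^2
    dense <- 36 * C^2
    expect_lt(ml, dense)
  }
})
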