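tiny_cfg <- function(...) mfdnet_config(input_size = 16L, stem_channels = 4L,
                                        fused_width = 8L, fc_dim = 8L, seed = 3L, ...)

test_that("build_model assembles deterministically and books its parameters", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(ns$get_params(m1$blocks), ns$get_params(m2$blocks))
  # one DL/dL/BL triple per stage
  m_one <- build_model(tiny_cfg(num_stages = 1L))
  expect_length(m_one$blocks$stages, 1L)
  expect_named(m_one$blocks$stages[[1]], c("dw", "dpw1", "dpw2", "bs"))
  # parameter total equals the sum over blocks
  total <- count_block_params(m1$blocks)
  parts <- sum(model_summary(m1)$params)
  expect_identical(total, as.integer(parts))
  expect_error(mfdnet_config(num_stages = 0L), "num_stages")
  expect_error(mfdnet_config(compression_ratio = 1.2), "compression_ratio")
  expect_error(mfdnet_config(input_size = 50L, num_stages = 3L), "divisible")
})

test_that("a distillation stage follows the channel compression schedule", {
  cfg <- mfdnet_config(input_size = 56L, stem_channels = 32L, seed = 1L,
                       num_stages = 3L)
  m <- build_model(cfg)
  x <- array(rnorm(56 * 56 * 32), c(56, 56, 32, 1))
  st <- distill_stage_forward(m$blocks$stages[[1]], x)
  expect_identical(dim(st$distilled), c(56L, 56L, 16L, 1L))  # ratio 0.5 of 32
  expect_identical(dim(st$depth), c(56L, 56L, 64L, 1L))      # doubled channels
  expect_true(all(is.finite(st$distilled)))
  expect_true(all(is.finite(st$depth)))
  # all-zero stage weights: distilled output zero, depth passes input through
  stz <- m$blocks$stages[[1]]
  for (nm in names(stz$dw$params)) stz$dw$params[[nm]][] <- 0
  for (nm in names(stz$dpw1$params)) stz$dpw1$params[[nm]][] <- 0
  for (nm in names(stz$dpw2$params)) stz$dpw2$params[[nm]][] <- 0
  zz <- bsconv_weights(32L, 32L, mu = 0.97, init = "zero")  # qprime = 32
  zz$params$pw1 <- diag(32); zz$params$pw2 <- diag(32)
  stz$bs <- zz
  st0 <- distill_stage_forward(stz, x)
  expect_true(all(st0$distilled == 0))
  expect_identical(st0$depth, x)
})

test_that("fusion concatenates channels then compresses to the fused width", {
  set.seed(31)
  a <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  b <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  w <- ns$pw_weights(12L, 6L)
  y <- fuse_features(list(a), b, w)
  expect_identical(dim(y), c(8L, 8L, 6L, 2L))
  # pre-compression concat has C = 12: identity-padded compression returns
  # the first input's channels unchanged
  wid <- ns$pw_weights(12L, 4L, bias = FALSE)
  wid$params$W <- cbind(diag(4), matrix(0, 4, 8))
  ysel <- fuse_features(list(a), b, wid)
  expect_equal(ysel, a, tolerance = 1e-12)
  # multi-resolution inputs are pooled to the target resolution
  hi <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  w2 <- ns$pw_weights(10L, 5L)
  y2 <- fuse_features(list(hi), b, w2)
  expect_identical(dim(y2), c(8L, 8L, 5L, 2L))
  bad <- array(rnorm(6 * 8 * 2 * 2), c(6, 8, 2, 2))
  expect_error(fuse_features(list(bad), b, w2), "not integer multiples")
})

test_that("forward pass obeys the head contract on a batch of 8", {
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  set.seed(32)
  x <- array(runif(16 * 16 * 8), c(16, 16, 8))
  out <- model_forward(m, x)
  expect_named(out$logits, c("ER", "PR", "HER2", "KI67"))
  for (nm in names(out$logits)) {
    expect_identical(dim(out$logits[[nm]]), c(8L, 2L))
    expect_equal(rowSums(out$probs[[nm]]), rep(1, 8), tolerance = 1e-6)
  }
  # duplicated images give identical rows in every head
  x[, , 2] <- x[, , 1]
  out2 <- model_forward(m, x)
  for (nm in names(out2$logits))
    expect_equal(out2$logits[[nm]][1, ], out2$logits[[nm]][2, ], tolerance = 1e-12)
  expect_error(model_forward(m, array(runif(8 * 8 * 2), c(8, 8, 2))),
               "expected 16x16")
})

test_that("head outputs are permutation-equivariant over the batch", {
  m <- build_model(tiny_cfg())
  set.seed(33)
  x <- array(runif(16 * 16 * 5), c(16, 16, 5))
  perm <- c(4, 1, 5, 2, 3)
  o1 <- model_forward(m, x)
  o2 <- model_forward(m, x[, , perm])
  for (nm in names(o1$logits))
    expect_equal(o2$logits[[nm]], o1$logits[[nm]][perm, ], tolerance = 1e-12)
})

test_that("end-to-end analytic gradients match finite differences on a tiny model", {
  m <- build_model(tiny_cfg())
  set.seed(34)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 2, 4,
              dimnames = list(NULL, c("ER", "PR", "HER2", "KI67")))
  fw <- ns$.model_fwd(m, x)
  lg <- ns$batch_loss_grad(fw$logits, y, "per_head_ce")
  gr <- ns$.model_bwd(m, fw$cache, lg$glogits)
  gp <- ns$get_params(m$blocks)
  gflat <- unlist(gr, use.names = FALSE)
  pflat <- unlist(gp, use.names = FALSE)
  expect_length(gflat, length(pflat))
  refill <- function(vec) {
    i <- 0L
    walk <- function(s) {
      if (is.numeric(s)) {
        v <- vec[i + seq_along(s)]; i <<- i + length(s)
        attributes(v) <- attributes(s); return(v)
      }
      lapply(s, walk)
    }
    walk(gp)
  }
  lossfun <- function(vec) {
    mm <- m
    mm$blocks <- ns$set_params(m$blocks, refill(vec))
    ns$batch_loss_grad(ns$.model_fwd(mm, x)$logits, y, "per_head_ce")$loss
  }
  idx <- sample(length(pflat), 40)
  num <- vapply(idx, function(i) {
    vp <- pflat; vp[i] <- vp[i] + 1e-4
    vm <- pflat; vm[i] <- vm[i] - 1e-4
    (lossfun(vp) - lossfun(vm)) / 2e-4
  }, numeric(1))
  expect_lt(max_rel_err(num, gflat[idx], floor = 1e-3), 1e-3)
})

test_that("ablation configurations strictly shrink the parameter count", {
  full <- count_block_params(build_model(tiny_cfg())$blocks)
  no_esca <- count_block_params(build_model(tiny_cfg(use_esca = FALSE))$blocks)
  no_distill <- count_block_params(build_model(tiny_cfg(use_distill = FALSE))$blocks)
  sam_only <- count_block_params(
    build_model(tiny_cfg(esca_channel_attention = FALSE))$blocks)
  expect_lt(no_esca, full)
  expect_lt(no_distill, full)
  expect_lt(sam_only, full)
  expect_lt(no_esca, sam_only)
})

test_that("checkpoints round-trip through the named-array archive + JSON sidecar", {
  m <- build_model(tiny_cfg())
  dir <- withr::local_tempdir()
  save_checkpoint(m, file.path(dir, "ck"))
  m2 <- load_checkpoint(file.path(dir, "ck"))
  expect_identical(ns$get_params(m2$blocks), ns$get_params(m$blocks))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  o1 <- model_forward(m, x); o2 <- model_forward(m2, x)
  expect_identical(o1$logits, o2$logits)
})
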