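test_that("soft-max is symmetric, stable and matches closed forms", {
  expect_equal(softmax_probs(c(0, 0, 0)), rep(1 / 3, 3), tolerance = 1e-12)
  # huge logits do not overflow
  p <- softmax_probs(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_equal(softmax_probs(c(log(1), log(3))), c(0.25, 0.75), tolerance = 1e-12)
  # rows always sum to 1
  set.seed(21)
  z <- matrix(rnorm(50 * 4, sd = 20), 50, 4)
  expect_equal(rowSums(softmax_probs(z)), rep(1, 50), tolerance = 1e-9)
})

test_that("cross-entropy matches closed forms and decreases in the true-class probability", {
  expect_equal(cross_entropy_loss(c(0, 1, 0), c(0, 1, 0)), 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), c(1, 0)), log(2),
               tolerance = 1e-12, ignore_attr = TRUE)
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) cross_entropy_loss(c(p, 1 - p), c(1, 0)), numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_warning(cross_entropy_loss(c(0, 1), c(1, 0)), "clamped")
})

test_that("gradient of cross-entropy after soft-max is sigma minus y", {
  set.seed(22)
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    z <- rnorm(C, sd = 2)
    y <- as.integer(seq_len(C) == sample(C, 1))
    ana <- softmax_probs(z) - y
    num <- vapply(seq_len(C), function(i) {
      zp <- z; zp[i] <- zp[i] + 1e-6
      zm <- z; zm[i] <- zm[i] - 1e-6
      (cross_entropy_loss(softmax_probs(zp), y) -
         cross_entropy_loss(softmax_probs(zm), y)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(num - ana)), 1e-6)
  }
})

test_that("concurrent soft-max reduces to soft-max and honours its limits", {
  set.seed(23)
  # r = 0, one-hot y: every scored (positive-tag) entry -- the only entries
  # that enter the concurrent cross-entropy -- equals the plain soft-max,
  # so the two losses coincide exactly
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    z <- rnorm(C, sd = 3)
    tgt <- sample(C, 1)
    y <- as.integer(seq_len(C) == tgt)
    r0 <- matrix(0, C, C)
    s <- concurrent_softmax_probs(z, y, r0)
    expect_equal(s[tgt], softmax_probs(z)[tgt], tolerance = 1e-12)
    expect_equal(-sum(y * log(s)),
                 cross_entropy_loss(softmax_probs(z), y),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # full co-occurrence suppresses the whole denominator
  z <- rnorm(4)
  r1 <- matrix(1, 4, 4)
  expect_equal(concurrent_softmax_probs(z, c(0, 0, 0, 0), r1), rep(1, 4),
               tolerance = 1e-12)
  # symmetric two-class case
  expect_equal(concurrent_softmax_probs(c(0, 0), c(1, 0), matrix(0, 2, 2))[1],
               0.5, tolerance = 1e-12)
  # every score lies in (0, 1]
  for (rep in 1:20) {
    C <- 4L
    z <- rnorm(C, sd = 4)
    y <- rbinom(C, 1, 0.5)
    r <- matrix(runif(C * C), C, C); r <- (r + t(r)) / 2
    s <- concurrent_softmax_probs(z, y, r)
    expect_true(all(s > 0 & s <= 1 + 1e-12))
  }
  # analytic gradient of the concurrent loss matches finite differences
  z <- rnorm(4); y <- c(1, 0, 1, 0)
  r <- matrix(runif(16, 0, 0.6), 4, 4); r <- (r + t(r)) / 2; diag(r) <- 0
  ana <- ns$concurrent_softmax_grad(z, y, r)
  num <- vapply(1:4, function(i) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    (-sum(y * log(concurrent_softmax_probs(zp, y, r))) +
       sum(y * log(concurrent_softmax_probs(zm, y, r)))) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(num - ana)), 1e-6)
})

test_that("co-occurrence estimation equals a brute-force pairwise counter", {
  # perfect co-occurrence and disjoint tags
  lab <- cbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(0, 0, 0))
  r <- estimate_cooccurrence(lab)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], 0)
  expect_error(estimate_cooccurrence(lab[0, , drop = FALSE]), "empty")
  # random tables vs brute force up to N = 1000
  set.seed(24)
  for (rep in 1:5) {
    N <- sample(50:1000, 1)
    lab <- matrix(rbinom(N * 4, 1, runif(1, 0.2, 0.8)), N, 4)
    r <- estimate_cooccurrence(lab)
    expect_true(isSymmetric(unname(r)))
    for (i in 1:4) for (j in 1:4) {
      brute <- sum(lab[, i] == 1 & lab[, j] == 1) / N
      expect_equal(unname(r[i, j]), brute, tolerance = 1e-12)
    }
  }
  # independent tags: joint close to the product of marginals
  set.seed(25)
  lab <- cbind(rbinom(1e4, 1, 0.5), rbinom(1e4, 1, 0.4))
  r <- estimate_cooccurrence(lab)
  expect_lt(abs(r[1, 2] - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))
})

test_that("SGD steps, refuses non-finite gradients, and contracts a quadratic", {
  expect_equal(sgd_update(1.0, 0.0, 0.1), 1.0)
  expect_equal(sgd_update(1.0, 2.0, 0.1), 0.8)
  expect_warning(w2 <- sgd_update(c(1, 2), c(NaN, 0), 0.1), "refused")
  expect_equal(as.numeric(w2), c(1, 2))
  expect_true(attr(w2, "refused"))
  # L = w^2, 50 steps of gamma = 0.1 from w = 1: geometric decay (1-2*0.1)^50
  w <- 1
  for (i in 1:50) w <- sgd_update(w, 2 * w, 0.1)
  expect_equal(w, 0.8^50, tolerance = 1e-12)
  expect_lt(abs(w), 1e-4)
  # nested structures update elementwise
  nest <- list(a = matrix(1, 2, 2), b = list(c = rep(2, 3)))
  gr <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  up <- sgd_update(nest, gr, 0.5)
  expect_equal(up$a, matrix(0.5, 2, 2))
  expect_equal(up$b$c, rep(1.5, 3))
})

test_that("confusion metrics match the printed worked example and hand counts", {
  # printed precision/recall pair reproduces the printed F1 (percent scale)
  expect_equal(round(f1_score(89.33, 75.63), 2), 81.91)
  # hand-counted confusion
  m <- confusion_and_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                             c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(m[c("tp", "fp", "fn", "tn")], list(tp = 3L, fp = 1L, fn = 1L, tn = 5L))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  # perfect predictions
  mp <- confusion_and_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(mp[c("precision", "recall", "accuracy", "f1")]),
               c(precision = 1, recall = 1, accuracy = 1, f1 = 1))
  # undefined ratios flagged as 0
  mu <- confusion_and_metrics(c(0, 0), c(0, 0))
  expect_equal(mu$precision, 0)
  expect_true("precision" %in% mu$undefined)
  expect_error(confusion_and_metrics(c(1, 0), c(1)), "length mismatch")
})

test_that("F1 lies between precision and recall (harmonic-mean property)", {
  set.seed(26)
  for (rep in 1:100) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})
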