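# Speckle-textured ultrasound phantom generator.  Each image holds one
# hypoechoic nodule; four latent patient attributes (nodule size,
# echogenicity drop, margin irregularity, elongation) drive the four binary
# immunomarker labels through calibrated logistic models, with a shared
# patient factor inducing configurable pairwise label co-occurrence.

smooth_field <- function(n, sigma, margin = 8L) {
  # smoothed standard-normal field, generated oversized then cropped so the
  # zero-padded convolution borders never reach the image
  m <- n + 2L * margin
  g <- array(stats::rnorm(m * m), c(m, m, 1L, 1L))
  k <- max(3L, 2L * ceiling(2 * sigma) + 1L)
  ax <- seq(-(k - 1) / 2, (k - 1) / 2)
  kern <- exp(-ax^2 / (2 * sigma^2))
  kern2 <- outer(kern, kern)
  kern2 <- kern2 / sqrt(sum(kern2^2))   # keep unit variance
  w <- array(kern2, c(k, k, 1L, 1L))
  sm <- dense_conv_fwd(g, w, NULL)
  sm[margin + seq_len(n), margin + seq_len(n), 1L, 1L]
}

#' Phantom image specification
#'
#' @param size square image edge in pixels.
#' @param center nodule centre `(row, col)` in pixels.
#' @param semi_axes ellipse semi-axes `(a, b)` in pixels.
#' @param rotation ellipse rotation in degrees.
#' @param echogenicity_drop fractional intensity drop inside the nodule,
#'   in `[0, 1)`.
#' @param irregularity margin irregularity amplitude as a fraction of the
#'   local radius (radial sinusoid perturbation).
#' @param edge_width margin transition width in pixels; small values give a
#'   circumscribed (sharp) margin, large values an indistinct one.
#' @param background_level mean tissue intensity before speckle.
#' @param speckle_smoothing Gaussian smoothing sd (pixels) of the two
#'   quadrature fields whose Rayleigh envelope forms the speckle.
#' @param seed image seed.
#' @return a `phantom_spec` list, validated.
#' @export
phantom_spec <- function(size = 96L, center = c(size / 2, size / 2),
                         semi_axes = c(14, 11), rotation = 0,
                         echogenicity_drop = 0.5, irregularity = 0.1,
                         edge_width = 1.5, background_level = 0.55,
                         speckle_smoothing = 0.9, seed = 1L) {
  stopifnot(size >= 16, echogenicity_drop >= 0, echogenicity_drop < 1,
            irregularity >= 0, irregularity < 0.5, all(semi_axes > 0),
            edge_width > 0)
  reach <- max(semi_axes) * (1 + irregularity) + 2 * edge_width + 2
  if (center[1] - reach < 0 || center[1] + reach > size ||
      center[2] - reach < 0 || center[2] + reach > size)
    stop("phantom_spec: nodule (including irregular margin) would exit the frame")
  structure(list(size = as.integer(size), center = center,
                 semi_axes = semi_axes, rotation = rotation,
                 echogenicity_drop = echogenicity_drop,
                 irregularity = irregularity, edge_width = edge_width,
                 background_level = background_level,
                 speckle_smoothing = speckle_smoothing,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one speckle phantom image with a hypoechoic nodule
#'
#' The background is a smooth tissue field multiplied by a Rayleigh-envelope
#' speckle texture; the nodule region -- an ellipse whose boundary radius is
#' perturbed by a random low-order sinusoid of relative amplitude
#' `irregularity` -- is darkened by factor `(1 - echogenicity_drop)` with a
#' soft edge.  Deterministic under `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`[0, 1]` matrix) and `box` (single-row YOLO
#'   box data frame tightly bounding the nodule).
#' @export
generate_phantom_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    n <- spec$size
    tissue <- spec$background_level * (1 + 0.05 * smooth_field(n, 6))
    g1 <- smooth_field(n, spec$speckle_smoothing)
    g2 <- smooth_field(n, spec$speckle_smoothing)
    env <- sqrt(g1^2 + g2^2)
    speckle <- env / mean(env)
    img <- tissue * speckle

    # irregular ellipse mask: elliptical radius perturbed by sinusoids
    th <- spec$rotation * pi / 180
    rows <- matrix(seq_len(n) - 0.5 - spec$center[1], n, n)
    cols <- matrix(seq_len(n) - 0.5 - spec$center[2], n, n, byrow = TRUE)
    xr <- cos(th) * cols + sin(th) * rows
    yr <- -sin(th) * cols + cos(th) * rows
    rho <- sqrt((xr / spec$semi_axes[1])^2 + (yr / spec$semi_axes[2])^2)
    ang <- atan2(yr, xr)
    nharm <- 3L
    ms <- sample(3:7, nharm)
    amp <- stats::runif(nharm); amp <- amp / sum(amp)
    ph <- stats::runif(nharm, 0, 2 * pi)
    pert <- Reduce(`+`, lapply(seq_len(nharm), function(i)
      amp[i] * sin(ms[i] * ang + ph[i])))
    boundary <- 1 + spec$irregularity * pert
    edge_w <- spec$edge_width / mean(spec$semi_axes)
    inside <- 1 / (1 + exp((rho - boundary) / edge_w))
    img <- img * (1 - spec$echogenicity_drop * inside)
    img <- pmin(pmax(img, 0), 1)

    mask <- inside > 0.5
    ri <- range(which(rowSums(mask) > 0)); ci <- range(which(colSums(mask) > 0))
    box <- data.frame(class_id = 0L,
                      cx = (ci[1] - 1 + ci[2]) / 2 / n,
                      cy = (ri[1] - 1 + ri[2]) / 2 / n,
                      w = (ci[2] - ci[1] + 1) / n,
                      h = (ri[2] - ri[1] + 1) / n)
    list(image = img, box = box)
  })
}

## ---- cohort / label model ----

#' Cohort specification for the synthetic patient population
#'
#' Each patient carries four standard-normal latent attributes (size,
#' echogenicity, margin irregularity, elongation) plus a shared factor `u`.
#' Index `k` is positive with probability
#' `plogis(intercept_k + slope_k * attribute_k + lambda_k * u)`; the
#' intercepts are calibrated by root-finding on the Gauss-Hermite integral of
#' the logistic-normal marginal so the population frequencies match
#' `marginals` to well under 0.5%.
#'
#' The `"paper-cohort"` preset uses the reported patient statistics:
#' ER+ 79.8%, PR+ 72.2%, HER-2 severe 49.6% (scores 2+/3+), Ki-67 severe
#' 70.2% (proliferation index >= 14%, i.e. intermediate plus high).
#'
#' @param n_patients number of patients (preset 294).
#' @param n_images total images, distributed over patients (preset 500).
#' @param marginals named vector of target positive frequencies for
#'   ER, PR, HER2, KI67.
#' @param slopes named vector of logistic loadings of each index on its
#'   latent attribute; the default 25 makes the image-label association
#'   nearly deterministic so classification difficulty reflects the model,
#'   not label noise.
#' @param cooccurrence latent correlation in `[0, 1)` between the four index
#'   logits, induced by a shared patient factor (0 = labels pairwise
#'   independent; default 0.02 = mild positive co-occurrence, keeping the
#'   labels nearly image-determined).
#' @param image_size phantom edge in pixels.
#' @param seed cohort seed.
#' @param preset `"paper-cohort"` fills `n_patients`, `n_images` and
#'   `marginals` with the reported cohort statistics; `"custom"` uses the
#'   arguments as given.
#' @return a `cohort_spec` with calibrated `intercepts`.
#' @export
cohort_spec <- function(n_patients = 294L, n_images = 500L,
                        marginals = c(ER = 0.798, PR = 0.722,
                                      HER2 = 0.496, KI67 = 0.702),
                        slopes = c(ER = 25, PR = 25, HER2 = 25, KI67 = 25),
                        cooccurrence = 0.02, image_size = 96L, seed = 1L,
                        preset = c("custom", "paper-cohort")) {
  preset <- match.arg(preset)
  if (preset == "paper-cohort") {
    n_patients <- 294L; n_images <- 500L
    marginals <- c(ER = 0.798, PR = 0.722, HER2 = 0.496, KI67 = 0.702)
  }
  stopifnot(all(marginals > 0), all(marginals < 1),
            all(names(marginals) == LABEL_COLUMNS),
            all(slopes > 0), cooccurrence >= 0, cooccurrence < 1,
            n_patients >= 1, n_images >= n_patients)
  lambdas <- vapply(LABEL_COLUMNS, function(k)
    cooccurrence_lambda(slopes[[k]], cooccurrence), numeric(1))
  intercepts <- vapply(LABEL_COLUMNS, function(k)
    calibrate_intercept(marginals[[k]], sqrt(slopes[[k]]^2 + lambdas[[k]]^2)),
    numeric(1))
  structure(list(n_patients = as.integer(n_patients),
                 n_images = as.integer(n_images),
                 marginals = marginals, slopes = slopes,
                 intercepts = intercepts, cooccurrence = cooccurrence,
                 lambdas = lambdas,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "cohort_spec")
}

# shared-factor loading giving latent correlation rho between index logits
cooccurrence_lambda <- function(slope, rho) slope * sqrt(rho / (1 - rho))

# solve E[plogis(b + sd * Z)] = target, Z ~ N(0,1), by root-finding on the
# latent integral; adaptive quadrature because the integrand approaches a
# step function for steep slopes, where fixed Gauss-Hermite rules are biased
calibrate_intercept <- function(target, sd) {
  marg <- function(b)
    stats::integrate(function(z) stats::plogis(b + sd * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  stats::uniroot(function(b) marg(b) - target, c(-20 * (1 + sd), 20 * (1 + sd)),
                 tol = 1e-10)$root
}

#' Draw per-patient latent attributes
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @return data frame with standard-normal columns `t_size`, `t_echo`,
#'   `t_margin`, `t_elong` and the shared factor `u`.
#' @export
draw_patient_attributes <- function(n, seed = 1L) {
  with_local_seed(seed, {
    data.frame(t_size = stats::rnorm(n), t_echo = stats::rnorm(n),
               t_margin = stats::rnorm(n), t_elong = stats::rnorm(n),
               u = stats::rnorm(n))
  })
}

#' Sample the four binary labels from patient attributes
#'
#' Index assignments: ER loads on echogenicity, PR on size, HER-2 on margin
#' irregularity, Ki-67 on elongation, each
#' `~ Bernoulli(plogis(intercept + slope * attribute + lambda * u))` with
#' `u` the shared patient factor.  Because the four attributes are
#' independent, labels are pairwise independent when `cooccurrence = 0`.
#'
#' @param attributes data frame from [draw_patient_attributes()] (columns
#'   `t_size`, `t_echo`, `t_margin`, `t_elong`, `u`).
#' @param cohort a [cohort_spec()].
#' @param seed RNG seed for the Bernoulli draws.
#' @return integer 0/1 matrix with columns ER, PR, HER2, KI67.
#' @export
sample_labels <- function(attributes, cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  att <- list(ER = attributes$t_echo, PR = attributes$t_size,
              HER2 = attributes$t_margin, KI67 = attributes$t_elong)
  n <- nrow(attributes)
  with_local_seed(seed, {
    out <- sapply(LABEL_COLUMNS, function(k) {
      p <- stats::plogis(cohort$intercepts[[k]] + cohort$slopes[[k]] * att[[k]] +
                           cohort$lambdas[[k]] * attributes$u)
      as.integer(stats::runif(n) < p)
    })
    matrix(out, nrow = n, dimnames = list(NULL, LABEL_COLUMNS))
  })
}

# map latent attributes to physical nodule parameters; ranges chosen so the
# nodule plus its irregular margin never clips the training window
attributes_to_phantom <- function(att, image_size) {
  scale <- image_size / 96
  r <- pmin(pmax(12 * exp(0.18 * att$t_size), 8), 17) * scale
  # aspect is kept >= 1 and monotone in the latent: under the random nodule
  # rotation only the magnitude of the elongation is observable
  aspect <- 1 + 2.2 * stats::plogis(1.5 * att$t_elong)
  list(semi_axes = c(r * sqrt(aspect), r / sqrt(aspect)),
       echogenicity_drop = 0.35 + 0.50 * stats::plogis(1.2 * att$t_echo),
       irregularity = 0.02 + 0.33 * stats::plogis(att$t_margin),
       edge_width = (0.6 + 5.0 * stats::plogis(1.5 * att$t_margin)) * scale)
}

#' Generate a synthetic cohort dataset on disk
#'
#' Distributes `n_images` over `n_patients` (every patient gets at least
#' one), draws one latent attribute vector and one label set per patient
#' (shared across that patient's images), renders each image with per-image
#' nuisance variation (centre jitter, rotation, fresh speckle), and writes
#' PNG images, per-image YOLO box files and the label CSV to `out_dir`.
#'
#' @param cohort a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @return the `dataset_manifest`, loadable with [load_manifest()].
#' @export
generate_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_pat <- cohort$n_patients; n_img <- cohort$n_images
  atts <- draw_patient_attributes(n_pat, seed = cohort$seed)
  labels <- sample_labels(atts, cohort, seed = cohort$seed + 1L)
  counts <- with_local_seed(cohort$seed + 2L, {
    cnt <- rep(1L, n_pat)
    extra <- n_img - n_pat
    if (extra > 0) {
      add <- table(sample.int(n_pat, extra, replace = TRUE))
      cnt[as.integer(names(add))] <- cnt[as.integer(names(add))] + as.integer(add)
    }
    cnt
  })
  sz <- cohort$image_size
  rows <- vector("list", n_img)
  k <- 0L
  base_rot <- with_local_seed(cohort$seed + 3L, stats::runif(n_pat, 0, 180))
  for (p in seq_len(n_pat)) {
    ph <- attributes_to_phantom(atts[p, ], sz)
    for (j in seq_len(counts[p])) {
      k <- k + 1L
      img_seed <- cohort$seed * 1000L + k
      # views of one patient share approximate probe orientation: a
      # patient-level base rotation with a small per-view jitter
      jit <- with_local_seed(img_seed, {
        list(center = sz / 2 + stats::runif(2, -0.05, 0.05) * sz,
             rotation = base_rot[p] + stats::runif(1, -10, 10))
      })
      # shrink extreme nodules so the irregular margin always fits the frame
      allowed <- sz / 2 - 2 * ph$edge_width - 4
      need <- max(ph$semi_axes) * (1 + ph$irregularity)
      if (need > allowed) ph$semi_axes <- ph$semi_axes * allowed / need
      reach <- max(ph$semi_axes) * (1 + ph$irregularity) + 2 * ph$edge_width + 3
      ctr <- pmin(pmax(jit$center, reach), sz - reach)
      sp <- phantom_spec(size = sz, center = ctr, semi_axes = ph$semi_axes,
                         rotation = jit$rotation,
                         echogenicity_drop = ph$echogenicity_drop,
                         irregularity = ph$irregularity,
                         edge_width = ph$edge_width,
                         seed = img_seed)
      r <- generate_phantom_image(sp)
      iid <- sprintf("img%04d", k)
      save_gray_image(r$image, file.path(out_dir, paste0(iid, ".png")))
      write_yolo_boxes(r$box, file.path(out_dir, paste0(iid, ".txt")))
      rows[[k]] <- data.frame(patient_id = sprintf("pat%04d", p),
                              image_id = iid,
                              ER = labels[p, "ER"], PR = labels[p, "PR"],
                              HER2 = labels[p, "HER2"], KI67 = labels[p, "KI67"],
                              stringsAsFactors = FALSE)
    }
  }
  lab <- do.call(rbind, rows)
  write_label_table(lab, file.path(out_dir, "labels.csv"))
  load_manifest(file.path(out_dir, "labels.csv"), out_dir)
}
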